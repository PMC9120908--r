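#' Length-weighted arm-level copy number from segments
#'
#' Aggregates a tumor copy-number segment table (PURPLE-style) to one copy
#' number per chromosome arm: the mean segment copy number weighted by the
#' length of each segment's intersection with the arm. Arms whose covered
#' fraction falls below `min_covered_frac` are reported `NA`.
#'
#' @param segments data frame with `chromosome`, `start`, `end` (0-based
#'   half-open) and `copy_number` (or `copyNumber`) columns.
#' @param arm_table an `arm_table`.
#' @param min_covered_frac minimum fraction of the arm covered by segments
#'   for the arm-level value to be reported (default 0.5).
#' @return Named numeric vector of arm copy numbers over included arms.
#' @export
arm_copy_number <- function(segments, arm_table, min_covered_frac = 0.5) {
  stopifnot(inherits(arm_table, "arm_table"))
  if ("copyNumber" %in% names(segments) && !"copy_number" %in% names(segments))
    segments$copy_number <- segments$copyNumber
  stopifnot(all(c("chromosome", "start", "end", "copy_number")
                %in% names(segments)))
  segments$chromosome <- strip_chr(segments$chromosome)
  if (any(segments$end <= segments$start))
    stop("segment with end <= start", call. = FALSE)
  if (any(segments$copy_number < 0))
    stop("negative copy number", call. = FALSE)
  # overlapping segments on one chromosome are a data error
  for (ch in unique(segments$chromosome)) {
    sub <- segments[segments$chromosome == ch, ]
    sub <- sub[order(sub$start), ]
    bad <- which(sub$start[-1] < sub$end[-nrow(sub)])
    if (length(bad))
      stop("overlapping segments on chromosome ", ch, ": [",
           sub$start[bad[1]], ",", sub$end[bad[1]], ") and [",
           sub$start[bad[1] + 1], ",", sub$end[bad[1] + 1], ")",
           call. = FALSE)
  }
  arms <- arm_table[arm_table$included, ]
  out <- stats::setNames(rep(NA_real_, nrow(arms)), arms$arm_id)
  for (i in seq_len(nrow(arms))) {
    sub <- segments[segments$chromosome == arms$chrom[i], ]
    if (nrow(sub) == 0) next
    ov <- pmin(sub$end, arms$end[i]) - pmax(sub$start, arms$start[i])
    keep <- ov > 0
    if (!any(keep)) next
    covered <- sum(ov[keep])
    if (covered / (arms$end[i] - arms$start[i]) < min_covered_frac) next
    out[i] <- sum(ov[keep] * sub$copy_number[keep]) / covered
  }
  out
}

#' Log2 deviation of arm copy number from the diploid expectation
#'
#' d_a = log2(CN_a / expected_cn), with copy numbers floored (default 0.1)
#' so homozygous deletions do not map to -Inf.
#'
#' @param cn named numeric vector of arm copy numbers (NA allowed).
#' @param expected_cn expected normal copy number, 2 for autosomes.
#' @param floor lower bound applied to CN before the log.
#' @return An `arm_cn_profile`: named vector of log2 deviations.
#' @export
log2_deviation <- function(cn, expected_cn = 2, floor = 0.1) {
  if (expected_cn <= 0) stop("expected_cn must be positive", call. = FALSE)
  stopifnot(all(cn >= 0, na.rm = TRUE), floor > 0)
  d <- log2(pmax(cn, floor) / expected_cn)
  structure(d, class = "arm_cn_profile")
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average ranks. The p-value uses the
#' exact permutation null distribution when n <= 10 and there are no ties,
#' and the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#' Pairs with a missing value on either side are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, got ", n, call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector: Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)          # average ranks on ties
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  p <- if (n <= 10 && !ties) {
    suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                     exact = TRUE)$p.value)
  } else {
    r <- min(max(rho, -1 + 1e-15), 1 - 1e-15)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Tissue-plasma copy-number concordance for one patient
#'
#' Spearman correlation between the arm-level tissue log2 copy-number
#' deviations and the plasma per-arm Z-scores, over the arms defined on
#' both sides.
#'
#' @param tissue an `arm_cn_profile` (named log2 deviations) or named
#'   numeric vector.
#' @param plasma_z named numeric vector of plasma arm Z-scores.
#' @param min_arms minimum number of shared arms (default 10).
#' @return list with `rho`, `p`, `n_arms`.
#' @export
patient_concordance <- function(tissue, plasma_z, min_arms = 10) {
  shared <- intersect(names(tissue)[is.finite(unclass(tissue))],
                      names(plasma_z)[is.finite(plasma_z)])
  if (length(shared) < min_arms)
    stop("only ", length(shared), " shared arms; need at least ", min_arms,
         call. = FALSE)
  sp <- spearman_cor(unclass(tissue)[shared], plasma_z[shared])
  list(rho = sp$rho, p = sp$p, n_arms = sp$n)
}

#' Read a PURPLE-style copy-number segment table
#'
#' TSV with `chromosome`, `start`, `end`, `copyNumber` columns; 1-based
#' inclusive input coordinates are converted to 0-based half-open.
#'
#' @param path file path.
#' @param one_based input coordinates are 1-based inclusive (default TRUE).
#' @return Data frame of segments with 0-based half-open coordinates.
#' @export
read_segments <- function(path, one_based = TRUE) {
  df <- read_tsv_strict(path)
  if ("copyNumber" %in% names(df)) df$copy_number <- df$copyNumber
  stopifnot(all(c("chromosome", "start", "end", "copy_number") %in% names(df)))
  if (one_based) df$start <- df$start - 1
  df
}
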