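#' Normalize arm counts to arm fractions
#'
#' Per-arm read counts are normalized to fractions of the total retained
#' count over scoring (included) arms, making all downstream statistics
#' invariant to sequencing depth.
#'
#' @param v an `arm_counts` object.
#' @param arm_table the `arm_table` the counts were binned against.
#' @return A `normalized_profile`: sample id plus a named fraction vector
#'   over included arms summing to 1.
#' @export
normalize_counts <- function(v, arm_table) {
  stopifnot(inherits(v, "arm_counts"), inherits(arm_table, "arm_table"))
  if (v$total_retained == 0)
    stop("cannot normalize: zero retained reads", call. = FALSE)
  wanted <- arm_table$arm_id[arm_table$included]
  if (!all(wanted %in% names(v$counts)))
    stop("counts lack included arm(s): ",
         paste(setdiff(wanted, names(v$counts)), collapse = ", "),
         call. = FALSE)
  counts <- v$counts[wanted]
  if (any(counts == 0))
    warning("zero-count included arm(s): ",
            paste(names(counts)[counts == 0], collapse = ", "),
            call. = FALSE)
  structure(list(sample_id = v$sample_id,
                 fractions = counts / sum(counts),
                 arm_set = paste(names(counts), collapse = ",")),
            class = "normalized_profile")
}

#' Build a healthy reference panel
#'
#' Computes the per-arm mean and standard deviation (sample SD, n-1
#' denominator: panels are small) of control arm fractions, plus the control
#' distribution (mean, SD) of the raw summed-square score needed for the
#' restandardized genome-wide score.
#'
#' Each control's raw score is computed leave-one-out by default: control i
#' is standardized against the panel rebuilt without it. This matches the
#' distribution of a fresh diploid sample, which is never part of the panel
#' it is scored against; scoring controls against a panel that includes them
#' shrinks their Z-scores and biases fresh-sample restandardized scores
#' upward by about one panel SD at n = 20.
#'
#' @param controls list of `normalized_profile` objects sharing one arm set.
#' @param min_n minimum number of controls (default 10).
#' @param leave_one_out compute control raw scores against the panel without
#'   the control itself (default TRUE).
#' @return A `reference_panel`.
#' @export
build_panel <- function(controls, min_n = 10, leave_one_out = TRUE) {
  stopifnot(is.list(controls), length(controls) >= 2)
  if (length(controls) < min_n)
    stop("panel needs at least ", min_n, " controls, got ", length(controls),
         call. = FALSE)
  arm_set <- controls[[1]]$arm_set
  if (!all(vapply(controls, function(p) identical(p$arm_set, arm_set), TRUE)))
    stop("controls do not share one arm set", call. = FALSE)
  X <- do.call(rbind, lapply(controls, `[[`, "fractions"))
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  if (any(sigma == 0))
    stop("zero standard deviation for arm(s): ",
         paste(colnames(X)[sigma == 0], collapse = ", "), call. = FALSE)
  n <- nrow(X)
  s_raw <- if (leave_one_out) {
    vapply(seq_len(n), function(i) {
      m <- colMeans(X[-i, , drop = FALSE])
      s <- apply(X[-i, , drop = FALSE], 2, stats::sd)
      if (any(s == 0))
        stop("zero leave-one-out SD for arm(s): ",
             paste(colnames(X)[s == 0], collapse = ", "), call. = FALSE)
      sum(((X[i, ] - m) / s)^2)
    }, numeric(1))
  } else {
    apply(X, 1, function(x) sum(((x - mu) / sigma)^2))
  }
  structure(list(n_controls = n, mu = mu, sigma = sigma,
                 s_mu = mean(s_raw), s_sigma = stats::sd(s_raw),
                 control_s_raw = s_raw,
                 leave_one_out = leave_one_out,
                 arm_set = arm_set),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel>", x$n_controls, "controls,",
      length(x$mu), "arms; control raw score",
      sprintf("%.2f +/- %.2f", x$s_mu, x$s_sigma), "\n")
  invisible(x)
}

#' Per-arm Z-scores against a reference panel
#'
#' z_a = (x_a - mu_a) / sigma_a for every scoring arm, where mu_a and
#' sigma_a are the panel mean and SD of the arm fraction.
#'
#' @param p a `normalized_profile`.
#' @param panel a `reference_panel` built on the same arm set.
#' @return Named numeric vector of Z-scores.
#' @export
arm_z_scores <- function(p, panel) {
  stopifnot(inherits(p, "normalized_profile"),
            inherits(panel, "reference_panel"))
  if (!identical(p$arm_set, panel$arm_set))
    stop("arm set of sample does not match the reference panel",
         call. = FALSE)
  (p$fractions - panel$mu) / panel$sigma
}

#' Genome-wide aneuploidy score
#'
#' The raw score is the sum of squared arm Z-scores,
#' `s_raw = sum(z_a^2)`. Two reporting modes are provided:
#' \describe{
#'   \item{restandardized (default)}{`(s_raw - s_mu) / s_sigma`, a second
#'     standardization against the control panel's own raw-score
#'     distribution. The raw sum over ~39 arms has null expectation near the
#'     number of arms, so only the restandardized score is coherent with the
#'     conventional high/low cutoff of 5 and with published per-patient
#'     scores below 1.}
#'   \item{sum_sq}{the literal raw sum, exported so the two conventions can
#'     be compared.}
#' }
#'
#' @param z named vector of arm Z-scores covering the panel's arm set.
#' @param panel the `reference_panel` (supplies `s_mu`, `s_sigma`).
#' @param mode "restandardized" or "sum_sq".
#' @return list with `s_raw`, `score`, `mode`.
#' @export
genome_wide_score <- function(z, panel,
                              mode = c("restandardized", "sum_sq")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(z), all(is.finite(z)))
  s_raw <- sum(z^2)
  score <- if (mode == "sum_sq") s_raw else {
    if (!is.finite(panel$s_sigma) || panel$s_sigma <= 0)
      stop("restandardized mode needs a positive control-score SD",
           call. = FALSE)
    (s_raw - panel$s_mu) / panel$s_sigma
  }
  list(s_raw = s_raw, score = score, mode = mode)
}

#' Classify a genome-wide aneuploidy score
#'
#' @param score numeric score(s).
#' @param cutoff high/low threshold; scores `>= cutoff` are "high"
#'   (boundary inclusive), default 5.
#' @return character vector, "high" or "low".
#' @export
classify_score <- function(score, cutoff = 5) {
  if (any(is.na(score))) stop("score is NA/NaN", call. = FALSE)
  stopifnot(all(is.finite(score)))
  ifelse(score >= cutoff, "high", "low")
}

#' Score one sample end-to-end
#'
#' Convenience wrapper: normalize counts, compute arm Z-scores, the
#' genome-wide score and the high/low call.
#'
#' @inheritParams normalize_counts
#' @inheritParams genome_wide_score
#' @inheritParams classify_score
#' @return An `aneuploidy_result`: sample id, per-arm `z`, `s_raw`, `score`,
#'   `mode`, `call`, `cutoff`.
#' @export
score_sample <- function(v, panel, arm_table,
                         mode = c("restandardized", "sum_sq"), cutoff = 5) {
  mode <- match.arg(mode)
  p <- normalize_counts(v, arm_table)
  z <- arm_z_scores(p, panel)
  gs <- genome_wide_score(z, panel, mode)
  structure(list(sample_id = v$sample_id, z = z, s_raw = gs$s_raw,
                 score = gs$score, mode = mode,
                 call = classify_score(gs$score, cutoff), cutoff = cutoff),
            class = "aneuploidy_result")
}

#' @export
print.aneuploidy_result <- function(x, ...) {
  cat(sprintf("<aneuploidy_result> %s: score %.3f (%s, raw %.2f) -> %s\n",
              x$sample_id, x$score, x$mode, x$s_raw, x$call))
  invisible(x)
}

#' Read / write a reference panel file
#'
#' The panel is stored as TSV (`arm`, `mu`, `sigma`) preceded by one
#' JSON header line (prefixed `#`) carrying `n_controls`, `s_mu`, `s_sigma`
#' and the arm-set id.
#'
#' @param panel a `reference_panel`.
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  hdr <- jsonlite::toJSON(list(n_controls = panel$n_controls,
                               s_mu = panel$s_mu, s_sigma = panel$s_sigma,
                               leave_one_out = panel$leave_one_out,
                               arm_set = panel$arm_set),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(data.frame(arm = names(panel$mu), mu = panel$mu,
                                sigma = panel$sigma),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#"))
    stop("panel file lacks JSON header line", call. = FALSE)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(n_controls = hdr$n_controls,
                 mu = stats::setNames(df$mu, df$arm),
                 sigma = stats::setNames(df$sigma, df$arm),
                 s_mu = hdr$s_mu, s_sigma = hdr$s_sigma,
                 control_s_raw = NULL,
                 leave_one_out = hdr$leave_one_out,
                 arm_set = hdr$arm_set),
            class = "reference_panel")
}
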