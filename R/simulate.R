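#' Baseline arm weights from arm lengths
#'
#' Expected arm read fractions for a diploid genome, proportional to the
#' lengths of the included arms. LINE-1 amplicons are treated as uniformly
#' dispersed; locus-specific density is not modeled.
#'
#' @param arm_table an `arm_table`.
#' @return Named weight vector summing to 1 over included arms.
#' @export
arm_weights <- function(arm_table) {
  stopifnot(inherits(arm_table, "arm_table"))
  a <- arm_table[arm_table$included, ]
  w <- stats::setNames(as.numeric(a$end - a$start), a$arm_id)
  w / sum(w)
}

#' Default aneuploid copy-number profile
#'
#' A per-arm tumor copy-number vector with eight altered arms typical of
#' urothelial cancer: gains (CN 3) of 1q, 5p, 8q and 20q and single-copy
#' losses (CN 1) of 8p, 9p, 9q and 10q; all other arms diploid.
#'
#' @param arm_table an `arm_table`.
#' @return Named numeric copy-number vector over included arms.
#' @export
uc_cn_profile <- function(arm_table) {
  a <- arm_table[arm_table$included, ]
  cn <- stats::setNames(rep(2, nrow(a)), a$arm_id)
  cn[intersect(c("1q", "5p", "8q", "20q"), names(cn))] <- 3
  cn[intersect(c("8p", "9p", "9q", "10q"), names(cn))] <- 1
  cn
}

#' Synthetic cfDNA mixture model
#'
#' Bundles the parameters of one simulated plasma sample: baseline arm
#' weights `w` (diploid expected fractions), per-arm tumor copy number
#' `cn`, and tumor fraction `f` (the share of cfDNA that is tumor-derived).
#'
#' @param w named baseline weight vector (positive, sums to 1).
#' @param cn named per-arm copy-number vector on the same arms.
#' @param f tumor fraction in `[0, 1]`.
#' @return A `tumor_model` list.
#' @export
tumor_model <- function(w, cn = NULL, f = 0) {
  stopifnot(all(w > 0), abs(sum(w) - 1) < 1e-8, f >= 0, f <= 1)
  if (is.null(cn)) cn <- stats::setNames(rep(2, length(w)), names(w))
  stopifnot(identical(names(w), names(cn)), all(cn >= 0))
  structure(list(w = w, cn = cn, f = f), class = "tumor_model")
}

#' Expected arm fractions of a cfDNA mixture
#'
#' At tumor fraction f, the expected read fraction of arm a is
#' `p_a = w_a ((1-f) + f CN_a / 2)`, renormalized to sum to 1: normal
#' cfDNA contributes two copies of every arm, tumor cfDNA contributes
#' `CN_a` copies.
#'
#' @param model a `tumor_model`.
#' @return Named fraction vector summing to 1.
#' @export
expected_mixture_fractions <- function(model) {
  stopifnot(inherits(model, "tumor_model"))
  p <- model$w * ((1 - model$f) + model$f * model$cn / 2)
  if (all(p == 0)) stop("all mixture weights are zero", call. = FALSE)
  p / sum(p)
}

# Dirichlet draw by inverse-CDF gamma sampling. Using qgamma on a common
# uniform stream couples draws across nearby parameter values (common
# random numbers), so samples simulated at increasing tumor fraction with
# the same seed shift smoothly rather than independently.
r_dirichlet_inv <- function(alpha) {
  u <- stats::runif(length(alpha))
  g <- stats::qgamma(u, shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Multinomial draw by sequential conditional binomials, also inverse-CDF.
r_multinom_inv <- function(n, p) {
  k <- length(p)
  out <- integer(k)
  rem_n <- n; rem_p <- 1
  for (i in seq_len(k - 1)) {
    if (rem_n == 0) break
    pr <- if (rem_p > 0) min(1, max(0, p[i] / rem_p)) else 0
    out[i] <- stats::qbinom(stats::runif(1), rem_n, pr)
    rem_n <- rem_n - out[i]
    rem_p <- rem_p - p[i]
  }
  out[k] <- rem_n
  stats::setNames(out, names(p))
}

# One Dirichlet-multinomial count vector around expected fractions p with
# precision `dispersion` (Inf = pure multinomial).
r_dirmult <- function(total_reads, p, dispersion) {
  q <- if (is.finite(dispersion)) r_dirichlet_inv(dispersion * p) else p
  r_multinom_inv(total_reads, stats::setNames(as.numeric(q), names(p)))
}

#' Simulate a healthy reference panel
#'
#' Draws `n` diploid control samples as Dirichlet-multinomial counts around
#' the baseline arm weights: biological/technical inter-individual
#' variation (the Dirichlet precision `dispersion`) on top of multinomial
#' read sampling. `dispersion = Inf` recovers a pure multinomial.
#'
#' @param n number of controls (>= 2).
#' @param w named baseline weight vector.
#' @param total_reads reads per sample (default 100,000, just above the
#'   assay's 90,000-read floor).
#' @param dispersion Dirichlet precision (default 5e5, ~0.9\% per-arm
#'   biological CV on top of the ~2\% multinomial sampling CV at 100k
#'   reads).
#' @param seed integer seed.
#' @return List of `arm_counts` objects.
#' @export
simulate_panel <- function(n, w, total_reads = 1e5, dispersion = 5e5,
                           seed = NULL) {
  stopifnot(n >= 2, total_reads >= 1)
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be positive and sum to 1", call. = FALSE)
  with_seed(seed, lapply(seq_len(n), function(i) {
    counts <- r_dirmult(total_reads, w, dispersion)
    structure(list(sample_id = sprintf("control_%02d", i), counts = counts,
                   total_retained = sum(counts), total_discarded = 0L,
                   arm_set = paste(names(w), collapse = ",")),
              class = "arm_counts")
  }))
}

#' Simulate one cfDNA sample at a given tumor fraction
#'
#' Counts are drawn (Dirichlet-multinomial) around the expected mixture
#' fractions of the model. With equal seeds, draws at different tumor
#' fractions are coupled through common random numbers.
#'
#' @param model a `tumor_model`.
#' @inheritParams simulate_panel
#' @param sample_id sample label.
#' @return An `arm_counts` object.
#' @export
simulate_cfdna_sample <- function(model, total_reads = 1e5,
                                  dispersion = 5e5, seed = NULL,
                                  sample_id = "cfdna_sample") {
  if (total_reads < 1) stop("total_reads must be >= 1", call. = FALSE)
  p <- expected_mixture_fractions(model)
  with_seed(seed, {
    counts <- r_dirmult(total_reads, p, dispersion)
    structure(list(sample_id = sample_id, counts = counts,
                   total_retained = sum(counts), total_discarded = 0L,
                   arm_set = paste(names(p), collapse = ",")),
              class = "arm_counts")
  })
}

#' Simulate a tumor copy-number segment table
#'
#' Emits each included arm as 1-3 abutting segments whose copy number is
#' the model's arm copy number plus Gaussian noise, truncated at 0. Output
#' matches what [arm_copy_number()] consumes.
#'
#' @param model a `tumor_model` (its `cn` field is the tumor profile; the
#'   clonal tissue profile is simulated, i.e. no dilution by `f`).
#' @param arm_table an `arm_table`.
#' @param noise SD of the per-segment copy-number noise.
#' @param seed integer seed.
#' @return Data frame of segments (`chromosome`, `start`, `end`,
#'   `copy_number`), 0-based half-open.
#' @export
simulate_segments <- function(model, arm_table, noise = 0.1, seed = NULL) {
  arms <- arm_table[arm_table$included, ]
  stopifnot(all(arms$arm_id %in% names(model$cn)))
  with_seed(seed, do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    n_seg <- sample.int(3, 1)
    cuts <- sort(c(arms$start[i], arms$end[i],
                   if (n_seg > 1)
                     round(stats::runif(n_seg - 1, arms$start[i],
                                        arms$end[i]))))
    cuts <- unique(cuts)
    cn0 <- model$cn[[arms$arm_id[i]]]
    data.frame(chromosome = arms$chrom[i],
               start = cuts[-length(cuts)], end = cuts[-1],
               copy_number = pmax(0, cn0 + stats::rnorm(length(cuts) - 1,
                                                        0, noise)))
  })))
}

#' Simulate plasma variant calls for one patient
#'
#' For clonal heterozygous variants, the expected plasma VAF is the tumor
#' fraction times the tissue VAF (at f = 1 plasma recovers tissue). Observed
#' VAFs add molecular sampling noise: molecular coverage is drawn
#' negative-binomially around `mean_coverage` (occasionally dipping below
#' the 100-read floor so the true-call rule is exercised) and variant reads
#' binomially at the expected VAF.
#'
#' @param model a `tumor_model` (only `f` is used).
#' @param n_variants number of variants.
#' @param tissue_vafs tissue VAFs in percent (drawn uniformly in 10-60 when
#'   NULL).
#' @param mean_coverage mean molecular coverage per amplicon.
#' @param lod per-amplicon limit of detection in percent.
#' @param subject subject label.
#' @param seed integer seed.
#' @return Data frame of variant calls with a `status` column.
#' @export
simulate_variants <- function(model, n_variants = 2, tissue_vafs = NULL,
                              mean_coverage = 2500, lod = 0.1,
                              subject = "S1", seed = NULL) {
  stopifnot(n_variants >= 1)
  with_seed(seed, {
    if (is.null(tissue_vafs))
      tissue_vafs <- stats::runif(n_variants, 10, 60)
    stopifnot(length(tissue_vafs) == n_variants)
    exp_vaf <- model$f * tissue_vafs            # percent
    cov <- stats::rnbinom(n_variants, size = 5, mu = mean_coverage) + 1L
    vr <- stats::rbinom(n_variants, cov, exp_vaf / 100)
    calls <- data.frame(subject = subject,
                        gene = sprintf("GENE%d", seq_len(n_variants)),
                        tissue_vaf = tissue_vafs,
                        plasma_vaf = 100 * vr / cov,
                        molecular_coverage = cov,
                        variant_reads = vr,
                        lod = lod)
    evaluate_variants(calls)
  })
}

#' Simulate a clinical cohort
#'
#' Generates patient records with the effect structure of the association
#' stage: a binary aneuploidy-score-high flag and a short
#' treatment-free-interval (TFI < 3 months) flag act on clinical benefit
#' through a logistic model with specified odds ratios; time on treatment
#' runs in 21-day cycles, stops earlier for non-responders, and is censored
#' administratively at `max_days`.
#'
#' @param n number of patients (>= 20; default 74).
#' @param or_score generating odds ratio of response for score-high
#'   (default 0.11).
#' @param or_tfi generating odds ratio of response for TFI < 3 months
#'   (default 0.12).
#' @param p_high probability of a high score (default 0.284).
#' @param p_tfi probability of TFI < 3 months (default 0.25).
#' @param intercept baseline log-odds of response for score-low, long-TFI
#'   patients (default 0: 50\% response).
#' @param mean_cycles_resp,mean_cycles_nonresp mean treatment cycles by
#'   response.
#' @param max_days administrative censoring time (default 735).
#' @param seed integer seed.
#' @return Data frame with `patient_id`, `score_high`, `tfi_short`,
#'   `response` (0/1), `time_on_treatment`, `event`.
#' @export
simulate_cohort <- function(n = 74, or_score = 0.11, or_tfi = 0.12,
                            p_high = 0.284, p_tfi = 0.25, intercept = 0,
                            mean_cycles_resp = 12, mean_cycles_nonresp = 2.5,
                            max_days = 735, seed = NULL) {
  stopifnot(n >= 20, or_score > 0, or_tfi > 0)
  with_seed(seed, {
    high <- stats::rbinom(n, 1, p_high)
    tfi <- stats::rbinom(n, 1, p_tfi)
    eta <- intercept + log(or_score) * high + log(or_tfi) * tfi
    resp <- stats::rbinom(n, 1, stats::plogis(eta))
    mean_cycles <- ifelse(resp == 1, mean_cycles_resp, mean_cycles_nonresp)
    cycles <- 1L + stats::rpois(n, pmax(mean_cycles - 1, 0))
    days <- pmin(21L * cycles, max_days)
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               score_high = high, tfi_short = tfi, response = resp,
               time_on_treatment = days,
               event = as.integer(days < max_days))
  })
}
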