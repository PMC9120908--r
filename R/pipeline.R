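# md5 of the packaged mutation-overview fixture; load_table1_fixture()
# refuses to return silently corrupted data.
TABLE1_MD5 <- "53eb961285e32d0feef6ac295c055483"

#' Packaged plasma mutation-overview fixture
#'
#' The published per-subject mutation overview shipped with the package:
#' 27 plasma variant measurements (22 evaluable, 5 failed assays) across 21
#' subjects, each with tissue VAF, plasma VAF (or "Failed") and the
#' subject's genome-wide aneuploidy score. The file checksum is verified on
#' load.
#'
#' @return list with `variants` (data frame with detection `status`) and
#'   `scores` (named per-subject aneuploidy score vector).
#' @examples
#' fx <- load_table1_fixture()
#' detection_rate(fx$variants)
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_plasma_mutations.tsv",
                      package = "mfastseqr", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), TABLE1_MD5))
    stop("packaged fixture checksum mismatch: ", path, call. = FALSE)
  df <- read_tsv_strict(path, colClasses = "character")
  df$subject <- as.character(df$subject)
  df$tissue_vaf <- as.numeric(df$tissue_vaf)
  df$aneuploidy_score <- as.numeric(df$aneuploidy_score)
  scores <- vapply(split(df$aneuploidy_score, df$subject), unique, numeric(1))
  scores <- scores[order(as.numeric(names(scores)))]
  list(variants = evaluate_variants(df), scores = scores)
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  if (is.null(config$stages) || length(config$stages) == 0)
    stop("config needs a non-empty stages list", call. = FALSE)
  known <- c("simulate_panel", "simulate_samples", "build_panel", "score",
             "variants", "table1")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  needs_sim <- any(c("simulate_panel", "simulate_samples") %in% config$stages)
  if (needs_sim && is.null(config$seed))
    stop("config needs a seed for simulation stages", call. = FALSE)
  for (f in c(config$counts_files, config$panel_file, config$variants_file))
    if (!is.null(f) && !file.exists(f))
      stop("input file not found: ", f, call. = FALSE)
  config
}

#' Run a configured multi-stage analysis
#'
#' Executes the requested stages in dependency order from a single config
#' (a list, or the path of a YAML file). Supported stages:
#' \describe{
#'   \item{simulate_panel}{draw healthy controls
#'     (`panel: {n, total_reads, dispersion}`).}
#'   \item{simulate_samples}{draw cfDNA samples at given tumor fractions
#'     (`samples: {tumor_fractions, total_reads, dispersion}`).}
#'   \item{build_panel}{build the reference panel from simulated controls
#'     or from `counts_files`, write `panel.tsv`.}
#'   \item{score}{score samples (simulated or `counts_files`) against the
#'     panel (`score: {mode, cutoff}`), write `scores.tsv`.}
#'   \item{variants}{detection summary of `variants_file` (or the packaged
#'     fixture), write `variant_summary.tsv`.}
#'   \item{table1}{classify the packaged fixture's per-subject scores at
#'     the configured cutoff, write `table1_calls.tsv`.}
#' }
#' A serialized copy of the config and a JSON run manifest (stage list,
#' outputs, config hash) are written next to the outputs. All randomness
#' flows through `config$seed`; a rerun with the same config produces
#' byte-identical outputs.
#'
#' @param config list or path to a YAML file.
#' @return Invisibly, a run report list (outputs per stage, config hash).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_yaml <- yaml::as.yaml(config)
  writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))
  cfg_hash <- unname(tools::md5sum(file.path(out_dir, "config.yaml")))

  arms <- arm_table_hg19(exclusions = config$arms$exclusions %||%
                           default_arm_exclusions())
  w <- arm_weights(arms)
  report <- list(config_hash = cfg_hash, stages = config$stages,
                 outputs = character(0))
  controls <- NULL; samples <- NULL; panel <- NULL
  seeds <- if (!is.null(config$seed)) derive_seeds(config$seed, 4)

  if ("simulate_panel" %in% config$stages) {
    pc <- config$panel %||% list()
    controls <- simulate_panel(pc$n %||% 20, w,
                               total_reads = pc$total_reads %||% 1e5,
                               dispersion = pc$dispersion %||% 5e5,
                               seed = seeds[1])
  }
  if ("simulate_samples" %in% config$stages) {
    sc <- config$samples %||% list()
    fs <- sc$tumor_fractions %||% 0.1
    sample_seeds <- derive_seeds(seeds[2], length(fs))
    samples <- lapply(seq_along(fs), function(i) {
      m <- tumor_model(w, uc_cn_profile(arms), f = fs[i])
      simulate_cfdna_sample(m, total_reads = sc$total_reads %||% 1e5,
                            dispersion = sc$dispersion %||% 5e5,
                            seed = sample_seeds[i],
                            sample_id = sprintf("sample_f%g", fs[i]))
    })
  }
  if ("build_panel" %in% config$stages) {
    if (is.null(controls) && !is.null(config$counts_files))
      controls <- lapply(config$counts_files, read_arm_counts, arm_table = arms)
    if (is.null(controls))
      stop("build_panel: no controls (simulate_panel or counts_files)",
           call. = FALSE)
    profs <- lapply(controls, normalize_counts, arm_table = arms)
    panel <- build_panel(profs, min_n = config$panel$min_n %||% 10)
    out <- file.path(out_dir, "panel.tsv")
    write_panel(panel, out)
    report$outputs <- c(report$outputs, out)
  }
  if ("score" %in% config$stages) {
    if (is.null(panel)) {
      if (is.null(config$panel_file))
        stop("score: no panel (build_panel stage or panel_file)",
             call. = FALSE)
      panel <- read_panel(config$panel_file)
    }
    if (is.null(samples) && !is.null(config$score$counts_files))
      samples <- lapply(config$score$counts_files, read_arm_counts,
                        arm_table = arms)
    if (is.null(samples))
      stop("score: no samples (simulate_samples stage or score$counts_files)",
           call. = FALSE)
    res <- lapply(samples, score_sample, panel = panel, arm_table = arms,
                  mode = config$score$mode %||% "restandardized",
                  cutoff = config$score$cutoff %||% 5)
    out <- file.path(out_dir, "scores.tsv")
    write_tsv(data.frame(
      sample_id = vapply(res, `[[`, "", "sample_id"),
      s_raw = vapply(res, `[[`, 0, "s_raw"),
      score = vapply(res, `[[`, 0, "score"),
      mode = vapply(res, `[[`, "", "mode"),
      call = vapply(res, `[[`, "", "call")), out)
    report$outputs <- c(report$outputs, out)
  }
  if ("variants" %in% config$stages) {
    calls <- if (!is.null(config$variants_file))
      read_variant_table(config$variants_file)
    else load_table1_fixture()$variants
    ds <- detection_rate(calls)
    out <- file.path(out_dir, "variant_summary.tsv")
    write_tsv(data.frame(n_total = ds$n_total, n_evaluable = ds$n_evaluable,
                         n_detected = ds$n_detected, rate = ds$rate), out)
    report$outputs <- c(report$outputs, out)
  }
  if ("table1" %in% config$stages) {
    fx <- load_table1_fixture()
    cutoff <- config$score$cutoff %||% 5
    out <- file.path(out_dir, "table1_calls.tsv")
    write_tsv(data.frame(subject = names(fx$scores), score = fx$scores,
                         call = classify_score(fx$scores, cutoff)), out)
    report$outputs <- c(report$outputs, out)
  }
  manifest <- list(config_hash = cfg_hash, stages = config$stages,
                   outputs = basename(report$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
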