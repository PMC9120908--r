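#' Plasma variant detection status
#'
#' Applies the true-call rule for plasma (cfDNA) variants: a variant is
#' `detected` when molecular coverage is at least 100 reads, at least 3 of
#' them support the variant, and the observed VAF is greater than or equal
#' to the per-amplicon limit of detection (LOD; the boundary passes).
#' Rows whose plasma assay failed are `failed`; evaluable rows with VAF 0
#' are `not_detected`; rows with a positive VAF that violate the
#' coverage/variant-read/LOD rule are `rejected`.
#'
#' Published mutation-overview tables often print only the plasma VAF (or
#' "Failed") without the underlying counts; when `molecular_coverage`,
#' `variant_reads` and `lod` columns are absent, status is derived from the
#' VAF alone (positive = detected, 0 = not detected).
#'
#' @param calls data frame of variant calls; must carry `plasma_vaf`
#'   (numeric, or the string "Failed"), optionally `molecular_coverage`,
#'   `variant_reads`, `lod` (all per row), and `subject`.
#' @return `calls` with an added `status` factor in
#'   \{detected, not_detected, failed, rejected\}.
#' @export
evaluate_variants <- function(calls) {
  stopifnot(is.data.frame(calls), "plasma_vaf" %in% names(calls))
  raw <- as.character(calls$plasma_vaf)
  failed <- tolower(trimws(raw)) == "failed"
  vaf <- suppressWarnings(as.numeric(raw))
  if (any(!failed & is.na(vaf)))
    stop("unparseable plasma VAF: ",
         paste(unique(raw[!failed & is.na(vaf)]), collapse = ", "),
         call. = FALSE)
  if (any(vaf < 0, na.rm = TRUE) || any(vaf > 100, na.rm = TRUE))
    stop("plasma VAF outside [0, 100]", call. = FALSE)

  has_counts <- all(c("molecular_coverage", "variant_reads", "lod")
                    %in% names(calls))
  status <- character(nrow(calls))
  status[failed] <- "failed"
  ev <- !failed
  if (has_counts) {
    cov <- calls$molecular_coverage
    vr <- calls$variant_reads
    lod <- calls$lod
    if (any(cov[ev] < 0, na.rm = TRUE) || any(vr[ev] < 0, na.rm = TRUE))
      stop("negative coverage or variant-read count", call. = FALSE)
    if (any(vr[ev] > cov[ev], na.rm = TRUE))
      stop("variant reads exceed molecular coverage", call. = FALSE)
    ok <- ev & cov >= 100 & vr >= 3 & vaf >= lod & vaf > 0
    status[ok] <- "detected"
    status[ev & !ok & vaf == 0] <- "not_detected"
    status[ev & !ok & vaf > 0] <- "rejected"
  } else {
    status[ev & vaf > 0] <- "detected"
    status[ev & vaf == 0] <- "not_detected"
  }
  calls$plasma_vaf_num <- ifelse(failed, NA_real_, vaf)
  calls$status <- factor(status, levels = c("detected", "not_detected",
                                            "failed", "rejected"))
  calls
}

#' Maximal plasma VAF per patient
#'
#' The maximum plasma VAF over a patient's evaluable (non-failed) variants;
#' zeros count (a patient whose variants were all assayed but undetected has
#' max VAF 0). Patients whose every variant failed get `NA` (undefined).
#' Rejected calls carry a measured VAF and are included.
#'
#' @param calls data frame as returned by [evaluate_variants()]; needs
#'   `subject`, `plasma_vaf_num`, `status`.
#' @return Named numeric vector, one entry per subject.
#' @export
max_vaf_per_patient <- function(calls) {
  if (!"status" %in% names(calls)) calls <- evaluate_variants(calls)
  out <- vapply(split(calls, as.character(calls$subject)), function(sub) {
    v <- sub$plasma_vaf_num[sub$status != "failed"]
    if (length(v) == 0) NA_real_ else max(v)
  }, numeric(1))
  out[order(suppressWarnings(as.numeric(names(out))), names(out))]
}

#' Cohort plasma detection summary
#'
#' Counts evaluable (non-failed) variant calls and those passing the
#' true-call rule, with the detection rate and per-patient maximal VAF.
#'
#' @inheritParams max_vaf_per_patient
#' @return A `detection_summary` list: `n_total`, `n_evaluable`,
#'   `n_detected`, `rate`, `per_patient_max_vaf`.
#' @export
detection_rate <- function(calls) {
  if (nrow(calls) == 0) stop("no variant calls", call. = FALSE)
  if (!"status" %in% names(calls)) calls <- evaluate_variants(calls)
  n_eval <- sum(calls$status != "failed")
  n_det <- sum(calls$status == "detected")
  if (n_eval == 0)
    warning("no evaluable calls: every plasma assay failed", call. = FALSE)
  structure(list(n_total = nrow(calls),
                 n_evaluable = n_eval,
                 n_detected = n_det,
                 rate = if (n_eval > 0) n_det / n_eval else NA_real_,
                 per_patient_max_vaf = max_vaf_per_patient(calls)),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf("<detection_summary> %d/%d evaluable variants detected (%.0f%%)\n",
              x$n_detected, x$n_evaluable, 100 * x$rate))
  invisible(x)
}

#' Read a plasma variant-call table
#'
#' TSV with at least `subject` and `plasma_vaf` columns (plus
#' `molecular_coverage`, `variant_reads`, `lod` for full-rule filtering).
#'
#' @param path file path.
#' @return Data frame with a `status` column.
#' @export
read_variant_table <- function(path) {
  evaluate_variants(read_tsv_strict(path, colClasses = NA))
}
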