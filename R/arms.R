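#' Chromosome-arm coordinate model
#'
#' An `arm_table` is a data frame with one row per chromosome arm and columns
#' `chrom`, `arm` ("p"/"q"), `arm_id` (e.g. "8q"), `start`, `end` (0-based
#' half-open) and `included` (whether the arm participates in scoring).
#' Rows are ordered deterministically: chromosomes in karyotype order, p
#' before q. The genome build tag is kept in `attr(x, "build")`.
#'
#' By default the 39 autosomal arms used for scoring exclude the acrocentric
#' p-arms (13p, 14p, 15p, 21p, 22p), which carry almost no uniquely mappable
#' sequence, and both sex chromosomes, which would confound a mixed-sex
#' reference panel.
#'
#' @param exclusions character vector of arm ids to flag `included = FALSE`.
#' @return An `arm_table` data frame.
#' @export
default_arm_exclusions <- function() {
  c("13p", "14p", "15p", "21p", "22p",
    "Xp", "Xq", "Yp", "Yq")
}

new_arm_table <- function(df, build) {
  df <- df[order(chrom_order(df$chrom), df$arm), , drop = FALSE]
  rownames(df) <- NULL
  stopifnot(all(df$start < df$end), !anyDuplicated(df$arm_id))
  # arms of one chromosome must not overlap and p must precede q
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) == 2) {
      p <- sub[sub$arm == "p", ]; q <- sub[sub$arm == "q", ]
      if (nrow(p) == 1 && nrow(q) == 1 && p$end > q$start)
        stop("arms of chromosome ", ch, " overlap", call. = FALSE)
    }
  }
  structure(df, build = build, class = c("arm_table", "data.frame"))
}

#' Load the packaged hg19 chromosome-arm table
#'
#' Arm boundaries are derived from the standard hg19 centromere (acen band)
#' coordinates: the p arm spans `[0, centromere_start)` and the q arm
#' `[centromere_end, chromosome_end)`.
#'
#' @inheritParams default_arm_exclusions
#' @return An `arm_table`.
#' @examples
#' arms <- arm_table_hg19()
#' sum(arms$included)  # 39 scoring arms
#' @export
arm_table_hg19 <- function(exclusions = default_arm_exclusions()) {
  path <- system.file("extdata", "hg19_arms.tsv", package = "mfastseqr",
                      mustWork = TRUE)
  df <- read_tsv_strict(path)
  df$arm_id <- paste0(df$chrom, df$arm)
  df$included <- !(df$arm_id %in% exclusions)
  new_arm_table(df[, c("chrom", "arm", "arm_id", "start", "end", "included")],
                build = "hg19")
}

#' Build an arm table from a UCSC cytoBand file
#'
#' Reads a cytoBand-style headerless TSV (chrom, start, end, band name,
#' Giemsa stain) and merges the bands on each side of the centromere (the
#' `acen` bands) into one interval per arm.
#'
#' @param cytoband_file path to a cytoBand TSV.
#' @param build genome-build tag stored on the result.
#' @param exclusions arm ids flagged `included = FALSE`.
#' @return An `arm_table`.
#' @export
load_arm_table <- function(cytoband_file, build = "hg19",
                           exclusions = default_arm_exclusions()) {
  if (!file.exists(cytoband_file))
    stop("file not found: ", cytoband_file, call. = FALSE)
  lines <- readLines(cytoband_file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    stop("empty cytoband file: ", cytoband_file, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5)
  if (length(bad))
    stop("malformed cytoband row at line ", bad[1], ": ", lines[bad[1]],
         call. = FALSE)
  bands <- data.frame(
    chrom = strip_chr(vapply(fields, `[[`, "", 1)),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2))),
    end   = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3))),
    band  = vapply(fields, `[[`, "", 4),
    stain = vapply(fields, `[[`, "", 5),
    stringsAsFactors = FALSE)
  if (anyNA(bands$start) || anyNA(bands$end)) {
    bad <- which(is.na(bands$start) | is.na(bands$end))[1]
    stop("malformed cytoband row at line ", bad, ": non-numeric coordinates",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(bands, bands$chrom), function(sub) {
    cen <- sub[sub$stain == "acen", ]
    if (nrow(cen) == 0)
      stop("chromosome ", sub$chrom[1], " has no centromeric (acen) band",
           call. = FALSE)
    data.frame(chrom = sub$chrom[1], arm = c("p", "q"),
               start = c(min(sub$start), max(cen$end)),
               end = c(min(cen$start), max(sub$end)),
               stringsAsFactors = FALSE)
  }))
  out$arm_id <- paste0(out$chrom, out$arm)
  out$included <- !(out$arm_id %in% exclusions)
  new_arm_table(out[, c("chrom", "arm", "arm_id", "start", "end", "included")],
                build = build)
}

new_arm_counts <- function(sample_id, counts, total_discarded, arm_table) {
  stopifnot(all(counts >= 0), all(names(counts) == arm_table$arm_id))
  total_retained <- sum(counts[arm_table$included])
  structure(list(sample_id = sample_id,
                 counts = counts,
                 total_retained = total_retained,
                 total_discarded = total_discarded,
                 arm_set = paste(arm_table$arm_id[arm_table$included],
                                 collapse = ",")),
            class = "arm_counts")
}

#' @export
print.arm_counts <- function(x, ...) {
  cat("<arm_counts> sample", x$sample_id, "-", x$total_retained,
      "retained,", x$total_discarded, "discarded\n")
  invisible(x)
}

# Assign 0-based positions on one chromosome to arm row indices (NA = no arm,
# e.g. centromeric). Arms within a chromosome are few, findInterval suffices.
assign_positions <- function(pos0, arms_sub) {
  idx <- rep(NA_integer_, length(pos0))
  for (i in seq_len(nrow(arms_sub))) {
    hit <- pos0 >= arms_sub$start[i] & pos0 < arms_sub$end[i]
    idx[hit] <- i
  }
  idx
}

#' Bin aligned reads into per-arm counts
#'
#' Each retained alignment is assigned to exactly one chromosome arm by its
#' leftmost mapped position. Unmapped records, secondary/supplementary
#' alignments (when `primary_only`), records below `min_mapq`, reads on
#' reference sequences absent from the arm table, and reads falling in the
#' centromeric gap or on excluded arms are all counted in `total_discarded`,
#' so that `total_retained + total_discarded` equals the number of input
#' records. Duplicates are kept: amplicon libraries are intentionally
#' duplicated.
#'
#' @param file path to a BAM or SAM file (SAM is converted on the fly).
#' @param arm_table an `arm_table`.
#' @param min_mapq minimum mapping quality; the default 1 drops multimappers,
#'   which are uninformative for arm assignment of LINE-1 amplicons.
#' @param primary_only drop secondary and supplementary alignments.
#' @param sample_id sample label; defaults to the file base name.
#' @return An `arm_counts` object.
#' @export
count_reads_by_arm <- function(file, arm_table, min_mapq = 1,
                               primary_only = TRUE, sample_id = NULL) {
  stopifnot(inherits(arm_table, "arm_table"))
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  sample_id <- sample_id %||% sub("\\.(b|s)am$", "", basename(file))
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  recs <- Rsamtools::scanBam(
    file, param = Rsamtools::ScanBamParam(what = c("rname", "pos", "mapq",
                                                   "flag")))[[1]]
  n_records <- length(recs$flag)
  if (n_records == 0) stop("empty sample: no alignment records", call. = FALSE)

  flag <- recs$flag
  keep <- !bitwAnd(flag, 4L)                       # mapped
  if (primary_only)
    keep <- keep & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  mapq <- recs$mapq
  mapq[is.na(mapq)] <- 0L
  keep <- keep & mapq >= min_mapq & !is.na(recs$pos)

  counts <- stats::setNames(integer(nrow(arm_table)), arm_table$arm_id)
  if (any(keep)) {
    rname <- strip_chr(recs$rname[keep])
    pos0 <- recs$pos[keep] - 1L                    # SAM is 1-based
    unknown <- !(rname %in% arm_table$chrom)
    if (any(unknown))
      warning(sum(unknown), " read(s) on reference sequences absent from ",
              "the arm table (e.g. ", rname[unknown][1], "); discarded",
              call. = FALSE)
    for (ch in unique(rname[!unknown])) {
      sel <- rname == ch
      sub <- arm_table[arm_table$chrom == ch, ]
      idx <- assign_positions(pos0[sel], sub)
      tab <- table(factor(sub$arm_id[idx[!is.na(idx)]], levels = sub$arm_id))
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  v <- new_arm_counts(sample_id, counts,
                      total_discarded = n_records -
                        sum(counts[arm_table$included]),
                      arm_table = arm_table)
  if (v$total_retained == 0) stop("empty sample: zero retained reads",
                                  call. = FALSE)
  v
}

#' Sample-level quality control on arm counts
#'
#' A sample fails when fewer than `min_reads` reads were retained on scoring
#' arms (default 90,000, the assay's sequencing floor). Included arms with
#' zero counts do not fail the sample but are flagged with a warning.
#'
#' @param v an `arm_counts` object.
#' @param arm_table the `arm_table` the counts were binned against.
#' @param min_reads minimum retained reads.
#' @return list with `pass`, `total_retained`, `zero_arms`.
#' @export
qc_sample <- function(v, arm_table, min_reads = 90000) {
  stopifnot(inherits(v, "arm_counts"), inherits(arm_table, "arm_table"))
  zero <- names(v$counts)[arm_table$included & v$counts == 0]
  if (length(zero))
    warning("included arm(s) with zero counts: ",
            paste(zero, collapse = ", "), call. = FALSE)
  list(pass = v$total_retained >= min_reads,
       total_retained = v$total_retained,
       min_reads = min_reads,
       zero_arms = zero)
}

#' Read / write per-arm count tables
#'
#' Counts are exchanged as TSV with columns `sample_id`, `arm`, `count`.
#'
#' @param v an `arm_counts` object.
#' @param path output path.
#' @export
write_arm_counts <- function(v, path) {
  write_tsv(data.frame(sample_id = v$sample_id, arm = names(v$counts),
                       count = as.integer(v$counts)), path)
}

#' @rdname write_arm_counts
#' @param arm_table arm table used to validate and order the counts.
#' @export
read_arm_counts <- function(path, arm_table) {
  df <- read_tsv_strict(path)
  stopifnot(all(c("sample_id", "arm", "count") %in% names(df)))
  missing <- setdiff(arm_table$arm_id, df$arm)
  if (length(missing))
    stop("count table lacks arm(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  counts <- stats::setNames(df$count[match(arm_table$arm_id, df$arm)],
                            arm_table$arm_id)
  new_arm_counts(df$sample_id[1], counts, total_discarded = 0L,
                 arm_table = arm_table)
}
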