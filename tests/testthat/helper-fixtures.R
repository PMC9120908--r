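# Shared in-code fixtures: a toy two-chromosome genome, cytoband and SAM
# writers, and independent brute-force oracles used against the package's
# own implementations.

# Toy genome: chr1 of 100 bp (p = [0,40), centromere [40,60), q = [60,100)),
# chr2 of 60 bp (p = [0,20), centromere [20,30), q = [30,60)).
toy_cytoband_lines <- function() {
  c("chr1\t0\t20\tp36\tgneg",
    "chr1\t20\t40\tp11\tgpos50",
    "chr1\t40\t50\tp11.1\tacen",
    "chr1\t50\t60\tq11.1\tacen",
    "chr1\t60\t100\tq44\tgneg",
    "chr2\t0\t10\tp12\tgneg",
    "chr2\t10\t20\tp11\tgneg",
    "chr2\t20\t25\tp11.1\tacen",
    "chr2\t25\t30\tq11.1\tacen",
    "chr2\t30\t60\tq21\tgneg")
}

toy_arm_table <- function(exclusions = character(0)) {
  f <- tempfile(fileext = ".txt")
  writeLines(toy_cytoband_lines(), f)
  on.exit(unlink(f))
  load_arm_table(f, build = "toy", exclusions = exclusions)
}

# Minimal SAM writer; reads are (rname, pos 1-based, mapq, flag).
write_toy_sam <- function(path, reads, seqs = c(chr1 = 100L, chr2 = 60L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), seqs))
  body <- sprintf("r%d\t%d\t%s\t%d\t%d\t5M\t*\t0\t0\tACGTA\t*",
                  seq_len(nrow(reads)), reads$flag, reads$rname,
                  reads$pos, reads$mapq)
  writeLines(c(hdr, body), path)
  path
}

# arm_counts from an explicit named count vector, via the TSV reader so only
# exported API is exercised.
counts_from_vector <- function(counts, arm_table, sample_id = "s1") {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  utils::write.table(data.frame(sample_id = sample_id, arm = names(counts),
                                count = as.integer(counts)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  read_arm_counts(f, arm_table)
}

profile_from_counts <- function(counts, arm_table, sample_id = "s1") {
  suppressWarnings(normalize_counts(
    counts_from_vector(counts, arm_table, sample_id), arm_table))
}

# Independent oracles ------------------------------------------------------

# Pearson correlation from the definitional sums (no stats::cor).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

oracle_spearman_rho <- function(x, y) oracle_pearson(rank(x), rank(y))

# Closed-form Pearson chi-square, sum (O-E)^2/E from first principles.
oracle_chisq <- function(t) {
  e <- outer(rowSums(t), colSums(t)) / sum(t)
  sum((t - e)^2 / e)
}

# Brute-force product-limit estimator at each distinct event time.
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    n_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}

# All permutations of a small vector (for exact Spearman p enumeration).
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# Standard simulated-analysis setup reused across tests.
sim_setup <- function(panel_n = 20, seed = 101) {
  arms <- arm_table_hg19()
  w <- arm_weights(arms)
  ctl <- simulate_panel(panel_n, w, seed = seed)
  panel <- build_panel(lapply(ctl, normalize_counts, arm_table = arms))
  list(arms = arms, w = w, panel = panel)
}
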