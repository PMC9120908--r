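#' @keywords internal
"_PACKAGE"

# Chromosome names are compared without the "chr" prefix throughout.
strip_chr <- function(x) sub("^chr", "", as.character(x))

# Deterministic chromosome order: 1..22, X, Y, then anything else lexically.
chrom_order <- function(x) {
  x <- strip_chr(x)
  canonical <- c(as.character(1:22), "X", "Y")
  idx <- match(x, canonical)
  idx[is.na(idx)] <- length(canonical) + rank(x[is.na(idx)], ties.method = "first")
  idx
}

# Run expr with a temporarily seeded RNG; restores the caller's RNG state so
# generators are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Child seeds derived from one master seed, kept inside 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
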