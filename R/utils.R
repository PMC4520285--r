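# Internal helpers shared across modules.  All genomic coordinates inside
# the package are 0-based half-open; BED is written natively, GFF3 is
# converted on I/O.

#' Derive a stream-specific seed from a master seed
#'
#' All stochastic operations take an explicit integer seed; stages derive
#' sub-seeds from it so that a single pipeline seed determines every file.
#' Kept below 2^31 - 1.
#' @param seed master integer seed
#' @param k stream index (>= 0)
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629L)
}

# run expr with a local RNG state so callers' streams are not disturbed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Gaussian kernel smoothing of a non-negative coverage vector.
# Returns a vector of the same length; kernel truncated at 4 sigma.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  hw <- ceiling(4 * sigma)
  k <- stats::dnorm(-hw:hw, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  padded <- c(rep(0, hw), x, rep(0, hw))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(hw + 1):(hw + n)])
}

# stopifnot with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

#' Read a BED file of read starts
#'
#' Reads a BED3/BED6 file and returns 0-based forward-read start positions.
#' Reverse-strand records are dropped (the pipeline's forward-only
#' convention: reverse reads dose the same nucleosome from the other
#' extremity).
#' @param path BED file path
#' @param contig optional contig filter
#' @return integer vector of 0-based start positions
#' @export
read_starts_bed <- function(path, contig = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(contig))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
  str <- as.character(GenomicRanges::strand(gr))
  gr <- gr[str %in% c("+", "*")]
  as.integer(GenomicRanges::start(gr) - 1L)
}

#' Write read starts as BED6
#'
#' @param starts integer vector of 0-based start positions
#' @param path output path
#' @param contig contig name
#' @param name record name (sample id)
#' @param read_length read length used for the end coordinate
#' @export
write_starts_bed <- function(starts, path, contig = "chrI",
                             name = "read", read_length = 50L) {
  starts <- sort(as.integer(starts))
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = starts + 1L, width = read_length),
    strand = "+")
  gr$name <- name
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# write a data.frame as TSV (the package's interchange format)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
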