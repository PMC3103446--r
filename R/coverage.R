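## Fragment coverage by blind extension.
##
## Every read is extended from its 5' end to the user-supplied shear size
## (the fragment length the chromatin was sheared to, typically 200-500 bp);
## the shear size is never estimated from the data. Coverage at a position is
## the number of extended fragments overlapping it.

#' Extend reads to fragment intervals
#'
#' Blind extension: a plus-strand read at `pos5` becomes
#' `[pos5, pos5 + ext_len)`; a minus-strand read (whose `pos5` is its
#' rightmost aligned base) becomes `[pos5 - ext_len + 1, pos5 + 1)`. The
#' interval is clipped to `[0, chrom_len)`; a fragment falling entirely
#' outside the chromosome yields an empty interval (`start == end`) and is
#' counted in the `n_outside` attribute.
#'
#' @param reads Read table (rows are vectorized).
#' @param ext_len Fragment/shear size in bp (>= 1). A value below the read
#'   length triggers a single warning.
#' @param chrom_len Chromosome length in bp.
#' @return `data.frame(start, end)` of clipped half-open intervals, with an
#'   `n_outside` attribute.
#' @export
extend_read <- function(reads, ext_len, chrom_len) {
  validate_reads(reads)
  if (!is_count(ext_len) || ext_len < 1) stop_fatal("ext_len must be >= 1")
  if (nrow(reads) && any(reads$read_len > ext_len))
    warning("ext_len (", ext_len, ") is smaller than some read lengths; ",
            "fragments will be shorter than the reads", call. = FALSE)
  a <- ifelse(reads$strand == "+", reads$pos5, reads$pos5 - ext_len + 1)
  b <- a + ext_len
  outside <- b <= 0 | a >= chrom_len
  ## clipping maps fully-outside fragments to empty intervals (start == end)
  a <- pmin(pmax(a, 0), chrom_len)
  b <- pmin(pmax(b, 0), chrom_len)
  structure(data.frame(start = as.numeric(a), end = as.numeric(b)),
            n_outside = sum(outside))
}

#' Build a per-chromosome fragment coverage profile
#'
#' Extends every read to `ext_len` (see [extend_read()]) and accumulates the
#' depth of overlapping fragments into one dense integer vector per
#' chromosome. The result is deterministic and independent of read order, and
#' conserves mass exactly: the profile sums to the total clipped fragment
#' extent.
#'
#' @param reads Read table.
#' @param ext_len Fragment/shear size in bp.
#' @param chrom_table A [derive_chrom_table()]/[load_chrom_table()] table.
#'   Reads on chromosomes absent from the table are dropped with a warning.
#' @param max_dup Optional cap on reads sharing an identical
#'   (chrom, pos5, strand); `Inf` (default) disables duplicate collapsing.
#' @return An object of class `coverage_profile`: a list with `cov` (named
#'   list of integer vectors), `frag_starts` (sorted 0-based clipped fragment
#'   start positions per chromosome, the counting anchors used by the region
#'   caller), `ext_len`, `n_fragments`, `n_dropped`, `n_outside`.
#' @export
build_coverage <- function(reads, ext_len, chrom_table, max_dup = Inf) {
  validate_reads(reads)
  stopifnot(inherits(chrom_table, "chrom_table"))
  if (!is_count(ext_len) || ext_len < 1) stop_fatal("ext_len must be >= 1")
  known <- reads$chrom %in% names(chrom_table)
  n_dropped <- sum(!known)
  if (n_dropped)
    warning(n_dropped, " read(s) on chromosomes absent from the table dropped",
            call. = FALSE)
  reads <- reads[known, , drop = FALSE]
  if (is.finite(max_dup) && nrow(reads)) {
    key <- paste(reads$chrom, reads$pos5, reads$strand)
    reads <- reads[stats::ave(seq_along(key), key, FUN = seq_along) <= max_dup,
                   , drop = FALSE]
  }
  cov <- vector("list", length(chrom_table))
  names(cov) <- names(chrom_table)
  frag_starts <- cov
  n_outside <- 0L
  n_fragments <- 0L
  for (chrom in names(chrom_table)) {
    len <- as.integer(chrom_table[[chrom]])
    sub <- reads[reads$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0L) {
      cov[[chrom]] <- integer(len)
      frag_starts[[chrom]] <- numeric(0)
      next
    }
    iv <- extend_read(sub, ext_len, len)
    n_outside <- n_outside + attr(iv, "n_outside")
    nonempty <- iv$end > iv$start
    n_fragments <- n_fragments + sum(nonempty)
    a <- iv$start[nonempty]
    b <- iv$end[nonempty]
    d <- tabulate(a + 1, nbins = len + 1L) - tabulate(b + 1, nbins = len + 1L)
    cov[[chrom]] <- as.integer(cumsum(d)[seq_len(len)])
    frag_starts[[chrom]] <- sort(a)
  }
  if (n_outside)
    warning(n_outside, " fragment(s) fell entirely outside their chromosome",
            call. = FALSE)
  structure(list(cov = cov, frag_starts = frag_starts, ext_len = ext_len,
                 chrom_table = chrom_table, n_fragments = n_fragments,
                 n_dropped = n_dropped, n_outside = n_outside),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile> ", length(x$cov), " chromosome(s), ",
      x$n_fragments, " fragments, ext_len=", x$ext_len, "\n", sep = "")
  invisible(x)
}

#' Genome-wide expected background depth
#'
#' The mean coverage depth per bp: total profile mass divided by total
#' chromosome length. Feeds the Poisson region threshold.
#'
#' @param profile A `coverage_profile`.
#' @return Expected depth per bp (lambda).
#' @export
genome_background_rate <- function(profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  total_len <- sum(vapply(profile$cov, length, 0L))
  if (total_len == 0) stop_fatal("zero-length genome")
  sum(vapply(profile$cov, function(v) sum(as.numeric(v)), 0)) / total_len
}
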