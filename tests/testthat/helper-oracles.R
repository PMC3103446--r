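## Independent brute-force oracles and fixture builders used across tests.

reads_df <- function(chrom, pos5, strand, read_len = 36L) {
  data.frame(chrom = chrom, pos5 = as.integer(pos5), strand = strand,
             read_len = as.integer(read_len), stringsAsFactors = FALSE)
}

## Exact Poisson upper tail by term-wise summation (independent of ppois).
oracle_poisson_tail <- function(h, lambda, kmax = 500L) {
  if (h < 1) return(1)
  k <- h:max(h, kmax)
  sum(exp(-lambda + k * log(lambda) - lgamma(k + 1)))
}

## Position-by-position candidate-region scan (independent of rle).
oracle_region_scan <- function(depth, h, max_gap) {
  n <- length(depth)
  regions <- list()
  i <- 1L
  while (i <= n) {
    if (depth[i] >= h) {
      start <- i
      last_above <- i
      j <- i + 1L
      while (j <= n) {
        if (depth[j] >= h) {
          last_above <- j
        } else {
          ## count below-threshold run ahead
          k <- j
          while (k <= n && depth[k] < h) k <- k + 1L
          gap <- k - j
          if (k > n || gap >= max_gap) break
          j <- k
          last_above <- k  # will be overwritten; k is above threshold
          next
        }
        j <- j + 1L
      }
      regions[[length(regions) + 1L]] <-
        c(start - 1L, last_above, max(depth[start:last_above]))
      i <- last_above + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(regions))
    return(data.frame(start = numeric(), end = numeric(),
                      max_height = numeric()))
  m <- do.call(rbind, regions)
  data.frame(start = as.numeric(m[, 1]), end = as.numeric(m[, 2]),
             max_height = as.numeric(m[, 3]))
}

## Quadratic-time Benjamini-Hochberg reference.
oracle_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(vapply(js, function(j) m * p[j] / sum(p <= p[j]), 0), 1)
  }, 0)
}

## Brute-force checks of the alternator contract on one segment.
## (a) a sub-cutoff position separates consecutive summits;
## (b) each summit is the leftmost maximum between its flanking valleys
##     (valley = leftmost minimum of the inter-summit stretch);
## (c) emitted indices strictly increase.
check_alternator_properties <- function(seg, delta, idx) {
  n <- length(seg)
  if (length(idx) == 0L) return(TRUE)
  if (is.unsorted(idx, strictly = TRUE)) return(FALSE)
  valleys <- integer(0)
  if (length(idx) > 1L) {
    for (k in seq_len(length(idx) - 1L)) {
      gap <- (idx[k] + 1L):(idx[k + 1L] - 1L)
      if (!any(seg[gap] < delta * seg[idx[k]])) return(FALSE)  # (a)
      valleys <- c(valleys, gap[which.min(seg[gap])])
    }
  }
  bounds <- c(1L, valleys, n)
  for (k in seq_along(idx)) {
    stretch <- bounds[k]:bounds[k + 1L]
    if (stretch[which.max(seg[stretch])] != idx[k]) return(FALSE)  # (b)
  }
  TRUE
}

## Re-parse a variableStep wiggle into per-chromosome sparse coverage.
parse_wiggle_lines <- function(lines) {
  out <- list()
  chrom <- NULL
  for (line in lines) {
    if (startsWith(line, "variableStep")) {
      chrom <- sub('.*chrom=([^ ]+).*', "\\1", line)
      out[[chrom]] <- data.frame(pos = integer(), value = numeric())
    } else {
      f <- strsplit(line, " ", fixed = TRUE)[[1]]
      out[[chrom]] <- rbind(out[[chrom]],
                            data.frame(pos = as.integer(f[1]),
                                       value = as.numeric(f[2])))
    }
  }
  out
}

## Minimal SAM writer for fixtures.
write_sam_fixture <- function(path, sq, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  writeLines(c(hdr, records), path)
  invisible(path)
}

sam_record <- function(qname, flag, rname, pos1, cigar, seq = NULL) {
  n <- if (is.null(seq)) sum(as.integer(
    regmatches(cigar, gregexpr("[0-9]+(?=[MIS=X])", cigar, perl = TRUE))[[1]]))
  else nchar(seq)
  if (is.null(seq)) seq <- paste(rep("A", n), collapse = "")
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s", qname, flag, rname,
          pos1, cigar, seq, paste(rep("I", nchar(seq)), collapse = ""))
}

## Evenly spaced single-peak dataset with known truth (specificity geometry).
make_spiked_dataset <- function(seed, n_peaks = 100L, chrom_len = 1e7,
                                n_bg = 20000L, n_frag = 100L,
                                ext_len = 200L, read_len = 36L) {
  seeds <- rangercall:::derive_seeds(seed, 2L)
  bg <- generate_background(chrom_len, n_bg, read_len, ext_len,
                            seed = seeds[1])
  margin <- 5 * ext_len
  centers <- round(seq(margin, chrom_len - margin, length.out = n_peaks))
  spikes <- rangercall:::with_seed(
    seeds[2],
    rangercall:::spike_fragments(centers, n_frag, ext_len, read_len, "chr1"))
  truth <- data.frame(chrom = "chr1", pos = centers,
                      pair_id = sprintf("site_%d", seq_len(n_peaks)),
                      n_fragments = n_frag, separation = NA_real_,
                      stringsAsFactors = FALSE)
  list(reads = rbind(bg, spikes), truth = truth)
}

empty_reads_for_test <- function() rangercall:::empty_reads()
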