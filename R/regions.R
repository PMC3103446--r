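## Enriched-region detection and significance.
##
## Broad candidate regions are maximal above-threshold runs of the treatment
## coverage profile (threshold = analytic Poisson tail on the genome-wide
## mean depth). Each region is then scored against the control with a
## two-sample binomial test (control counts rescaled to the treatment scale),
## or against a Poisson background model when no control is available, and
## the genome-wide p-value vector is put under Benjamini-Hochberg FDR
## control.

#' Poisson depth threshold for candidate regions
#'
#' The smallest integer depth `h >= 1` whose Poisson upper-tail probability
#' at background rate `lambda` falls below the per-bp tail probability `p0`:
#' `P(Poisson(lambda) >= h) < p0`.
#'
#' @param lambda Expected background depth per bp (>= 0).
#' @param p0 Per-bp tail probability, in (0, 1); default `1e-4`.
#' @return Integer threshold `h`.
#' @export
poisson_region_threshold <- function(lambda, p0 = 1e-4) {
  stopifnot(length(lambda) == 1L, lambda >= 0, p0 > 0, p0 < 1)
  h <- max(1L, as.integer(stats::qpois(p0, lambda, lower.tail = FALSE)))
  tail <- function(h) stats::ppois(h - 1, lambda, lower.tail = FALSE)
  while (tail(h) >= p0) h <- h + 1L
  while (h > 1L && tail(h - 1L) < p0) h <- h - 1L
  h
}

#' Detect contiguous above-threshold regions
#'
#' Maximal runs of positions with depth `>= h`; neighbouring runs separated
#' by fewer than `max_gap` below-threshold positions are merged, with the gap
#' positions included in the merged region.
#'
#' @param depth Integer coverage vector for one chromosome.
#' @param h Depth threshold (>= 1).
#' @param max_gap Merge gap in bp (>= 0; 0 disables merging).
#' @return `data.frame(start, end, max_height)` of disjoint sorted 0-based
#'   half-open regions.
#' @export
detect_candidate_regions <- function(depth, h, max_gap = 0) {
  stopifnot(h >= 1, max_gap >= 0)
  above <- depth >= h
  r <- rle(above)
  if (!any(r$values)) return(empty_regions())
  ## merge short interior gaps
  if (max_gap > 0 && length(r$lengths) > 2L) {
    interior <- !r$values & seq_along(r$values) > 1L &
      seq_along(r$values) < length(r$values)
    r$values[interior & r$lengths < max_gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  s <- starts[keep]
  e <- ends[keep]
  mh <- vapply(seq_along(s),
               function(i) max(depth[(s[i] + 1L):e[i]]), 0)
  data.frame(start = as.numeric(s), end = as.numeric(e),
             max_height = as.numeric(mh))
}

empty_regions <- function() {
  data.frame(start = numeric(), end = numeric(), max_height = numeric())
}

#' Fit the control-to-treatment scaling factor
#'
#' Zero-intercept least-squares slope of treatment bin counts on control bin
#' counts over background bins (bins overlapping candidate regions excluded),
#' giving the multiplier `r` that places control counts on the treatment
#' scale. When the regression is infeasible (fewer than 2 usable bins, zero
#' control variance, or a non-positive slope) the fit falls back to the
#' library-size ratio total-treatment / total-control.
#'
#' @param treat_bin_counts,ctrl_bin_counts Fragment counts per genomic bin.
#' @param excluded_bins Indices of bins overlapping candidate regions.
#' @return List with `r`, `method` (`"regression"` or `"library_ratio"`) and
#'   `n_bins_used`, class `scaling_fit`.
#' @export
fit_control_scaling <- function(treat_bin_counts, ctrl_bin_counts,
                                excluded_bins = integer()) {
  stopifnot(length(treat_bin_counts) == length(ctrl_bin_counts))
  use <- setdiff(seq_along(treat_bin_counts), excluded_bins)
  t_u <- treat_bin_counts[use]
  c_u <- ctrl_bin_counts[use]
  r <- NA_real_
  method <- "library_ratio"
  if (length(use) >= 2L && stats::var(c_u) > 0 && sum(c_u^2) > 0) {
    slope <- sum(t_u * c_u) / sum(c_u^2)
    if (is.finite(slope) && slope > 0) {
      r <- slope
      method <- "regression"
    }
  }
  if (method == "library_ratio") {
    tot_c <- sum(ctrl_bin_counts)
    if (tot_c > 0) {
      r <- sum(treat_bin_counts) / tot_c
    } else {
      warning("control has no fragments; scaling factor set to 1",
              call. = FALSE)
      r <- 1
    }
  }
  structure(list(r = r, method = method,
                 n_bins_used = if (method == "regression") length(use) else
                   length(treat_bin_counts)),
            class = "scaling_fit")
}

#' Binomial region p-value (treatment vs control)
#'
#' One-sided two-sample binomial test: given `k_t` treatment fragments and
#' `k_c` (scaled, rounded) control fragments in a region, under the null the
#' treatment draws are Binomial(k_t + k_c, 1/2);
#' `p = P(X >= k_t)`. `p = 1` when `k_t = 0`.
#'
#' @param treat_count Treatment fragment count(s) in the region.
#' @param ctrl_count_scaled Control fragment count(s) on the treatment scale
#'   (rounded to the nearest non-negative integer internally).
#' @return p-value(s), vectorized.
#' @export
region_pvalue_binomial <- function(treat_count, ctrl_count_scaled) {
  stopifnot(all(treat_count >= 0), all(ctrl_count_scaled >= 0))
  kc <- pmax(0, round(ctrl_count_scaled))
  p <- stats::pbinom(treat_count - 1, treat_count + kc, 0.5,
                     lower.tail = FALSE)
  p[treat_count == 0] <- 1
  p
}

#' Poisson region p-value (no-control mode)
#'
#' Under a uniform background of depth `lambda`, the expected number of
#' fragment starts in a region of length `region_len` is
#' `mu = lambda * region_len / ext_len`; `p = P(Poisson(mu) >= treat_count)`.
#'
#' @param treat_count Treatment fragment count(s) in the region.
#' @param lambda Background depth per bp.
#' @param region_len Region length(s) in bp.
#' @param ext_len Fragment length used to build the profile.
#' @return p-value(s), vectorized.
#' @export
region_pvalue_poisson <- function(treat_count, lambda, region_len, ext_len) {
  stopifnot(lambda >= 0)
  mu <- lambda * region_len / ext_len
  p <- stats::ppois(treat_count - 1, mu, lower.tail = FALSE)
  p[treat_count == 0] <- 1
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment, preserving input order; ties share a q-value.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @return q-values in the same order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) && (any(p_values < 0) || any(p_values > 1)))
    stop_fatal("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

## Fragment starts falling in [start, end), per region, from the sorted
## anchor vector of one chromosome.
count_starts_in <- function(sorted_starts, start, end) {
  findInterval(end - 1e-9, sorted_starts) -
    findInterval(start - 1e-9, sorted_starts)
}

## Fragment counts per fixed-width genomic bin and the set of bins touched
## by candidate regions; used by the scaling regression.
bin_layout <- function(chrom_table, bin_size) {
  n_bins <- stats::setNames(pmax(as.integer(ceiling(chrom_table / bin_size)), 1L),
                            names(chrom_table))
  offsets <- stats::setNames(cumsum(c(0L, n_bins[-length(n_bins)])),
                             names(chrom_table))
  list(n_bins = n_bins, offsets = offsets, total = sum(n_bins))
}

bin_counts <- function(profile, layout, bin_size) {
  counts <- integer(layout$total)
  for (chrom in names(profile$frag_starts)) {
    st <- profile$frag_starts[[chrom]]
    if (!length(st)) next
    idx <- layout$offsets[[chrom]] + pmin(floor(st / bin_size) + 1L,
                                          layout$n_bins[[chrom]])
    tab <- tabulate(idx, nbins = layout$total)
    counts <- counts + tab
  }
  counts
}

#' Call enriched regions genome-wide
#'
#' Thresholds the treatment profile at the Poisson depth threshold, merges
#' gapped runs, counts treatment (and scaled control) fragment starts per
#' region, assigns binomial (control) or Poisson (no control) p-values,
#' applies Benjamini-Hochberg FDR across all candidate regions genome-wide
#' and keeps regions with `q <= fdr_cutoff`.
#'
#' @param treat_profile Treatment `coverage_profile`.
#' @param ctrl_profile Optional control `coverage_profile` (same `ext_len`
#'   and chromosome table).
#' @param config A [caller_config()] list.
#' @param workers Parallel workers for per-chromosome region detection.
#' @return `data.frame` of surviving regions, sorted by (chrom, start), with
#'   columns `chrom`, `start`, `end`, `max_height`, `treat_count`,
#'   `ctrl_count_scaled`, `p_value`, `q_value`, `rank` (ascending p, ties by
#'   descending height then coordinate). Attributes: `threshold`, `lambda`,
#'   `scaling` and `n_candidates`.
#' @export
call_regions <- function(treat_profile, ctrl_profile = NULL,
                         config = caller_config(), workers = 1L) {
  stopifnot(inherits(treat_profile, "coverage_profile"))
  if (!is.null(ctrl_profile)) {
    stopifnot(inherits(ctrl_profile, "coverage_profile"))
    if (ctrl_profile$ext_len != treat_profile$ext_len)
      stop_fatal("treatment and control profiles use different ext_len")
  }
  lambda <- genome_background_rate(treat_profile)
  h <- poisson_region_threshold(lambda, config$thr_p)
  chroms <- names(treat_profile$cov)
  per_chrom <- run_parallel(chroms, function(chrom) {
    reg <- detect_candidate_regions(treat_profile$cov[[chrom]], h,
                                    config$max_gap)
    if (nrow(reg) == 0L) return(NULL)
    reg$chrom <- chrom
    reg$treat_count <- count_starts_in(treat_profile$frag_starts[[chrom]],
                                       reg$start, reg$end)
    if (!is.null(ctrl_profile))
      reg$ctrl_count <- count_starts_in(ctrl_profile$frag_starts[[chrom]],
                                        reg$start, reg$end)
    reg
  }, workers)
  regions <- do.call(rbind, per_chrom)
  scaling <- NULL
  if (is.null(regions) || nrow(regions) == 0L) {
    out <- cbind(data.frame(chrom = character()), empty_regions(),
                 data.frame(treat_count = numeric(),
                            ctrl_count_scaled = numeric(),
                            p_value = numeric(), q_value = numeric(),
                            rank = integer()))
  } else {
    if (!is.null(ctrl_profile)) {
      bin_size <- config$scaling_bin
      layout <- bin_layout(treat_profile$chrom_table, bin_size)
      tb <- bin_counts(treat_profile, layout, bin_size)
      cb <- bin_counts(ctrl_profile, layout, bin_size)
      excl <- unique(unlist(lapply(split(regions, regions$chrom),
        function(rg) {
          chrom <- rg$chrom[1L]
          lo <- floor(rg$start / bin_size)
          hi <- floor((rg$end - 1) / bin_size)
          layout$offsets[[chrom]] +
            unique(unlist(Map(seq, lo + 1L, hi + 1L)))
        })))
      scaling <- fit_control_scaling(tb, cb, excl)
      regions$ctrl_count_scaled <- regions$ctrl_count * scaling$r
      regions$p_value <- region_pvalue_binomial(regions$treat_count,
                                                regions$ctrl_count_scaled)
      regions$ctrl_count <- NULL
    } else {
      regions$ctrl_count_scaled <- NA_real_
      regions$p_value <- region_pvalue_poisson(
        regions$treat_count, lambda, regions$end - regions$start,
        treat_profile$ext_len)
    }
    regions$q_value <- bh_fdr(regions$p_value)
    regions$rank <- order(order(regions$p_value, -regions$max_height,
                                regions$chrom, regions$start))
    out <- regions[regions$q_value <= config$fdr_cutoff, , drop = FALSE]
    out <- out[order(out$chrom, out$start),
               c("chrom", "start", "end", "max_height", "treat_count",
                 "ctrl_count_scaled", "p_value", "q_value", "rank")]
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- h
  attr(out, "lambda") <- lambda
  attr(out, "scaling") <- scaling
  attr(out, "n_candidates") <- if (is.null(regions)) 0L else nrow(regions)
  out
}

## Chromosome-keyed parallel map with deterministic gather order.
run_parallel <- function(keys, fn, workers) {
  if (workers > 1L && .Platform$OS.type == "unix" && length(keys) > 1L) {
    res <- parallel::mclapply(keys, fn, mc.cores = workers,
                              mc.preschedule = TRUE)
    err <- vapply(res, inherits, TRUE, what = "try-error")
    if (any(vapply(res, inherits, TRUE, what = "condition")) || any(err))
      stop_fatal("parallel worker failed")
    res
  } else {
    lapply(keys, fn)
  }
}
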