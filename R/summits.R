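## Summit detection inside enriched regions.
##
## The region segment is lightly smoothed, then scanned left to right by the
## summit-valley-alternator: while seeking a summit the running maximum M is
## tracked and the summit (the leftmost position of M) is emitted as soon as
## the signal drops below delta * M; the scan then seeks a valley, tracking
## the running minimum m, and re-arms for the next summit once the signal
## rises above m / delta. Larger delta splits shallower valleys. Two
## post-filters follow: summits separated only by zero raw coverage collapse
## to the higher one, and summits far below the region's top summit can be
## dropped (comparable-heights filter).

#' Centered moving-average smoothing
#'
#' At the segment boundaries the window shrinks to the available positions
#' and the divisor is the actual count (no zero padding). `window = 1` is the
#' identity.
#'
#' @param segment Numeric vector of depths.
#' @param window Odd window width in bp (>= 1).
#' @return Smoothed vector, same length.
#' @export
smooth_profile <- function(segment, window) {
  if (!is_count(window) || window < 1 || window %% 2 == 0)
    stop_fatal("smoothing window must be an odd integer >= 1")
  n <- length(segment)
  if (window == 1L || n == 0L) return(as.numeric(segment))
  k <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, as.numeric(segment)))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Summit-valley-alternator scan
#'
#' Two-state left-to-right scan over a region segment (see the module
#' description above). Plateau ties keep the leftmost maximum. A scan ending
#' in summit-seek emits its pending maximum; one ending in valley-seek emits
#' nothing further.
#'
#' @param segment Numeric vector of (smoothed) depths, length >= 1.
#' @param delta Sensitivity factor, strictly inside (0, 1).
#' @return Strictly increasing 1-based summit indices, segment-relative.
#' @export
summit_valley_alternator <- function(segment, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta <= 0 || delta >= 1)
    stop_fatal("delta must lie strictly inside (0, 1)")
  n <- length(segment)
  if (n == 0L) stop_fatal("segment must have length >= 1")
  out <- integer(n)
  k <- 0L
  seeking_summit <- TRUE
  M <- segment[1L]
  iM <- 1L
  m <- 0
  if (n > 1L) for (i in 2:n) {
    v <- segment[i]
    if (seeking_summit) {
      if (v > M) {
        M <- v
        iM <- i
      } else if (v < delta * M) {
        k <- k + 1L
        out[k] <- iM
        seeking_summit <- FALSE
        m <- v
      }
    } else {
      if (v < m) {
        m <- v
      } else if (v > m / delta) {
        seeking_summit <- TRUE
        M <- v
        iM <- i
      }
    }
  }
  if (seeking_summit) {
    k <- k + 1L
    out[k] <- iM
  }
  out[seq_len(k)]
}

#' Suppress summits split only by zero coverage
#'
#' For each consecutive summit pair whose intervening positions contain at
#' least one zero-depth position on the raw (unsmoothed) track, the lower
#' summit is removed (on a height tie, the right one); this is applied
#' iteratively until stable. It prevents a sparsely covered event from being
#' reported as several summits.
#'
#' @param summits `data.frame(idx, height)` with 1-based segment-relative
#'   indices sorted increasingly.
#' @param segment Raw (unsmoothed) depth vector of the region.
#' @return The filtered summit `data.frame`.
#' @export
suppress_zero_gap_summits <- function(summits, segment) {
  if (is.null(summits) || nrow(summits) < 2L) return(summits)
  zeros <- which(segment == 0)
  if (!length(zeros)) return(summits)
  repeat {
    if (nrow(summits) < 2L) break
    i_lo <- summits$idx[-nrow(summits)]
    i_hi <- summits$idx[-1L]
    ## zero strictly between the pair?
    has_zero <- findInterval(i_hi - 1L, zeros) - findInterval(i_lo, zeros) > 0L
    j <- which(has_zero)[1L]
    if (is.na(j)) break
    drop <- if (summits$height[j] < summits$height[j + 1L]) j else j + 1L
    summits <- summits[-drop, , drop = FALSE]
  }
  rownames(summits) <- NULL
  summits
}

#' Comparable-heights summit filter
#'
#' Removes summits whose height falls below `min_rel_height` times the
#' highest summit of the region; `min_rel_height = 0` disables the filter,
#' `1` keeps only the maximal summit(s). Used when downstream analysis needs
#' summits of comparable heights (e.g. counting twin peaks per region).
#'
#' @param summits `data.frame(idx, height)` (or any frame with a `height`
#'   column).
#' @param min_rel_height Fraction of the maximum height in \[0, 1\].
#' @return The filtered summit `data.frame`.
#' @export
filter_relative_height <- function(summits, min_rel_height) {
  stopifnot(min_rel_height >= 0, min_rel_height <= 1)
  if (is.null(summits) || nrow(summits) == 0L || min_rel_height == 0)
    return(summits)
  keep <- summits$height >= min_rel_height * max(summits$height)
  out <- summits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call summits inside one enriched region
#'
#' Pipeline: slice the raw treatment profile over `[start, end)`, smooth it,
#' run the alternator, take heights from the smoothed track, suppress
#' zero-gap summits (zero test on the raw track), apply the
#' comparable-heights filter, and map surviving indices to absolute 0-based
#' chromosome coordinates. Every region is guaranteed at least one summit: if
#' all are filtered away, the leftmost global maximum of the smoothed segment
#' is reinstated.
#'
#' @param region One-row region record with `start` and `end` (0-based
#'   half-open).
#' @param profile Raw (unsmoothed) treatment coverage vector for the region's
#'   chromosome.
#' @param config List with `delta`, `smooth_window`, `min_rel_height` (see
#'   [caller_config()]).
#' @return `data.frame(pos, height)`: absolute 0-based summit positions and
#'   smoothed-track heights.
#' @export
call_summits <- function(region, profile, config) {
  seg <- as.numeric(profile[(region$start + 1L):region$end])
  sm <- smooth_profile(seg, config$smooth_window)
  idx <- summit_valley_alternator(sm, config$delta)
  summits <- data.frame(idx = idx, height = sm[idx])
  summits <- suppress_zero_gap_summits(summits, seg)
  summits <- filter_relative_height(summits, config$min_rel_height)
  if (nrow(summits) == 0L) {
    iM <- which.max(sm)
    summits <- data.frame(idx = iM, height = sm[iM])
  }
  data.frame(pos = region$start + summits$idx - 1L, height = summits$height)
}
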