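## Semi-synthetic spike-in benchmarks with known truth.
##
## A uniform background of fragments emulates a no-antibody control lane;
## point-source binding events are spiked in as clusters of fragments that
## all cover a known center, singly (specificity benchmark) or in pairs at
## fixed separations (inter-peak resolution benchmark, 13 datasets spanning
## 200-500 bp). The evaluation metrics are recall, the unmatched-call
## fraction (false-positive rate), summit spatial error, and for pairs the
## fraction resolved into two distinct matched summits.

## Fragments -> sequenced reads: the read is the 5'-most read_len bases of
## the fragment on its strand.
fragments_to_reads <- function(starts, strand, ext_len, read_len, chrom) {
  pos5 <- ifelse(strand == "+", starts, starts + ext_len - 1L)
  data.frame(chrom = rep_len(chrom, length(starts)),
             pos5 = as.integer(pos5), strand = strand,
             read_len = rep_len(as.integer(read_len), length(starts)),
             stringsAsFactors = FALSE)
}

#' Generate uniform background reads
#'
#' Fragment starts are uniform over the positions where the whole fragment
#' fits on the chromosome (equivalent to re-drawing any clipped draw);
#' strands are fair coin flips. Deterministic given `seed`.
#'
#' @param chrom_len Chromosome length in bp (must be >= `ext_len`).
#' @param n_reads Number of reads.
#' @param read_len Read length in bp (default 36).
#' @param ext_len Fragment length in bp (default 200).
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @return Read table; attribute `truth` is an empty truth table.
#' @export
generate_background <- function(chrom_len, n_reads, read_len = 36L,
                                ext_len = 200L, seed = 1L, chrom = "chr1") {
  if (chrom_len < ext_len)
    stop_fatal("chromosome shorter than the fragment length")
  stopifnot(n_reads >= 0)
  reads <- with_seed(seed, {
    starts <- sample.int(chrom_len - ext_len + 1L, n_reads,
                         replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    fragments_to_reads(starts, strand, ext_len, read_len, chrom)
  })
  attr(reads, "truth") <- empty_truth()
  reads
}

empty_truth <- function() {
  data.frame(chrom = character(), pos = numeric(), pair_id = character(),
             n_fragments = numeric(), separation = numeric(),
             stringsAsFactors = FALSE)
}

#' Spike a point-source binding peak
#'
#' Each fragment start is uniform over `(center - ext_len, center]`, so every
#' fragment covers the center and the raw fragment coverage at the center
#' equals `n_fragments` exactly; the emitted read is the 5'-most `read_len`
#' bases of the fragment on its (fair-coin) strand.
#'
#' @param center 0-based peak center; must satisfy
#'   `ext_len <= center <= chrom_len - ext_len`.
#' @param n_fragments Fragments in the peak.
#' @param ext_len,read_len Fragment and read length in bp.
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @param chrom_len Chromosome length in bp.
#' @return Read table.
#' @export
spike_peak <- function(center, n_fragments, ext_len = 200L, read_len = 36L,
                       seed = 1L, chrom = "chr1", chrom_len) {
  if (center < ext_len || center > chrom_len - ext_len)
    stop_fatal("peak center must lie in [ext_len, chrom_len - ext_len]")
  with_seed(seed, spike_fragments(center, n_fragments, ext_len, read_len,
                                  chrom))
}

## vectorized spike sampler (no seed handling; callers manage the RNG)
spike_fragments <- function(centers, n_fragments, ext_len, read_len, chrom) {
  centers <- rep(centers, each = n_fragments)
  starts <- centers - sample.int(ext_len, length(centers), replace = TRUE) + 1L
  strand <- sample(c("+", "-"), length(centers), replace = TRUE)
  fragments_to_reads(starts, strand, ext_len, read_len, chrom)
}

#' Generate the paired-peak separation series
#'
#' One dataset per inter-peak separation (default 200 to 500 bp in 25 bp
#' steps, 13 datasets). Each dataset is a uniform background plus
#' `pairs_per_dataset` spiked peak pairs at the given separation, with pair
#' anchors evenly spaced at least 5 kb apart; the control is an independent
#' uniform background with the same total read count as the treatment (the
#' "same number of reads" matching rule). Truth records both summits of each
#' pair.
#'
#' @param separations Inter-peak separations in bp.
#' @param pairs_per_dataset Peak pairs per dataset.
#' @param n_fragments_per_peak Fragments per spiked peak.
#' @param background List with `chrom_len`, `n_reads`, `read_len`, `ext_len`.
#' @param seed Master seed; per-dataset seeds are derived from it.
#' @param chrom Chromosome name.
#' @return List of datasets, each a list with `separation`, `treatment`,
#'   `control` (read tables) and `truth`.
#' @export
generate_paired_series <- function(separations = seq(200L, 500L, by = 25L),
                                   pairs_per_dataset = 1000L,
                                   n_fragments_per_peak = 100L,
                                   background = list(chrom_len = 1e7,
                                                     n_reads = 20000L,
                                                     read_len = 36L,
                                                     ext_len = 200L),
                                   seed = 1L, chrom = "chr1") {
  stopifnot(all(separations > 0), pairs_per_dataset >= 1)
  ext <- background$ext_len
  margin <- ext + max(separations)
  span <- background$chrom_len - 2 * margin
  spacing <- if (pairs_per_dataset > 1) floor(span / (pairs_per_dataset - 1))
    else span
  if (spacing < 5000 + max(separations))
    stop_fatal("pair anchors would collide: need >= 5 kb spacing, got ",
               spacing - max(separations), " bp")
  anchors <- margin + (seq_len(pairs_per_dataset) - 1) * spacing
  seeds <- derive_seeds(seed, 3L * length(separations))
  lapply(seq_along(separations), function(i) {
    sep <- separations[i]
    centers <- as.vector(rbind(anchors, anchors + sep))
    truth <- data.frame(chrom = chrom, pos = centers,
                        pair_id = rep(sprintf("pair_%d",
                                              seq_len(pairs_per_dataset)),
                                      each = 2L),
                        n_fragments = n_fragments_per_peak, separation = sep,
                        stringsAsFactors = FALSE)
    bg <- generate_background(background$chrom_len, background$n_reads,
                              background$read_len, ext,
                              seed = seeds[3L * i - 2L], chrom = chrom)
    spikes <- with_seed(seeds[3L * i - 1L],
                        spike_fragments(centers, n_fragments_per_peak, ext,
                                        background$read_len, chrom))
    treatment <- rbind(bg, spikes)
    control <- generate_background(background$chrom_len, nrow(treatment),
                                   background$read_len, ext,
                                   seed = seeds[3L * i], chrom = chrom)
    list(separation = sep, treatment = treatment, control = control,
         truth = truth)
  })
}

#' Write a truth table as BED
#'
#' Single-bp BED intervals with the pair id in the name column; values
#' round-trip through [read_truth_bed()].
#'
#' @param truth Truth table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", truth$chrom,
                     as.integer(truth$pos), as.integer(truth$pos) + 1L,
                     truth$pair_id, as.integer(truth$n_fragments)), path)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  f <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = f[[1L]], pos = as.numeric(f[[2L]]), pair_id = f[[4L]],
             n_fragments = as.numeric(f[[5L]]), separation = NA_real_,
             stringsAsFactors = FALSE)
}

#' Evaluate peak calls against a known truth
#'
#' Greedy one-to-one matching by increasing distance: candidate (call, truth)
#' pairs on the same chromosome within `match_dist` are assigned in order of
#' distance, each call and each truth at most once. A truth matched within
#' `match_dist` is recovered; calls matching no truth are false positives; a
#' peak pair is resolved iff both of its truth summits are matched (by
#' distinct calls, which one-to-one matching guarantees).
#'
#' @param calls `data.frame` with `chrom` and `pos` (summit positions), or a
#'   numeric vector of positions (single chromosome).
#' @param truth Truth table (see [generate_paired_series()]).
#' @param match_dist Maximum matching distance in bp (default 100).
#' @return List of class `eval_report`: `recall`, `fpr`, `spatial_errors`,
#'   `resolved_fraction` (NA when the truth has no pairs), `n_calls`,
#'   `n_truth`.
#' @export
evaluate_calls <- function(calls, truth, match_dist = 100) {
  if (is.numeric(calls)) {
    chrom0 <- if (nrow(truth)) truth$chrom[1L] else "chr1"
    calls <- data.frame(chrom = rep_len(chrom0, length(calls)), pos = calls,
                        stringsAsFactors = FALSE)
  }
  n_calls <- nrow(calls)
  n_truth <- nrow(truth)
  matched_truth <- logical(n_truth)
  matched_call <- logical(n_calls)
  errors <- numeric(0)
  if (n_calls && n_truth) {
    cand <- do.call(rbind, lapply(unique(truth$chrom), function(chrom) {
      ti <- which(truth$chrom == chrom)
      ci <- which(calls$chrom == chrom)
      if (!length(ti) || !length(ci)) return(NULL)
      ord <- order(calls$pos[ci])
      ci <- ci[ord]
      cpos <- calls$pos[ci]
      lo <- findInterval(truth$pos[ti] - match_dist - 1e-9, cpos) + 1L
      hi <- findInterval(truth$pos[ti] + match_dist, cpos)
      keep <- lo <= hi
      if (!any(keep)) return(NULL)
      idx <- unlist(Map(seq, lo[keep], hi[keep]))
      t_rep <- rep(ti[keep], hi[keep] - lo[keep] + 1L)
      data.frame(truth = t_rep, call = ci[idx],
                 dist = abs(truth$pos[t_rep] - cpos[idx]))
    }))
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand$dist, cand$truth, cand$call), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        ti <- cand$truth[k]
        ci <- cand$call[k]
        if (!matched_truth[ti] && !matched_call[ci]) {
          matched_truth[ti] <- TRUE
          matched_call[ci] <- TRUE
          errors <- c(errors, cand$dist[k])
        }
      }
    }
  }
  resolved <- NA_real_
  if (n_truth && any(!is.na(truth$pair_id)) && anyDuplicated(truth$pair_id)) {
    by_pair <- tapply(matched_truth, truth$pair_id, all)
    resolved <- mean(by_pair)
  }
  structure(list(recall = if (n_truth) mean(matched_truth) else NA_real_,
                 fpr = if (n_calls) mean(!matched_call) else 0,
                 spatial_errors = errors,
                 resolved_fraction = resolved,
                 n_calls = n_calls, n_truth = n_truth),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> recall=%.3f fpr=%.3f resolved=%s calls=%d truth=%d\n",
              x$recall, x$fpr,
              ifelse(is.na(x$resolved_fraction), "NA",
                     sprintf("%.3f", x$resolved_fraction)),
              x$n_calls, x$n_truth))
  invisible(x)
}

#' Default benchmark caller runner
#'
#' Returns a function that maps one synthetic dataset to a summit table:
#' derive the chromosome table from the dataset's reads, build treatment and
#' control coverage, call peaks with `config`, and flatten to one row per
#' summit.
#'
#' @param config A [caller_config()]; defaults to the resolution preset.
#' @return A function of one dataset, for [resolution_curve()].
#' @export
default_caller_runner <- function(config = caller_config("resolution")) {
  function(dataset) {
    tab <- derive_chrom_table(rbind(dataset$treatment, dataset$control))
    treat <- build_coverage(dataset$treatment, config$ext_len, tab)
    ctrl <- build_coverage(dataset$control, config$ext_len, tab)
    regions <- call_peaks(treat, ctrl, config)
    summits_table(regions)
  }
}

#' Flatten a called region table to one row per summit
#'
#' @param regions Output of [call_peaks()].
#' @return `data.frame(chrom, pos, height)`.
#' @export
summits_table <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      height = numeric(), stringsAsFactors = FALSE))
  n <- vapply(regions$summits, nrow, 0L)
  data.frame(chrom = rep(regions$chrom, n),
             pos = unlist(lapply(regions$summits, `[[`, "pos")),
             height = unlist(lapply(regions$summits, `[[`, "height")),
             stringsAsFactors = FALSE)
}

#' Inter-peak resolution curve
#'
#' Runs the caller on every dataset of a paired-peak series and reports, per
#' separation, the fraction of pairs resolved into two distinct matched
#' summits and the unmatched-call fraction.
#'
#' @param series Output of [generate_paired_series()].
#' @param caller_runner Function mapping a dataset to a summit table;
#'   defaults to the resolution-mode preset caller.
#' @param match_dist Matching distance for [evaluate_calls()].
#' @return `data.frame(separation, resolved_fraction, fpr, recall)`, ordered
#'   by separation.
#' @export
resolution_curve <- function(series, caller_runner = default_caller_runner(),
                             match_dist = 100) {
  rows <- lapply(series, function(dataset) {
    calls <- caller_runner(dataset)
    ev <- evaluate_calls(calls, dataset$truth, match_dist)
    data.frame(separation = dataset$separation,
               resolved_fraction = ev$resolved_fraction, fpr = ev$fpr,
               recall = ev$recall)
  })
  out <- do.call(rbind, rows)
  out[order(out$separation), , drop = FALSE]
}
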