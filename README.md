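# rangercall

A dual-mode ChIP-seq peak caller for R. ChIP-seq experiments pile sequenced
reads up around protein–DNA binding sites; the analysis problem is to find
the enriched intervals (peaks) and, within them, the single-bp positions of
maximal coverage (summits) that best estimate the binding sites. Most callers
are tuned either for punctate transcription-factor sites or for broad
histone-modification domains; `rangercall` handles both, and is built to
resolve closely spaced binding events that region-level callers merge into
one call. It is aimed at people running ChIP-seq pipelines who want a
scriptable caller with explicit, reproducible statistics, plus a benchmark
harness for measuring caller behaviour on data with known truth.

## Method

1. **Coverage by blind extension.** Every mapped read is extended from its
   5′ end to the user-supplied shear size *L* (the fragment length of the
   sheared chromatin, default 200 bp; never estimated from the data).
   Coverage at a base is the number of extended fragments overlapping it.
2. **Broad region detection.** With genome-wide mean depth λ, candidate
   regions are maximal runs of coverage ≥ *h*, where *h* is the smallest
   integer with P(Poisson(λ) ≥ *h*) < p₀ (default p₀ = 10⁻⁴); runs separated
   by fewer than `max_gap` (100 bp) low positions are merged.
3. **Significance and FDR.** With a control, each region with k_t treatment
   and k_c rescaled control fragments gets the one-sided binomial p-value
   P(X ≥ k_t), X ~ Binomial(k_t + k_c, ½); the control-to-treatment scale
   factor r is a zero-intercept regression of 10 kb background bin counts
   (library-size ratio as fallback). Without a control, the p-value is a
   Poisson tail with mean λ·len/*L*. Benjamini–Hochberg FDR is applied
   genome-wide over all candidate regions (cutoff 0.01) — never per
   chromosome.
4. **Summit-valley-alternator.** Inside each surviving region the smoothed
   profile is scanned left to right: track the running maximum *M*; when the
   signal drops below δ·*M* (δ ∈ (0,1)), emit the leftmost position of *M*
   as a summit and seek a valley; re-arm for the next summit when the signal
   climbs above (running minimum)/δ. Larger δ splits shallower valleys.
   Summits separated only by zero raw coverage collapse to the higher one,
   and an optional comparable-heights filter keeps summits near the region
   maximum.
5. **Presets.** `resolution` mode (δ = 0.8, 5 bp smoothing) for punctate
   sites; `region` mode (δ = 0.5, 31 bp smoothing) for broad domains.
   Execution is partitioned by chromosome; output is byte-identical for any
   worker count.

## Worked example

Simulate a 1 Mb chromosome with a uniform background, one isolated binding
site at 250,000 and a twin pair at 600,000/600,360, plus a matched control,
then call peaks in resolution mode:

```r
library(rangercall)
treat <- rbind(
  generate_background(1e6, 2000, seed = 1),
  spike_peak(250000, 100, seed = 2, chrom_len = 1e6),
  spike_peak(600000, 100, seed = 3, chrom_len = 1e6),
  spike_peak(600360, 100, seed = 4, chrom_len = 1e6))
ctrl <- generate_background(1e6, nrow(treat), seed = 5)
write_reads_bed(treat, "treat.bed")
write_reads_bed(ctrl, "ctrl.bed")
res <- run_peak_caller("treat.bed", "ctrl.bed",
                       caller_config("resolution"), "demo")
```

`demo_regions.bed` (BED6 prefix, then summit position and height; score is
−log₁₀(q), capped at 330):

```
#chrom  start   end     name      score    strand  summit  summit_height
chr1    249809  250192  region_1  28.5978  .       249998  99.6
chr1    599806  600540  region_2  59.6039  .       599999  101.6
chr1    599806  600540  region_2  59.6039  .       600360  99.4
```

Both spiked events are recovered: the lone site gives one region with a
summit 2 bp from the planted center, and the 360 bp twin is reported as one
enriched region carrying two summits, 1 bp and 0 bp from their planted
centers. `demo.log` records the stage counters (here: background λ = 0.46,
depth threshold 6, 2 candidate regions, 2 passing FDR).

The same run is available from a shell via the installed script:

```sh
inst/cli/rangercall --data treat.bed --control ctrl.bed \
    --mode resolution --fdr 0.01 --output demo
```

## Benchmark generators

`generate_background()`, `spike_peak()` and `generate_paired_series()` build
semi-synthetic datasets with known truth: uniform background reads, spiked
point-source peaks whose raw coverage at the planted center equals the
fragment count exactly, and a 13-dataset series of peak pairs at separations
200–500 bp with an equal-read-count control. `evaluate_calls()` scores calls
against truth (greedy one-to-one matching within 100 bp) and
`resolution_curve()` reports the fraction of pairs resolved into two
distinct matched summits per separation.

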