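test_that("Poisson region threshold matches exact tail summation", {
  expect_equal(poisson_region_threshold(0, 1e-4), 1L)
  # independent oracle: smallest h with term-wise tail sum < p0
  h_oracle <- function(lambda, p0) {
    h <- 1L
    while (oracle_poisson_tail(h, lambda) >= p0) h <- h + 1L
    h
  }
  expect_equal(poisson_region_threshold(1, 1e-4), h_oracle(1, 1e-4))
  expect_equal(poisson_region_threshold(1, 1e-4), 7L)
  expect_lt(oracle_poisson_tail(7, 1), 1e-4)
  expect_gte(oracle_poisson_tail(6, 1), 1e-4)
  for (lam in c(0.3, 2.5, 10))
    expect_equal(poisson_region_threshold(lam, 1e-3), h_oracle(lam, 1e-3))
  # stochastic ordering: higher background demands a higher threshold
  expect_gte(poisson_region_threshold(2, 1e-4), poisson_region_threshold(1, 1e-4))
})

test_that("candidate regions are maximal runs with sub-gap merging", {
  depth <- c(0, 0, 3, 4, 5, 0, 0, 6, 7, 0)
  r <- detect_candidate_regions(depth, h = 3, max_gap = 1)
  expect_equal(r$start, c(2, 7))
  expect_equal(r$end, c(5, 9))
  expect_equal(r$max_height, c(5, 7))
  r <- detect_candidate_regions(depth, h = 3, max_gap = 3)
  expect_equal(cbind(r$start, r$end), cbind(2, 9))
  expect_equal(r$max_height, 7)
  expect_equal(nrow(detect_candidate_regions(c(1, 2, 1), h = 3, max_gap = 1)),
               0L)
})

test_that("region detection agrees with a position-by-position oracle", {
  set.seed(303)
  for (i in 1:1000) {
    n <- sample.int(200, 1)
    depth <- sample(0:6, n, replace = TRUE)
    h <- sample(1:5, 1)
    gap <- sample(0:6, 1)
    got <- detect_candidate_regions(depth, h, gap)
    want <- oracle_region_scan(depth, h, gap)
    expect_equal(got, want, info = sprintf("case %d (h=%d gap=%d)", i, h, gap))
  }
})

test_that("control scaling uses zero-intercept regression with library fallback", {
  t <- c(10, 20, 30, 40)
  fit <- fit_control_scaling(t, t)
  expect_equal(fit$r, 1)
  expect_equal(fit$method, "regression")
  fit <- fit_control_scaling(t, 2 * t)
  expect_equal(fit$r, 0.5)
  expect_warning(fit <- fit_control_scaling(t, c(0, 0, 0, 0)), "no fragments")
  expect_equal(fit$method, "library_ratio")
  expect_equal(fit$r, 1)
  # excluded bins are ignored by the regression
  fit <- fit_control_scaling(c(100, 10, 20), c(1, 10, 20),
                             excluded_bins = 1L)
  expect_equal(fit$r, 1)
  expect_equal(fit$n_bins_used, 2L)
})

test_that("binomial region p-values match exact tail sums", {
  # oracle: sum of C(10, k)/2^10 over k = 5..10
  expect_equal(sum(choose(10, 5:10)) / 2^10, 0.623046875)
  expect_equal(region_pvalue_binomial(5, 5), 0.623046875)
  expect_equal(region_pvalue_binomial(10, 0), 2^-10)
  expect_equal(region_pvalue_binomial(0, 7), 1)
  # scaled control counts are rounded to the nearest integer
  expect_equal(region_pvalue_binomial(5, 4.6), region_pvalue_binomial(5, 5))
})

test_that("Poisson region p-values match the exact tail and are monotone", {
  expect_equal(region_pvalue_poisson(0, 1, 200, 200), 1)
  p7 <- region_pvalue_poisson(7, 1, 200, 200)  # mu = 1
  expect_equal(p7, oracle_poisson_tail(7, 1), tolerance = 1e-12)
  expect_equal(p7, 8.32e-5, tolerance = 1e-2)
  p <- region_pvalue_poisson(1:10, 1, 200, 200)
  expect_true(all(diff(p) < 0))
})

test_that("BH q-values match a quadratic-time reference", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.05, 10)), rep(0.05, 10))
  set.seed(404)
  for (i in 1:20) {
    p <- round(runif(sample.int(30, 1)), 3)
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_regions recovers a spiked peak and respects the FDR cutoff", {
  tab <- structure(c(chr1 = 1e6), class = "chrom_table",
                   provenance = "precomputed")
  reads <- rbind(generate_background(1e6, 500L, seed = 5L),
                 spike_peak(5e5, 100L, seed = 6L, chrom_len = 1e6))
  prof <- build_coverage(reads, 200L, tab)
  cfg <- caller_config("resolution")
  res <- call_regions(prof, NULL, cfg)
  expect_equal(nrow(res), 1L)
  expect_true(res$start <= 5e5 && res$end > 5e5)
  expect_true(res$q_value <= 0.01)
  # fdr_cutoff = 0 drops everything here (p-values are positive)
  res0 <- call_regions(prof, NULL, caller_config("resolution", fdr_cutoff = 0))
  expect_equal(nrow(res0), 0L)
})

test_that("identical treatment and control yield no significant regions", {
  prof <- build_coverage(generate_background(1e6, 2000L, seed = 8L), 200L,
                         structure(c(chr1 = 1e6), class = "chrom_table",
                                   provenance = "precomputed"))
  res <- call_regions(prof, prof, caller_config("resolution"))
  expect_equal(nrow(res), 0L)
})

test_that("regions at FDR 0.01 nest inside regions at FDR 0.05", {
  set.seed(9)
  tab <- structure(c(chr1 = 1e6), class = "chrom_table",
                   provenance = "precomputed")
  # weak spikes so some q-values land between 0.01 and 0.05
  reads <- rbind(generate_background(1e6, 4000L, seed = 10L),
                 rangercall:::with_seed(11L, rangercall:::spike_fragments(
                   seq(5e4, 9.5e5, by = 5e4), 8L, 200L, 36L, "chr1")))
  prof <- build_coverage(reads, 200L, tab)
  r1 <- call_regions(prof, NULL, caller_config("resolution", fdr_cutoff = 0.01))
  r5 <- call_regions(prof, NULL, caller_config("resolution", fdr_cutoff = 0.05))
  key <- function(r) paste(r$chrom, r$start, r$end)
  expect_true(all(key(r1) %in% key(r5)))
  expect_gte(nrow(r5), nrow(r1))
})

test_that("q-values come from the genome-wide gather, not per-chromosome BH", {
  tab <- structure(c(chr1 = 2e5, chr2 = 2e5), class = "chrom_table",
                   provenance = "precomputed")
  # strong peaks on chr1, weak on chr2: p distributions differ by chromosome
  reads <- rbind(
    generate_background(2e5, 400L, seed = 21L),
    rangercall:::with_seed(22L, rangercall:::spike_fragments(
      c(5e4, 1e5, 15e4), 60L, 200L, 36L, "chr1")),
    {
      r <- generate_background(2e5, 400L, seed = 23L)
      r$chrom <- "chr2"
      r
    },
    {
      r <- rangercall:::with_seed(24L, rangercall:::spike_fragments(
        c(5e4, 1e5, 15e4), 10L, 200L, 36L, "chr1"))
      r$chrom <- "chr2"
      r
    })
  prof <- build_coverage(reads, 200L, tab)
  cfg <- caller_config("resolution", fdr_cutoff = 1)
  joint <- call_regions(prof, NULL, cfg)
  expect_true(all(c("chr1", "chr2") %in% joint$chrom))
  # naive per-chromosome BH on the same p-values must disagree somewhere
  naive_q <- unsplit(lapply(split(joint$p_value, joint$chrom), bh_fdr),
                     joint$chrom)
  expect_equal(bh_fdr(joint$p_value), joint$q_value)
  expect_false(isTRUE(all.equal(naive_q, joint$q_value)))
})
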