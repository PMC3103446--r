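test_that("BED records map to the read model with 0-based half-open semantics", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t136\tr1\t0\t+",
               "chr1\t200\t236\tr2\t0\t-"), bed)
  reads <- parse_alignments(bed)
  expect_equal(reads$pos5, c(100L, 235L))
  expect_equal(reads$strand, c("+", "-"))
  expect_equal(reads$read_len, c(36L, 36L))
  expect_equal(attr(reads, "n_parsed"), 2L)
  expect_equal(attr(reads, "chroms"), "chr1")
})

test_that("SAM parsing converts 1-based coordinates and minus-strand 5' ends", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(sam, c(chr1 = 10000L), c(
    sam_record("r1", 0L, "chr1", 101L, "36M"),
    sam_record("r2", 16L, "chr1", 1001L, "36M"),
    sam_record("r3", 4L, "*", 0L, "*", seq = "ACGT"),  # unmapped: skipped
    sam_record("r4", 16L, "chr1", 2001L, "20M5D16M")))
  reads <- parse_alignments(sam)
  expect_equal(nrow(reads), 3L)
  expect_equal(reads$pos5[1], 100L)
  # FLAG=16, POS=1001, 36M: span [1000, 1036), minus-strand 5' end = 1035
  expect_equal(reads$pos5[2], 1035L)
  expect_equal(reads$strand[2], "-")
  expect_equal(reads$read_len[2], 36L)
  # deletions consume reference: span 41 bp
  expect_equal(reads$read_len[3], 41L)
  expect_equal(reads$pos5[3], 2000L + 41L - 1L)
  expect_equal(attr(reads, "n_skipped"), 1L)
})

test_that("BAM input parses identically to the same records in SAM", {
  sam <- withr::local_tempfile(fileext = ".sam")
  recs <- c(sam_record("r1", 0L, "chr1", 101L, "36M"),
            sam_record("r2", 16L, "chr1", 1001L, "36M"),
            sam_record("r3", 0L, "chr1", 5001L, "36M"))
  write_sam_fixture(sam, c(chr1 = 10000L), recs)
  bam <- suppressMessages(Rsamtools::asBam(
    sam, withr::local_tempfile(), overwrite = TRUE))
  from_sam <- parse_alignments(sam)
  from_bam <- parse_alignments(bam, format = "bam")
  ord <- function(x) x[order(x$pos5), ]
  expect_equal(ord(as.data.frame(from_bam)), ord(as.data.frame(from_sam)),
               ignore_attr = TRUE)
})

test_that("format resolution honors explicit flags and rejects unknown extensions", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("chr1\t100\t136\tr1\t0\t+", f)
  expect_error(parse_alignments(f), "bed, sam, bam, bowtie, eland")
  expect_equal(parse_alignments(f, format = "bed")$pos5, 100L)
  expect_error(parse_alignments("no/such/file.bed"), "not found")
})

test_that("malformed lines fail fast with a line number, or skip when lenient", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t136\tr1\t0\t+",
               "chr1\tnotanumber\t10\tr2\t0\t+"), bed)
  expect_error(parse_alignments(bed), "line 2")
  expect_warning(reads <- parse_alignments(bed, lenient = TRUE), "skipped")
  expect_equal(nrow(reads), 1L)
})

test_that("Bowtie and Eland legacy readers map columns to the read model", {
  bt <- withr::local_tempfile(fileext = ".bowtie")
  seq36 <- strrep("A", 36)
  writeLines(c(paste("r1", "+", "chr1", "100", seq36, "IIII", "0", sep = "\t"),
               paste("r2", "-", "chr1", "100", seq36, "IIII", "0", sep = "\t")),
             bt)
  reads <- parse_alignments(bt)
  expect_equal(reads$pos5, c(100L, 135L))
  el <- withr::local_tempfile(fileext = ".eland")
  writeLines(c(paste("r1", seq36, "U0", "1", "0", "0", "chr1", "101", "F",
                     sep = "\t"),
               paste("r2", seq36, "NM", "0", "0", "0", "-", "-", "-",
                     sep = "\t")), el)
  reads <- parse_alignments(el)
  expect_equal(nrow(reads), 1L)
  expect_equal(reads$pos5, 100L)
  expect_equal(attr(reads, "n_skipped"), 1L)
})

test_that("BED serialization round-trips the read model exactly", {
  set.seed(42)
  reads <- reads_df("chr1", sample.int(1e5, 50) + 100L,
                    sample(c("+", "-"), 50, TRUE),
                    sample(30:40, 50, TRUE))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(reads, bed)
  back <- parse_alignments(bed)
  expect_equal(as.data.frame(back), reads, ignore_attr = TRUE)
})

test_that("SAM and BED serializations of one fragment set parse identically", {
  reads <- reads_df("chr1", c(100L, 535L, 900L), c("+", "-", "+"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(reads, bed)
  sam <- withr::local_tempfile(fileext = ".sam")
  start1 <- ifelse(reads$strand == "+", reads$pos5,
                   reads$pos5 - reads$read_len + 1L) + 1L
  write_sam_fixture(sam, c(chr1 = 10000L), vapply(seq_len(nrow(reads)),
    function(i) sam_record(paste0("r", i),
                           if (reads$strand[i] == "-") 16L else 0L,
                           "chr1", start1[i],
                           paste0(reads$read_len[i], "M")), ""))
  expect_equal(as.data.frame(parse_alignments(sam)),
               as.data.frame(parse_alignments(bed)), ignore_attr = TRUE)
})

test_that("chromosome tables derive from reads with sorted deterministic order", {
  reads <- reads_df(c("chr2", "chr1"), c(50L, 100L), c("+", "+"))
  tab <- derive_chrom_table(reads)
  expect_equal(names(tab), c("chr1", "chr2"))
  expect_equal(as.numeric(tab), c(136, 86))
  expect_equal(attr(tab, "provenance"), "derived_from_reads")
  # minus-strand reads only need pos5 + 1
  tab2 <- derive_chrom_table(reads_df("chr1", 99L, "-"))
  expect_equal(as.numeric(tab2), 100)
  expect_equal(as.numeric(derive_chrom_table(reads, slack = 10)),
               c(146, 96))
  expect_error(derive_chrom_table(empty_reads_for_test()), "empty")
})

test_that("precomputed chromosome tables validate lengths and names", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t1000", "chr2\t500"), f)
  tab <- load_chrom_table(f)
  expect_equal(as.numeric(tab), c(1000, 500))
  expect_equal(attr(tab, "provenance"), "precomputed")
  writeLines("chr1\t0", f)
  expect_error(load_chrom_table(f), "line 1")
  writeLines(c("chr1\t100", "chr1\t200"), f)
  expect_error(load_chrom_table(f), "duplicate")
})

test_that("wiggle output is 1-based, sparse, and gzip round-trips byte-identically", {
  tab <- structure(c(chr1 = 5, chr2 = 4), class = "chrom_table",
                   provenance = "precomputed")
  prof <- build_coverage(reads_df("chr1", 2L, "+", 3L), 3L, tab)
  wig <- withr::local_tempfile(fileext = ".wig")
  write_wiggle(prof, wig)
  lines <- readLines(wig)
  expect_equal(lines, c("variableStep chrom=chr1 span=1", "3 1", "4 1", "5 1",
                        "variableStep chrom=chr2 span=1"))
  gz <- withr::local_tempfile(fileext = ".wig.gz")
  write_wiggle(prof, gz, compress = TRUE)
  expect_identical(readLines(gzfile(gz)), lines)
})

test_that("wiggle re-parsed position-by-position equals the nonzero profile", {
  set.seed(7)
  tab <- structure(c(chr1 = 500), class = "chrom_table",
                   provenance = "precomputed")
  reads <- reads_df("chr1", sample.int(450, 40), sample(c("+", "-"), 40, TRUE),
                    20L)
  prof <- build_coverage(reads, 30L, tab)
  wig <- withr::local_tempfile(fileext = ".wig")
  write_wiggle(prof, wig)
  sparse <- parse_wiggle_lines(readLines(wig))$chr1
  v <- prof$cov$chr1
  expect_equal(sparse$pos, which(v != 0))
  expect_equal(sparse$value, v[v != 0])
})

test_that("peak files carry a BED6 prefix with capped -log10(q) scores", {
  calls <- data.frame(chrom = "chr1", start = 100, end = 400,
                      max_height = 10, treat_count = 20,
                      ctrl_count_scaled = 1, p_value = 1e-4,
                      q_value = c(0.01))
  calls$summits <- list(data.frame(pos = 250, height = 9.5))
  f <- withr::local_tempfile(fileext = ".bed")
  write_peaks(calls, f, mode = "region")
  row <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_equal(row[1:6], c("chr1", "100", "400", "region_1", "2", "."))
  calls$q_value <- 0
  write_peaks(calls, f, mode = "resolution")
  row <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_equal(as.numeric(row[5]), 330)
  expect_equal(row[7:8], c("250", "9.5"))
  write_peaks(calls[0, ], f, mode = "region")
  expect_equal(length(readLines(f)), 1L)  # header only
})
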