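## Alignment input, chromosome tables and track/peak output.
##
## All internal coordinates are 0-based half-open. SAM/BAM input (1-based)
## and wiggle output (1-based) are converted at the boundary, nowhere else.

ACCEPTED_FORMATS <- c("bed", "sam", "bam", "bowtie", "eland")

#' Parse an aligned-read file into the uniform read model
#'
#' Reads one of the supported alignment formats and reduces every mapped
#' record to the four fields the caller needs: chromosome, the 0-based
#' coordinate of the read's 5'-most aligned base (`pos5`; for minus-strand
#' reads this is the *rightmost* aligned base), strand, and aligned length on
#' the reference.
#'
#' Unmapped records are skipped and counted. Malformed lines abort with the
#' offending line number unless `lenient = TRUE`, in which case they are
#' skipped with a warning.
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"`, `"bed"`, `"sam"`, `"bam"`, `"bowtie"`,
#'   `"eland"`. `"auto"` resolves by file extension; an explicit format always
#'   wins over the extension.
#' @param lenient Skip malformed lines with a warning instead of failing.
#' @param eland_dialect Column layout for the legacy Eland text format; only
#'   `"sorted"` (chrom, 1-based position, F/R strand in columns 7-9) is
#'   implemented. Neither historic Eland dialect is canonical.
#' @return A `data.frame` with columns `chrom`, `pos5`, `strand`, `read_len`,
#'   carrying attributes `n_parsed`, `n_skipped` and `chroms` (the observed
#'   chromosome name set).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t136\tr1\t0\t+", bed)
#' parse_alignments(bed)
#' @export
parse_alignments <- function(path, format = "auto", lenient = FALSE,
                             eland_dialect = "sorted") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_fatal("alignment file not found: ", path)
  format <- match.arg(format, c("auto", ACCEPTED_FORMATS))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% ACCEPTED_FORMATS)
      stop_fatal("cannot resolve alignment format from extension '", ext,
                 "' of ", path, "; accepted formats: ",
                 paste(ACCEPTED_FORMATS, collapse = ", "))
    format <- ext
  }
  res <- switch(format,
    bed    = parse_bed(path, lenient),
    sam    = parse_sam(path, lenient),
    bam    = parse_bam(path),
    bowtie = parse_bowtie(path, lenient),
    eland  = parse_eland(path, lenient, eland_dialect))
  reads <- validate_reads(res$reads)
  attr(reads, "n_parsed") <- nrow(reads)
  attr(reads, "n_skipped") <- res$n_skipped
  attr(reads, "chroms") <- sort(unique(reads$chrom))
  reads
}

## Report or skip malformed lines; `bad` is a logical index over `lines`.
handle_bad_lines <- function(bad, what, lenient) {
  if (!any(bad)) return(invisible())
  if (!lenient)
    stop_fatal("malformed ", what, " at line ", which(bad)[1L])
  warning(sum(bad), " malformed ", what, " line(s) skipped", call. = FALSE)
  invisible()
}

split_columns <- function(lines) strsplit(lines, "\t", fixed = TRUE)

parse_bed <- function(path, lenient) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- split_columns(lines[keep])
  nf <- lengths(fields)
  bad <- logical(length(lines))
  ok <- nf >= 6L
  m <- matrix("", nrow = sum(ok), ncol = 6L)
  if (any(ok)) m <- do.call(rbind, lapply(fields[ok], `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  strand <- m[, 6L]
  rowbad <- is.na(start) | is.na(end) | start < 0L | end <= start |
    !strand %in% c("+", "-")
  bad[keep] <- !ok
  bad[which(keep)[ok][rowbad]] <- TRUE
  handle_bad_lines(bad, "BED record", lenient)
  good <- !rowbad & !is.na(rowbad)
  len <- end[good] - start[good]
  pos5 <- ifelse(strand[good] == "+", start[good], end[good] - 1L)
  list(reads = data.frame(chrom = m[good, 1L], pos5 = as.integer(pos5),
                          strand = strand[good], read_len = as.integer(len),
                          stringsAsFactors = FALSE),
       n_skipped = sum(bad))
}

parse_sam <- function(path, lenient) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "@") & nzchar(lines)
  fields <- split_columns(lines[keep])
  nf <- lengths(fields)
  bad <- logical(length(lines))
  ok <- nf >= 11L
  bad[keep] <- !ok
  fields <- fields[ok]
  flag <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  rname <- vapply(fields, `[`, "", 3L)
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
  cigar <- vapply(fields, `[`, "", 6L)
  rowbad <- is.na(flag) | is.na(pos1)
  unmapped <- !rowbad & (bitwAnd(flag, 4L) > 0L | rname == "*" |
                           cigar == "*" | pos1 == 0L)
  mapped <- !rowbad & !unmapped
  width <- rep(NA_integer_, length(cigar))
  if (any(mapped)) {
    w <- try(GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[mapped]),
             silent = TRUE)
    if (inherits(w, "try-error")) {
      ## pinpoint the first bad CIGAR for the error contract
      for (i in which(mapped)) {
        wi <- try(GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[i]),
                  silent = TRUE)
        if (inherits(wi, "try-error")) rowbad[i] <- TRUE else width[i] <- wi
      }
    } else width[mapped] <- w
  }
  bad[which(keep)[ok][rowbad]] <- TRUE
  handle_bad_lines(bad, "SAM record", lenient)
  use <- mapped & !rowbad
  minus <- bitwAnd(flag[use], 16L) > 0L
  start0 <- pos1[use] - 1L
  pos5 <- ifelse(minus, start0 + width[use] - 1L, start0)
  list(reads = data.frame(chrom = rname[use], pos5 = as.integer(pos5),
                          strand = ifelse(minus, "-", "+"),
                          read_len = as.integer(width[use]),
                          stringsAsFactors = FALSE),
       n_skipped = sum(bad) + sum(unmapped))
}

parse_bam <- function(path) {
  ga <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(path))
  strand <- as.character(GenomicAlignments::strand(ga))
  strand[strand == "*"] <- "+"
  start0 <- GenomicAlignments::start(ga) - 1L
  end0 <- GenomicAlignments::end(ga) - 1L  # inclusive rightmost base
  pos5 <- ifelse(strand == "-", end0, start0)
  n_total <- Rsamtools::countBam(path)$records
  list(reads = data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
                          pos5 = as.integer(pos5), strand = strand,
                          read_len = as.integer(end0 - start0 + 1L),
                          stringsAsFactors = FALSE),
       n_skipped = n_total - length(ga))
}

## Bowtie legacy default output: name, strand, chrom, 0-based leftmost
## offset, sequence, quals, ... (columns 2-5 used).
parse_bowtie <- function(path, lenient) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  fields <- split_columns(lines[keep])
  nf <- lengths(fields)
  bad <- logical(length(lines))
  ok <- nf >= 5L
  bad[keep] <- !ok
  fields <- fields[ok]
  strand <- vapply(fields, `[`, "", 2L)
  chrom <- vapply(fields, `[`, "", 3L)
  off <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
  len <- nchar(vapply(fields, `[`, "", 5L))
  rowbad <- is.na(off) | off < 0L | !strand %in% c("+", "-") | len < 1L
  bad[which(keep)[ok][rowbad]] <- TRUE
  handle_bad_lines(bad, "Bowtie record", lenient)
  g <- !rowbad
  pos5 <- ifelse(strand[g] == "+", off[g], off[g] + len[g] - 1L)
  list(reads = data.frame(chrom = chrom[g], pos5 = as.integer(pos5),
                          strand = strand[g], read_len = as.integer(len[g]),
                          stringsAsFactors = FALSE),
       n_skipped = sum(bad))
}

## Eland "sorted" dialect: id, seq, match code, N0, N1, N2, chrom,
## 1-based leftmost position, strand F/R. Non-unique/unmapped codes skipped.
parse_eland <- function(path, lenient, dialect = "sorted") {
  dialect <- match.arg(dialect, "sorted")
  lines <- readLines(path)
  keep <- nzchar(lines)
  fields <- split_columns(lines[keep])
  nf <- lengths(fields)
  bad <- logical(length(lines))
  ok <- nf >= 9L
  bad[keep] <- !ok
  fields <- fields[ok]
  code <- vapply(fields, `[`, "", 3L)
  mapped <- grepl("^U[0-2]$", code)
  chrom <- vapply(fields, `[`, "", 7L)
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 8L)))
  sr <- vapply(fields, `[`, "", 9L)
  len <- nchar(vapply(fields, `[`, "", 2L))
  rowbad <- mapped & (is.na(pos1) | pos1 < 1L | !sr %in% c("F", "R"))
  bad[which(keep)[ok][rowbad]] <- TRUE
  handle_bad_lines(bad, "Eland record", lenient)
  g <- mapped & !rowbad
  strand <- ifelse(sr[g] == "F", "+", "-")
  start0 <- pos1[g] - 1L
  pos5 <- ifelse(strand == "+", start0, start0 + len[g] - 1L)
  list(reads = data.frame(chrom = chrom[g], pos5 = as.integer(pos5),
                          strand = strand, read_len = as.integer(len[g]),
                          stringsAsFactors = FALSE),
       n_skipped = sum(bad) + sum(!mapped))
}

#' Serialize reads as BED6
#'
#' Writes the read model back to BED6 (0-based half-open), the carrier format
#' of the synthetic benchmark datasets. `parse_alignments()` on the result
#' reproduces `chrom`, `pos5`, `strand` and `read_len` exactly.
#'
#' @param reads Read table as returned by [parse_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  validate_reads(reads)
  start <- ifelse(reads$strand == "+", reads$pos5,
                  reads$pos5 - reads$read_len + 1L)
  lines <- sprintf("%s\t%d\t%d\tr%d\t0\t%s", reads$chrom, start,
                   start + reads$read_len, seq_len(nrow(reads)), reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Derive a chromosome table from observed reads
#'
#' Chromosome length is taken as the maximum observed read end
#' (`pos5 + read_len` on the plus strand, `pos5 + 1` on the minus strand)
#' plus `slack`. Chromosomes iterate in lexicographic order.
#'
#' @param reads Read table.
#' @param slack Extra bp added to every derived length (default 0).
#' @return Named numeric vector of lengths, class `chrom_table`, with a
#'   `provenance` attribute of `"derived_from_reads"`.
#' @export
derive_chrom_table <- function(reads, slack = 0) {
  validate_reads(reads)
  if (nrow(reads) == 0L)
    stop_fatal("cannot derive a chromosome table from an empty read set")
  ends <- ifelse(reads$strand == "+", reads$pos5 + reads$read_len,
                 reads$pos5 + 1L)
  len <- tapply(ends, reads$chrom, max) + slack
  chrom_table(len[sort(names(len))], provenance = "derived_from_reads")
}

chrom_table <- function(lengths, provenance) {
  structure(as.numeric(lengths), names = names(lengths),
            provenance = provenance, class = "chrom_table")
}

#' @export
print.chrom_table <- function(x, ...) {
  cat("<chrom_table> ", length(x), " chromosome(s), ",
      attr(x, "provenance"), "\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Load a precomputed chromosome table
#'
#' Reads a two-column `name<TAB>length` file (UCSC chrom.sizes dialect).
#' Duplicate names, non-integer or non-positive lengths are fatal, with the
#' offending line number.
#'
#' @param path Path to the table.
#' @return A `chrom_table` with provenance `"precomputed"`.
#' @export
load_chrom_table <- function(path) {
  if (!file.exists(path)) stop_fatal("chromosome table not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "[\t ]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    lno <- which(keep)[i]
    if (length(f) != 2L)
      stop_fatal("chromosome table line ", lno, ": expected 2 fields")
    len <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(len) || len != floor(len) || len < 1)
      stop_fatal("chromosome table line ", lno,
                 ": length must be a positive integer, got '", f[2L], "'")
  }
  nm <- vapply(fields, `[`, "", 1L)
  dup <- duplicated(nm)
  if (any(dup))
    stop_fatal("chromosome table line ", which(keep)[which(dup)[1L]],
               ": duplicate chromosome '", nm[which(dup)[1L]], "'")
  len <- as.numeric(vapply(fields, `[`, "", 2L))
  names(len) <- nm
  chrom_table(len[sort(nm)], provenance = "precomputed")
}

#' Export a coverage profile as UCSC variableStep wiggle
#'
#' One `variableStep chrom=<name> span=<span>` header per chromosome;
#' positions are 1-based and zero-coverage positions are omitted. With
#' `compress = TRUE` the identical text is written gzip-compressed.
#'
#' @param profile A [build_coverage()] profile.
#' @param path Output path.
#' @param compress Write gzip-compressed bytes of the same text.
#' @param span Wiggle span in bp (default 1).
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(profile, path, compress = FALSE, span = 1) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (length(profile$cov) == 0L) stop_fatal("empty coverage profile")
  con <- if (compress) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  for (chrom in names(profile$cov)) {
    writeLines(sprintf("variableStep chrom=%s span=%d", chrom,
                       as.integer(span)), con)
    v <- profile$cov[[chrom]]
    nz <- which(v != 0L)
    if (length(nz))
      writeLines(paste(nz, v[nz]), con)
  }
  invisible(path)
}

#' Write called peaks
#'
#' Tab-delimited with a guaranteed BED6-compatible prefix: chrom, region
#' start (0-based), region end (half-open), region id, score =
#' -log10(q-value) capped at 330, strand ".". In resolution mode one row is
#' written per summit, with two extra columns: summit position (0-based) and
#' summit height.
#'
#' @param calls Region table from [call_regions()]/[call_peaks()], sorted by
#'   (chrom, start); a `summits` list-column is required in resolution mode.
#' @param path Output path.
#' @param mode `"region"` (one row per region) or `"resolution"` (one row per
#'   summit).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(calls, path, mode = c("region", "resolution")) {
  mode <- match.arg(mode)
  hdr <- c("#chrom", "start", "end", "name", "score", "strand")
  if (mode == "resolution") hdr <- c(hdr, "summit", "summit_height")
  lines <- paste(hdr, collapse = "\t")
  if (!is.null(calls) && nrow(calls)) {
    score <- peak_score(calls$q_value)
    id <- sprintf("region_%d", seq_len(nrow(calls)))
    base <- sprintf("%s\t%d\t%d\t%s\t%s\t.", calls$chrom,
                    as.integer(calls$start), as.integer(calls$end), id,
                    sprintf("%.6g", score))
    if (mode == "region") {
      lines <- c(lines, base)
    } else {
      rows <- lapply(seq_len(nrow(calls)), function(i) {
        s <- calls$summits[[i]]
        if (is.null(s) || nrow(s) == 0L) return(character())
        sprintf("%s\t%d\t%s", base[i], as.integer(s$pos),
                sprintf("%.6g", s$height))
      })
      lines <- c(lines, unlist(rows))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## -log10(q) capped at 330 (q = 0 maps to the cap).
peak_score <- function(q) {
  s <- -log10(q)
  s[!is.finite(s) | s > 330] <- 330
  s
}
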