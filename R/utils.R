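#' @keywords internal
"_PACKAGE"

## Run an expression under a fixed RNG seed without touching the caller's
## RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive independent sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_fatal <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x)

## Empty aligned-read table: the uniform internal read model.
empty_reads <- function() {
  data.frame(chrom = character(), pos5 = integer(), strand = character(),
             read_len = integer(), stringsAsFactors = FALSE)
}

validate_reads <- function(reads) {
  need <- c("chrom", "pos5", "strand", "read_len")
  if (!is.data.frame(reads) || !all(need %in% names(reads)))
    stop_fatal("reads must be a data.frame with columns ",
               paste(need, collapse = ", "))
  if (nrow(reads) && !all(reads$strand %in% c("+", "-")))
    stop_fatal("read strand must be '+' or '-'")
  if (nrow(reads) && any(reads$read_len < 1L))
    stop_fatal("read_len must be >= 1")
  invisible(reads)
}
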