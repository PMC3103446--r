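## End-to-end orchestration: presets, config files, the in-memory calling
## engine and the file-based run. Work is partitioned by chromosome
## (chromosome-level independence), gathered centrally for the scaling fit
## and the genome-wide FDR step, then partitioned again for summit calling.
## Output is byte-identical for any worker count.

#' Mode presets
#'
#' `"region"` targets broad histone-mark domains (delta 0.5, smoothing window
#' 31 bp, output keyed on regions); `"resolution"` targets punctate
#' transcription-factor sites (delta 0.8, smoothing window 5 bp, output keyed
#' on summits). Shared defaults: fragment length 200 bp, FDR cutoff 0.01,
#' per-bp threshold tail probability 1e-4, merge gap 100 bp,
#' comparable-heights filter off, scaling bins 10 kb.
#'
#' @param mode `"region"` or `"resolution"`.
#' @return Named list of preset defaults.
#' @export
apply_preset <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L ||
      !mode %in% c("region", "resolution"))
    stop_fatal("unknown mode '", paste(mode, collapse = ","),
               "'; use 'region' or 'resolution'")
  shared <- list(mode = mode, ext_len = 200L, fdr_cutoff = 0.01,
                 thr_p = 1e-4, max_gap = 100L, min_rel_height = 0,
                 workers = 1L, wiggle = "off", scaling_bin = 10000L,
                 seed = NULL, chrom_table_path = NULL)
  if (mode == "region") c(shared, list(delta = 0.5, smooth_window = 31L))
  else c(shared, list(delta = 0.8, smooth_window = 5L))
}

CONFIG_DOMAINS <- list(
  mode = function(v) v %in% c("region", "resolution"),
  ext_len = function(v) is_count(v) && v >= 1,
  fdr_cutoff = function(v) is.numeric(v) && v >= 0 && v <= 1,
  delta = function(v) is.numeric(v) && v > 0 && v < 1,
  smooth_window = function(v) is_count(v) && v >= 1 && v %% 2 == 1,
  max_gap = function(v) is_count(v) && v >= 0,
  thr_p = function(v) is.numeric(v) && v > 0 && v < 1,
  min_rel_height = function(v) is.numeric(v) && v >= 0 && v <= 1,
  workers = function(v) is_count(v) && v >= 1,
  wiggle = function(v) v %in% c("off", "plain", "gzip"),
  scaling_bin = function(v) is_count(v) && v >= 1,
  seed = function(v) is.null(v) || is_count(v),
  chrom_table_path = function(v) is.null(v) || is.character(v))

#' Build a full caller configuration
#'
#' Starts from the [apply_preset()] defaults for `mode`, overlays values read
#' from a config file (if any), then overlays explicit arguments; i.e.
#' explicit settings override the file, which overrides the preset. Every
#' field is validated against its domain.
#'
#' @param mode `"region"` or `"resolution"` (default `"resolution"`).
#' @param ... Explicit overrides (any preset field, e.g. `delta`,
#'   `fdr_cutoff`, `ext_len`, `smooth_window`, `max_gap`, `thr_p`,
#'   `min_rel_height`, `workers`, `wiggle`, `seed`, `chrom_table_path`).
#' @param config_file Optional `key = value` file parsed by [load_config()].
#' @return Validated config list of class `caller_config`.
#' @export
caller_config <- function(mode = "resolution", ..., config_file = NULL) {
  file_cfg <- if (!is.null(config_file)) load_config(config_file) else list()
  if (!missing(mode)) file_cfg$mode <- NULL  # an explicit mode wins
  eff_mode <- if (!is.null(file_cfg$mode)) file_cfg$mode else mode
  cfg <- utils::modifyList(apply_preset(eff_mode), file_cfg)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(CONFIG_DOMAINS))
  if (length(unknown))
    stop_fatal("unknown configuration field(s): ",
               paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, dots)
  for (key in names(CONFIG_DOMAINS)) {
    if (key %in% c("seed", "chrom_table_path") && is.null(cfg[[key]])) next
    if (!CONFIG_DOMAINS[[key]](cfg[[key]]))
      stop_fatal("configuration field '", key, "' has an invalid value: ",
                 paste(cfg[[key]], collapse = ","))
  }
  cfg$ext_len <- as.integer(cfg$ext_len)
  cfg$smooth_window <- as.integer(cfg$smooth_window)
  cfg$max_gap <- as.integer(cfg$max_gap)
  cfg$workers <- as.integer(cfg$workers)
  structure(cfg, class = "caller_config")
}

#' @export
print.caller_config <- function(x, ...) {
  cat("<caller_config> mode=", x$mode, " ext=", x$ext_len, " fdr=",
      x$fdr_cutoff, " delta=", x$delta, " smooth=", x$smooth_window,
      " max_gap=", x$max_gap, "\n", sep = "")
  invisible(x)
}

CONFIG_FILE_KEYS <- c(mode = "mode", ext = "ext_len", fdr = "fdr_cutoff",
                      delta = "delta", smooth = "smooth_window",
                      max_gap = "max_gap", thr_p = "thr_p",
                      min_rel_height = "min_rel_height", workers = "workers",
                      wiggle = "wiggle", genome = "chrom_table_path",
                      seed = "seed")

#' Parse a key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Recognized keys: `mode`,
#' `ext`, `fdr`, `delta`, `smooth`, `max_gap`, `thr_p`, `min_rel_height`,
#' `workers`, `wiggle`, `genome`, `seed`. Unknown keys or unparsable values
#' are fatal, with the line number. Returns only the keys present; precedence
#' against presets and flags is applied by [caller_config()].
#'
#' @param path Config file path.
#' @return Named list (a partial configuration).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_fatal("config file not found: ", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^\\s*([A-Za-z_.-]+)\\s*=\\s*(.*?)\\s*$",
                                  line))[[1L]]
    if (length(m) != 3L)
      stop_fatal("config line ", i, ": expected 'key = value'")
    key <- gsub("-", "_", m[2L])
    val <- m[3L]
    if (!key %in% names(CONFIG_FILE_KEYS))
      stop_fatal("config line ", i, ": unknown key '", m[2L], "'")
    field <- CONFIG_FILE_KEYS[[key]]
    parsed <- if (field %in% c("mode", "wiggle", "chrom_table_path")) val
      else suppressWarnings(as.numeric(val))
    if (!is.character(parsed) && is.na(parsed))
      stop_fatal("config line ", i, ": cannot parse value '", val,
                 "' for key '", m[2L], "'")
    if (!CONFIG_DOMAINS[[field]](parsed))
      stop_fatal("config line ", i, ": value '", val,
                 "' outside the domain of '", m[2L], "'")
    out[[field]] <- parsed
  }
  out
}

#' Call peaks from coverage profiles (in-memory engine)
#'
#' Runs [call_regions()] genome-wide and then fills each surviving region's
#' summits with [call_summits()] (parallel over chromosomes). This is the
#' core engine that [run_peak_caller()] wraps with file I/O.
#'
#' @param treat_profile Treatment `coverage_profile`.
#' @param ctrl_profile Optional control `coverage_profile`.
#' @param config A [caller_config()].
#' @return Region table as from [call_regions()], plus a `summits`
#'   list-column of `data.frame(pos, height)` per region.
#' @export
call_peaks <- function(treat_profile, ctrl_profile = NULL,
                       config = caller_config()) {
  regions <- call_regions(treat_profile, ctrl_profile, config,
                          workers = config$workers)
  regions$summits <- vector("list", nrow(regions))
  if (nrow(regions)) {
    chroms <- unique(regions$chrom)
    per_chrom <- run_parallel(chroms, function(chrom) {
      idx <- which(regions$chrom == chrom)
      cov <- treat_profile$cov[[chrom]]
      lapply(idx, function(i) call_summits(regions[i, ], cov, config))
    }, config$workers)
    names(per_chrom) <- chroms
    for (chrom in chroms)
      regions$summits[regions$chrom == chrom] <- per_chrom[[chrom]]
  }
  regions
}

#' Run the peak caller end to end
#'
#' Stages: parse alignments, resolve the chromosome table (precomputed or
#' derived from the input reads), build treatment/control coverage, detect
#' and score regions per chromosome, gather for the scaling fit and the
#' genome-wide FDR filter, call summits per chromosome, and write sorted
#' outputs: `<prefix>_regions.bed` (BED6-prefixed peak table; one row per
#' summit in resolution mode), `<prefix>_summits.txt`, an optional
#' `<prefix>.wig[.gz]` and `<prefix>.log`.
#'
#' @param treatment_path Treatment alignment file.
#' @param control_path Optional control alignment file.
#' @param config A [caller_config()].
#' @param output_prefix Path prefix for outputs.
#' @param format Alignment format for both inputs (`"auto"` by extension).
#' @return Invisibly, a list with `regions` (the filled region table),
#'   `files` (paths written) and `log` (stage counters).
#' @export
run_peak_caller <- function(treatment_path, control_path = NULL,
                            config = caller_config(),
                            output_prefix = "rangercall", format = "auto") {
  if (!file.exists(treatment_path))
    stop_fatal("[parse] treatment file not found: ", treatment_path)
  if (!is.null(control_path) && !file.exists(control_path))
    stop_fatal("[parse] control file not found: ", control_path)
  treat_reads <- parse_alignments(treatment_path, format)
  ctrl_reads <- if (!is.null(control_path))
    parse_alignments(control_path, format)
  tab <- if (!is.null(config$chrom_table_path))
    load_chrom_table(config$chrom_table_path)
  else derive_chrom_table(rbind(treat_reads,
                                if (is.null(ctrl_reads)) empty_reads()
                                else ctrl_reads))
  treat_profile <- build_coverage(treat_reads, config$ext_len, tab)
  ctrl_profile <- if (!is.null(ctrl_reads))
    build_coverage(ctrl_reads, config$ext_len, tab)
  regions <- call_peaks(treat_profile, ctrl_profile, config)

  files <- c(regions = paste0(output_prefix, "_regions.bed"),
             summits = paste0(output_prefix, "_summits.txt"),
             log = paste0(output_prefix, ".log"))
  write_peaks(regions, files[["regions"]],
              mode = if (config$mode == "resolution") "resolution" else "region")
  write_summit_table(regions, files[["summits"]])
  if (config$wiggle != "off") {
    wig <- paste0(output_prefix, ".wig",
                  if (config$wiggle == "gzip") ".gz" else "")
    write_wiggle(treat_profile, wig, compress = config$wiggle == "gzip")
    files <- c(files, wiggle = wig)
  }
  log <- c(
    sprintf("treatment_reads_parsed\t%d", attr(treat_reads, "n_parsed")),
    sprintf("treatment_reads_skipped\t%d", attr(treat_reads, "n_skipped")),
    if (!is.null(ctrl_reads))
      sprintf("control_reads_parsed\t%d", attr(ctrl_reads, "n_parsed")),
    sprintf("chromosomes\t%d", length(tab)),
    sprintf("chrom_table_provenance\t%s", attr(tab, "provenance")),
    sprintf("background_lambda\t%g", attr(regions, "lambda")),
    sprintf("depth_threshold\t%d", attr(regions, "threshold")),
    sprintf("candidate_regions\t%d", attr(regions, "n_candidates")),
    sprintf("regions_passing_fdr\t%d", nrow(regions)),
    sprintf("summits\t%d", sum(vapply(regions$summits, nrow, 0L))),
    "effective_config:",
    vapply(setdiff(names(CONFIG_DOMAINS), c("seed", "chrom_table_path")),
           function(k) sprintf("  %s\t%s", k, format(config[[k]])), ""))
  writeLines(log, files[["log"]])
  invisible(list(regions = regions, files = files, log = log))
}

write_summit_table <- function(regions, path) {
  lines <- "#chrom\tsummit\tsummit_end\tregion\theight"
  if (nrow(regions)) {
    id <- sprintf("region_%d", seq_len(nrow(regions)))
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      s <- regions$summits[[i]]
      if (is.null(s) || nrow(s) == 0L) return(character())
      sprintf("%s\t%d\t%d\t%s\t%s", regions$chrom[i], as.integer(s$pos),
              as.integer(s$pos) + 1L, id[i],
              sprintf("%.6g", s$height))
    })
    lines <- c(lines, unlist(rows))
  }
  writeLines(lines, path)
  invisible(path)
}
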