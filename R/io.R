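# Plain-text artifacts: memory dumps, tidy run logs, landscape exports,
# declarative JSON configs, and run manifests. Every CSV round-trips to
# full double precision ("%.17g").

#' Five-number boxplot summary with the 1.5 x IQR whisker rule
#'
#' Quartiles use the standard linear-interpolation (type-7) convention.
#' Whiskers extend to the most extreme observations within 1.5 x IQR of the
#' quartiles (clipped to the data); points beyond are outliers.
#'
#' @param values Numeric vector, length >= 1.
#' @return List of class `boxplot_summary`: `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `outliers`, `n`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) == 0L || any(!is.finite(values)))
    stop("need at least one finite value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(median = q[2L], q1 = q[1L], q3 = q[3L],
                 whisker_lo = min(values[inside]),
                 whisker_hi = max(values[inside]),
                 outliers = values[!inside],
                 n = length(values)),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf(
    "boxplot summary (n = %d): median %.3g [Q1 %.3g, Q3 %.3g], whiskers [%.3g, %.3g], %d outlier(s)\n",
    x$n, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi,
    length(x$outliers)))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read an episodic memory dump
#'
#' Plain-text CSV with header `what,when,cell,x,y,value`, one row per entry
#' (all entries, or only nonzero ones), preceded by a `#`-comment metadata
#' line carrying the array shape, grid size and object names so the reader
#' can reconstruct the memory exactly. Values are written with 17
#' significant digits and round-trip bit-exactly.
#'
#' @param mem An `epimem` with grid width/height metadata.
#' @param path Output file.
#' @param nonzero_only Drop all-zero entries (default keeps the dump small).
#' @return `write_memory()`: `path`, invisibly. `read_memory()`: the
#'   reconstructed `epimem`.
#' @export
write_memory <- function(mem, path, nonzero_only = TRUE) {
  stopifnot(inherits(mem, "epimem"))
  d <- dim(mem)
  width <- attr(mem, "width"); height <- attr(mem, "height")
  if (is.null(width)) stop("memory lacks grid metadata", call. = FALSE)
  wn <- attr(mem, "what_names")
  if (is.null(wn)) wn <- as.character(seq_len(d[1L]) - 1L)
  meta <- sprintf("# epimem n_what=%d n_when=%d width=%d height=%d what=%s",
                  d[1L], d[2L], width, height, paste(wn, collapse = "|"))
  v <- unclass(mem)
  idx <- if (nonzero_only) which(v != 0, arr.ind = TRUE)
         else arrayInd(seq_along(v), dim(v))
  lines <- c(meta, "what,when,cell,x,y,value")
  if (nrow(idx)) {
    cell <- idx[, 3L] - 1L
    lines <- c(lines, paste(wn[idx[, 1L]], idx[, 2L] - 1L, cell,
                            cell %% width, cell %/% width,
                            fmt_num(v[idx]), sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_memory
#' @export
read_memory <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec(
    "^# epimem n_what=(\\d+) n_when=(\\d+) width=(\\d+) height=(\\d+) what=(.*)$",
    first))[[1L]]
  if (length(m) != 6L) stop("not a memory dump: ", path, call. = FALSE)
  n_what <- as.integer(m[2L]); n_when <- as.integer(m[3L])
  width <- as.integer(m[4L]); height <- as.integer(m[5L])
  wn <- strsplit(m[6L], "|", fixed = TRUE)[[1L]]
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(what = "character"))
  mem <- make_memory(n_what, n_when, width * height, what_names = wn,
                     width = width, height = height)
  if (nrow(df)) {
    i <- match(df$what, wn)
    if (anyNA(i)) stop("unknown object name in dump", call. = FALSE)
    mem[cbind(i, df$when + 1L, df$cell + 1L)] <- df$value
  }
  mem
}

#' Write / read a tidy records log
#'
#' One row per (run, day, hour) decision-and-outcome record, plain CSV.
#'
#' @param records A records data.frame or result object.
#' @param path File path.
#' @return `write_records()`: `path`, invisibly. `read_records()`: the
#'   data.frame.
#' @export
write_records <- function(records, path) {
  if (inherits(records, "pp_result") || inherits(records, "elm_result"))
    records <- records$records
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export per-hour expected-value landscape tables
#'
#' Writes one CSV per hour of the day with columns
#' `what,x,y,value,magnitude` — the scatter-plot data of the
#' mental-time-travel readout. Selecting different hour files of the same
#' persistent memory is travelling forward or backward in time.
#'
#' @param mem An `epimem`, or the path of a [write_memory()] dump.
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix; files are `<prefix><hour>.csv`.
#' @return Character vector of the written paths, invisibly.
#' @export
export_landscape <- function(mem, out_dir, prefix = "landscape_hour_") {
  if (is.character(mem)) mem <- read_memory(mem)
  stopifnot(inherits(mem, "epimem"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ls_all <- landscape(mem)
  paths <- character(0)
  for (hh in seq_len(dim(mem)[2L]) - 1L) {
    sub <- ls_all[ls_all$when == hh,
                  c("what", "x", "y", "value", "magnitude"), drop = FALSE]
    p <- file.path(out_dir, paste0(prefix, hh, ".csv"))
    lines <- c("what,x,y,value,magnitude",
               if (nrow(sub)) paste(sub$what, sub$x, sub$y,
                                    fmt_num(sub$value), fmt_num(sub$magnitude),
                                    sep = ","))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Load a scenario configuration from a JSON file
#'
#' The file is a flat key-value document; keys must be arguments of
#' [elm_config()] / [pp_config()] (unknown keys are rejected) and missing
#' keys take the published defaults. The merged configuration is validated.
#'
#' @param path JSON file.
#' @param scenario `"elm"` or `"pp"`.
#' @return An `elm_config` or `pp_config`.
#' @export
load_config <- function(path, scenario = c("elm", "pp")) {
  scenario <- match.arg(scenario)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctor <- if (scenario == "elm") elm_config else pp_config
  known <- names(formals(ctor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(ctor, raw)
}

#' Write a run manifest
#'
#' A JSON snapshot of everything needed to reproduce a scenario's outputs:
#' scenario id, full configuration, base seed, the derived per-run seeds,
#' artifact paths and the package version.
#'
#' @param scenario Scenario id string.
#' @param config The scenario config used.
#' @param artifacts Named character vector/list of output paths.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(scenario, config, artifacts, path) {
  manifest <- list(
    scenario = scenario,
    package_version = as.character(utils::packageVersion("cuttlemem")),
    base_seed = config$base_seed,
    run_seeds = config$base_seed + seq_len(config$n_runs) - 1L,
    config = unclass(config),
    artifacts = as.list(artifacts)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
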