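#' Construct an ultrasonic A-scan trace
#'
#' An `ultrasonic_trace` holds one radio-frequency A-scan: the sampled
#' amplitude sequence together with its sampling rate and a label. The
#' default sampling rate (10 MHz) and the typical record length (2000
#' samples per pulse) match a 1 MHz pulse-echo acquisition front end for
#' plant stems.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units). Must
#'   contain at least 16 finite values; the pickers need a minimum of
#'   support on each side of a candidate change point.
#' @param sampling_rate Sampling rate in Hz (default `1e7`).
#' @param trace_id Character label for the trace.
#'
#' @return An object of class `ultrasonic_trace`: a list with elements
#'   `samples`, `sampling_rate` and `trace_id`.
#' @seealso [read_traces()], [aic_curve()], [pick_primary_echo()]
#' @export
#' @examples
#' tr <- ultrasonic_trace(sin(seq(0, 20, length.out = 200)), trace_id = "demo")
#' tr
ultrasonic_trace <- function(samples, sampling_rate = 1e7, trace_id = "trace") {
  samples <- as.numeric(samples)
  if (length(samples) < 16L) {
    stop("trace must contain at least 16 samples, got ", length(samples))
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("trace '", trace_id, "' contains non-finite samples")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         trace_id = as.character(trace_id)[1L]),
    class = "ultrasonic_trace"
  )
}

#' @export
print.ultrasonic_trace <- function(x, ...) {
  cat("<ultrasonic_trace> ", x$trace_id, "\n", sep = "")
  cat("  samples      : ", length(x$samples),
      sprintf("  (range %.4g .. %.4g)", min(x$samples), max(x$samples)), "\n",
      sep = "")
  cat("  sampling rate: ", format(x$sampling_rate, big.mark = ","), " Hz\n",
      sep = "")
  invisible(x)
}

# coerce numeric vectors on the fly so the pickers accept raw vectors too
as_trace <- function(x, trace_id = "trace") {
  if (inherits(x, "ultrasonic_trace")) return(x)
  ultrasonic_trace(x, trace_id = trace_id)
}

#' Convert between sample index and printed time units
#'
#' Picked onsets are reported both as 1-based sample indices and in the
#' printed time unit of the reference tables, where one unit spans 100
#' samples (sample 153 prints as 1.53). At a 10 MHz sampling rate this
#' printed unit corresponds to 10 microseconds of physical time; it is kept
#' as a display convention, not an SI claim.
#'
#' @param i Integer sample index (1-based), vectorised.
#' @param pu Time value in printed units, vectorised.
#'
#' @return `index_to_pu()` returns `i / 100`; `pu_to_index()` returns the
#'   integer index `round(100 * pu)`. The two are exact inverses on integer
#'   indices.
#' @export
#' @examples
#' index_to_pu(153)     # 1.53
#' pu_to_index(3.51)    # 351
index_to_pu <- function(i) {
  if (any(i < 1)) stop("sample index must be >= 1")
  i / 100
}

#' @rdname index_to_pu
#' @export
pu_to_index <- function(pu) {
  if (any(pu < 0)) stop("printed-time value must be >= 0")
  as.integer(round(100 * pu))
}

#' Construct an echo pick
#'
#' Bundles the result of the hybrid picker for one trace: the onset of the
#' primary echo plus the diagnostics needed to audit it (position of the
#' classical AIC global minimum and the peak value of the mixed curve).
#'
#' @param onset_index 1-based sample index of the picked primary-echo onset.
#' @param classic_min_index 1-based index of the global AIC minimum.
#' @param mixed_peak_value Value of the mixed differential-AIC curve at its
#'   maximum.
#' @param trace_id Label of the trace the pick belongs to.
#' @param n_samples Trace length, used to validate the pick.
#'
#' @return An object of class `echo_pick` with fields `trace_id`,
#'   `onset_index`, `onset_pu`, `classic_min_index`, `mixed_peak_value`.
#' @export
echo_pick <- function(onset_index, classic_min_index, mixed_peak_value,
                      trace_id, n_samples) {
  onset_index <- as.integer(onset_index)
  classic_min_index <- as.integer(classic_min_index)
  if (classic_min_index < 1L || classic_min_index > onset_index ||
      onset_index > n_samples) {
    stop("invalid pick: need 1 <= classic_min_index <= onset_index <= N ",
         sprintf("(got %d <= %d <= %d)", classic_min_index, onset_index,
                 n_samples))
  }
  structure(
    list(trace_id = as.character(trace_id)[1L],
         onset_index = onset_index,
         onset_pu = index_to_pu(onset_index),
         classic_min_index = classic_min_index,
         mixed_peak_value = as.numeric(mixed_peak_value)),
    class = "echo_pick"
  )
}

#' @export
print.echo_pick <- function(x, ...) {
  cat("<echo_pick> ", x$trace_id, "\n", sep = "")
  cat(sprintf("  primary echo onset : sample %d  (%.2f pu)\n",
              x$onset_index, x$onset_pu))
  cat(sprintf("  classic AIC minimum: sample %d  (%.2f pu)\n",
              x$classic_min_index, index_to_pu(x$classic_min_index)))
  cat(sprintf("  mixed-curve peak   : %.4g\n", x$mixed_peak_value))
  invisible(x)
}

#' Read A-scan traces from a delimited text file
#'
#' Reads one or more traces from plain delimited text: one amplitude column
#' per trace, optionally preceded by a single header line naming the traces.
#' Comma, tab or whitespace separation is auto-detected. Lines starting with
#' `#` are ignored, so files written by the command-line tools read back
#' unchanged.
#'
#' The sampling rate is taken from a sidecar configuration file
#' (`<path>.yaml`, `<path>.yml` or `<path>.json` holding a
#' `sampling_rate_hz` entry) when present, otherwise it defaults to 10 MHz.
#'
#' @param path Path to the trace file.
#' @param sampling_rate Sampling rate override in Hz; `NULL` (default) means
#'   sidecar-or-default.
#'
#' @return A list of [ultrasonic_trace] objects, one per column.
#' @export
read_traces <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty trace file: ", path)

  sep <- if (grepl("\t", lines[1L])) "\t" else if (grepl(",", lines[1L])) "," else ""
  split_row <- function(line) {
    if (sep == "") strsplit(trimws(line), "\\s+")[[1L]]
    else trimws(strsplit(line, sep, fixed = TRUE)[[1L]])
  }

  first <- split_row(lines[1L])
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  ids <- if (has_header) first else NULL
  body <- if (has_header) lines[-1L] else lines
  if (length(body) == 0L) stop("trace file has a header but no data: ", path)

  rows <- lapply(body, split_row)
  ncols <- length(rows[[1L]])
  if (any(vapply(rows, length, 1L) != ncols)) {
    bad <- which(vapply(rows, length, 1L) != ncols)[1L]
    stop("ragged row ", bad + has_header, " in ", path)
  }
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncols)
  for (r in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[r]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' at row %d, column %d of %s",
                   rows[[r]][bad[1L]], r + has_header, bad[1L], path))
    }
    mat[r, ] <- vals
  }

  if (is.null(ids)) {
    stem <- sub("\\.[^.]*$", "", basename(path))
    ids <- if (ncols == 1L) stem else paste0(stem, "_", seq_len(ncols))
  }
  rate <- if (!is.null(sampling_rate)) sampling_rate else sidecar_rate(path)
  lapply(seq_len(ncols), function(j) {
    ultrasonic_trace(mat[, j], sampling_rate = rate, trace_id = ids[j])
  })
}

# sampling rate from a sidecar yaml/json config, default 10 MHz
sidecar_rate <- function(path, default = 1e7) {
  for (ext in c(".yaml", ".yml", ".json")) {
    sc <- paste0(path, ext)
    if (file.exists(sc)) {
      cfg <- if (ext == ".json") jsonlite::fromJSON(sc) else yaml::read_yaml(sc)
      if (!is.null(cfg$sampling_rate_hz)) return(as.numeric(cfg$sampling_rate_hz))
    }
  }
  default
}

#' Write and read echo-pick tables
#'
#' Picks are stored as plain CSV with one row per trace and the five columns
#' `trace_id`, `onset_index`, `onset_pu`, `classic_min_index`,
#' `mixed_peak_value`. `read_picks()` skips `#` comment lines, so files with
#' provenance headers written by the command-line interface round-trip.
#'
#' @param picks A single [echo_pick] or a list of them.
#' @param path Output (or input) file path.
#'
#' @return `write_picks()` returns `path` invisibly; `read_picks()` returns
#'   a data frame with the five pick columns.
#' @export
write_picks <- function(picks, path) {
  if (inherits(picks, "echo_pick")) picks <- list(picks)
  if (length(picks) == 0L) stop("no picks to write")
  df <- do.call(rbind, lapply(picks, function(p) {
    stopifnot(inherits(p, "echo_pick"))
    data.frame(trace_id = p$trace_id, onset_index = p$onset_index,
               onset_pu = p$onset_pu, classic_min_index = p$classic_min_index,
               mixed_peak_value = p$mixed_peak_value,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_picks
#' @export
read_picks <- function(path) {
  if (!file.exists(path)) stop("pick file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("trace_id", "onset_index", "onset_pu", "classic_min_index",
            "mixed_peak_value")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("pick file lacks columns: ", paste(missing, collapse = ", "))
  }
  df[need]
}
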