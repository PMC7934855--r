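#' Write and read flow trace files
#'
#' Traces are stored as two-column comma-separated text with header
#' `time_s,flow_ml_s`, one row per sample, UTF-8, decimal point.
#'
#' @param trace a `breath_trace`.
#' @param path file path.
#' @return `write_trace_file` returns `path` invisibly.
#' @export
write_trace_file <- function(trace, path) {
  stopifnot(inherits(trace, "breath_trace"))
  t <- trace$t0 + (seq_along(trace$samples) - 1L) / trace$sampling_rate
  utils::write.csv(data.frame(time_s = t, flow_ml_s = trace$samples),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_file
#' @param invert if `TRUE`, flip the sign of the flow column (for rigs
#'   wired with expiration-positive polarity).
#' @param animal_id label to store on the trace; default is the file name
#'   without extension.
#' @param max_step_deviation tolerated relative deviation of successive
#'   time steps from the median step before resampling kicks in.
#' @param gap_factor a time step larger than `gap_factor` times the median
#'   step is treated as a recording dropout and raises an error naming its
#'   location.
#' @return `read_trace_file` returns a `breath_trace`. Mild sampling
#'   jitter (above `max_step_deviation`) is resolved by linear resampling
#'   onto the median step with a warning; dropouts, non-monotone time,
#'   non-numeric rows and empty files are errors.
#' @export
read_trace_file <- function(path, invert = FALSE, animal_id = NULL,
                            max_step_deviation = 0.01, gap_factor = 5) {
  if (!file.exists(path)) {
    stop("ingestion error: file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) {
      stop("ingestion error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (nrow(df) < 2L || ncol(df) < 2L) {
    stop("ingestion error in ", path,
         ": need at least 2 rows of (time, flow)", call. = FALSE)
  }
  tm <- df[[1L]]
  x <- df[[2L]]
  if (anyNA(tm) || anyNA(x)) {
    bad <- which(is.na(tm) | is.na(x))[1L]
    stop("ingestion error in ", path, ": non-numeric or missing value at ",
         "data line ", bad, call. = FALSE)
  }
  dt <- diff(tm)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L]
    stop("ingestion error in ", path, ": non-monotone time at data line ",
         bad + 1L, call. = FALSE)
  }
  med <- stats::median(dt)
  if (any(dt > gap_factor * med)) {
    bad <- which(dt > gap_factor * med)[1L]
    stop(sprintf(
      "ingestion error in %s: gap of %.6g s (%.1fx the median step) between data lines %d and %d",
      path, dt[bad], dt[bad] / med, bad, bad + 1L), call. = FALSE)
  }
  if (max(abs(dt - med)) > max_step_deviation * med) {
    warning("non-uniform sampling in ", path,
            "; resampling to the median step of ", format(med), " s")
    grid <- seq(tm[1L], tm[length(tm)], by = med)
    x <- stats::approx(tm, x, xout = grid)$y
    tm <- grid
  }
  if (invert) x <- -x
  if (is.null(animal_id)) {
    animal_id <- sub("\\.[^.]*$", "", basename(path))
  }
  breath_trace(x, sampling_rate = 1 / med, animal_id = animal_id,
               t0 = tm[1L])
}

#' Write and read breath tables
#'
#' Breath tables round-trip as tab-separated text with the segmentation
#' columns and any QC columns appended downstream.
#'
#' @param table a `breath_table`.
#' @param path file path.
#' @export
write_breath_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_breath_table
#' @param animal_id,sampling_rate metadata restored onto the table.
#' @export
read_breath_table <- function(path, animal_id = "unknown",
                              sampling_rate = NA_real_) {
  df <- utils::read.delim(path)
  as_breath_table(df, animal_id, sampling_rate)
}

#' Write a ground-truth schedule as TSV
#'
#' @param truth a GroundTruth data frame from [simulate_schedule()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
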