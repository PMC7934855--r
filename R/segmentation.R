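#' Segmentation parameters
#'
#' @param hysteresis flow threshold in mL/s for validating breath onsets.
#'   `NULL` (default) uses 5% of the trace's robust amplitude, measured as
#'   the interquartile range of the baseline-corrected flow, so the default
#'   is invariant to calibration scale.
#' @param min_insp_duration detector floor on inspiratory duration in
#'   seconds; candidate breaths shorter than this are discarded before any
#'   QC. Distinct from (and by default far below) the 0.025 s QC rule.
#' @param baseline_window width in seconds of the rolling-mean baseline
#'   estimate subtracted before crossing detection; `0` (default) subtracts
#'   the global mean instead. A rolling window tolerates slow drift from
#'   bias-flow imbalance; the mean is used rather than the median because
#'   volume-conserving breaths integrate to zero however asymmetric the
#'   waveform, while the median of a waveform with unequal
#'   inspiratory/expiratory fractions is a biased zero-flow estimate.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(hysteresis = NULL,
                                min_insp_duration = 0,
                                baseline_window = 0) {
  if (!is.null(hysteresis)) {
    check_positive(hysteresis, "hysteresis", strict = FALSE)
  }
  check_positive(min_insp_duration, "min_insp_duration", strict = FALSE)
  check_positive(baseline_window, "baseline_window", strict = FALSE)
  structure(list(hysteresis = hysteresis,
                 min_insp_duration = min_insp_duration,
                 baseline_window = baseline_window),
            class = "segmentation_params")
}

#' Construct a flow trace object
#'
#' @param samples numeric vector of calibrated flow values in mL/s
#'   (positive = inspiration by convention).
#' @param sampling_rate sampling frequency in Hz.
#' @param animal_id label.
#' @param t0 time of the first sample in seconds.
#' @return an object of class `breath_trace`.
#' @export
breath_trace <- function(samples, sampling_rate, animal_id = "unknown",
                         t0 = 0) {
  check_positive(sampling_rate, "sampling_rate")
  if (length(samples) < 2L) {
    stop("invalid trace: need at least 2 samples", call. = FALSE)
  }
  if (anyNA(samples)) {
    stop("invalid trace: missing values in flow samples", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 animal_id = animal_id, t0 = t0),
            class = "breath_trace")
}

# Baseline-corrected flow: subtract a centred rolling mean (window in
# seconds) or the global mean when window == 0. The mean, not the median,
# estimates zero flow here: breaths that conserve volume integrate to zero
# regardless of inspiratory/expiratory asymmetry, whereas the median of an
# asymmetric waveform (inspiration shorter than expiration) is biased.
remove_baseline <- function(x, fs, window) {
  if (window <= 0) return(x - mean(x))
  n <- length(x)
  k <- max(3L, as.integer(round(window * fs)))
  if (k >= n) return(x - mean(x))
  half <- k %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  x - (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment a flow trace into breaths
#'
#' Breaths are delimited by upward zero-crossings of the baseline-corrected
#' flow, validated by hysteresis: an onset is the zero-crossing preceding
#' an excursion above `+h` that itself follows an excursion below `-h`
#' (h = the hysteresis threshold). Inspiration runs from the onset to the
#' next non-positive sample; expiration fills the remainder of the breath
#' up to the next onset (so any end-expiratory pause is counted within the
#' expiratory time under this onset-to-onset convention). Inspired and
#' expired tidal volumes are trapezoidal integrals of the two phases; the
#' final incomplete breath (no successor onset) is dropped.
#'
#' @param trace a `breath_trace` (see [breath_trace()], [read_trace_file()],
#'   [simulate_trace()]).
#' @param params a [segmentation_params()].
#' @return a `breath_table`: a data frame with columns `index` (0-based),
#'   `onset_s`, `ti_s`, `te_s`, `vti_ml`, `vte_ml`, `length_s`, `rate_bpm`,
#'   plus attributes `animal_id` and `sampling_rate`. Fewer than two
#'   detected onsets give an empty table with a warning, not an error.
#' @export
segment_breaths <- function(trace, params = segmentation_params()) {
  stopifnot(inherits(trace, "breath_trace"))
  stopifnot(inherits(params, "segmentation_params"))
  fs <- trace$sampling_rate
  x <- remove_baseline(trace$samples, fs, params$baseline_window)
  n <- length(x)

  h <- params$hysteresis
  if (is.null(h)) h <- 0.05 * stats::IQR(x)
  if (h <= 0) h <- .Machine$double.eps

  # Hysteresis state: +1 after exceeding +h, -1 after dropping below -h,
  # carried forward through the dead band.
  s <- integer(n)
  s[x > h] <- 1L
  s[x < -h] <- -1L
  nz <- which(s != 0L)
  if (length(nz) == 0L) {
    warning("no flow excursions beyond the hysteresis threshold; ",
            "returning an empty breath table")
    return(empty_breath_table(trace))
  }
  filled <- s[nz][pmax(findInterval(seq_len(n), nz), 1L)]
  filled[seq_len(nz[1L] - 1L)] <- 0L

  # An onset needs a -1 (sub-threshold expiration) beforehand; the single
  # possible 0 -> 1 transition at the start of the trace also counts, so
  # the first breath is not structurally missed.
  up <- which(filled[-1L] == 1L & filled[-n] != 1L) + 1L

  # Map each validated threshold crossing back to the preceding upward
  # zero-crossing; that crossing is the breath onset.
  zc_up <- which(x[-n] <= 0 & x[-1L] > 0) # index of last non-positive sample
  onset_idx <- integer(0)
  if (length(up)) {
    pos <- findInterval(up - 1L, zc_up)
    onset_idx <- unique(zc_up[pos[pos >= 1L]] + 1L)
    # A trace that starts inside the dead band and rises (no zero-crossing
    # on record) begins at an onset: take the first sample.
    if (any(pos == 0L) && x[1L] <= h) onset_idx <- union(1L, onset_idx)
  }

  if (length(onset_idx) < 2L) {
    warning("fewer than 2 breath onsets detected; ",
            "returning an empty breath table")
    return(empty_breath_table(trace))
  }

  # First non-positive sample after each onset ends the inspiration.
  zc_dn <- which(x[-n] > 0 & x[-1L] <= 0) + 1L # first non-positive sample
  m <- length(onset_idx)
  insp_end <- zc_dn[findInterval(onset_idx, zc_dn) + 1L]

  o <- onset_idx[-m]
  nxt <- onset_idx[-1L]
  e <- insp_end[-m]
  ok <- !is.na(e) & e <= nxt
  e[!ok] <- nxt[!ok] # degenerate: inspiration runs to the next onset

  # Sub-sample crossing times by linear interpolation, so durations are
  # not quantized to the sample grid (keeps duration estimates stable
  # under resampling). Upward crossing between samples i and i+1; the
  # forced trace-start onset (index 1) has no bracketing pair.
  up_cross_time <- function(i) {
    f <- ifelse(i > 1L, x[pmax(i - 1L, 1L)] / (x[pmax(i - 1L, 1L)] - x[i]), 1)
    f[!is.finite(f)] <- 0
    (i - 2L + f) / fs
  }
  dn_cross_time <- function(i) { # x[i-1] > 0 >= x[i]
    f <- x[i - 1L] / (x[i - 1L] - x[i])
    f[!is.finite(f)] <- 0
    (i - 2L + f) / fs
  }
  onset_t <- up_cross_time(onset_idx)

  ct <- cumtrapz(x, 1 / fs)
  ti <- dn_cross_time(e) - onset_t[-m]
  len <- diff(onset_t)
  te <- len - ti
  vti <- ct[e] - ct[o]
  vte <- abs(ct[nxt] - ct[e])

  keep <- ti >= params$min_insp_duration & ti > 0 & te > 0
  tab <- data.frame(index = seq_len(sum(keep)) - 1L,
                    onset_s = trace$t0 + onset_t[-m][keep],
                    ti_s = ti[keep],
                    te_s = te[keep],
                    vti_ml = pmax(vti[keep], 0),
                    vte_ml = vte[keep],
                    length_s = len[keep],
                    rate_bpm = 60 / len[keep])
  as_breath_table(tab, trace$animal_id, fs)
}

as_breath_table <- function(df, animal_id, sampling_rate) {
  structure(df, class = c("breath_table", "data.frame"),
            animal_id = animal_id, sampling_rate = sampling_rate)
}

empty_breath_table <- function(trace) {
  as_breath_table(
    data.frame(index = integer(0), onset_s = numeric(0), ti_s = numeric(0),
               te_s = numeric(0), vti_ml = numeric(0), vte_ml = numeric(0),
               length_s = numeric(0), rate_bpm = numeric(0)),
    trace$animal_id, trace$sampling_rate)
}

#' Match detected breaths to a ground-truth schedule
#'
#' Greedy one-to-one matching of detected onsets to true onsets within a
#' time tolerance, walking both sorted sequences once. Used to score the
#' segmenter against the simulator's ground truth.
#'
#' @param table a `breath_table` from [segment_breaths()].
#' @param truth a GroundTruth data frame from [simulate_schedule()].
#' @param tolerance maximum |detected - true| onset difference in seconds
#'   for a match.
#' @return a list with `hits`, `misses` (true breaths with no detection),
#'   `spurious` (detections with no true breath), `hit_rate`
#'   (hits / true count), and `matches` (data frame of matched index pairs
#'   with onset errors).
#' @export
attach_ground_truth <- function(table, truth, tolerance = 0.01) {
  det <- table$onset_s
  tru <- truth$onset_s
  i <- 1L; j <- 1L
  mi <- integer(0); mj <- integer(0)
  while (i <= length(det) && j <= length(tru)) {
    d <- det[i] - tru[j]
    if (abs(d) <= tolerance) {
      mi <- c(mi, i); mj <- c(mj, j)
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  hits <- length(mi)
  list(hits = hits,
       misses = length(tru) - hits,
       spurious = length(det) - hits,
       hit_rate = if (length(tru)) hits / length(tru) else NA_real_,
       matches = data.frame(detected = mi, true = mj,
                            onset_error_s = det[mi] - tru[mj]))
}
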