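#' Interbreath-interval irregularity series
#'
#' IBII for a pair of consecutive breaths is
#' `|length(n+1) - length(n)| / length(n)`; it is 0 for perfectly regular
#' breathing and scale-invariant. Only pairs of breaths that were
#' consecutive in the original recording are eligible: a gap in the
#' original `index` column (an excluded breath between them) breaks the
#' chain, and the pair is skipped rather than bridged.
#'
#' @param table a reliable `breath_table` (e.g. `apply_qc(...)$reliable`),
#'   ordered by original index.
#' @return numeric vector of IBII values (empty if fewer than 2 eligible
#'   pairs).
#' @export
ibii_series <- function(table) {
  n <- nrow(table)
  if (n < 2L) return(numeric(0))
  consecutive <- diff(table$index) == 1L
  l <- table$length_s
  (abs(diff(l)) / l[-n])[consecutive]
}

#' Summarize one animal's respiration
#'
#' Computes the per-animal respiratory metrics from the reliable breaths:
#' `frequency` is the mean instantaneous rate (60/length, breaths/min),
#' `tidal_volume` the mean inspired volume (mL), `minute_ventilation`
#' their product (mL/min, exact by construction), and `ibii_mean` the mean
#' of [ibii_series()]. When the animal is excluded (fewer reliable breaths
#' than the QC minimum) all metrics are `NA`.
#'
#' @param table the reliable `breath_table` from [apply_qc()].
#' @param report the matching `qc_report`.
#' @return a one-row data frame of class `animal_summary` with columns
#'   `animal_id`, `n_reliable`, `frequency`, `tidal_volume`,
#'   `minute_ventilation`, `ibii_mean`, `ibii_n_pairs`, `animal_excluded`.
#' @export
summarize_animal <- function(table, report) {
  stopifnot(inherits(report, "qc_report"))
  excluded <- isTRUE(report$animal_excluded) || nrow(table) == 0L
  ibii <- ibii_series(table)
  if (excluded) {
    out <- data.frame(animal_id = report$animal_id,
                      n_reliable = nrow(table),
                      frequency = NA_real_, tidal_volume = NA_real_,
                      minute_ventilation = NA_real_, ibii_mean = NA_real_,
                      ibii_n_pairs = NA_integer_, animal_excluded = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    f <- mean(table$rate_bpm)
    vt <- mean(table$vti_ml)
    out <- data.frame(animal_id = report$animal_id,
                      n_reliable = nrow(table),
                      frequency = f, tidal_volume = vt,
                      minute_ventilation = f * vt,
                      ibii_mean = if (length(ibii)) mean(ibii) else NA_real_,
                      ibii_n_pairs = length(ibii),
                      animal_excluded = FALSE,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("animal_summary", "data.frame")
  out
}
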