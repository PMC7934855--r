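#' QC configuration
#'
#' Thresholds of the artifact-rejection cascade. Defaults are the published
#' constants: breaths with an inspiratory time under 0.025 s, an expiratory
#' time over 10 s, or an expired tidal volume more than twice the inspired
#' one are excluded; a sliding window of 200 breaths removes intervals in
#' which more than 10% of breaths are faster than 600 breaths/min; animals
#' with fewer than 100 reliable breaths are excluded. All comparisons are
#' strict, so boundary-equal breaths are retained.
#'
#' @param ti_min inspiratory-time floor in seconds.
#' @param te_max expiratory-time ceiling in seconds.
#' @param vte_vti_ratio_max maximum allowed expired/inspired volume ratio.
#' @param window_len sliding-window length in breaths.
#' @param fast_fraction_max fraction of fast breaths above which a window
#'   is rejected (strictly more than).
#' @param fast_rate instantaneous rate in breaths/min above which a breath
#'   counts as fast (strictly faster than).
#' @param min_reliable_breaths animal-level reliability minimum.
#' @param window_scope `"survivors"` (default) runs the window filter over
#'   the breaths that passed the per-breath rules; `"all"` runs it over
#'   every breath. The original analysis code's order is not recoverable;
#'   filtering survivors avoids counting movement spikes twice.
#' @param window_action `"interval"` (default) excludes every breath of a
#'   rejected window; `"fast_only"` excludes only the fast breaths within
#'   rejected windows.
#' @return an object of class `qc_config`. Non-default thresholds are
#'   recorded and echoed in the QC report.
#' @export
qc_config <- function(ti_min = 0.025,
                      te_max = 10,
                      vte_vti_ratio_max = 2,
                      window_len = 200,
                      fast_fraction_max = 0.10,
                      fast_rate = 600,
                      min_reliable_breaths = 100,
                      window_scope = c("survivors", "all"),
                      window_action = c("interval", "fast_only")) {
  check_positive(ti_min, "ti_min")
  check_positive(te_max, "te_max")
  check_positive(vte_vti_ratio_max, "vte_vti_ratio_max")
  check_positive(window_len, "window_len")
  check_positive(fast_rate, "fast_rate")
  check_positive(min_reliable_breaths, "min_reliable_breaths")
  if (!is.numeric(fast_fraction_max) || length(fast_fraction_max) != 1L ||
      is.na(fast_fraction_max) || fast_fraction_max <= 0 ||
      fast_fraction_max >= 1) {
    stop("invalid config: `fast_fraction_max` must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (window_len < 1) {
    stop("invalid config: `window_len` must be >= 1", call. = FALSE)
  }
  cfg <- structure(list(ti_min = ti_min, te_max = te_max,
                        vte_vti_ratio_max = vte_vti_ratio_max,
                        window_len = as.integer(window_len),
                        fast_fraction_max = fast_fraction_max,
                        fast_rate = fast_rate,
                        min_reliable_breaths = as.integer(min_reliable_breaths),
                        window_scope = match.arg(window_scope),
                        window_action = match.arg(window_action)),
                   class = "qc_config")
  defaults <- list(ti_min = 0.025, te_max = 10, vte_vti_ratio_max = 2,
                   window_len = 200L, fast_fraction_max = 0.10,
                   fast_rate = 600, min_reliable_breaths = 100L,
                   window_scope = "survivors", window_action = "interval")
  changed <- names(defaults)[!mapply(identical, cfg[names(defaults)], defaults)]
  attr(cfg, "non_default") <- changed
  cfg
}

#' Flag per-breath artifacts
#'
#' Sets the three per-breath artifact flags. Each flag is a pure function
#' of the breath and the thresholds (no neighbourhood dependence):
#' `artifact_ti` iff `ti < ti_min`, `artifact_te` iff `te > te_max`,
#' `artifact_ratio` iff `vte > vte_vti_ratio_max * vti`. A breath with
#' `vti = 0` and `vte > 0` is ratio-flagged; one with `vti = vte = 0` is
#' not (0 > 2*0 is false either way — the convention falls out of the
#' strict inequality).
#'
#' @param table a `breath_table`.
#' @param cfg a [qc_config()].
#' @return the table with logical columns `artifact_ti`, `artifact_te`,
#'   `artifact_ratio` appended (other columns untouched).
#' @export
flag_artifact_breaths <- function(table, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  table$artifact_ti <- table$ti_s < cfg$ti_min
  table$artifact_te <- table$te_s > cfg$te_max
  table$artifact_ratio <- table$vte_ml > cfg$vte_vti_ratio_max * table$vti_ml
  table
}

#' Flag breaths inside rejected fast-breathing windows
#'
#' Evaluates every contiguous window of `window_len` breaths (step 1) over
#' the filter scope (by default, breaths that passed the per-breath rules).
#' A window is rejected iff its count of breaths with rate strictly above
#' `fast_rate` strictly exceeds `fast_fraction_max * window_len`; every
#' breath covered by at least one rejected window gets
#' `in_fast_window = TRUE` (or, with `window_action = "fast_only"`, only
#' the fast breaths within rejected windows do). If fewer than
#' `window_len` breaths are in scope, the whole sequence is a single
#' window, so the rule still applies to short recordings.
#'
#' @param table a `breath_table`, already run through
#'   [flag_artifact_breaths()] when `window_scope = "survivors"`.
#' @param cfg a [qc_config()].
#' @return the table with a logical `in_fast_window` column appended.
#' @export
flag_fast_windows <- function(table, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  table$in_fast_window <- logical(nrow(table))
  if (nrow(table) == 0L) return(table)

  if (cfg$window_scope == "survivors") {
    need <- c("artifact_ti", "artifact_te", "artifact_ratio")
    if (!all(need %in% names(table))) {
      stop("per-breath artifact flags must be computed before the window filter",
           call. = FALSE)
    }
    scope <- which(!(table$artifact_ti | table$artifact_te |
                       table$artifact_ratio))
  } else {
    scope <- seq_len(nrow(table))
  }
  if (length(scope) == 0L) return(table)

  fast <- table$rate_bpm[scope] > cfg$fast_rate
  n <- length(fast)
  w <- min(cfg$window_len, n)
  limit <- cfg$fast_fraction_max * w

  # rolling count of fast breaths in each window of w, step 1
  cs <- c(0, cumsum(fast))
  counts <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  bad_start <- which(counts > limit)

  covered <- logical(n)
  if (length(bad_start)) {
    delta <- integer(n + 1L)
    delta[bad_start] <- delta[bad_start] + 1L
    ends <- bad_start + w
    delta[ends] <- delta[ends] - 1L
    covered <- cumsum(delta[seq_len(n)]) > 0L
  }
  if (cfg$window_action == "fast_only") covered <- covered & fast

  table$in_fast_window[scope] <- covered
  table
}

#' Apply the full QC cascade
#'
#' Runs [flag_artifact_breaths()] then [flag_fast_windows()], derives the
#' per-breath `reliable` flag (no flag set) and the first-failing
#' `exclusion_reason` (checked in the order ti, te, ratio, fast_window),
#' and assembles the QC report. Animal-level exclusion (fewer reliable
#' breaths than the minimum) is a report field, never an error.
#'
#' @param table a `breath_table` from [segment_breaths()].
#' @param cfg a [qc_config()].
#' @return a list of class `qc_result` with elements
#'   \describe{
#'     \item{flagged}{the input table with all QC columns appended;}
#'     \item{reliable}{the reliable breaths only, re-indexed in `index`
#'       order but retaining original `index` and `onset_s`;}
#'     \item{report}{a `qc_report` list: per-reason exclusion counts,
#'       `n_input`, `n_reliable`, `animal_excluded`, the configuration and
#'       which of its fields are non-default.}
#'   }
#' @export
apply_qc <- function(table, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  tab <- flag_artifact_breaths(table, cfg)
  tab <- flag_fast_windows(tab, cfg)
  tab$reliable <- !(tab$artifact_ti | tab$artifact_te | tab$artifact_ratio |
                      tab$in_fast_window)
  reason <- character(nrow(tab))
  reason[tab$in_fast_window] <- "fast_window"
  reason[tab$artifact_ratio] <- "vte_vti_ratio"
  reason[tab$artifact_te] <- "te_over_max"
  reason[tab$artifact_ti] <- "ti_under_min"
  tab$exclusion_reason <- reason

  reliable <- tab[tab$reliable, , drop = FALSE]
  rownames(reliable) <- NULL
  reliable <- as_breath_table(reliable, attr(table, "animal_id"),
                              attr(table, "sampling_rate"))

  report <- structure(list(
    animal_id = attr(table, "animal_id"),
    n_input = nrow(tab),
    n_reliable = nrow(reliable),
    n_excluded = nrow(tab) - nrow(reliable),
    excluded_by_reason = table(factor(
      reason[reason != ""],
      levels = c("ti_under_min", "te_over_max", "vte_vti_ratio",
                 "fast_window"))),
    animal_excluded = nrow(reliable) < cfg$min_reliable_breaths,
    config = cfg,
    non_default_config = attr(cfg, "non_default")
  ), class = "qc_report")

  structure(list(flagged = as_breath_table(tab, attr(table, "animal_id"),
                                           attr(table, "sampling_rate")),
                 reliable = reliable,
                 report = report),
            class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report for %s\n", x$animal_id))
  cat(sprintf("  breaths: %d in, %d reliable, %d excluded\n",
              x$n_input, x$n_reliable, x$n_excluded))
  for (r in names(x$excluded_by_reason)) {
    cat(sprintf("    %-14s %d\n", r, x$excluded_by_reason[[r]]))
  }
  cat(sprintf("  animal excluded (< %d reliable breaths): %s\n",
              x$config$min_reliable_breaths, x$animal_excluded))
  if (length(x$non_default_config)) {
    cat("  non-default thresholds:",
        paste(x$non_default_config, collapse = ", "), "\n")
  }
  invisible(x)
}
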