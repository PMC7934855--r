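# Shared fixtures: hand-built breath tables and the brute-force window
# oracle used to cross-check the optimized sliding-window filter.

# Build a breath table directly from per-breath fields (bypassing
# segmentation) so QC and metrics can be tested on exact values.
make_table <- function(lengths, ti = NULL, vti = 0.2, vte = NULL,
                       animal_id = "fixture") {
  n <- length(lengths)
  if (is.null(ti)) ti <- 0.4 * lengths
  if (is.null(vte)) vte <- vti
  tab <- data.frame(index = seq_len(n) - 1L,
                    onset_s = cumsum(c(0, lengths[-n])),
                    ti_s = rep_len(ti, n),
                    te_s = lengths - rep_len(ti, n),
                    vti_ml = rep_len(vti, n),
                    vte_ml = rep_len(vte, n),
                    length_s = lengths,
                    rate_bpm = 60 / lengths)
  breathkit:::as_breath_table(tab, animal_id, 1000)
}

# A table of n regular breaths at `rate` bpm with `fast_at` positions
# replaced by breaths at `fast_rate_bpm`.
make_rate_table <- function(n, rate = 150, fast_at = integer(0),
                            fast_rate_bpm = 700) {
  lengths <- rep(60 / rate, n)
  lengths[fast_at] <- 60 / fast_rate_bpm
  make_table(lengths)
}

# Independent O(n * w) sliding-window oracle: enumerate every window
# directly and mark all breaths of every rejected window.
oracle_fast_windows <- function(rates, window_len, fast_fraction_max,
                                fast_rate) {
  n <- length(rates)
  fast <- rates > fast_rate
  w <- min(window_len, n)
  flagged <- logical(n)
  for (start in seq_len(n - w + 1L)) {
    idx <- start:(start + w - 1L)
    if (sum(fast[idx]) > fast_fraction_max * w) flagged[idx] <- TRUE
  }
  flagged
}

# Quick simulator configs for tests (short, clean by default).
quick_config <- function(duration = 60, base_rate = 150, irregularity = 0,
                         seed = 1, ...) {
  sim_config(duration = duration, base_rate = base_rate,
             irregularity = irregularity, seed = seed, ...)
}
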