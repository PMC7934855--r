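#' Map an IBII target to the lognormal jitter width
#'
#' Breath lengths are drawn as `L = T0 * exp(sigma * Z + sigma^2 / 2)` with
#' `Z ~ N(0, 1)` i.i.d.; the `+ sigma^2 / 2` term centres the jitter so the
#' expected instantaneous rate `E[60 / L]` equals the configured base rate.
#' For this model the population mean IBII has the closed form
#' `exp(sigma^2) * (2 * pnorm(sigma * sqrt(2)) - 1)`, which is inverted
#' numerically here.
#'
#' @param target desired mean IBII (>= 0).
#' @return the lognormal sigma achieving the target.
#' @keywords internal
#' @export
ibii_target_to_sigma <- function(target) {
  check_positive(target, "irregularity", strict = FALSE)
  if (target == 0) return(0)
  f <- function(s) exp(s^2) * (2 * stats::pnorm(s * sqrt(2)) - 1) - target
  stats::uniroot(f, c(1e-8, 5), tol = 1e-12)$root
}

# Population mean IBII for a given lognormal sigma (inverse of the above).
sigma_to_mean_ibii <- function(sigma) {
  exp(sigma^2) * (2 * stats::pnorm(sigma * sqrt(2)) - 1)
}

#' Simulate a breath schedule (ground truth only)
#'
#' Draws the per-breath schedule that [simulate_trace()] renders into a
#' sampled flow signal: onset times, inspiratory/expiratory durations,
#' inspired/expired volumes, and artifact labels. Useful on its own when
#' only ground-truth summaries are needed (e.g. large Monte-Carlo studies
#' that would be wasteful at the waveform level).
#'
#' @param config a [sim_config()].
#' @return a `data.frame` (the GroundTruth) with one row per breath and
#'   columns `onset_s`, `ti_s`, `te_s`, `vti_ml`, `vte_ml`, `length_s`,
#'   `is_artifact`, `artifact_kind`.
#' @export
simulate_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  t0 <- 60 / config$base_rate
  sigma <- ibii_target_to_sigma(config$irregularity)
  n_guess <- ceiling(config$duration / t0 * 1.5) + 20L

  lengths <- t0 * exp(sigma * stats::rnorm(n_guess) + sigma^2 / 2)
  while (sum(lengths) < config$duration) {
    lengths <- c(lengths, t0 * exp(sigma * stats::rnorm(n_guess) + sigma^2 / 2))
  }

  vt <- config$base_tidal_volume
  gt <- data.frame(
    length_s = lengths,
    ti_s = config$insp_fraction * lengths,
    vti_ml = vt,
    vte_ml = vt,
    is_artifact = FALSE,
    artifact_kind = "",
    stringsAsFactors = FALSE
  )
  gt$te_s <- gt$length_s - gt$ti_s

  gt <- inject_artifacts(gt, config)

  gt$onset_s <- cumsum(c(0, gt$length_s[-nrow(gt)]))
  keep <- gt$onset_s + gt$length_s <= config$duration + 1e-9
  gt <- gt[keep, , drop = FALSE]
  rownames(gt) <- NULL
  gt[, c("onset_s", "ti_s", "te_s", "vti_ml", "vte_ml", "length_s",
         "is_artifact", "artifact_kind")]
}

# Replace/modify scheduled breaths with artifact events. Event counts are
# Poisson at the configured per-minute rates; placements are uniform over
# breaths not already claimed by another artifact.
inject_artifacts <- function(gt, config) {
  rates <- config$artifact_rates
  pars <- config$artifact_params
  minutes <- config$duration / 60
  used <- rep(FALSE, nrow(gt))

  pick_free <- function(span) {
    free <- which(!used)
    free <- free[free + span - 1L <= nrow(gt)]
    if (!length(free)) return(NA_integer_)
    for (attempt in seq_len(20L)) {
      i <- free[sample.int(length(free), 1L)]
      if (!any(used[i:(i + span - 1L)])) return(i)
    }
    NA_integer_
  }

  # Sniff burst: a contiguous run of fast, shallow breaths.
  n_burst <- stats::rpois(1, rates$sniff_burst * minutes)
  for (b in seq_len(n_burst)) {
    len <- as.integer(pars$burst_len)
    i <- pick_free(len)
    if (is.na(i)) next
    idx <- i:(i + len - 1L)
    blen <- 60 / pars$burst_rate
    bvt <- config$base_tidal_volume * pars$burst_volume_scale
    gt$length_s[idx] <- blen
    gt$ti_s[idx] <- config$insp_fraction * blen
    gt$te_s[idx] <- blen - gt$ti_s[idx]
    gt$vti_ml[idx] <- bvt
    gt$vte_ml[idx] <- bvt
    gt$is_artifact[idx] <- TRUE
    gt$artifact_kind[idx] <- "sniff_burst"
    used[idx] <- TRUE
  }

  one_breath_artifact <- function(gt, kind, n_events, mutate) {
    for (e in seq_len(n_events)) {
      i <- pick_free(1L)
      if (is.na(i)) next
      gt[i, ] <- mutate(gt[i, ])
      gt$is_artifact[i] <- TRUE
      gt$artifact_kind[i] <- kind
      used[i] <<- TRUE
    }
    gt
  }

  gt <- one_breath_artifact(
    gt, "long_expiration",
    stats::rpois(1, rates$long_expiration * minutes),
    function(row) {
      row$te_s <- pars$long_exp_duration
      row$length_s <- row$ti_s + row$te_s
      row
    })

  gt <- one_breath_artifact(
    gt, "asymmetric_volume",
    stats::rpois(1, rates$asymmetric_volume * minutes),
    function(row) {
      row$vte_ml <- pars$vte_vti_ratio * row$vti_ml
      row
    })

  gt <- one_breath_artifact(
    gt, "movement_spike",
    stats::rpois(1, rates$movement_spike * minutes),
    function(row) row)  # waveform distortion only; schedule unchanged

  gt
}

#' Simulate a calibrated flow trace with ground truth
#'
#' Renders the breath schedule from [simulate_schedule()] into a uniformly
#' sampled flow signal. Each breath is a positive half-sine (inspiration)
#' followed by a negative half-sine (expiration); amplitudes are set
#' analytically so the half-wave time-integrals equal the scheduled
#' inspired and expired volumes. Movement-spike artifacts add a short
#' biphasic high-amplitude transient inside the affected breath; bias flow
#' adds a constant offset and `noise_sd` adds white noise.
#'
#' @param config a [sim_config()].
#' @param animal_id label stored on the trace.
#' @return a list with elements `trace` (a `breath_trace`: `samples` in
#'   mL/s, `sampling_rate`, `animal_id`, `t0`) and `truth` (the
#'   GroundTruth data frame, see [simulate_schedule()]).
#' @examples
#' sim <- simulate_trace(sim_config(duration = 10, irregularity = 0, seed = 7))
#' str(sim$trace$samples)
#' @export
simulate_trace <- function(config, animal_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_schedule(config)
  fs <- config$sampling_rate
  n <- floor(config$duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)

  if (nrow(truth) > 0) {
    idx <- findInterval(t, truth$onset_s)
    inside <- idx >= 1L &
      t < truth$onset_s[pmax(idx, 1L)] + truth$length_s[pmax(idx, 1L)]
    ii <- idx[inside]
    tau <- t[inside] - truth$onset_s[ii]
    ti <- truth$ti_s[ii]
    te <- truth$te_s[ii]
    a_in <- pi * truth$vti_ml[ii] / (2 * ti)
    a_ex <- pi * truth$vte_ml[ii] / (2 * te)
    insp <- tau < ti
    val <- numeric(length(tau))
    val[insp] <- a_in[insp] * sin(pi * tau[insp] / ti[insp])
    val[!insp] <- -a_ex[!insp] * sin(pi * (tau[!insp] - ti[!insp]) / te[!insp])
    x[inside] <- val

    spikes <- which(truth$artifact_kind == "movement_spike")
    for (s in spikes) {
      amp <- config$artifact_params$spike_amplitude *
        pi * truth$vti_ml[s] / (2 * truth$ti_s[s])
      sd_dur <- config$artifact_params$spike_duration
      t_start <- truth$onset_s[s] + 0.5 * truth$length_s[s] - sd_dur / 2
      sel <- t >= t_start & t < t_start + sd_dur
      x[sel] <- x[sel] + amp * sin(2 * pi * (t[sel] - t_start) / sd_dur)
    }
  }

  x <- x + config$bias_flow
  if (config$noise_sd > 0) {
    # noise drawn after the schedule so the schedule stream is unaffected
    x <- x + stats::rnorm(n, 0, config$noise_sd)
  }

  trace <- structure(list(samples = x, sampling_rate = fs,
                          animal_id = animal_id, t0 = 0),
                     class = "breath_trace")
  list(trace = trace, truth = truth)
}

#' Simulate a cohort of animals from phenotype presets
#'
#' @param preset_counts named integer vector or list mapping preset names
#'   (see [phenotype_presets()]) to the number of animals.
#' @param base_config a [sim_config()] supplying shared settings (duration,
#'   sampling rate, artifact rates, ...).
#' @param seed master seed; each animal's stream is derived from it by a
#'   fixed counter scheme, so adding animals or presets never changes the
#'   traces of animals already present.
#' @param schedule_only if `TRUE`, skip waveform rendering and return only
#'   ground-truth schedules (fast; for simulation studies).
#' @return a list with one element per animal: `animal_id`, `genotype`,
#'   `config`, `trace` (unless `schedule_only`), `truth`.
#' @export
simulate_cohort <- function(preset_counts, base_config = sim_config(),
                            seed = 1L, schedule_only = FALSE) {
  counts <- unlist(preset_counts)
  if (length(counts) == 0) {
    stop("empty cohort: at least one preset with n >= 1 is required",
         call. = FALSE)
  }
  if (any(counts < 1)) {
    stop("invalid cohort: every preset needs n_animals >= 1", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(phenotype_presets()))
  if (length(unknown)) {
    stop("unknown preset: ", paste(unknown, collapse = ", "), call. = FALSE)
  }

  out <- list()
  counter <- 0L
  for (preset in names(counts)) {
    cfg0 <- phenotype_preset(preset, base_config)
    for (k in seq_len(counts[[preset]])) {
      counter <- counter + 1L
      cfg <- cfg0
      cfg$seed <- as.integer(derive_seed(seed, counter))
      id <- sprintf("%s_%02d", preset, k)
      if (schedule_only) {
        out[[id]] <- list(animal_id = id, genotype = preset, config = cfg,
                          truth = simulate_schedule(cfg))
      } else {
        sim <- simulate_trace(cfg, animal_id = id)
        out[[id]] <- list(animal_id = id, genotype = preset, config = cfg,
                          trace = sim$trace, truth = sim$truth)
      }
    }
  }
  out
}

#' Mean IBII of a ground-truth schedule
#'
#' Computes the interbreath-interval irregularity over the scheduled breath
#' lengths (all breaths, in schedule order), for calibration checks against
#' the `irregularity` target.
#'
#' @param truth a GroundTruth data frame from [simulate_schedule()].
#' @return the mean of `|L(n+1) - L(n)| / L(n)` over consecutive pairs.
#' @export
schedule_mean_ibii <- function(truth) {
  l <- truth$length_s
  if (length(l) < 2) return(NA_real_)
  mean(abs(diff(l)) / l[-length(l)])
}
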