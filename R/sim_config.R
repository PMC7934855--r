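#' Simulator configuration
#'
#' Builds a validated configuration for the synthetic respiratory waveform
#' generator. Defaults describe a 30-minute recording sampled at 1 kHz from
#' a healthy adult mouse breathing at 250 breaths/min with a 0.2 mL tidal
#' volume and mildly irregular breath lengths; all artifact rates default
#' to zero so the default trace is clean.
#'
#' @param duration recording length in seconds.
#' @param sampling_rate sampling frequency in Hz.
#' @param base_rate baseline breathing rate in breaths/min. Breath-length
#'   jitter is centred so that the expected instantaneous rate (mean of
#'   60/length) equals `base_rate`.
#' @param base_tidal_volume inspired volume per breath in mL.
#' @param irregularity target mean interbreath-interval irregularity (IBII)
#'   of the clean breath schedule, dimensionless (0 = perfectly regular).
#' @param insp_fraction fraction of each breath length spent in inspiration,
#'   strictly between 0 and 1.
#' @param artifact_rates named list of expected artifact events per minute
#'   for `sniff_burst`, `long_expiration`, `asymmetric_volume` and
#'   `movement_spike`.
#' @param artifact_params named list of artifact magnitudes:
#'   `burst_rate` (breaths/min inside a sniff burst), `burst_len` (breaths
#'   per burst), `burst_volume_scale` (tidal volume of burst breaths
#'   relative to `base_tidal_volume`), `long_exp_duration` (s),
#'   `vte_vti_ratio` (expired/inspired ratio of asymmetric breaths),
#'   `spike_amplitude` (movement-spike amplitude relative to the breath's
#'   peak inspiratory flow), `spike_duration` (s).
#' @param bias_flow constant flow offset in mL/s emulating the chamber bias
#'   flow; removed by the baseline step of the analysis.
#' @param noise_sd standard deviation of additive white noise, mL/s.
#' @param seed integer seed; identical configuration and seed give a
#'   bit-identical trace and ground truth.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_trace()], [phenotype_preset()]
#' @export
sim_config <- function(duration = 1800,
                       sampling_rate = 1000,
                       base_rate = 250,
                       base_tidal_volume = 0.2,
                       irregularity = 0.1,
                       insp_fraction = 0.4,
                       artifact_rates = list(),
                       artifact_params = list(),
                       bias_flow = 0,
                       noise_sd = 0,
                       seed = 1L) {
  check_positive(duration, "duration")
  check_positive(sampling_rate, "sampling_rate")
  check_positive(base_rate, "base_rate")
  check_positive(base_tidal_volume, "base_tidal_volume")
  check_positive(irregularity, "irregularity", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (!is.numeric(insp_fraction) || length(insp_fraction) != 1L ||
      is.na(insp_fraction) || insp_fraction <= 0 || insp_fraction >= 1) {
    stop("invalid config: `insp_fraction` must lie strictly between 0 and 1",
         call. = FALSE)
  }

  rates <- utils::modifyList(default_artifact_rates(), as.list(artifact_rates))
  unknown <- setdiff(names(rates), names(default_artifact_rates()))
  if (length(unknown)) {
    stop("invalid config: unknown artifact rate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(rates)) {
    check_positive(rates[[k]], paste0("artifact_rates$", k), strict = FALSE)
  }

  params <- utils::modifyList(default_artifact_params(),
                              as.list(artifact_params))
  unknown <- setdiff(names(params), names(default_artifact_params()))
  if (length(unknown)) {
    stop("invalid config: unknown artifact parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  structure(list(duration = duration,
                 sampling_rate = sampling_rate,
                 base_rate = base_rate,
                 base_tidal_volume = base_tidal_volume,
                 irregularity = irregularity,
                 insp_fraction = insp_fraction,
                 artifact_rates = rates,
                 artifact_params = params,
                 bias_flow = bias_flow,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

default_artifact_rates <- function() {
  list(sniff_burst = 0, long_expiration = 0,
       asymmetric_volume = 0, movement_spike = 0)
}

default_artifact_params <- function() {
  list(burst_rate = 700,        # breaths/min, above the 600 bpm QC cutoff
       burst_len = 30,          # breaths per sniffing run
       burst_volume_scale = 0.3,
       long_exp_duration = 12,  # s, above the 10 s QC ceiling
       vte_vti_ratio = 2.5,     # above the 2x QC ratio
       spike_amplitude = 3,     # x peak inspiratory flow
       spike_duration = 0.03)   # s
}

#' Phenotype presets for the cohort simulator
#'
#' Presets encode the qualitative genotype orderings reported for
#' SCA1-model mice: at 6 months a reduced tidal volume with a compensatory
#' frequency increase (so minute ventilation is mildly elevated); late in
#' life a more pronounced tidal-volume deficit without further frequency
#' compensation (minute ventilation falls); and a rescued late phenotype
#' with a slight tidal-volume improvement and a clear frequency increase
#' over late-stage SCA1. Absolute values are package choices (no numeric
#' baselines are published for these genotypes) set to typical awake-mouse
#' plethysmography magnitudes.
#'
#' @param name one of `"WT"`, `"SCA1_6mo"`, `"SCA1_late"`,
#'   `"SCA1_rescued_late"`.
#' @param base_config a [sim_config()] supplying everything the preset does
#'   not override.
#' @return a `sim_config` with the preset's rate, tidal volume and
#'   irregularity applied.
#' @export
phenotype_preset <- function(name, base_config = sim_config()) {
  presets <- phenotype_presets()
  if (!name %in% names(presets)) {
    stop("unknown preset: ", name, " (expected one of ",
         paste(names(presets), collapse = ", "), ")", call. = FALSE)
  }
  ov <- presets[[name]]
  cfg <- unclass(base_config)
  cfg[names(ov)] <- ov
  do.call(sim_config, c(cfg[c("duration", "sampling_rate", "base_rate",
                              "base_tidal_volume", "irregularity",
                              "insp_fraction", "bias_flow", "noise_sd",
                              "seed")],
                        list(artifact_rates = cfg$artifact_rates,
                             artifact_params = cfg$artifact_params)))
}

#' @rdname phenotype_preset
#' @export
phenotype_presets <- function() {
  list(
    WT = list(base_rate = 250, base_tidal_volume = 0.20,
              irregularity = 0.10),
    SCA1_6mo = list(base_rate = 330, base_tidal_volume = 0.17,
                    irregularity = 0.15),
    SCA1_late = list(base_rate = 330, base_tidal_volume = 0.13,
                     irregularity = 0.20),
    SCA1_rescued_late = list(base_rate = 370, base_tidal_volume = 0.14,
                             irregularity = 0.15)
  )
}
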