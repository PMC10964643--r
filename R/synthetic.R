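#' Condition-specific generator parameters
#'
#' Shape parameters of one synthetic slow wave potential class: a flat
#' baseline before wounding, a smooth (sigmoidal) depolarization of depth
#' `amplitude_mV` over `depol_duration_s`, then exponential relaxation back
#' toward baseline with half-recovery time `repol_half_time_s`, plus white
#' measurement noise and an integrated (random-walk) baseline drift.
#'
#' @param amplitude_mV Depolarization depth in mV (positive; rendered as a
#'   negative-going deflection).
#' @param depol_duration_s Duration of the depolarization ramp, seconds.
#' @param repol_half_time_s Time from the depolarization minimum to half
#'   recovery, seconds.
#' @param baseline_mV Pre-wound baseline potential, mV.
#' @param noise_sd_mV Standard deviation of additive white noise, mV.
#' @param drift_sd_mV_per_s Standard deviation of the integrated drift after
#'   one second, mV.
#' @return A `swp_condition_params` list.
#' @export
swp_condition_params <- function(amplitude_mV, depol_duration_s,
                                 repol_half_time_s, baseline_mV = 0,
                                 noise_sd_mV = 0.15,
                                 drift_sd_mV_per_s = 0.02) {
  if (amplitude_mV <= 0 || depol_duration_s <= 0 || repol_half_time_s <= 0)
    swp_abort("amplitude, depol duration and repol half time must be positive",
              "swp_config_error")
  if (noise_sd_mV < 0 || drift_sd_mV_per_s < 0)
    swp_abort("noise and drift standard deviations must be non-negative",
              "swp_config_error")
  structure(list(amplitude_mV = amplitude_mV,
                 depol_duration_s = depol_duration_s,
                 repol_half_time_s = repol_half_time_s,
                 baseline_mV = baseline_mV,
                 noise_sd_mV = noise_sd_mV,
                 drift_sd_mV_per_s = drift_sd_mV_per_s),
            class = "swp_condition_params")
}

# Default class profiles. Kinetics and depth separate the three light regimes
# by >= 25% in both repolarization half time and amplitude (the generator must
# encode a decodable darkness effect); systemic (leaf 13) responses are
# shallower and slower than local (leaf 8) ones, as is typical for
# vascular-transmitted signals. Magnitudes are illustrative defaults in the
# few-mV range reported for surface-recorded SWPs, not measured values.
default_profiles <- function() {
  list(
    leaf8 = list(
      Normal = swp_condition_params(8,    15, 60),
      SED    = swp_condition_params(10,   20, 90),
      LED    = swp_condition_params(13,   25, 130)),
    leaf13 = list(
      Normal = swp_condition_params(5,    20, 70),
      SED    = swp_condition_params(6.5,  25, 100),
      LED    = swp_condition_params(8.5,  30, 140)))
}

#' Synthetic dataset configuration
#'
#' @param profiles Nested list `list(leaf8 = list(Normal=, SED=, LED=),
#'   leaf13 = ...)` of [swp_condition_params()]; defaults emulate separable
#'   light-regime classes.
#' @param n_per_condition Named integer vector of plants per condition
#'   (default `c(Normal = 20, SED = 20, LED = 15)`, each measured on both
#'   leaves).
#' @param pre_wound_s Seconds of baseline recorded before wounding.
#' @param sampling_rate_hz Acquisition rate, Hz.
#' @param seed Master seed; per-recording seeds are derived from it.
#' @return A `swp_synthetic_config` list.
#' @export
swp_synthetic_config <- function(profiles = default_profiles(),
                                 n_per_condition = c(Normal = 20, SED = 20,
                                                     LED = 15),
                                 pre_wound_s = 30, sampling_rate_hz = 100,
                                 seed = 10) {
  if (!all(swp_conditions() %in% names(n_per_condition)))
    swp_abort("n_per_condition must name Normal, SED and LED",
              "swp_config_error")
  if (any(n_per_condition[swp_conditions()] < 1))
    swp_abort("n_per_condition entries must be >= 1", "swp_config_error")
  for (lf in c("leaf8", "leaf13"))
    for (cond in swp_conditions())
      if (!inherits(profiles[[lf]][[cond]], "swp_condition_params"))
        swp_abort(sprintf("profiles$%s$%s missing or invalid", lf, cond),
                  "swp_config_error")
  structure(list(profiles = profiles,
                 n_per_condition = n_per_condition[swp_conditions()],
                 pre_wound_s = pre_wound_s,
                 sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed)),
            class = "swp_synthetic_config")
}

#' Synthesize one SWP recording
#'
#' Generates baseline for `pre_wound_s` seconds, a monotone smoothstep drop of
#' depth `amplitude_mV` over `depol_duration_s`, then exponential recovery
#' `baseline - A * 2^(-t / repol_half_time_s)`; white noise and random-walk
#' drift are added on top. The recording extends 1.5 half-times past the
#' minimum, so the noiseless trace crosses the half-recovery level exactly
#' one half-time after the minimum.
#'
#' @param params [swp_condition_params()].
#' @param sample_id,leaf,condition Recording metadata.
#' @param seed Integer seed controlling noise and drift.
#' @param pre_wound_s,sampling_rate_hz Acquisition settings.
#' @return An [swp_recording()].
#' @export
synthesize_recording <- function(params, sample_id, leaf, condition, seed,
                                 pre_wound_s = 30, sampling_rate_hz = 100) {
  stopifnot(inherits(params, "swp_condition_params"))
  rate <- sampling_rate_hz
  n_pre <- round(pre_wound_s * rate)
  n_dep <- round(params$depol_duration_s * rate)
  n_rec <- ceiling(1.5 * params$repol_half_time_s * rate)
  b <- params$baseline_mV
  A <- params$amplitude_mV

  u <- seq_len(n_dep) / n_dep
  depol <- b - A * (3 * u^2 - 2 * u^3)        # smoothstep: 0 -> -A
  t_rec <- seq_len(n_rec) / rate
  recov <- b - A * 2^(-t_rec / params$repol_half_time_s)
  clean <- c(rep(b, n_pre + 1), depol, recov)  # +1: the sample at wounding

  with_seed(seed, {
    noise <- if (params$noise_sd_mV > 0)
      stats::rnorm(length(clean), 0, params$noise_sd_mV) else 0
    drift <- if (params$drift_sd_mV_per_s > 0)
      cumsum(stats::rnorm(length(clean), 0,
                          params$drift_sd_mV_per_s / sqrt(rate))) else 0
    swp_recording(sample_id = sample_id, leaf = leaf, condition = condition,
                  values = clean + noise + drift,
                  wound_index = n_pre + 1L, sampling_rate_hz = rate)
  })
}

#' Synthesize a full dataset
#'
#' Generates `n_per_condition` recordings per condition for each leaf
#' (default 20/20/15, i.e. 55 per leaf, 110 in total) and, when `out_dir` is
#' given, writes one trace CSV per recording plus one manifest per leaf
#' (`manifest_leaf8.csv`, `manifest_leaf13.csv`). Per-recording seeds are
#' derived deterministically from `cfg$seed` and the sample identity.
#'
#' @param cfg A [swp_synthetic_config()].
#' @param out_dir Output directory, or `NULL` to keep everything in memory.
#' @return A list with `recordings` (all recordings, leaf 8 then leaf 13) and
#'   `manifests` (named list of [swp_manifest()], trace_file columns empty
#'   when `out_dir` is `NULL`).
#' @export
synthesize_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "swp_synthetic_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    swp_abort(sprintf("cannot create output directory %s", out_dir),
              "swp_io_error")
  recordings <- list()
  manifests <- list()
  for (leaf in swp_leaves()) {
    rows <- list()
    for (cond in swp_conditions()) {
      pars <- cfg$profiles[[paste0("leaf", leaf)]][[cond]]
      for (k in seq_len(cfg$n_per_condition[[cond]])) {
        sid <- sprintf("leaf%d_%s_%02d", leaf, cond, k)
        rec <- synthesize_recording(
          pars, sample_id = sid, leaf = leaf, condition = cond,
          seed = derive_seed(cfg$seed, sid),
          pre_wound_s = cfg$pre_wound_s,
          sampling_rate_hz = cfg$sampling_rate_hz)
        path <- ""
        if (!is.null(out_dir)) {
          path <- paste0(sid, ".csv")
          write_trace(rec, file.path(out_dir, path))
        }
        recordings[[sid]] <- rec
        rows[[sid]] <- data.frame(sample_id = sid, leaf = leaf,
                                  condition = cond, trace_file = path,
                                  stringsAsFactors = FALSE)
      }
    }
    man <- swp_manifest(do.call(rbind, rows), provenance = "synthetic")
    manifests[[paste0("leaf", leaf)]] <- man
    if (!is.null(out_dir))
      write_manifest(man, file.path(out_dir,
                                    sprintf("manifest_leaf%d.csv", leaf)))
  }
  list(recordings = unname(recordings), manifests = manifests)
}
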