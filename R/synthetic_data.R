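#' Tuning parameters of a single simulated voxel
#'
#' A voxel's trial response amplitude to an effective ILD `x` is
#' `baseline + slope * plogis((s * x - center) / width) +
#'  bump_amp * exp(-x^2 / (2 * bump_width^2))`,
#' where `s = +1` for right-preferring (typically left-hemisphere,
#' contralateral) voxels and `-1` for left-preferring ones.  The logistic
#' term encodes contralateral preference; the Gaussian term an optional
#' midline "bump".
#'
#' @param baseline Response amplitude at the sigmoid midpoint floor.
#' @param slope Amplitude range of the logistic term.
#' @param preferred_side `"left"` or `"right"`: side of space (ILD sign)
#'   producing the larger response.
#' @param sigmoid_center Logistic midpoint, dB.
#' @param sigmoid_width Logistic width, dB (> 0).
#' @param bump_amp Amplitude of the midline Gaussian bump.
#' @param bump_width Bump standard deviation, dB (> 0).
#' @return An object of class `voxel_tuning_params`.
#' @export
voxel_tuning_params <- function(baseline = 1, slope = 1,
                                preferred_side = c("right", "left"),
                                sigmoid_center = 0, sigmoid_width = 10,
                                bump_amp = 0, bump_width = 5) {
  preferred_side <- match.arg(preferred_side)
  stopifnot(sigmoid_width > 0, bump_width > 0,
            is.finite(baseline), is.finite(slope), is.finite(bump_amp))
  structure(list(baseline = baseline, slope = slope,
                 preferred_side = preferred_side,
                 sigmoid_center = sigmoid_center,
                 sigmoid_width = sigmoid_width,
                 bump_amp = bump_amp, bump_width = bump_width),
            class = "voxel_tuning_params")
}

#' Voxel response amplitude to an effective ILD
#'
#' @param effective_ild_db Effective (perceptually weighted) ILD, dB.
#' @param params A [voxel_tuning_params()] object.
#' @param hemisphere `"L"` or `"R"`; used to infer the preferred side
#'   (contralateral) when `params$preferred_side` is `NULL`.
#' @return Response amplitude (arbitrary units shared with betas).
#' @export
tuning_response <- function(effective_ild_db, params, hemisphere = NULL) {
  stopifnot(is.finite(effective_ild_db))
  side <- params$preferred_side
  if (is.null(side)) {
    if (is.null(hemisphere)) stop("need 'preferred_side' or 'hemisphere'")
    side <- if (hemisphere == "L") "right" else "left"
  }
  s <- if (side == "right") 1 else -1
  params$baseline +
    params$slope *
      stats::plogis((s * effective_ild_db - params$sigmoid_center) /
                      params$sigmoid_width) +
    params$bump_amp *
      exp(-effective_ild_db^2 / (2 * params$bump_width^2))
}

roi_profile_defaults <- list(
  HG   = list(slope = 1, bump_amp = 0),
  aSTG = list(slope = 0, bump_amp = 0),   # no ILD modulation
  pSTG = list(slope = 1, bump_amp = 0)
)

#' Build a simulated voxel population
#'
#' Voxels are generated per ROI and hemisphere with contralateral
#' preference (left-hemisphere voxels prefer rightward ILD and vice
#' versa).  ROI profiles follow the study's functional picture: HG and
#' pSTG carry an ILD-tuned logistic slope, aSTG is flat (slope and bump
#' zero).  Slopes and centers are jittered across voxels.
#'
#' @param n_per_roi Voxels per ROI per hemisphere.
#' @param rois ROI names; profiles known for `"HG"`, `"aSTG"`, `"pSTG"`.
#' @param hemispheres Subset of `c("L", "R")`.
#' @param baseline Mean baseline amplitude.
#' @param slope Mean logistic amplitude for tuned ROIs.
#' @param slope_jitter_sd SD of across-voxel slope jitter (truncated at
#'   zero).
#' @param sigmoid_center,center_jitter_sd Mean and jitter SD of the
#'   logistic midpoint, dB.
#' @param sigmoid_width Logistic width, dB.
#' @param bump_amp,bump_width Midline bump amplitude and width (applied
#'   to tuned ROIs only).
#' @param noise_sd Marginal SD of the additive scan noise.
#' @param ar1 Lag-1 autocorrelation of the scan noise.
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `voxel_population` with one row per
#'   voxel and attributes `noise_sd`, `ar1`.
#' @export
make_voxel_population <- function(n_per_roi = 100,
                                  rois = c("HG", "aSTG", "pSTG"),
                                  hemispheres = c("L", "R"),
                                  baseline = 1, slope = 1,
                                  slope_jitter_sd = 0.2,
                                  sigmoid_center = 0, center_jitter_sd = 15,
                                  sigmoid_width = 10,
                                  bump_amp = 0, bump_width = 5,
                                  noise_sd = 0.5, ar1 = 0.3,
                                  seed = NULL) {
  stopifnot(n_per_roi >= 1, sigmoid_width > 0, bump_width > 0,
            noise_sd >= 0, abs(ar1) < 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  vid <- 0L
  for (roi in rois) {
    prof <- roi_profile_defaults[[roi]]
    if (is.null(prof)) prof <- list(slope = slope, bump_amp = bump_amp)
    roi_slope <- if (identical(prof$slope, 0)) 0 else slope
    roi_bump <- if (identical(prof$bump_amp, 0) && roi == "aSTG") 0 else bump_amp
    for (hemi in hemispheres) {
      sl <- if (roi_slope == 0) rep(0, n_per_roi)
            else pmax(0, stats::rnorm(n_per_roi, roi_slope, slope_jitter_sd))
      ctr <- stats::rnorm(n_per_roi, sigmoid_center, center_jitter_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        voxel_id = vid + seq_len(n_per_roi),
        roi = roi, hemisphere = hemi,
        baseline = baseline, slope = sl,
        preferred_side = if (hemi == "L") "right" else "left",
        sigmoid_center = ctr, sigmoid_width = sigmoid_width,
        bump_amp = roi_bump, bump_width = bump_width,
        stringsAsFactors = FALSE)
      vid <- vid + n_per_roi
    }
  }
  pop <- do.call(rbind, rows)
  attr(pop, "noise_sd") <- noise_sd
  attr(pop, "ar1") <- ar1
  class(pop) <- c("voxel_population", "data.frame")
  pop
}

#' Ground-truth trial amplitudes for a population and event table
#'
#' Each trial's per-click ILD profile (under the given mode) is reduced
#' to a perceptually weighted effective ILD and passed through every
#' voxel's tuning function.  SILENT trials evoke amplitude 0.
#'
#' @param population A [make_voxel_population()] object.
#' @param events An [make_run_events()] event table.
#' @param mode `"full_cue"` or `"onset_only"`.
#' @param weights Temporal weight vector (length `n_clicks`).
#' @param n_clicks Number of clicks per train.
#' @return Trials x voxels amplitude matrix.
#' @export
trial_amplitudes <- function(population, events,
                             mode = c("full_cue", "onset_only"),
                             weights = uniform_weights(n_clicks),
                             n_clicks = 16) {
  mode <- match.arg(mode)
  stopifnot(inherits(population, "voxel_population"))
  w <- weight_vector(weights)
  conds <- events$condition
  eff <- vapply(conds, function(cnd) {
    if (cnd == "SILENT") return(NA_real_)
    effective_ild(make_ild_profile(as.numeric(cnd), mode, n_clicks), w)
  }, numeric(1), USE.NAMES = FALSE)
  amp <- matrix(0, nrow = length(conds), ncol = nrow(population))
  vox_params <- lapply(seq_len(nrow(population)), function(v)
    voxel_tuning_params(
      baseline = population$baseline[v], slope = population$slope[v],
      preferred_side = population$preferred_side[v],
      sigmoid_center = population$sigmoid_center[v],
      sigmoid_width = population$sigmoid_width[v],
      bump_amp = population$bump_amp[v],
      bump_width = population$bump_width[v]))
  sound <- !is.na(eff)
  for (v in seq_len(nrow(population)))
    amp[sound, v] <- vapply(eff[sound], tuning_response, numeric(1),
                            params = vox_params[[v]])
  amp
}

#' Simulate an event-related BOLD run
#'
#' Forward model of the measurement: ground-truth trial amplitudes from
#' the population tuning and temporal weights, linear HRF superposition
#' sampled at the scan grid, plus additive AR(1) Gaussian noise.
#'
#' @param population A [make_voxel_population()] object.
#' @param events An [make_run_events()] event table.
#' @param mode `"full_cue"` or `"onset_only"`.
#' @param weights Temporal weight vector.
#' @param hrf A [build_hrf()] kernel.
#' @param tr Repetition time, s.
#' @param noise_sd,ar1 Override the population's noise parameters.
#' @param n_clicks Clicks per train.
#' @param seed Optional integer seed (noise only).
#' @return An object of class `simulated_dataset`: list with `bold`
#'   (voxels x scans), `tr`, `events`, `truth` (trials x voxels),
#'   `population`, `mode`, `hrf`.
#' @export
simulate_experiment <- function(population, events,
                                mode = c("full_cue", "onset_only"),
                                weights = uniform_weights(n_clicks),
                                hrf = build_hrf(), tr = 2,
                                noise_sd = attr(population, "noise_sd"),
                                ar1 = attr(population, "ar1"),
                                n_clicks = 16, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(noise_sd)) noise_sd <- 0
  if (is.null(ar1)) ar1 <- 0
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  stopifnot(abs(ar1) < 1)
  if (!is.null(seed)) set.seed(seed)
  amp <- trial_amplitudes(population, events, mode, weights, n_clicks)
  trial_dur <- attr(events, "trial_dur")
  if (is.null(trial_dur)) trial_dur <- 1
  n_scans <- ceiling((max(events$onset_s) + trial_dur + hrf$duration) / tr) + 1
  m <- event_kernel_matrix(events$onset_s, hrf, tr, n_scans)
  clean <- m %*% amp                                  # scans x voxels
  if (noise_sd > 0) {
    innov_sd <- noise_sd * sqrt(1 - ar1^2)
    noise <- vapply(seq_len(ncol(clean)), function(v) {
      e <- stats::rnorm(n_scans, sd = innov_sd)
      if (ar1 != 0) as.numeric(stats::filter(e, ar1, method = "recursive"))
      else e
    }, numeric(n_scans))
    clean <- clean + noise
  }
  structure(list(bold = t(clean), tr = tr, events = events, truth = amp,
                 population = population, mode = mode, hrf = hrf),
            class = "simulated_dataset")
}

#' Simulate matched full-cue and onset-only runs
#'
#' Convenience wrapper generating one run per stimulus mode from the
#' same population and temporal weights, each with its own
#' continuous-carryover sequence and jittered event table.
#'
#' @param population A [make_voxel_population()] object.
#' @param weights Temporal weight vector shared by both modes.
#' @param pair_multiplicity Carryover pair multiplicity (2 gives the
#'   study's 200-trial runs over 10 conditions).
#' @param hrf,tr,n_clicks As in [simulate_experiment()].
#' @param iti_range Inter-trial jitter range, s.
#' @param seed Integer seed; sub-seeds are derived per mode.
#' @return Named list with elements `full_cue` and `onset_only`.
#' @export
simulate_modes <- function(population, weights = uniform_weights(n_clicks),
                           pair_multiplicity = 2, hrf = build_hrf(),
                           tr = 2, n_clicks = 16, iti_range = c(0, 5),
                           seed = 1) {
  modes <- c("full_cue", "onset_only")
  out <- lapply(seq_along(modes), function(i) {
    sseed <- (seed * 7 + i * 1013) %% .Machine$integer.max
    seqn <- make_carryover_sequence(length(study_conditions()),
                                    pair_multiplicity, seed = sseed,
                                    labels = study_conditions())
    ev <- make_run_events(seqn, iti_range = iti_range, seed = sseed + 1)
    simulate_experiment(population, ev, modes[i], weights, hrf, tr,
                        n_clicks = n_clicks, seed = sseed + 2)
  })
  names(out) <- modes
  out
}
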