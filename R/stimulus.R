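#' The nine ILD levels of the study design
#'
#' Interaural level differences, in dB, used as stimulus conditions.
#' Negative values denote leftward ILD (left ear more intense); positive
#' values, rightward.
#'
#' @return Numeric vector `c(-30, -20, -10, -5, 0, 5, 10, 20, 30)`.
#' @export
ild_levels <- function() c(-30, -20, -10, -5, 0, 5, 10, 20, 30)

#' All ten trial conditions (nine ILDs plus silence)
#'
#' The tenth, inaudible "SILENT" condition completes the carryover design
#' but is excluded from tuning and classification analyses.
#'
#' @return Character vector of condition labels.
#' @export
study_conditions <- function() c(as.character(ild_levels()), "SILENT")

#' Synthesize a single Gabor click
#'
#' A Gabor click is a cosine at `center_freq` under a Gaussian envelope.
#' The envelope width is set so that the half-power (-3 dB) width of the
#' Gaussian magnitude spectrum equals the requested bandwidth in octaves,
#' converted to Hz around the center frequency.  The envelope has unit
#' peak; level scaling is applied downstream.
#'
#' @param center_freq Center frequency in Hz.
#' @param bandwidth_oct -3 dB spectral bandwidth in octaves.
#' @param sample_rate Sampling rate in Hz; must exceed twice the upper
#'   -3 dB spectral edge of the click.
#' @param trunc_sd Envelope truncation point in units of the temporal
#'   Gaussian standard deviation.
#' @return Numeric vector of samples, symmetric about its peak.
#' @export
make_gabor_click <- function(center_freq, bandwidth_oct, sample_rate,
                             trunc_sd = 4) {
  if (!is.finite(center_freq) || center_freq <= 0)
    stop("'center_freq' must be a positive number")
  if (!is.finite(bandwidth_oct) || bandwidth_oct <= 0)
    stop("'bandwidth_oct' must be a positive number")
  upper_edge <- center_freq * 2^(bandwidth_oct / 2)
  if (!is.finite(sample_rate) || sample_rate <= 2 * upper_edge)
    stop(sprintf(
      "'sample_rate' (%g Hz) must exceed twice the upper spectral edge (%g Hz)",
      sample_rate, upper_edge))
  bw_hz <- center_freq * (2^(bandwidth_oct / 2) - 2^(-bandwidth_oct / 2))
  sigma_f <- bw_hz / (2 * sqrt(log(2)))   # half-power points at +- sigma_f*sqrt(ln 2)
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(trunc_sd * sigma_t * sample_rate)
  t <- (-half:half) / sample_rate
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * center_freq * t)
}

#' Parametric description of a binaural Gabor click train
#'
#' @param center_freq Click center frequency, Hz.
#' @param bandwidth_oct Click -3 dB bandwidth, octaves.
#' @param n_clicks Number of clicks in the train.
#' @param ici Inter-click interval, seconds.
#' @param ild_profile Per-click ILD in dB, length `n_clicks`; positive =
#'   right ear louder.
#' @param abl Average binaural level, dB SPL (represented digitally
#'   relative to `full_scale_db`).
#' @param sample_rate Sampling rate, Hz.
#' @param full_scale_db dB SPL value mapped to digital amplitude 1.
#' @return An object of class `click_train_spec`.
#' @export
click_train_spec <- function(center_freq = 4000, bandwidth_oct = 0.8,
                             n_clicks = 16, ici = 0.002,
                             ild_profile = rep(0, n_clicks), abl = 80,
                             sample_rate = 44100, full_scale_db = 100) {
  if (n_clicks < 1) stop("'n_clicks' must be >= 1")
  if (ici <= 0) stop("'ici' must be positive")
  if (length(ild_profile) != n_clicks)
    stop("'ild_profile' must have length 'n_clicks'")
  structure(
    list(center_freq = center_freq, bandwidth_oct = bandwidth_oct,
         n_clicks = as.integer(n_clicks), ici = ici,
         ild_profile = as.numeric(ild_profile), abl = abl,
         sample_rate = sample_rate, full_scale_db = full_scale_db),
    class = "click_train_spec")
}

#' Nominal duration of a click train
#'
#' `n_clicks` clicks at one click per `ici` seconds span
#' `n_clicks * ici` seconds nominally (16 clicks at 2 ms = 32 ms).
#'
#' @param spec A [click_train_spec()].
#' @return Duration in seconds.
#' @export
train_duration <- function(spec) {
  stopifnot(inherits(spec, "click_train_spec"))
  spec$n_clicks * spec$ici
}

#' Render a stereo click-train waveform
#'
#' Clicks are placed at onsets `k * ici`.  A click with ILD `d` is scaled
#' by +d/2 dB in the louder ear and -d/2 dB in the other, relative to the
#' ABL-calibrated reference amplitude, so the average binaural level is
#' preserved for every ILD.  Positive `d` makes the right ear louder.
#'
#' @param spec A [click_train_spec()].
#' @return A `stereo_waveform`: list with `left`, `right` sample vectors
#'   and `sample_rate`.
#' @export
render_click_train <- function(spec) {
  stopifnot(inherits(spec, "click_train_spec"))
  if (length(spec$ild_profile) != spec$n_clicks)
    stop("'ild_profile' must have length 'n_clicks'")
  click <- make_gabor_click(spec$center_freq, spec$bandwidth_oct,
                            spec$sample_rate)
  ref_amp <- 10^((spec$abl - spec$full_scale_db) / 20)
  fs <- spec$sample_rate
  nclk <- length(click)
  n <- ceiling((spec$n_clicks - 1) * spec$ici * fs) + nclk
  left <- numeric(n)
  right <- numeric(n)
  for (k in seq_len(spec$n_clicks)) {
    d <- spec$ild_profile[k]
    i0 <- round((k - 1) * spec$ici * fs)
    idx <- i0 + seq_len(nclk)
    left[idx] <- left[idx] + click * ref_amp * 10^(-d / 40)
    right[idx] <- right[idx] + click * ref_amp * 10^(d / 40)
  }
  structure(list(left = left, right = right, sample_rate = fs),
            class = "stereo_waveform")
}

#' Per-click ILD profile for a trial condition
#'
#' In the full-cue mode every click carries the condition ILD; in the
#' onset-only mode only the first click does and clicks 2..n carry 0 dB,
#' the headphone analogue of the Franssen effect.
#'
#' @param condition_ild Condition ILD in dB.
#' @param mode `"full_cue"` or `"onset_only"`.
#' @param n_clicks Number of clicks.
#' @return Numeric ILD vector of length `n_clicks`.
#' @export
make_ild_profile <- function(condition_ild,
                             mode = c("full_cue", "onset_only"),
                             n_clicks = 16) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(condition_ild), length(condition_ild) == 1,
            n_clicks >= 1)
  if (mode == "full_cue") rep(condition_ild, n_clicks)
  else c(condition_ild, rep(0, n_clicks - 1))
}

#' Normalize a temporal weighting vector
#'
#' Perceptual weights applied to the per-click binaural cues; they must
#' be non-negative and are normalized to sum to one.
#'
#' @param w Numeric vector of non-negative weights.
#' @return Normalized numeric weight vector.
#' @export
weight_vector <- function(w) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and non-negative")
  s <- sum(w)
  if (s <= 0) stop("weights must not all be zero")
  w / s
}

#' Uniform temporal weights (the sensory hypothesis)
#' @param n_clicks Number of clicks.
#' @return Weight vector with each entry `1/n_clicks`.
#' @export
uniform_weights <- function(n_clicks = 16) weight_vector(rep(1, n_clicks))

#' Onset-dominant temporal weights (the perceptual hypothesis)
#'
#' Default shape mirrors measured temporal weighting functions for ILD:
#' largest weight on the first click, a small contribution from the
#' middle, and renewed weight on the final clicks.
#'
#' @param n_clicks Number of clicks (>= 5).
#' @param w_onset Weight on click 1.
#' @param w_offset Total weight shared by the last three clicks.
#' @return Normalized weight vector.
#' @export
onset_dominant_weights <- function(n_clicks = 16, w_onset = 0.4,
                                   w_offset = 0.4) {
  stopifnot(n_clicks >= 5, w_onset >= 0, w_offset >= 0,
            w_onset + w_offset <= 1)
  w_mid <- 1 - w_onset - w_offset
  n_mid <- n_clicks - 4
  w <- c(w_onset, rep(w_mid / n_mid, n_mid), rep(w_offset / 3, 3))
  weight_vector(w)
}

#' Equal onset/offset temporal weights
#'
#' Weight 0.5 on the first click and 0.5 on the last, zero elsewhere;
#' under this weighting the onset-only effective ILD is exactly half the
#' full-cue value, predicting a 50% reduction in response modulation.
#'
#' @param n_clicks Number of clicks (>= 2).
#' @return Normalized weight vector.
#' @export
equal_onset_offset_weights <- function(n_clicks = 16) {
  stopifnot(n_clicks >= 2)
  weight_vector(c(0.5, rep(0, n_clicks - 2), 0.5))
}

#' Perceptually weighted effective ILD
#'
#' The scalar cue value driving a perceptually weighted response: the
#' weight-normalized dot product of the per-click ILD profile and the
#' temporal weighting function.  With uniform weights an onset-only
#' profile yields 1/n of the condition ILD (the "average physical cue");
#' with all weight on click 1 it equals the onset ILD exactly.
#'
#' @param ild_profile Per-click ILD vector, dB.
#' @param weights Non-negative weights, same length (normalized
#'   internally).
#' @return Effective ILD in dB.
#' @export
effective_ild <- function(ild_profile, weights) {
  if (length(ild_profile) != length(weights))
    stop("'ild_profile' and 'weights' must have the same length")
  sum(ild_profile * weight_vector(weights))
}

#' Continuous-carryover (serially balanced) condition sequence
#'
#' Generates a circular sequence over `n_conditions` labels in which
#' every ordered pair of conditions, self-pairs included, occurs exactly
#' `pair_multiplicity` times as an adjacent transition (counting the
#' wrap-around).  The sequence is an Eulerian circuit of the complete
#' directed graph with self-loops, each arc duplicated
#' `pair_multiplicity` times, randomized via Hierholzer's algorithm.
#' Length is `pair_multiplicity * n_conditions^2`; each condition occurs
#' `pair_multiplicity * n_conditions` times.
#'
#' @param n_conditions Number of conditions (>= 2).
#' @param pair_multiplicity Occurrences of each ordered pair (>= 1).
#' @param seed Optional integer seed for the randomized circuit.
#' @param labels Optional character vector of length `n_conditions`; if
#'   given, the sequence is returned as labels instead of integers.
#' @return Integer (or character) condition sequence, to be read
#'   circularly.
#' @export
make_carryover_sequence <- function(n_conditions, pair_multiplicity = 1,
                                    seed = NULL, labels = NULL) {
  n <- as.integer(n_conditions)
  m <- as.integer(pair_multiplicity)
  if (n < 2) stop("'n_conditions' must be >= 2")
  if (m < 1) stop("'pair_multiplicity' must be >= 1")
  if (!is.null(labels) && length(labels) != n)
    stop("'labels' must have length 'n_conditions'")
  if (!is.null(seed)) set.seed(seed)
  # Out-edge stacks: each vertex has m copies of every target, shuffled.
  adj <- lapply(seq_len(n), function(i) sample(rep(seq_len(n), m)))
  ptr <- rep(1L, n)
  deg <- n * m
  stack <- sample(seq_len(n), 1)
  circuit <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    if (ptr[v] <= deg) {
      u <- adj[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      stack <- c(stack, u)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  circuit <- rev(circuit)
  out <- circuit[-length(circuit)]   # circular: last vertex == first
  stopifnot(length(out) == m * n^2)
  if (is.null(labels)) out else labels[out]
}

#' Ordered-pair transition counts of a circular sequence
#'
#' @param sequence Condition sequence (read circularly).
#' @param conditions Optional vector of all condition labels (defaults
#'   to the sorted unique values of `sequence`).
#' @return Square matrix of counts; `[i, j]` is the number of times
#'   condition i is immediately followed by condition j.
#' @export
transition_counts <- function(sequence, conditions = NULL) {
  if (is.null(conditions)) conditions <- sort(unique(sequence))
  from <- factor(sequence, levels = conditions)
  to <- factor(c(sequence[-1], sequence[1]), levels = conditions)
  table(from = from, to = to)
}

#' Build a run event table from a condition sequence
#'
#' Assigns trial onsets with uniform inter-trial jitter and flags
#' occasional task targets.  Trials last `trial_dur` seconds; the gap to
#' the next trial is drawn uniformly from `iti_range`.  Targets are
#' flagged by a Bernoulli process whose per-trial probability matches
#' `target_rate` (events per second) at the expected trial spacing.
#'
#' @param sequence Condition label sequence (character or numeric).
#' @param trial_dur Trial duration, seconds.
#' @param iti_range Length-2 range of the inter-trial gap, seconds.
#' @param target_rate Target rate in events per second (default once
#'   per 13 s).
#' @param seed Optional integer seed.
#' @param warmup If `TRUE`, prepend the final sequence element as a
#'   warm-up trial so every analyzed trial has its circular predecessor.
#' @param start_time Onset of the first trial, seconds.
#' @return A `data.frame` of class `event_table` with columns
#'   `trial_index`, `onset_s`, `condition`, `is_target`, `is_warmup`,
#'   plus attributes `trial_dur` and `run_duration`.
#' @export
make_run_events <- function(sequence, trial_dur = 1, iti_range = c(0, 5),
                            target_rate = 1 / 13, seed = NULL,
                            warmup = FALSE, start_time = 0) {
  if (length(sequence) == 0) stop("'sequence' must be nonempty")
  stopifnot(length(iti_range) == 2, iti_range[1] >= 0,
            iti_range[2] >= iti_range[1], trial_dur > 0, target_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  cond <- as.character(sequence)
  is_warm <- logical(length(cond))
  if (warmup) {
    cond <- c(cond[length(cond)], cond)
    is_warm <- c(TRUE, logical(length(cond) - 1))
  }
  n <- length(cond)
  gaps <- if (n > 1) stats::runif(n - 1, iti_range[1], iti_range[2]) else numeric(0)
  onsets <- start_time + c(0, cumsum(trial_dur + gaps))
  p_target <- min(1, target_rate * (trial_dur + mean(iti_range)))
  is_target <- stats::runif(n) < p_target
  ev <- data.frame(trial_index = seq_len(n), onset_s = onsets,
                   condition = cond, is_target = is_target,
                   is_warmup = is_warm, stringsAsFactors = FALSE)
  attr(ev, "trial_dur") <- trial_dur
  attr(ev, "run_duration") <- onsets[n] + trial_dur
  class(ev) <- c("event_table", "data.frame")
  ev
}
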