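#' Difference-of-gammas HRF parameters
#'
#' Parameters of the canonical two-gamma hemodynamic response function:
#' time-to-peak and full width at half maximum of the positive lobe and
#' of the undershoot, and the undershoot amplitude ratio ("dip").
#' Defaults follow the Glover-style parameterization used for auditory
#' event-related analyses: peak1 = 3.5 s, fwhm1 = 5.2 s, peak2 = 10.8 s,
#' fwhm2 = 7.35 s, dip = 0.35.
#'
#' @param peak1,fwhm1 Time-to-peak and FWHM of the positive gamma, s.
#' @param peak2,fwhm2 Time-to-peak and FWHM of the undershoot gamma, s.
#' @param dip Undershoot/peak amplitude ratio in `[0, 1)`.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak1 = 3.5, fwhm1 = 5.2, peak2 = 10.8,
                       fwhm2 = 7.35, dip = 0.35) {
  stopifnot(peak1 > 0, fwhm1 > 0, peak2 > 0, fwhm2 > 0,
            dip >= 0, dip < 1)
  structure(list(peak1 = peak1, fwhm1 = fwhm1, peak2 = peak2,
                 fwhm2 = fwhm2, dip = dip),
            class = "hrf_params")
}

# Unit-peak gamma lobe parameterized by time-to-peak p and FWHM w:
# shape a = 8 ln2 (p/w)^2, scale b = p/a; g peaks at t = a*b = p with
# value 1, and g(0) = 0.
gamma_lobe <- function(t, p, w) {
  a <- 8 * log(2) * (p / w)^2
  b <- p / a
  g <- numeric(length(t))
  pos <- t > 0
  g[pos] <- (t[pos] / p)^a * exp(-(t[pos] - p) / b)
  g
}

#' Build a sampled hemodynamic response kernel
#'
#' The kernel is the difference of two unit-peak gamma lobes,
#' `h(t) = g1(t) - dip * g2(t)`, each lobe converted from (time-to-peak,
#' FWHM) to gamma (shape, scale) via the Gaussian approximation
#' `shape = (sqrt(8 ln 2) * peak / fwhm)^2`, `scale = peak / shape`.
#' The result is normalized to unit maximum so simulated amplitudes and
#' estimated betas share units; `h(0) = 0`.
#'
#' @param params An [hrf_params()] object.
#' @param dt Sampling step, s.
#' @param duration Kernel support, s; must cover the undershoot
#'   (`peak2 + 2 * fwhm2`).
#' @return An object of class `sampled_kernel`: list with `t`, `h`,
#'   `dt`, `duration`.
#' @export
build_hrf <- function(params = hrf_params(), dt = 0.1, duration = 30) {
  stopifnot(inherits(params, "hrf_params"), dt > 0)
  if (duration < params$peak2 + 2 * params$fwhm2)
    stop("'duration' too short to contain the undershoot; need >= ",
         params$peak2 + 2 * params$fwhm2, " s")
  t <- seq(0, duration, by = dt)
  h <- gamma_lobe(t, params$peak1, params$fwhm1) -
    params$dip * gamma_lobe(t, params$peak2, params$fwhm2)
  h <- h / max(h)
  structure(list(t = t, h = h, dt = dt, duration = duration),
            class = "sampled_kernel")
}

#' Evaluate a sampled kernel at arbitrary times
#'
#' Linear interpolation of the sampled kernel; zero outside its support.
#'
#' @param kernel A [build_hrf()] kernel.
#' @param times Numeric times, s.
#' @return Kernel values at `times`.
#' @export
hrf_at <- function(kernel, times) {
  stopifnot(inherits(kernel, "sampled_kernel"))
  out <- numeric(length(times))
  inside <- times >= 0 & times <= kernel$duration
  if (any(inside))
    out[inside] <- stats::approx(kernel$t, kernel$h, xout = times[inside])$y
  out
}

# Scans x trials matrix of kernel responses: M[k, i] = h(t_k - onset_i)
# at scan times t_k = (k - 1) * TR.  BOLD superposition is then M %*% a.
event_kernel_matrix <- function(onsets, kernel, tr, n_scans) {
  scan_t <- (seq_len(n_scans) - 1) * tr
  vapply(onsets, function(o) hrf_at(kernel, scan_t - o),
         numeric(n_scans))
}

#' Superpose event responses into a scan-sampled time series
#'
#' Linear superposition `sum_i a_i * h(t - t_i)` sampled at scan times
#' `0, TR, 2 TR, ...`; linear in the amplitudes and shift-equivariant.
#'
#' @param onsets Event onset times, s.
#' @param amplitudes Event amplitudes, same length as `onsets`.
#' @param kernel A [build_hrf()] kernel.
#' @param tr Repetition time, s.
#' @param n_scans Number of scans.
#' @return Numeric vector of length `n_scans`.
#' @export
convolve_events <- function(onsets, amplitudes, kernel, tr, n_scans) {
  if (length(onsets) != length(amplitudes))
    stop("'onsets' and 'amplitudes' must have the same length")
  stopifnot(tr > 0, n_scans >= 1)
  if (length(onsets) == 0) return(numeric(n_scans))
  drop(event_kernel_matrix(onsets, kernel, tr, n_scans) %*% amplitudes)
}

#' Write a sampled kernel as two-column TSV
#'
#' @param kernel A [build_hrf()] kernel.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kernel_tsv <- function(kernel, path) {
  stopifnot(inherits(kernel, "sampled_kernel"))
  utils::write.table(data.frame(t = kernel$t, h = kernel$h), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
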