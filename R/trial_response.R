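#' Estimate single-trial response amplitudes (betas)
#'
#' For every trial and voxel the scans bracketing the 12-s window after
#' trial onset are cubic-spline interpolated onto a fine grid aligned at
#' the onset, and the interpolated trace is regressed on an intercept
#' plus the HRF sampled on the same grid.  The HRF coefficient is the
#' trial beta.  Because the kernel has unit peak, betas share units with
#' simulated ground-truth amplitudes.  Overlap from neighbouring trials
#' is not deconvolved; it is a known bias of the per-trial procedure.
#'
#' Trials whose window extends past the sampled run, or that are covered
#' by fewer than two scans, are flagged `excluded` and given `NA` betas.
#'
#' @param x A `simulated_dataset`, or a voxels x scans numeric matrix.
#' @param events Event table (required when `x` is a matrix).
#' @param hrf HRF kernel (defaults to the dataset's, else [build_hrf()]).
#' @param tr Repetition time, s (required when `x` is a matrix).
#' @param window Trial window length, s.
#' @param interp_dt Interpolation grid step, s.
#' @param subject,run,mode Optional metadata stored on the result.
#' @return An object of class `trial_betas`: list with `beta`
#'   (trials x voxels; `NA` rows for excluded trials), `condition`,
#'   `ild` (numeric, `NA` for SILENT), `excluded`, `voxels` (data frame
#'   of voxel metadata or `NULL`), and the metadata fields.
#' @export
extract_trial_betas <- function(x, events = NULL, hrf = NULL, tr = NULL,
                                window = 12, interp_dt = 0.1,
                                subject = NA, run = NA, mode = NA) {
  if (inherits(x, "simulated_dataset")) {
    bold <- x$bold
    if (is.null(events)) events <- x$events
    if (is.null(hrf)) hrf <- x$hrf
    if (is.null(tr)) tr <- x$tr
    if (is.na(mode)) mode <- x$mode
    voxels <- x$population[, intersect(c("voxel_id", "roi", "hemisphere"),
                                       names(x$population)), drop = FALSE]
  } else {
    bold <- as.matrix(x)
    if (is.null(events) || is.null(tr))
      stop("'events' and 'tr' are required when 'x' is a matrix")
    if (is.null(hrf)) hrf <- build_hrf()
    voxels <- NULL
  }
  stopifnot(window > 0, interp_dt > 0)
  n_scans <- ncol(bold)
  n_vox <- nrow(bold)
  scan_t <- (seq_len(n_scans) - 1) * tr
  grid <- seq(0, window, by = interp_dt)
  hgrid <- hrf_at(hrf, grid)
  design <- cbind(intercept = 1, hrf = hgrid)
  # one shared projector: beta = 2nd row of (X'X)^-1 X' applied to traces
  beta_row <- solve(crossprod(design), t(design))[2, ]
  n_trials <- nrow(events)
  beta <- matrix(NA_real_, n_trials, n_vox)
  excluded <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    onset <- events$onset_s[i]
    sel <- which(scan_t >= onset - 2 * tr & scan_t <= onset + window + 2 * tr)
    n_in <- sum(scan_t >= onset & scan_t <= onset + window)
    if (n_in < 2 || onset + window > scan_t[n_scans]) {
      excluded[i] <- TRUE
      next
    }
    xs <- scan_t[sel]
    interp <- vapply(seq_len(n_vox), function(v)
      stats::spline(xs, bold[v, sel], xout = onset + grid,
                    method = "natural")$y,
      numeric(length(grid)))
    beta[i, ] <- beta_row %*% interp
  }
  cond <- as.character(events$condition)
  structure(list(beta = beta, condition = cond,
                 ild = suppressWarnings(as.numeric(cond)),
                 excluded = excluded,
                 is_warmup = if (!is.null(events$is_warmup))
                   events$is_warmup else logical(n_trials),
                 voxels = voxels,
                 subject = subject, run = run, mode = mode),
            class = "trial_betas")
}

#' @export
print.trial_betas <- function(x, ...) {
  cat(sprintf("trial_betas: %d trials x %d voxels (%d excluded)\n",
              nrow(x$beta), ncol(x$beta), sum(x$excluded)))
  if (!is.na(x$mode)) cat(" mode:", x$mode, "\n")
  invisible(x)
}

#' Subset a trial-beta object
#'
#' Filters voxels by ROI/hemisphere and drops SILENT, warm-up, or
#' excluded trials, the standard preparation before tuning or
#' classification analyses.
#'
#' @param tb A [extract_trial_betas()] object.
#' @param roi,hemisphere Optional voxel filters (require voxel
#'   metadata).
#' @param drop_silent Drop SILENT trials.
#' @param drop_excluded Drop flagged/warm-up trials.
#' @return A filtered `trial_betas` object.
#' @export
filter_betas <- function(tb, roi = NULL, hemisphere = NULL,
                         drop_silent = TRUE, drop_excluded = TRUE) {
  stopifnot(inherits(tb, "trial_betas"))
  keep_v <- rep(TRUE, ncol(tb$beta))
  if (!is.null(roi) || !is.null(hemisphere)) {
    if (is.null(tb$voxels)) stop("no voxel metadata to filter on")
    if (!is.null(roi)) keep_v <- keep_v & tb$voxels$roi %in% roi
    if (!is.null(hemisphere))
      keep_v <- keep_v & tb$voxels$hemisphere %in% hemisphere
  }
  keep_t <- rep(TRUE, nrow(tb$beta))
  if (drop_silent) keep_t <- keep_t & tb$condition != "SILENT"
  if (drop_excluded) keep_t <- keep_t & !tb$excluded & !tb$is_warmup
  out <- tb
  out$beta <- tb$beta[keep_t, keep_v, drop = FALSE]
  out$condition <- tb$condition[keep_t]
  out$ild <- tb$ild[keep_t]
  out$excluded <- tb$excluded[keep_t]
  out$is_warmup <- tb$is_warmup[keep_t]
  if (!is.null(tb$voxels)) out$voxels <- tb$voxels[keep_v, , drop = FALSE]
  out
}
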