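# Small end-to-end fixture: one ROI/hemisphere population, one carryover
# run, simulated BOLD, extracted and filtered betas.
quick_pipeline <- function(seed, mode = "full_cue",
                           weights = uniform_weights(16),
                           roi = "pSTG", hemisphere = "L", n_vox = 40,
                           pair_multiplicity = 1, noise_sd = NULL,
                           iti_range = c(0, 5), ...) {
  pop_args <- list(n_per_roi = n_vox, rois = roi,
                   hemispheres = hemisphere, seed = seed, ...)
  if (!is.null(noise_sd)) pop_args$noise_sd <- noise_sd
  pop <- do.call(make_voxel_population, pop_args)
  sq <- make_carryover_sequence(length(study_conditions()),
                                pair_multiplicity, seed = seed + 1,
                                labels = study_conditions())
  ev <- make_run_events(sq, iti_range = iti_range, seed = seed + 2)
  ds <- simulate_experiment(pop, ev, mode, weights, seed = seed + 3)
  tb <- filter_betas(extract_trial_betas(ds))
  list(pop = pop, events = ev, ds = ds, tb = tb)
}

# Trial-beta stub built directly from a feature matrix and labels, for
# classifier tests that do not need the hemodynamic forward model.
beta_stub <- function(beta, ild) {
  structure(list(beta = beta, condition = as.character(ild),
                 ild = as.numeric(ild),
                 excluded = logical(nrow(beta)),
                 is_warmup = logical(nrow(beta)),
                 voxels = NULL, subject = NA, run = NA, mode = NA),
            class = "trial_betas")
}

# Gaussian class-separated features: k classes, n per class, separation
# delta between adjacent class means on every voxel.
separated_features <- function(classes = ild_levels(), n_per_class = 6,
                               n_vox = 10, delta = 1, noise = 1,
                               seed = 1) {
  set.seed(seed)
  ild <- rep(classes, each = n_per_class)
  mean_of <- delta * (match(ild, classes) - 1)
  beta <- matrix(stats::rnorm(length(ild) * n_vox, sd = noise),
                 length(ild), n_vox) + mean_of
  beta_stub(beta, ild)
}

# Two concatenated runs per condition mode, mirroring the study's two
# imaging runs per stimulus type; betas stacked with a run index.
two_run_betas <- function(seed, mode, weights, roi, n_vox = 100,
                          hemisphere = "L") {
  pop <- make_voxel_population(n_per_roi = n_vox, rois = roi,
                               hemispheres = hemisphere, seed = seed)
  tbs <- lapply(1:2, function(r) {
    sq <- make_carryover_sequence(10, 2, seed = seed + r,
                                  labels = study_conditions())
    ev <- make_run_events(sq, seed = seed + 10 + r)
    ds <- simulate_experiment(pop, ev, mode, weights,
                              seed = seed + 20 + r)
    filter_betas(extract_trial_betas(ds))
  })
  tb <- tbs[[1]]
  tb$beta <- rbind(tbs[[1]]$beta, tbs[[2]]$beta)
  tb$condition <- c(tbs[[1]]$condition, tbs[[2]]$condition)
  tb$ild <- c(tbs[[1]]$ild, tbs[[2]]$ild)
  tb$excluded <- c(tbs[[1]]$excluded, tbs[[2]]$excluded)
  tb$is_warmup <- c(tbs[[1]]$is_warmup, tbs[[2]]$is_warmup)
  tb$run <- rep(1:2, times = c(nrow(tbs[[1]]$beta), nrow(tbs[[2]]$beta)))
  tb
}

# Shared chance-level permutation null (one run covers the two
# chance-calibration checks).
.chance_cache <- new.env(parent = emptyenv())
chance_null <- function() {
  if (!exists("perm", envir = .chance_cache)) {
    px <- quick_pipeline(seed = 101, n_vox = 40, pair_multiplicity = 2)
    .chance_cache$tb <- px$tb
    .chance_cache$perm <- permutation_test(px$tb, n_perm = 25,
                                           n_repeats = 10,
                                           observed_repeats = 10,
                                           seed = 102)
  }
  list(tb = .chance_cache$tb, perm = .chance_cache$perm)
}
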