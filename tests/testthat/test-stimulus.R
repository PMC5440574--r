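test_that("gabor click peaks at the center frequency with the requested bandwidth", {
  fs <- 44100
  clk <- make_gabor_click(4000, 0.8, fs)
  nfft <- 2^16
  spec <- Mod(stats::fft(c(clk, numeric(nfft - length(clk)))))[1:(nfft / 2)]
  freq <- (seq_len(nfft / 2) - 1) * fs / nfft
  # spectral peak within one FFT bin of 4000 Hz
  expect_lt(abs(freq[which.max(spec)] - 4000), fs / nfft + 1e-9)
  # measured half-power width matches the requested octave bandwidth
  half_power <- which(spec >= max(spec) / sqrt(2))
  measured_bw <- freq[max(half_power)] - freq[min(half_power)]
  requested_bw <- 4000 * (2^0.4 - 2^-0.4)
  expect_equal(measured_bw / requested_bw, 1, tolerance = 0.02)
  # envelope symmetric about its maximum
  env <- abs(clk)
  expect_equal(clk, rev(clk), tolerance = 1e-12)
  expect_equal(which.max(env), (length(clk) + 1) / 2)
})

test_that("gabor click rejects aliasing-prone and non-positive parameters", {
  expect_error(make_gabor_click(4000, 0.8, 8000), "sample_rate")
  expect_error(make_gabor_click(-1, 0.8, 44100), "center_freq")
  expect_error(make_gabor_click(4000, 0, 44100), "bandwidth_oct")
})

test_that("rendered click trains honor the ILD split and the ABL", {
  # zero ILD: channels identical sample-for-sample
  sp0 <- click_train_spec(ild_profile = rep(0, 16))
  wf0 <- render_click_train(sp0)
  expect_identical(wf0$left, wf0$right)
  expect_equal(length(wf0$left), length(wf0$right))
  expect_true(all(is.finite(c(wf0$left, wf0$right))))

  # +30 dB full-cue: right/left RMS ratio is 10^(30/20)
  sp30 <- click_train_spec(ild_profile = rep(30, 16))
  wf30 <- render_click_train(sp30)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(wf30$right) / rms(wf30$left), 10^(30 / 20),
               tolerance = 1e-6)

  # ABL energy identity: the product of per-ear gains is independent of
  # the ILD, so RMS_L * RMS_R is constant across conditions
  prods <- vapply(ild_levels(), function(d) {
    wf <- render_click_train(click_train_spec(ild_profile = rep(d, 16)))
    log(rms(wf$left)) + log(rms(wf$right))
  }, numeric(1))
  expect_lt(max(prods) - min(prods), 1e-9)
})

test_that("train duration is n_clicks * ici (16 clicks at 2 ms = 32 ms)", {
  expect_identical(train_duration(click_train_spec()), 16 * 0.002)
  expect_error(click_train_spec(ild_profile = rep(0, 5)), "length")
})

test_that("ILD profiles follow the full-cue and onset-only definitions", {
  expect_equal(make_ild_profile(20, "full_cue", 16), rep(20, 16))
  expect_equal(make_ild_profile(20, "onset_only", 16),
               c(20, rep(0, 15)))
  expect_equal(make_ild_profile(0, "onset_only", 16),
               make_ild_profile(0, "full_cue", 16))
  expect_error(make_ild_profile(20, "sideways", 16))
})

test_that("effective ILD is the weight-normalized dot product", {
  onset30 <- make_ild_profile(30, "onset_only", 16)
  # uniform weighting: the average physical cue, 30/16
  expect_equal(effective_ild(onset30, uniform_weights(16)), 30 / 16)
  # equal onset/offset weighting: half the full-cue value
  expect_equal(effective_ild(onset30, equal_onset_offset_weights(16)), 15)
  # all weight on click 1: the onset ILD exactly
  delta <- c(1, rep(0, 15))
  set.seed(7)
  prof <- stats::rnorm(16, sd = 10)
  expect_equal(effective_ild(prof, delta), prof[1])
  # linearity in the profile
  for (a in c(-2, 0.5, 3)) {
    w <- stats::runif(16)
    expect_equal(effective_ild(a * prof, w), a * effective_ild(prof, w))
  }
  expect_error(effective_ild(prof, rep(1, 4)), "length")
  expect_error(weight_vector(c(-1, 2)), "non-negative")
})

test_that("two-condition carryover sequence matches brute-force enumeration", {
  # all circular length-4 sequences over {1,2} whose ordered-pair
  # transition counts are exactly one each
  grids <- expand.grid(rep(list(1:2), 4))
  valid <- apply(grids, 1, function(s) {
    tc <- table(factor(s, levels = 1:2),
                factor(c(s[-1], s[1]), levels = 1:2))
    all(tc == 1)
  })
  valid_set <- apply(grids[valid, ], 1, paste, collapse = "")
  for (seed in 1:5) {
    s <- make_carryover_sequence(2, 1, seed = seed)
    expect_length(s, 4)
    expect_true(paste(s, collapse = "") %in% valid_set)
  }
})

test_that("carryover sequences are serially balanced for every tested size", {
  for (cfg in list(c(3, 1), c(4, 2), c(10, 2), c(9, 3))) {
    n <- cfg[1]; m <- cfg[2]
    s <- make_carryover_sequence(n, m, seed = n * 10 + m)
    expect_length(s, m * n^2)
    expect_true(all(table(s) == m * n))
    expect_true(all(transition_counts(s, 1:n) == m))
  }
  # the study design: 10 conditions, multiplicity 2, labelled
  s <- make_carryover_sequence(10, 2, seed = 42,
                               labels = study_conditions())
  expect_length(s, 200)
  expect_true(all(table(s) == 20))
  # determinism: same seed, same sequence
  expect_identical(s, make_carryover_sequence(10, 2, seed = 42,
                                              labels = study_conditions()))
  expect_error(make_carryover_sequence(1, 1), ">= 2")
})

test_that("run event tables respect trial timing and target flags", {
  sq <- make_carryover_sequence(10, 2, seed = 1,
                                labels = study_conditions())
  ev <- make_run_events(sq, seed = 2)
  expect_s3_class(ev, "event_table")
  expect_true(all(diff(ev$onset_s) > 0))
  gaps <- diff(ev$onset_s) - 1
  expect_true(all(gaps >= 0 & gaps <= 5))
  # expected duration about 200 * (1 + 2.5) = 700 s
  expect_gt(attr(ev, "run_duration"), 600)
  expect_lt(attr(ev, "run_duration"), 800)

  # no jitter: onsets exactly 1 s apart
  ev0 <- make_run_events(sq, iti_range = c(0, 0), seed = 3)
  expect_equal(diff(ev0$onset_s), rep(1, 199))

  # no targets when the rate is zero
  evt <- make_run_events(sq, target_rate = 0, seed = 4)
  expect_false(any(evt$is_target))

  # warm-up trial repeats the circular predecessor of trial 1
  evw <- make_run_events(sq, seed = 5, warmup = TRUE)
  expect_equal(nrow(evw), 201)
  expect_true(evw$is_warmup[1])
  expect_identical(evw$condition[1], sq[length(sq)])
  expect_error(make_run_events(character(0)), "nonempty")
})
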