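Package: ildecode
Title: Simulation and Decoding of Interaural Level Difference Tuning in
    Auditory Cortex fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Synthesizes binaural Gabor click-train stimuli carrying
    full-cue or onset-only interaural level difference (ILD) profiles,
    builds serially balanced continuous-carryover trial sequences, and
    simulates event-related BOLD responses of ILD-tuned voxel populations
    under sensory (uniform) or perceptual (onset-dominant) temporal
    cue-weighting hypotheses.  Single-trial response amplitudes are
    estimated by regression of interpolated 12-s trial time courses
    against a difference-of-gammas hemodynamic response function; ILD
    tuning is quantified with repeated-measures ANOVA, side-grouped
    paired contrasts with false-discovery-rate control, and multi-voxel
    pattern classification (linear support vector machine over repeated
    stratified half-splits) with label-permutation inference on accuracy
    and root-mean-square decoding error.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
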