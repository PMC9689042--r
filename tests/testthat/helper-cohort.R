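# The full-scale calibrated study cohort (100 early + 100 advanced
# images, 5 ROIs of 64x64 each, master seed 7, calibration pilot seed 8)
# is expensive; build it lazily and share it across acceptance blocks.
.studyEnv <- new.env()
studyCohort <- function() {
  if (is.null(.studyEnv$ft)) {
    cfg <- calibrateGenerator(simulationConfig(), tolerance = 0.05,
                              seed = 8)
    co <- generateCohort(cfg, 100, 100, 5, seed = 7)
    .studyEnv$config <- cfg
    .studyEnv$ft <- extractFeatureTable(co)
  }
  list(config = .studyEnv$config, ft = .studyEnv$ft)
}
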