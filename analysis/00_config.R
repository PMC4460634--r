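# Shared settings for the analysis drivers. Each numbered script can be run
# standalone (later scripts read the earlier scripts' outputs from `outdir`).
library(grngpea)

outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- list(
  seed = 42L,      # master seed; every stage derives its own stream from it
  p = 400L,        # genes
  n = 180L,        # samples (the scale of a typical tumor cohort)
  B = 50L,         # bootstrap ensemble size
  n_draws = 25000L # permutation null pool size
)
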