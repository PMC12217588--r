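#!/usr/bin/env Rscript
# Step 1: simulate one n = 50 cohort per treatment preset and write the
# cohort CSVs under results/cohorts/. Re-running reproduces the same files.

suppressPackageStartupMessages(library(twosexlt))

seed <- 20250101L
dir.create("results/cohorts", showWarnings = FALSE, recursive = TRUE)

presets <- c("control", "paw1", "paw2")
for (i in seq_along(presets)) {
  spec <- preset_spec(presets[i])
  co <- generate_cohort(spec, seed = seed + i)
  path <- file.path("results/cohorts", paste0(presets[i], ".csv"))
  write_cohort(co, path)
  cat(sprintf("%-8s n01=%d adults=%d total eggs=%d -> %s\n",
              presets[i], co$n01, sum(co$records$sex != "N"),
              sum(co$eggs), path))
}
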