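#!/usr/bin/env Rscript
# Fit the seven-parameter dissolution model to the alkali-thermal dataset
# under the four model readings. Note: the published parameter vector for
# this dataset reproduces neither the published SSE (it evaluates to
# ~4.7e9) nor the published R^2; the refit here reports what the model and
# the printed table actually support.

suppressMessages(library(sludgekin))

sweep <- fit_variant_sweep(load_alkali_dataset())
message("sweep over model readings (alkali):")
print(sweep)

best <- sweep$fits[[sweep$best]]
message(sprintf("best reading: %s form, energy scale %g",
                best$model_config$solution_form, best$model_config$energy_scale))
message(sprintf("SSE %.4g (mg/L)^2 (published 2.828e7), R^2 %.4f (published 0.892)",
                best$sse, best$r_squared))

# audit of the published statistics against the printed table
y <- load_alkali_dataset()$data$protein_mg_L
sst <- sum((y - mean(y))^2)
message(sprintf("published SSE implies R^2 = %.4f; published R^2 is 0.892:",
                1 - 2.828e7 / sst))
message("the published SSE/R^2 pair is mutually inconsistent with its own table")

run_fit_workflow("alkali", "results/alkali_fit",
                 model_config = best$model_config)
write.csv(sweep$summary, "results/alkali_fit/variant_sweep.csv",
          row.names = FALSE, quote = FALSE)
message("wrote results/alkali_fit/")
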