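#!/usr/bin/env Rscript
# Compare sulfuric-acid and sodium-hydroxide catalysis through the fitted
# rate laws: rate constants evaluated at each catalyst's own working
# concentration and at a shared concentration, plus the catalyst influence
# coefficients f1 (lysis) and f2 (proteolysis).

suppressMessages(library(sludgekin))
dir.create("results", showWarnings = FALSE)

acid_fit <- fit_kinetics(load_acid_dataset())
alk_fit <- fit_kinetics(load_alkali_dataset())

# shared reference condition: 120 C, 3 h, alkali-side concentration (both
# catalysts' ranges contain it only on the alkali side, so also evaluate at
# each catalyst's fixture median)
shared <- reaction_conditions(3, 10800, 120, 65)
cmp <- compare_catalysts(acid_fit, alk_fit, shared)
print(cmp)

acid_med <- median(load_acid_dataset()$data$catalyst_conc)
alk_med <- median(load_alkali_dataset()$data$catalyst_conc)
own_a <- sludgekin:::rate_constants(acid_fit$params,
  reaction_conditions(acid_med, 10800, 120, 65), acid_fit$model_config)
own_b <- sludgekin:::rate_constants(alk_fit$params,
  reaction_conditions(alk_med, 10800, 120, 65), alk_fit$model_config)
message(sprintf("at own working concentrations (acid %g, alkali %g g/kg):",
                acid_med, alk_med))
message(sprintf("  Kf acid %.4g vs alkali %.4g 1/s; Ks acid %.4g vs alkali %.4g 1/s",
                own_a$Kf, own_b$Kf, own_a$Ks, own_b$Ks))

out <- data.frame(
  quantity = c("Kf_shared_acid", "Kf_shared_alkali", "Ks_shared_acid",
               "Ks_shared_alkali", "Kf_ratio", "Ks_ratio", "f1_acid",
               "f1_alkali", "f2_acid", "f2_alkali",
               "Kf_own_acid", "Kf_own_alkali", "Ks_own_acid", "Ks_own_alkali"),
  value = c(cmp$Kf_acid, cmp$Kf_alkali, cmp$Ks_acid, cmp$Ks_alkali,
            cmp$Kf_ratio, cmp$Ks_ratio,
            unclass(acid_fit$params)[["f1"]], unclass(alk_fit$params)[["f1"]],
            unclass(acid_fit$params)[["f2"]], unclass(alk_fit$params)[["f2"]],
            own_a$Kf, own_b$Kf, own_a$Ks, own_b$Ks))
write.csv(out, "results/catalyst_comparison.csv", row.names = FALSE,
          quote = FALSE)
message("wrote results/catalyst_comparison.csv")
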