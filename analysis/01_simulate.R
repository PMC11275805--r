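#!/usr/bin/env Rscript
# Simulate the screen: saturation library, ground-truth fitness, pooled
# selection counts for every condition, and the per-(variant, inhibitor)
# feature table for the predictor.

source("analysis/00_config.R")

lib <- build_library(REGION_START, REGION_END, WT_SEQ, stop_spacing = 11)
say("library: %d variants over %d positions (%d missense, %d synonymous, %d stop controls)",
    nrow(lib), REGION_END - REGION_START + 1,
    sum(lib$var_class == "missense"), sum(lib$var_class == "synonymous"),
    sum(lib$var_class == "nonsense"))

effects <- assign_true_scores(lib, CONDITIONS, RESISTANCE_SPEC,
                              seed = derive_seed(SEED, "effects"))
dmso <- effects[effects$condition == "DMSO", ]
say("DMSO truth: %.0f%% neutral-like (score > -0.5), %.0f%% deleterious",
    100 * mean(dmso$true_score > -0.5), 100 * mean(dmso$true_score <= -0.5))

counts <- do.call(rbind, lapply(CONDITIONS$condition, function(cn) {
  d <- DESIGN
  d$seed <- derive_seed(SEED, paste0("counts_", cn))
  simulate_counts(effects, cn, d, CONDITIONS)
}))
write_counts(counts, file.path(OUT, "counts.tsv"))
say("counts: %d cells across %d conditions at depth %g",
    nrow(counts), nrow(CONDITIONS), DESIGN$depth)

inh <- CONDITIONS[CONDITIONS$inhibitor_type != "DMSO", ]
features <- simulate_feature_table(lib, inh, effects,
                                   seed = derive_seed(SEED, "features"))
say("features: %d rows x %d catalogue features", nrow(features),
    length(feature_catalog()))

utils::write.table(CONDITIONS, file.path(OUT, "conditions.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
metdms:::met_write_tsv(effects, file.path(OUT, "true_scores.tsv"))
metdms:::met_write_tsv(features, file.path(OUT, "features.tsv"))
say("wrote counts.tsv, conditions.tsv, true_scores.tsv, features.tsv to %s", OUT)
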