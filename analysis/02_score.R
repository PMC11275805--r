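#!/usr/bin/env Rscript
# Filter count support, score every condition on the doubling-rate scale,
# recenter on DMSO, and compare conditions by Pearson correlation.

source("analysis/00_config.R")

tabs <- read_counts(file.path(OUT, "counts.tsv"))
filt <- lapply(tabs, filter_variants)
for (cn in names(filt)) {
  r <- filt[[cn]]$report
  say("%s: kept %d / %d variants (%d low mean, %d sparse, %d sparse at T0)",
      cn, sum(r$kept), nrow(r), sum(r$reason == "low_mean_count"),
      sum(r$reason == "high_zero_fraction"),
      sum(r$reason == "high_t0_zero_fraction"))
}
metdms:::met_write_tsv(do.call(rbind, lapply(filt, `[[`, "report")),
                       file.path(OUT, "filter_report.tsv"))

scores <- lapply(filt, function(f) {
  score_condition(normalize_counts(f$counts))
})
metdms:::met_write_tsv(do.call(rbind, scores), file.path(OUT, "scores.tsv"))

truth <- metdms:::met_read_tsv(file.path(OUT, "true_scores.tsv"))
for (cn in names(scores)) {
  sc <- scores[[cn]]
  tr <- truth[truth$condition == cn, ]
  m <- merge(sc, tr[, c("position", "mut_aa", "true_score")],
             by = c("position", "mut_aa"))
  say("%s: score vs truth r = %.3f, rmse = %.3f", cn,
      cor(m$beta, m$true_score, use = "complete.obs"),
      sqrt(mean((m$beta - m$true_score)^2, na.rm = TRUE)))
}

dmso_scores <- scores$DMSO
recentered <- lapply(scores[setdiff(names(scores), "DMSO")], recenter,
                     scores_dmso = dmso_scores)
metdms:::met_write_tsv(do.call(rbind, recentered),
                       file.path(OUT, "recentered.tsv"))

cm <- correlation_matrix(scores, value = "beta")
metdms:::met_write_tsv(data.frame(condition = rownames(cm),
                                  as.data.frame(cm), check.names = FALSE),
                       file.path(OUT, "correlations.tsv"))
types <- CONDITIONS$inhibitor_type[match(rownames(cm), CONDITIONS$condition)]
within_I <- cm[types == "I_a", types == "I_a"]
across <- cm[types == "I_a", types == "II"]
say("condition correlations: within type I mean r = %.2f, type I vs II mean r = %.2f",
    mean(within_I[upper.tri(within_I)]), mean(across))

hm <- make_heatmap_table(recentered[[1]], value = "gamma")
metdms:::met_write_tsv(hm, file.path(OUT, paste0("heatmap_",
                                                 names(recentered)[1], ".tsv")))
say("wrote filter_report, scores, recentered, correlations, heatmap tables")
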