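#!/usr/bin/env Rscript
# Resistance classification: per-inhibitor resistance mutations and
# positions, hotspot aggregation by inhibitor type, type-exclusive variant
# sets, and the most divergent type I vs type II inhibitor pair.

source("analysis/00_config.R")

scores_all <- metdms:::met_read_tsv(file.path(OUT, "scores.tsv"))
scores <- split(scores_all, scores_all$condition)
inh_names <- setdiff(names(scores), "DMSO")

calls <- lapply(scores[inh_names], call_resistance,
                scores_dmso = scores$DMSO)
calls_all <- do.call(rbind, calls)
metdms:::met_write_tsv(calls_all, file.path(OUT, "calls.tsv"))
for (cn in inh_names) {
  say("%s: %d resistance mutations at %d positions", cn,
      sum(calls[[cn]]$is_resistance, na.rm = TRUE),
      length(resistance_positions(calls[[cn]])[[cn]]))
}

# how many planted pairs were recovered?
truth <- metdms:::met_read_tsv(file.path(OUT, "true_scores.tsv"))
planted <- unique(variant_id(truth[truth$component == "resistant", ]))
hit <- unique(variant_id(calls_all[!is.na(calls_all$is_resistance) &
                                     calls_all$is_resistance, ]))
say("planted resistance variants recovered under >= 1 inhibitor: %d / %d",
    length(intersect(planted, hit)), length(planted))

hs <- hotspot_counts(calls_all, CONDITIONS)
metdms:::met_write_tsv(hs$counts, file.path(OUT, "hotspots.tsv"))
top <- do.call(rbind, lapply(split(hs$counts, hs$counts$inhibitor_type),
                             function(d) d[which.max(d$count), ]))
for (i in seq_len(nrow(top))) {
  say("top hotspot for type %s: position %d (%d resistance calls)",
      top$inhibitor_type[i], top$position[i], top$count[i])
}
shared <- hs$shared_sets
metdms:::met_write_tsv(
  data.frame(type_combination = rep(names(shared), lengths(shared)),
             variant = unlist(shared, use.names = FALSE)),
  file.path(OUT, "shared_sets.tsv"))
cross <- shared[grepl("\\+", names(shared))]
say("variants resistant across >= 2 inhibitor types: %d",
    length(unlist(cross)))

excl <- type_exclusive_resistance(calls_all, CONDITIONS)
metdms:::met_write_tsv(
  data.frame(inhibitor_type = rep(names(excl), lengths(excl)),
             variant = unlist(excl, use.names = FALSE)),
  file.path(OUT, "type_exclusive.tsv"))
say("type-exclusive resistance variants: %s",
    paste(sprintf("%s=%d", names(excl), lengths(excl)), collapse = ", "))

# divergent pair: first type I vs first type II inhibitor
a <- CONDITIONS$condition[match("I_a", CONDITIONS$inhibitor_type)]
b <- CONDITIONS$condition[match("II", CONDITIONS$inhibitor_type)]
dp <- differential_pairs(calls[[a]], calls[[b]])
metdms:::met_write_tsv(
  data.frame(direction = rep(c(paste0("gof_", a, "_lof_", b),
                               paste0("gof_", b, "_lof_", a)), lengths(dp)),
             variant = unlist(dp, use.names = FALSE)),
  file.path(OUT, "differential_pairs.tsv"))
say("%s vs %s: %d mutations GOF in %s / LOF in %s; %d with the opposite profile",
    a, b, length(dp$gof_a_lof_b), a, b, length(dp$gof_b_lof_a))
say("wrote calls, hotspots, shared_sets, type_exclusive, differential_pairs")
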