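#' Demo run configuration
#'
#' A small but fully featured experiment: a contiguous library region with
#' stop controls, a DMSO control plus two type I and two type II
#' inhibitors (and optionally one type I 1/2), planted resistance sites per
#' type, multinomial sequencing at moderate depth, and the default
#' thresholds of every analysis stage (mean count >= 4, zero fractions
#' <= 10/12 and <= 2/3, pseudocount 0.5, resistance test at cutoff 0.1
#' against effect threshold 0.5, DMSO cutoff 0, GOF threshold 0.75).
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param n_positions library length in residues.
#' @param depth reads per (replicate, timepoint) sample.
#' @param run_ml run the feature-augmented predictor stage.
#' @return nested configuration list consumed by [run_pipeline()].
#' @export
demo_config <- function(seed = 1, n_positions = 40, depth = 2e5,
                        run_ml = FALSE) {
  region_start <- 1059
  region_end <- region_start + n_positions - 1
  wt_seq <- paste(with_seed(derive_seed(seed, "wtseq"),
                            sample(AA_STANDARD, n_positions, replace = TRUE)),
                  collapse = "")
  conditions <- make_conditions(
    name = c("DMSO", "inhA1", "inhA2", "inhB1", "inhB2"),
    inhibitor_type = c("DMSO", "I_a", "I_a", "II", "II"))
  if (n_positions < 10) stop_input("demo_config needs n_positions >= 10")
  pos <- region_start:region_end
  idx <- pmax(1, round(n_positions * c(0.15, 0.15, 0.35, 0.55, 0.75)))
  resistance_spec <- list(
    I_a = data.frame(position = pos[idx[1:3]], mut_aa = c("R", "K", "H")),
    II = data.frame(position = pos[idx[4:5]], mut_aa = c("M", "F")))
  list(region_start = region_start, region_end = region_end,
       wt_sequence = wt_seq, stop_spacing = 11,
       conditions = conditions, resistance_spec = resistance_spec,
       effect_params = default_effect_params(),
       design = sim_design(depth = depth, seed = derive_seed(seed, "counts")),
       filter = list(mean_min = 4, zero_frac_max = 10 / 12,
                     zero_frac_t0_max = 2 / 3),
       scoring = list(pseudocount = 0.5, method = "counting"),
       classify = list(tail_cutoff = 0.1, effect_cutoff_beta = 0.5,
                       dmso_cutoff = 0, gof_threshold = 0.75),
       ml = list(enabled = run_ml, subset_cap = 16, hp_budget = 5, k = 5,
                 heldout_position_fraction = 0.20, tune_fraction = 0.20),
       seed = seed)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> filter -> score -> recenter -> correlate ->
#' classify -> hotspots -> differential comparison (-> optional predictor)
#' and writes every intermediate table as TSV plus a JSON manifest with
#' per-file checksums and all stage parameters. Re-running with the same
#' config reproduces byte-identical tables.
#'
#' @param config configuration list, see [demo_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con))
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    met_write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  log_line(con, "stage simulate: library %d-%d", config$region_start,
           config$region_end)
  lib <- build_library(config$region_start, config$region_end,
                       config$wt_sequence, config$stop_spacing)
  effects <- assign_true_scores(lib, config$conditions,
                                config$resistance_spec, config$effect_params,
                                seed = derive_seed(config$seed, "effects"))
  emit(effects, "true_scores.tsv")
  counts_all <- do.call(rbind, lapply(config$conditions$condition, function(cn) {
    d <- config$design
    d$seed <- derive_seed(config$seed, paste0("counts_", cn))
    simulate_counts(effects, cn, d, config$conditions)
  }))
  counts_path <- file.path(out_dir, "counts.tsv")
  write_counts(counts_all, counts_path)
  outputs <- c(outputs, counts_path)

  log_line(con, "stage filter")
  tabs <- read_counts(counts_path)
  filt <- lapply(tabs, function(tb) do.call(filter_variants,
                                            c(list(tb), config$filter)))
  emit(do.call(rbind, lapply(filt, `[[`, "report")), "filter_report.tsv")

  log_line(con, "stage score (%s)", config$scoring$method)
  scores <- lapply(filt, function(f) {
    score_condition(normalize_counts(f$counts, config$scoring$pseudocount),
                    method = config$scoring$method)
  })
  emit(do.call(rbind, scores), "scores.tsv")

  dmso_name <- config$conditions$condition[config$conditions$inhibitor_type == "DMSO"]
  inh_names <- setdiff(names(scores), dmso_name)
  log_line(con, "stage recenter vs %s", dmso_name)
  recentered <- lapply(scores[inh_names], recenter,
                       scores_dmso = scores[[dmso_name]])
  emit(do.call(rbind, recentered), "recentered.tsv")

  log_line(con, "stage correlate")
  cm <- correlation_matrix(scores, value = "beta")
  emit(data.frame(condition = rownames(cm), as.data.frame(cm),
                  check.names = FALSE), "correlations.tsv")

  log_line(con, "stage classify")
  calls <- lapply(inh_names, function(cn) {
    do.call(call_resistance, c(list(scores[[cn]], scores[[dmso_name]]),
                               config$classify))
  })
  names(calls) <- inh_names
  calls_all <- do.call(rbind, calls)
  emit(calls_all, "calls.tsv")

  log_line(con, "stage hotspots")
  hs <- hotspot_counts(calls_all, config$conditions)
  emit(hs$counts, "hotspots.tsv")
  shared <- if (length(hs$shared_sets)) {
    data.frame(type_combination = rep(names(hs$shared_sets),
                                      lengths(hs$shared_sets)),
               variant = unlist(hs$shared_sets, use.names = FALSE))
  } else data.frame(type_combination = character(0), variant = character(0))
  emit(shared, "shared_sets.tsv")
  excl <- type_exclusive_resistance(calls_all, config$conditions)
  emit(data.frame(inhibitor_type = rep(names(excl), lengths(excl)),
                  variant = unlist(excl, use.names = FALSE)),
       "type_exclusive.tsv")

  types <- config$conditions$inhibitor_type
  a <- config$conditions$condition[match("I_a", types)]
  b <- config$conditions$condition[match("II", types)]
  if (!is.na(a) && !is.na(b)) {
    log_line(con, "stage compare: %s vs %s", a, b)
    dp <- differential_pairs(calls[[a]], calls[[b]],
                             gof_threshold = config$classify$gof_threshold)
    emit(data.frame(direction = rep(c(paste0("gof_", a, "_lof_", b),
                                      paste0("gof_", b, "_lof_", a)),
                                    lengths(dp)),
                    variant = unlist(dp, use.names = FALSE)),
         "differential_pairs.tsv")
  }

  for (cn in inh_names[1]) {
    emit(make_heatmap_table(recentered[[cn]], value = "gamma"),
         paste0("heatmap_", cn, ".tsv"))
  }

  if (isTRUE(config$ml$enabled)) {
    log_line(con, "stage mlfit")
    inh_meta <- config$conditions[config$conditions$inhibitor_type != "DMSO", ]
    feats <- simulate_feature_table(lib, inh_meta, effects,
                                    seed = derive_seed(config$seed, "features"))
    emit(feats, "features.tsv")
    target <- do.call(rbind, recentered)
    key_f <- paste(variant_id(feats), feats$inhibitor)
    key_t <- paste(variant_id(target), target$inhibitor)
    feats$target <- target$beta_inh[match(key_f, key_t)]
    feats <- feats[!is.na(feats$target), ]
    hold <- c(inh_meta$condition[match("I_a", inh_meta$inhibitor_type)],
              inh_meta$condition[match("II", inh_meta$inhibitor_type)])
    sp <- make_splits(feats, heldout_inhibitors = hold,
                      heldout_position_fraction = config$ml$heldout_position_fraction,
                      tune_fraction = config$ml$tune_fraction,
                      seed = derive_seed(config$seed, "split"))
    ms <- model_search(feats, sp, subset_cap = config$ml$subset_cap,
                       k = config$ml$k, hp_budget = config$ml$hp_budget,
                       seed = derive_seed(config$seed, "search"))
    emit(ms$ranking, "ml_ranking.tsv")
    emit(ms$test_metrics, "ml_test_metrics.tsv")
  }

  manifest <- list(
    seed = config$seed,
    parameters = list(filter = config$filter, scoring = config$scoring,
                      classify = config$classify, ml = config$ml,
                      design = config$design[c("n_replicates", "n_timepoints",
                                               "depth", "noise_mode")]),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(con, "done: %d output files", length(outputs) + 1)
  invisible(manifest)
}

#' Heatmap-ready long table
#'
#' Expands a score/recentered/call table to the complete position x
#' mutation grid (alphabetical residues, `"*"` last) with missing cells
#' flagged, ready for tile plotting.
#'
#' @param table table carrying variant keys and the `value` column.
#' @param value column to emit (default `"beta"`).
#' @return data frame: `position`, `mut_aa`, `value`, `is_synonymous`,
#'   `is_missing`.
#' @export
make_heatmap_table <- function(table, value = "beta") {
  positions <- sort(unique(table$position))
  muts <- c(AA_STANDARD, STOP_SYMBOL)
  grid <- expand.grid(position = positions, mut_aa = muts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_t <- paste(table$position, table$mut_aa)
  idx <- match(paste(grid$position, grid$mut_aa), key_t)
  grid$value <- table[[value]][idx]
  grid$is_synonymous <- !is.na(idx) & table$var_class[idx] == "synonymous"
  grid$is_missing <- is.na(idx)
  grid <- grid[order(grid$position, grid$mut_aa == STOP_SYMBOL, grid$mut_aa), ]
  rownames(grid) <- NULL
  grid
}
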