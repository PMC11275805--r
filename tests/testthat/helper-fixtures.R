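# Shared fixtures: everything is generated in code at test time.

# Deterministic wild-type sequence for a region of n residues.
wt_seq <- function(n, seed = 101) {
  paste(metdms:::with_seed(seed, sample(metdms:::AA_STANDARD, n, replace = TRUE)),
        collapse = "")
}

small_library <- function(n = 10, start = 1059, stop_spacing = 11, seed = 101) {
  build_library(start, start + n - 1, wt_seq(n, seed), stop_spacing)
}

dmso_only <- function() make_conditions("DMSO", "DMSO")

two_type_conditions <- function() {
  make_conditions(c("DMSO", "inhA1", "inhA2", "inhB1", "inhB2"),
                  c("DMSO", "I_a", "I_a", "II", "II"))
}

# Long count table from an explicit variant x (replicate, timepoint) matrix.
# `counts` is a matrix with one row per variant and R*T columns ordered
# (r1t0, r1t1, ..., r2t0, ...).
toy_counts <- function(counts, var_class = NULL, condition = "DMSO",
                       n_rep = 3, n_tp = 4) {
  nv <- nrow(counts)
  if (is.null(var_class)) var_class <- rep("missense", nv)
  grid <- expand.grid(timepoint = 0:(n_tp - 1), replicate = 1:n_rep,
                      v = 1:nv)
  data.frame(position = grid$v, wt_aa = "A",
             mut_aa = metdms:::AA_STANDARD[(grid$v %% 19) + 1],
             var_class = var_class[grid$v], condition = condition,
             replicate = grid$replicate, timepoint = grid$timepoint,
             count = counts[cbind(grid$v,
                                  (grid$replicate - 1) * n_tp + grid$timepoint + 1)],
             stringsAsFactors = FALSE)
}

# Noise-free counts for given true scores (with synonymous controls added),
# scored end to end; returns merged score/truth table.
score_noise_free <- function(true_scores, g_wt = 2, n_tp = 4, n_rep = 2) {
  nv <- length(true_scores)
  lib <- data.frame(position = seq_len(nv + 2), wt_aa = "A",
                    mut_aa = c(metdms:::AA_STANDARD[seq_len(nv) %% 19 + 2],
                               "A", "A"),
                    var_class = c(rep("missense", nv), "synonymous",
                                  "synonymous"),
                    stringsAsFactors = FALSE)
  lib$mut_aa[lib$var_class == "synonymous"] <- "A"
  eff <- data.frame(lib, condition = "COND",
                    true_score = c(true_scores, 0, 0),
                    component = "manual", stringsAsFactors = FALSE)
  cond <- data.frame(condition = "COND", inhibitor_type = "DMSO",
                     wt_doublings_per_interval = g_wt)
  d <- sim_design(n_replicates = n_rep, n_timepoints = n_tp, depth = 1e6,
                  noise_mode = "none")
  cnt <- simulate_counts(eff, "COND", d, cond)
  sc <- score_condition(normalize_counts(cnt, pseudocount = 0))
  merge(sc, eff[, c("position", "mut_aa", "true_score")],
        by = c("position", "mut_aa"))
}

# Minimal score-table row constructor for classification tests.
score_row <- function(position, mut_aa, beta, se, df = 2, wt_aa = "A",
                      var_class = "missense", condition = "inh") {
  tail <- stats::pt((0.5 - beta) / se, df)
  data.frame(position = position, wt_aa = wt_aa, mut_aa = mut_aa,
             var_class = var_class, condition = condition, beta = beta,
             se = se, df = df, p_gt_wt = stats::pt(beta / se, df),
             p_lt_wt = 1 - stats::pt(beta / se, df),
             tail_prob_resist = tail, stringsAsFactors = FALSE)
}
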