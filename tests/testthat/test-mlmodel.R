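test_that("feature-subset enumeration is the power set with llr anchored", {
  subs <- enumerate_feature_subsets()
  expect_length(subs, 8192)                 # 2^13
  expect_true(all(vapply(subs, function(s) s[1] == "llr", logical(1))))
  expect_equal(subs[[1]], "llr")            # empty optional set
  expect_length(enumerate_feature_subsets(character(0)), 1)
  expect_length(enumerate_feature_subsets(c("a", "b", "c")), 8)
  # all subsets distinct
  keys <- vapply(subs[1:128], paste, "", collapse = ",")
  expect_equal(anyDuplicated(keys), 0)
  expect_error(enumerate_feature_subsets(c("a", "a")), "duplicate")
  # the first 64 subsets exhaust combinations of the first 6 optional features
  first6 <- optional_features()[1:6]
  used <- unique(unlist(subs[1:64]))
  expect_setequal(setdiff(used, "llr"), first6)
})

test_that("binning maps values to training-bin medians", {
  tab <- data.frame(rf_score = c(0.1, 0.2, 0.3, 1.5, 2.5, 3.5, 9),
                    llr = 1:7, ddG = 7:1)
  out <- bin_features(tab, features = "rf_score",
                      breaks = list(rf_score = c(1, 2, 3, 4)))
  # bin (-Inf,1]: training values {0.1,0.2,0.3} -> median 0.2
  expect_equal(out$rf_score[1:3], rep(0.2, 3))
  expect_equal(out$rf_score[4], 1.5)
  # value beyond the outermost breakpoint falls into the edge bin
  expect_equal(out$rf_score[7], 9)
  # monotone features pass through untouched
  expect_equal(out$llr, tab$llr)
  expect_equal(out$ddG, tab$ddG)
  expect_error(bin_features(tab, features = "llr"), "monotone")
  expect_error(bin_features(tab, features = "rf_score",
                            breaks = list(rf_score = c(2, 1))), "increasing")

  # constant feature: single effective bin
  tab$rf_score <- 5
  out2 <- bin_features(tab, features = "rf_score")
  expect_equal(out2$rf_score, rep(5, 7))

  # medians come from the training partition only; an empty training bin
  # is merged with its neighbour
  tab3 <- data.frame(rf_score = c(1, 2, 3, 100), llr = 0, ddG = 0)
  expect_warning(
    out3 <- bin_features(tab3, features = "rf_score",
                         breaks = list(rf_score = c(50)),
                         train_mask = c(TRUE, TRUE, TRUE, FALSE)),
    "empty training bin")
  expect_equal(out3$rf_score, rep(2, 4))
})

test_that("train/tune/test split obeys the three holdout rules exactly", {
  tab <- expand.grid(position = 1:10, mut_aa = c("C", "D", "E", "F"),
                     inhibitor = c("iA", "iB", "iC", "iD"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$wt_aa <- "A"
  sp <- make_splits(tab, heldout_inhibitors = c("iA", "iC"),
                    heldout_position_fraction = 0.2, seed = 41)
  # partition property: disjoint, exhaustive over non-excluded rows
  expect_equal(sp$train + sp$tune + sp$test, rep(1, nrow(tab)))
  # rule (a): every held-out-inhibitor row in test
  expect_true(all(sp$test[tab$inhibitor %in% c("iA", "iC")]))
  # rule (b): rows at held-out positions are in test even under training
  # inhibitors
  expect_length(sp$heldout_positions, 2)   # 20% of 10
  expect_true(all(sp$test[tab$position %in% sp$heldout_positions]))
  # rule (c): held-out residues
  expect_length(sp$heldout_amino_acids, 2)
  expect_true(all(sp$test[tab$mut_aa %in% sp$heldout_amino_acids]))
  # leakage: no train/tune row violates any rule
  viol <- (tab$inhibitor %in% c("iA", "iC")) |
    (tab$position %in% sp$heldout_positions) |
    (tab$mut_aa %in% sp$heldout_amino_acids)
  expect_false(any((sp$train | sp$tune) & viol))
  # hand enumeration of the expected test size
  expect_equal(sum(sp$test), sum(viol))

  # excluded inhibitors appear in no partition
  sp2 <- make_splits(tab, heldout_inhibitors = "iA",
                     excluded_inhibitors = "iD", seed = 41)
  expect_false(any((sp2$train | sp2$tune | sp2$test) & tab$inhibitor == "iD"))

  expect_error(make_splits(tab, heldout_inhibitors = "nope"), "absent")
  sp3 <- make_splits(tab, heldout_inhibitors = c("iA", "iC"), seed = 41)
  expect_identical(sp, sp3)
})

test_that("cross-validation geometry partitions positions and residues", {
  # the screen's own geometry: 230 positions, 18 residues, 10 folds
  folds <- make_cv_folds(1:230, metdms:::AA_STANDARD[1:18], k = 10, seed = 43)
  expect_length(folds$position_folds, 10)
  expect_true(all(lengths(folds$position_folds) == 23))
  got <- unlist(folds$position_folds)
  expect_length(got, 230)                  # disjoint (no re-sampling needed)
  expect_setequal(got, 1:230)              # exhaustive
  # residues: 10 groups of 2, with 2 of 18 residues re-sampled
  expect_true(all(lengths(folds$aa_folds) == 2))
  expect_setequal(unique(unlist(folds$aa_folds)), metdms:::AA_STANDARD[1:18])

  # k=2 toy case
  f2 <- make_cv_folds(1:4, c("C", "D", "E", "F"), k = 2, seed = 44)
  expect_true(all(lengths(f2$position_folds) == 2))
  expect_setequal(unlist(f2$position_folds), 1:4)
  expect_error(make_cv_folds(1:4, c("C", "D"), k = 1), "k must be")
})

test_that("monotone constraints hold under perturbation", {
  set.seed(45)
  n <- 300
  tab <- data.frame(llr = rnorm(n), ddG = rnorm(n),
                    residue_atp_distance = runif(n, 5, 30))
  tab$target <- tab$llr - 0.8 * tab$ddG + 0.05 * tab$residue_atp_distance +
    rnorm(n, 0, 0.2)
  fit <- fit_model(tab, c("llr", "ddG", "residue_atp_distance"), seed = 46)
  base <- tab[sample(n, 100), ]
  up_llr <- base; up_llr$llr <- up_llr$llr + abs(rnorm(100, 0.5))
  up_ddg <- base; up_ddg$ddG <- up_ddg$ddG + abs(rnorm(100, 0.5))
  expect_true(all(predict(fit, up_llr) >= predict(fit, base) - 1e-9))
  expect_true(all(predict(fit, up_ddg) <= predict(fit, base) + 1e-9))
})

test_that("model fitting validates features and can realise the target", {
  tab <- data.frame(llr = seq(-2, 2, length.out = 200))
  tab$target <- tab$llr
  expect_error(fit_model(tab, "ddG"), "llr")
  expect_error(fit_model(tab, c("llr", "nonsense_feature")), "unknown")
  fit <- fit_model(tab, "llr", seed = 47)
  expect_lt(mean((predict(fit, tab) - tab$target)^2), 0.05)
})

test_that("hyperparameter search reduces tuning error deterministically", {
  set.seed(48)
  n <- 240
  tab <- data.frame(llr = rnorm(n), ddG = rnorm(n))
  tab$target <- tab$llr - tab$ddG + rnorm(n, 0, 0.1)
  train <- tab[1:180, ]; tune <- tab[181:240, ]
  f1 <- fit_model(train, c("llr", "ddG"), tune = tune, hp_budget = 8, seed = 49)
  f2 <- fit_model(train, c("llr", "ddG"), tune = tune, hp_budget = 8, seed = 49)
  expect_identical(f1$params, f2$params)
  expect_false(is.na(f1$tune_mse))
  expect_lt(f1$tune_mse, var(tune$target))  # beats the trivial predictor
})

test_that("model search ranks subsets and recovers an informative feature", {
  lib <- small_library(16, seed = 51)
  cond <- two_type_conditions()
  eff <- assign_true_scores(lib, cond, seed = 51)
  inh <- cond[cond$inhibitor_type != "DMSO", ]
  ft <- simulate_feature_table(lib, inh, eff, seed = 51)
  metdms:::with_seed(52, {
    ft$target <- ft$llr - 0.1 * ft$residue_atp_distance + rnorm(nrow(ft), 0, 0.3)
  })
  sp <- make_splits(ft, heldout_inhibitors = c("inhA1", "inhB1"), seed = 53)
  subs <- enumerate_feature_subsets(c("residue_atp_distance", "crystal_rmsf"))
  ms <- model_search(ft, sp, subsets = subs, k = 4, hp_budget = 0, seed = 54)
  expect_equal(nrow(ms$ranking), 4)
  expect_setequal(ms$ranking$subset, 1:4)     # ranking permutes the input
  expect_true("residue_atp_distance" %in% ms$best_subset)
  expect_true(all(c("pearson", "mse") %in% names(ms$test_metrics)))
  # held-out inhibitors are evaluated in the test metrics
  expect_true(all(c("inhA1", "inhB1") %in% ms$test_metrics$inhibitor))
  # full-feature recovery beats llr-only on test correlation
  r <- ms$ranking
  llr_only <- r$cv_pearson[r$features == "llr"]
  with_dist <- max(r$cv_pearson[grepl("residue_atp_distance", r$features)])
  expect_gt(with_dist, llr_only)
})
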