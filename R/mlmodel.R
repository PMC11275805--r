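#' Enumerate feature subsets for the model search
#'
#' All `2^k` subsets of the optional features, each with `llr` (the
#' language-model log-likelihood ratio, the constant backbone feature)
#' prepended. With the full 13 optional features this is 8192 models.
#' Order is a deterministic binary counter over the optional features, so
#' truncating the list at `2^j` covers every combination of the first `j`
#' optional features.
#'
#' @param optional character vector of optional feature names (default the
#'   13-feature catalogue minus `llr`).
#' @return list of character vectors, each starting with `"llr"`.
#' @export
enumerate_feature_subsets <- function(optional = optional_features()) {
  if (anyDuplicated(optional)) stop_input("duplicate optional feature names")
  k <- length(optional)
  lapply(0:(2^k - 1), function(i) {
    bits <- bitwAnd(bitwShiftR(i, 0:(max(k, 1) - 1)), 1L) == 1L
    c("llr", optional[bits[seq_len(k)]])
  })
}

#' Bin feature values to training-bin medians
#'
#' Coarsens non-monotone features to guard against overfitting: each value
#' is replaced by the median of the training-partition values in its bin.
#' Breakpoints default to training quantiles (`n_bins` equal-probability
#' bins); a named list of manual breakpoints may be supplied. Values
#' outside the outermost breakpoints fall into the edge bins. The monotone
#' features `llr` and `ddG` are never binned. Empty training bins are
#' merged with their lower neighbour with a warning.
#'
#' @param table feature table (data frame containing the feature columns).
#' @param features columns to bin (default: catalogue minus `llr`/`ddG`,
#'   intersected with the table).
#' @param n_bins 4 or 5 (default 4).
#' @param breaks optional named list of numeric breakpoint vectors
#'   (interior breakpoints, strictly increasing).
#' @param train_mask logical vector marking training rows used to compute
#'   breakpoints and medians (default: all rows).
#' @return the table with binned feature columns; the bin spec is attached
#'   as attribute `"binspec"`.
#' @export
bin_features <- function(table, features = NULL, n_bins = 4, breaks = NULL,
                         train_mask = NULL) {
  if (is.null(features)) {
    features <- intersect(setdiff(feature_catalog(), c("llr", "ddG")),
                          names(table))
  }
  if (any(c("llr", "ddG") %in% features)) {
    stop_input("monotone features llr/ddG must not be binned")
  }
  if (is.null(train_mask)) train_mask <- rep(TRUE, nrow(table))
  spec <- list()
  for (f in features) {
    x <- table[[f]]
    xt <- x[train_mask]
    br <- if (!is.null(breaks[[f]])) {
      b <- breaks[[f]]
      if (is.unsorted(b, strictly = TRUE)) {
        stop_input("breakpoints for %s not strictly increasing", f)
      }
      b
    } else {
      uv <- sort(unique(xt))
      if (length(uv) <= n_bins) {
        # discrete feature: one bin per observed level
        (uv[-1] + uv[-length(uv)]) / 2
      } else {
        q <- stats::quantile(xt, probs = seq(0, 1, length.out = n_bins + 1),
                             names = FALSE)
        unique(q[-c(1, length(q))])
      }
    }
    cuts <- c(-Inf, br, Inf)
    bin <- findInterval(x, cuts, rightmost.closed = TRUE)
    bin_t <- bin[train_mask]
    meds <- rep(NA_real_, length(cuts) - 1)
    for (b in seq_along(meds)) {
      inb <- xt[bin_t == b]
      if (length(inb)) meds[b] <- stats::median(inb)
    }
    if (anyNA(meds)) {
      warning(sprintf("empty training bin(s) for %s merged with neighbor", f))
      for (b in seq_along(meds)) {
        if (is.na(meds[b])) {
          nb <- which(!is.na(meds))
          meds[b] <- meds[nb[which.min(abs(nb - b))]]
        }
      }
    }
    table[[f]] <- meds[bin]
    spec[[f]] <- list(breaks = br, medians = meds)
  }
  attr(table, "binspec") <- spec
  table
}

#' Train / tune / test split for the fitness predictor
#'
#' The test set unions three leakage-guarded holdouts: (a) every row of one
#' held-out type I and one held-out type II inhibitor, (b) every row at a
#' random `heldout_position_fraction` of positions, and (c) every row whose
#' mutant amino acid is one of two held-out residues. Of the remaining
#' rows, a random 20% become the hyperparameter tuning holdout and the rest
#' the training set. Rows of `excluded_inhibitors` (by default none here;
#' the pipeline excludes DMSO and the lone type I 1/2 condition upstream)
#' are dropped entirely.
#'
#' @param table feature table with `position`, `mut_aa`, `inhibitor`.
#' @param heldout_inhibitors character vector of inhibitors fully held out.
#' @param heldout_position_fraction default 0.20.
#' @param heldout_amino_acids two residue letters, or NULL to sample them.
#' @param tune_fraction fraction of non-test rows for tuning (default 0.2).
#' @param excluded_inhibitors inhibitors removed from all partitions.
#' @param seed integer seed.
#' @return list with logical row masks `train`, `tune`, `test`, plus
#'   `heldout_positions`, `heldout_amino_acids`, `excluded` mask.
#' @export
make_splits <- function(table, heldout_inhibitors,
                        heldout_position_fraction = 0.20,
                        heldout_amino_acids = NULL,
                        tune_fraction = 0.20,
                        excluded_inhibitors = character(0), seed = 1) {
  miss <- setdiff(heldout_inhibitors, table$inhibitor)
  if (length(miss)) stop_input("held-out inhibitor(s) absent from table: %s",
                               paste(miss, collapse = ", "))
  excluded <- table$inhibitor %in% excluded_inhibitors
  with_seed(seed, {
    pool <- table[!excluded, , drop = FALSE]
    positions <- sort(unique(pool$position))
    n_hold <- max(1, round(heldout_position_fraction * length(positions)))
    hp <- sort(sample(positions, n_hold))
    aas <- sort(unique(pool$mut_aa))
    ha <- if (is.null(heldout_amino_acids)) sort(sample(aas, 2)) else {
      if (length(heldout_amino_acids) != 2) {
        stop_input("heldout_amino_acids must be exactly 2 residues")
      }
      sort(heldout_amino_acids)
    }
    test <- !excluded & (table$inhibitor %in% heldout_inhibitors |
                           table$position %in% hp |
                           table$mut_aa %in% ha)
    rest <- which(!excluded & !test)
    tune_idx <- sample(rest, round(tune_fraction * length(rest)))
    tune <- rep(FALSE, nrow(table)); tune[tune_idx] <- TRUE
    train <- !excluded & !test & !tune
    list(train = train, tune = tune, test = test,
         heldout_positions = hp, heldout_amino_acids = ha,
         excluded = excluded)
  })
}

#' Position- and residue-partitioned cross-validation folds
#'
#' Partitions training positions into `k` equal groups (padding by
#' re-sampling positions when the count is not divisible by `k`) and
#' mutant amino acids into `k` groups of 2 (re-sampling residues when the
#' residue count differs from `2k`). Fold i's validation rows are those at
#' fold-i positions *or* carrying fold-i residues, so every fold probes
#' generalisation to unseen positions and unseen substitutions.
#'
#' @param positions unique training positions.
#' @param amino_acids unique training mutant residues.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list with `position_folds` and `aa_folds`, each a list of k
#'   vectors.
#' @export
make_cv_folds <- function(positions, amino_acids, k = 10, seed = 1) {
  if (k < 2) stop_input("k must be >= 2")
  positions <- unique(positions)
  amino_acids <- unique(amino_acids)
  with_seed(seed, {
    sh <- sample(positions)
    size <- ceiling(length(sh) / k)
    pad <- k * size - length(sh)
    if (pad > 0) sh <- c(sh, sample(positions, pad, replace = pad > length(positions)))
    pos_folds <- split(sh, rep(seq_len(k), each = size))
    aa <- sample(amino_acids)
    if (length(aa) < 2 * k) {
      aa <- c(aa, sample(amino_acids, 2 * k - length(aa),
                         replace = 2 * k - length(aa) > length(amino_acids)))
    } else if (length(aa) > 2 * k) {
      aa <- aa[seq_len(2 * k)]
    }
    aa_folds <- split(aa, rep(seq_len(k), each = 2))
    list(position_folds = unname(pos_folds), aa_folds = unname(aa_folds))
  })
}

xgb_feature_matrix <- function(table, features) {
  as.matrix(table[, features, drop = FALSE])
}

monotone_vector <- function(features) {
  m <- integer(length(features))
  m[features == "llr"] <- 1L
  m[features == "ddG"] <- -1L
  m
}

default_hyperparams <- function() {
  list(booster = "gbtree", max_depth = 4, eta = 0.1, gamma = 0,
       colsample_bytree = 1, alpha = 0, lambda = 1,
       grow_policy = "depthwise", nrounds = 80)
}

sample_hyperparams <- function(n) {
  lapply(seq_len(n), function(i) {
    list(booster = sample(c("gbtree", "dart"), 1),
         max_depth = sample(2:8, 1),
         eta = exp(stats::runif(1, log(0.02), log(0.3))),
         gamma = stats::runif(1, 0, 3),
         colsample_bytree = stats::runif(1, 0.5, 1),
         alpha = exp(stats::runif(1, log(1e-3), log(5))),
         lambda = exp(stats::runif(1, log(1e-2), log(10))),
         grow_policy = sample(c("depthwise", "lossguide"), 1),
         nrounds = sample(c(40, 60, 80, 120), 1))
  })
}

xgb_fit <- function(x, y, features, params, seed) {
  p <- list(booster = params$booster,
            max_depth = params$max_depth,
            eta = params$eta,
            gamma = params$gamma,
            colsample_bytree = params$colsample_bytree,
            alpha = params$alpha,
            lambda = params$lambda,
            grow_policy = params$grow_policy,
            tree_method = "hist",
            objective = "reg:squarederror",
            monotone_constraints = monotone_vector(features),
            nthread = 1, seed = seed)
  xgboost::xgb.train(params = p,
                     data = xgboost::xgb.DMatrix(x, label = y),
                     nrounds = params$nrounds, verbose = 0)
}

#' Fit the monotonicity-constrained gradient-boosted regressor
#'
#' Gradient-boosted decision trees (XGBoost) predicting the fitness target
#' from the selected features, with `llr` constrained to a non-decreasing
#' and `ddG` to a non-increasing effect on predictions. When a tuning
#' holdout and `hp_budget > 0` are given, hyperparameters (booster
#' variant, tree depth, number of trees, learning rate, minimum split
#' loss, column subsample, L1/L2 regularisation, growth policy) are chosen
#' by seeded random search minimising tuning MSE.
#'
#' @param train data frame of training rows (features + `target` column).
#' @param features character vector of feature names; must include `llr`.
#' @param tune optional data frame of tuning rows.
#' @param hp_budget number of random hyperparameter configurations to try
#'   (0 = use defaults).
#' @param params optional explicit hyperparameter list (overrides search).
#' @param seed integer seed.
#' @return object of class `met_gbm`: list with `model`, `features`,
#'   `params`, `tune_mse`.
#' @export
fit_model <- function(train, features, tune = NULL, hp_budget = 0,
                      params = NULL, seed = 1) {
  if (!"llr" %in% features) stop_input("llr must be among the model features")
  bad <- setdiff(features, feature_catalog())
  if (length(bad)) stop_input("unknown feature(s): %s", paste(bad, collapse = ", "))
  x <- xgb_feature_matrix(train, features)
  y <- train$target
  tune_mse <- NA_real_
  if (is.null(params)) {
    if (hp_budget > 0 && !is.null(tune)) {
      cands <- with_seed(seed, sample_hyperparams(hp_budget))
      xt <- xgb_feature_matrix(tune, features)
      mses <- vapply(seq_along(cands), function(i) {
        fit <- xgb_fit(x, y, features, cands[[i]], seed = seed + i)
        mean((predict(fit, xt) - tune$target)^2)
      }, numeric(1))
      params <- cands[[which.min(mses)]]
      tune_mse <- min(mses)
    } else {
      params <- default_hyperparams()
    }
  }
  model <- xgb_fit(x, y, features, params, seed = seed)
  structure(list(model = model, features = features, params = params,
                 tune_mse = tune_mse), class = "met_gbm")
}

#' @export
predict.met_gbm <- function(object, newdata, ...) {
  stats::predict(object$model, xgb_feature_matrix(newdata, object$features))
}

#' Cross-validate one feature subset
#'
#' Runs [make_cv_folds()] on the training rows and, per fold, fits the
#' model on the non-validation rows and evaluates Pearson r and MSE on the
#' fold's validation rows (rows at held-out positions or with held-out
#' residues). Metrics are fold averages.
#'
#' @param train training rows (features + `target`, `position`, `mut_aa`).
#' @param features feature subset (includes `llr`).
#' @param params hyperparameter list.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @return list with `cv_pearson`, `cv_mse`, `fold_metrics`, `folds`.
#' @export
crossvalidate <- function(train, features, params = default_hyperparams(),
                          k = 10, seed = 1) {
  folds <- make_cv_folds(unique(train$position), unique(train$mut_aa),
                         k = k, seed = seed)
  metrics <- data.frame(fold = seq_len(k), pearson = NA_real_, mse = NA_real_)
  for (i in seq_len(k)) {
    val <- train$position %in% folds$position_folds[[i]] |
      train$mut_aa %in% folds$aa_folds[[i]]
    if (!any(val) || all(val)) next
    fit <- fit_model(train[!val, , drop = FALSE], features, params = params,
                     seed = seed + i)
    pred <- predict(fit, train[val, , drop = FALSE])
    obs <- train$target[val]
    metrics$pearson[i] <- if (stats::sd(pred) > 0 && stats::sd(obs) > 0) {
      stats::cor(pred, obs)
    } else NA_real_
    metrics$mse[i] <- mean((pred - obs)^2)
  }
  list(cv_pearson = mean(metrics$pearson, na.rm = TRUE),
       cv_mse = mean(metrics$mse, na.rm = TRUE),
       fold_metrics = metrics, folds = folds)
}

#' Exhaustive (capped) feature-subset model search
#'
#' For each candidate subset: tunes hyperparameters on the tuning holdout
#' (random search, `hp_budget` trials), cross-validates with the chosen
#' hyperparameters on the full training set (train + tune) with
#' position/residue-partitioned folds, and ranks subsets by mean
#' cross-validation Pearson r. The winner is refit on the full training
#' set and evaluated per held-out inhibitor on the test partition.
#'
#' @param table feature table joined with a `target` column.
#' @param split output of [make_splits()].
#' @param subsets list of feature subsets (default: full enumeration).
#' @param subset_cap evaluate only the first `subset_cap` subsets of the
#'   deterministic enumeration (NULL = all).
#' @param k cross-validation folds (default 10).
#' @param hp_budget hyperparameter search trials per subset (default 10).
#' @param bin bin the non-monotone features first (default TRUE).
#' @param n_bins bins per feature (default 4).
#' @param seed integer seed.
#' @return list with `ranking` (data frame: subset id, features,
#'   cv_pearson, cv_mse, rank), `best` (`met_gbm` fit), `test_metrics`
#'   (per-inhibitor Pearson/MSE on test rows) and `overall_test`.
#' @export
model_search <- function(table, split, subsets = NULL, subset_cap = NULL,
                         k = 10, hp_budget = 10, bin = TRUE, n_bins = 4,
                         seed = 1) {
  if (is.null(subsets)) subsets <- enumerate_feature_subsets(
    intersect(optional_features(), names(table)))
  if (!is.null(subset_cap)) subsets <- subsets[seq_len(min(subset_cap,
                                                           length(subsets)))]
  if (!length(subsets)) stop_input("no feature subsets to search")
  if (bin) {
    table <- bin_features(table, train_mask = split$train | split$tune,
                          n_bins = n_bins)
  }
  train <- table[split$train, , drop = FALSE]
  tune <- table[split$tune, , drop = FALSE]
  full_train <- table[split$train | split$tune, , drop = FALSE]
  test <- table[split$test, , drop = FALSE]

  res <- data.frame(subset = seq_along(subsets),
                    features = vapply(subsets, paste, "", collapse = ","),
                    cv_pearson = NA_real_, cv_mse = NA_real_,
                    stringsAsFactors = FALSE)
  best_params <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    fs <- subsets[[i]]
    fit <- fit_model(train, fs, tune = tune, hp_budget = hp_budget,
                     seed = derive_seed(seed, paste0("hp", i)))
    best_params[[i]] <- fit$params
    cv <- crossvalidate(full_train, fs, params = fit$params, k = k,
                        seed = derive_seed(seed, paste0("cv", i)))
    res$cv_pearson[i] <- cv$cv_pearson
    res$cv_mse[i] <- cv$cv_mse
  }
  res$rank <- rank(-res$cv_pearson, ties.method = "first")
  win <- which(res$rank == 1)
  best <- fit_model(full_train, subsets[[win]], params = best_params[[win]],
                    seed = derive_seed(seed, "final"))
  pred <- predict(best, test)
  per_inh <- do.call(rbind, lapply(split(seq_len(nrow(test)), test$inhibitor),
    function(idx) {
      data.frame(inhibitor = test$inhibitor[idx[1]],
                 n = length(idx),
                 pearson = if (length(idx) >= 3) stats::cor(pred[idx],
                                                            test$target[idx])
                           else NA_real_,
                 mse = mean((pred[idx] - test$target[idx])^2),
                 stringsAsFactors = FALSE)
    }))
  rownames(per_inh) <- NULL
  list(ranking = res[order(res$rank), ],
       best = best,
       best_subset = subsets[[win]],
       test_metrics = per_inh,
       overall_test = list(pearson = stats::cor(pred, test$target),
                           mse = mean((pred - test$target)^2)))
}
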