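#' Wild-type normalisation of counts
#'
#' Log2-transforms counts (with a pseudocount) and centres each
#' (replicate, timepoint) sample on the mean of its synonymous
#' (wild-type-equivalent) variants, so wild type is 0 on the log2 scale and
#' slopes read directly as doubling-rate offsets. Alongside the normalised
#' value `m`, each cell carries `m_var`, the delta-method sampling variance
#' of `m` under multinomial/Poisson counting noise
#' (`1 / (ln2^2 (count + pseudocount))` plus the variance of the synonymous
#' reference mean), used by the count-based scorer.
#'
#' @param counts single-condition count table.
#' @param pseudocount added before the log2 transform (default 0.5; use 0
#'   for noise-free real-valued counts, which are strictly positive).
#' @return long data frame with the variant/replicate/timepoint keys, the
#'   normalised value `m`, and its counting variance `m_var`.
#' @export
normalize_counts <- function(counts, pseudocount = 0.5) {
  if (!nrow(counts)) stop_input("empty count table")
  if (!any(counts$var_class == "synonymous")) {
    stop_input("no synonymous variants: wild-type normalization undefined")
  }
  lg <- log2(counts$count + pseudocount)
  cv <- 1 / (log(2)^2 * (counts$count + pseudocount))
  sample_key <- paste(counts$replicate, counts$timepoint, sep = "|")
  syn <- counts$var_class == "synonymous"
  syn_mean <- tapply(lg[syn], sample_key[syn], mean)
  if (any(!unique(sample_key) %in% names(syn_mean))) {
    stop_input("some (replicate, timepoint) samples have no synonymous variant")
  }
  syn_var <- tapply(cv[syn], sample_key[syn], function(x) sum(x) / length(x)^2)
  m <- lg - as.numeric(syn_mean[sample_key])
  out <- data.frame(counts[, c("position", "wt_aa", "mut_aa", "var_class",
                               "condition", "replicate", "timepoint")],
                    m = m,
                    m_var = cv + as.numeric(syn_var[sample_key]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# OLS slope of y against x by closed form; returns NA with < 2 finite points.
ols_slope <- function(x, y) {
  ok <- is.finite(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Score a condition: per-variant fitness on the doubling-rate scale
#'
#' Regresses the wild-type-normalised log2 abundance of each variant on the
#' integer time index, separately per replicate, and combines replicate
#' slopes into a fitness score `beta` (log2 growth-rate offset from wild
#' type per sampling interval). Slopes are shift-invariant, so any integer
#' time labelling gives the same score. Two uncertainty estimators:
#'
#' * `method = "counting"` (default): each replicate slope gets a known
#'   counting variance propagated from `m_var`; the reported variance of
#'   `beta` combines the mean counting variance with the *total* observed
#'   between-replicate dispersion of the slopes,
#'   `se^2 = (mean(v_r) + var(slopes)) / R`, and tails are normal
#'   (`df = Inf`). Retaining the total dispersion rather than its excess
#'   over the counting floor is deliberately conservative: with R = 3 the
#'   positive-part excess estimator is too noisy to subtract and
#'   under-covers (compare the conservative initial estimate of
#'   Sidik-Jonkman random-effects variance estimation).
#' * `method = "replicate"`: the plain between-replicate estimator,
#'   `se = sd(slopes) / sqrt(R)`, `df = R - 1`. Exact Student-t pivot, but
#'   at R = 3 its 2-df tails make nominal-level intervals short.
#'
#' With a single replicate the OLS residual slope standard error is used
#' with `df = T - 2`.
#'
#' Tail probabilities: `p_gt_wt` = P(beta > 0), `p_lt_wt` = 1 - p_gt_wt,
#' and `tail_prob_resist` = P(beta < `resist_threshold`) under the
#' t(df) sampling distribution of the estimate — small values mean the
#' variant grows credibly faster than wild type plus the threshold margin.
#'
#' @param normalized output of [normalize_counts()].
#' @param method variance estimator, see above.
#' @param resist_threshold effect-size threshold of the resistance test
#'   (default 0.5 doublings per interval).
#' @return score table: variant keys, `condition`, `beta`, `se`, `df`,
#'   `p_gt_wt`, `p_lt_wt`, `tail_prob_resist`.
#' @export
score_condition <- function(normalized, method = c("counting", "replicate"),
                            resist_threshold = 0.5) {
  method <- match.arg(method)
  tps <- sort(unique(normalized$timepoint))
  if (length(tps) < 2) stop_input("need >= 2 timepoints to score")
  reps <- sort(unique(normalized$replicate))
  R <- length(reps)
  key <- paste0(normalized$wt_aa, normalized$position, normalized$mut_aa)
  vids <- unique(key)
  tc <- tps - mean(tps)
  stt <- sum(tc^2)
  w2 <- (tc / stt)^2

  slopes <- matrix(NA_real_, length(vids), R)
  count_var <- matrix(NA_real_, length(vids), R)
  for (r in seq_len(R)) {
    sub <- normalized[normalized$replicate == reps[r], ]
    ridx <- cbind(match(paste0(sub$wt_aa, sub$position, sub$mut_aa), vids),
                  match(sub$timepoint, tps))
    mmat <- matrix(NA_real_, length(vids), length(tps))
    mmat[ridx] <- sub$m
    slopes[, r] <- apply(mmat, 1, function(y) ols_slope(tps, y))
    if (!is.null(sub$m_var)) {
      vmat <- matrix(NA_real_, length(vids), length(tps))
      vmat[ridx] <- sub$m_var
      count_var[, r] <- vmat %*% w2
    }
  }
  n_ok <- rowSums(is.finite(slopes))
  if (any(n_ok == 0)) {
    warning(sprintf("%d variant(s) with < 2 finite timepoints in every replicate: NA score",
                    sum(n_ok == 0)))
  }
  beta <- rowMeans(slopes, na.rm = TRUE)
  beta[n_ok == 0] <- NA_real_

  if (R == 1) {
    se <- vapply(seq_along(vids), function(i) {
      sub <- normalized[key == vids[i], ]
      y <- sub$m[match(tps, sub$timepoint)]
      ok <- is.finite(y)
      if (sum(ok) < 3) return(NA_real_)
      fit <- stats::lm.fit(cbind(1, tps[ok]), y[ok])
      s2 <- sum(fit$residuals^2) / (sum(ok) - 2)
      sqrt(s2 / sum((tps[ok] - mean(tps[ok]))^2))
    }, numeric(1))
    df <- rep(length(tps) - 2, length(vids))
  } else if (method == "counting") {
    if (all(is.na(count_var))) {
      stop_input("method 'counting' needs the m_var column from normalize_counts()")
    }
    s2 <- apply(slopes, 1, stats::var, na.rm = TRUE)
    s2[n_ok < 2] <- NA_real_
    mv <- rowMeans(count_var, na.rm = TRUE)
    se <- sqrt((mv + s2) / pmax(n_ok, 1))
    df <- rep(Inf, length(vids))
    se[n_ok < 2] <- NA_real_
  } else {
    s2 <- apply(slopes, 1, stats::var, na.rm = TRUE)
    se <- sqrt(s2 / pmax(n_ok, 1))
    df <- n_ok - 1
    se[n_ok < 2] <- NA_real_
  }

  t_at <- function(thr) {
    z <- (thr - beta) / se
    p <- stats::pt(z, df)
    exact <- !is.na(se) & se == 0
    p[exact] <- (beta[exact] < thr) + 0.5 * (beta[exact] == thr)
    p
  }
  p_lt_wt <- t_at(0)
  tail_prob_resist <- t_at(resist_threshold)

  first <- normalized[!duplicated(key), c("position", "wt_aa", "mut_aa",
                                          "var_class", "condition")]
  first <- first[match(vids, paste0(first$wt_aa, first$position, first$mut_aa)), ]
  out <- data.frame(first, beta = as.numeric(beta), se = as.numeric(se),
                    df = as.numeric(df),
                    p_gt_wt = 1 - as.numeric(p_lt_wt),
                    p_lt_wt = as.numeric(p_lt_wt),
                    tail_prob_resist = as.numeric(tail_prob_resist),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Recenter inhibitor scores on DMSO
#'
#' Computes the recentered score `gamma = beta_inhibitor - beta_DMSO` per
#' variant, isolating drug sensitivity from expression/stability effects
#' shared between conditions. NA-propagating.
#'
#' @param scores_inh score table for an inhibitor condition.
#' @param scores_dmso score table for the DMSO control.
#' @return data frame with variant keys, `inhibitor`, `beta_inh`,
#'   `beta_dmso`, `gamma`.
#' @export
recenter <- function(scores_inh, scores_dmso) {
  vi <- variant_id(scores_inh)
  vd <- variant_id(scores_dmso)
  if (!length(intersect(vi, vd))) stop_input("disjoint variant sets")
  out <- data.frame(scores_inh[, c("position", "wt_aa", "mut_aa", "var_class")],
                    inhibitor = scores_inh$condition,
                    beta_inh = scores_inh$beta,
                    beta_dmso = scores_dmso$beta[match(vi, vd)],
                    stringsAsFactors = FALSE)
  out$gamma <- out$beta_inh - out$beta_dmso
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix across conditions
#'
#' @param tables named list of score tables (uses `value` column) or
#'   recentered tables.
#' @param value column to correlate (`"beta"` or `"gamma"`).
#' @param min_shared minimum shared scored variants per pair (default 3);
#'   pairs below it get NA with a warning.
#' @return symmetric matrix of pairwise-complete Pearson correlations with
#'   unit diagonal.
#' @export
correlation_matrix <- function(tables, value = "beta", min_shared = 3) {
  if (length(tables) < 2) stop_input("need >= 2 tables")
  if (is.null(names(tables))) names(tables) <- seq_along(tables)
  vids <- sort(unique(unlist(lapply(tables, variant_id))))
  mat <- sapply(tables, function(tb) {
    x <- rep(NA_real_, length(vids))
    x[match(variant_id(tb), vids)] <- tb[[value]]
    x
  })
  cm <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(mat))
  low <- shared < min_shared & row(shared) != col(shared)
  if (any(low)) {
    warning(sprintf("%d condition pair(s) share < %d variants: NA correlation",
                    sum(low) / 2, min_shared))
    cm[low] <- NA_real_
  }
  diag(cm) <- 1
  cm
}
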