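# Canonical, locale-independent ordering of inhibitor-type labels.
TYPE_ORDER <- c("I_a", "I_b", "I_half", "II", "III", "DMSO")

sort_types <- function(x) x[order(match(x, TYPE_ORDER))]

#' Call inhibitor-specific resistance mutations
#'
#' A variant is a resistance mutation for an inhibitor when it grows
#' credibly faster than wild type under that inhibitor but no faster than
#' wild type in DMSO: the one-sided test `beta_inh < effect_cutoff_beta`
#' must have tail probability at most `tail_cutoff`, and the DMSO score
#' must satisfy `beta_dmso <= dmso_cutoff`. The table also carries the
#' recentered score `gamma` and its GOF/LOF flags.
#'
#' @param scores_inh inhibitor score table (needs `beta`, `se`, `df`).
#' @param scores_dmso DMSO score table.
#' @param tail_cutoff test-statistic cutoff (default 0.1).
#' @param effect_cutoff_beta effect-size threshold on `beta_inh`
#'   (default 0.5 doublings per interval).
#' @param dmso_cutoff DMSO effect-size cutoff (default 0).
#' @param gof_threshold recentered-score threshold for gain-of-function
#'   (default 0.75).
#' @return call table: variant keys, `inhibitor`, `beta_inh`, `beta_dmso`,
#'   `tail_prob_resist`, `gamma`, `is_resistance`, `gof`, `lof`.
#' @export
call_resistance <- function(scores_inh, scores_dmso, tail_cutoff = 0.1,
                            effect_cutoff_beta = 0.5, dmso_cutoff = 0,
                            gof_threshold = 0.75) {
  vi <- variant_id(scores_inh)
  vd <- variant_id(scores_dmso)
  if (!length(intersect(vi, vd))) stop_input("disjoint variant sets")
  beta_dmso <- scores_dmso$beta[match(vi, vd)]
  z <- (effect_cutoff_beta - scores_inh$beta) / scores_inh$se
  tail <- stats::pt(z, scores_inh$df)
  exact <- !is.na(scores_inh$se) & scores_inh$se == 0
  tail[exact] <- (scores_inh$beta[exact] < effect_cutoff_beta) +
    0.5 * (scores_inh$beta[exact] == effect_cutoff_beta)
  gamma <- scores_inh$beta - beta_dmso
  is_res <- tail <= tail_cutoff & beta_dmso <= dmso_cutoff
  is_res[scores_inh$var_class == "synonymous"] <- FALSE
  out <- data.frame(scores_inh[, c("position", "wt_aa", "mut_aa", "var_class")],
                    inhibitor = scores_inh$condition,
                    beta_inh = scores_inh$beta,
                    beta_dmso = beta_dmso,
                    tail_prob_resist = tail,
                    gamma = gamma,
                    is_resistance = is_res,
                    gof = !is.na(gamma) & gamma > gof_threshold,
                    lof = !is.na(gamma) & gamma < 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Resistance positions per inhibitor
#'
#' A position is a resistance position for an inhibitor if at least one of
#' its mutations is a resistance mutation under that inhibitor.
#'
#' @param calls call table (possibly several inhibitors stacked).
#' @return named list mapping inhibitor to a sorted integer vector of
#'   positions.
#' @export
resistance_positions <- function(calls) {
  res <- calls[!is.na(calls$is_resistance) & calls$is_resistance, ]
  out <- lapply(split(res$position, res$inhibitor), function(p) sort(unique(p)))
  out[sort(names(out))]
}

#' Gain/loss-of-function flags from recentered scores
#'
#' In the growth-rate-differential sense, a mutation is gain-of-function
#' for an inhibitor when `gamma > gof_threshold` (grows much faster with
#' the drug than without) and loss-of-function when `gamma < 0`.
#'
#' @param recentered output of [recenter()].
#' @param gof_threshold default 0.75.
#' @return input with added `gof`, `lof`, `diff_class` columns.
#' @export
classify_gof_lof <- function(recentered, gof_threshold = 0.75) {
  g <- recentered$gamma
  recentered$gof <- !is.na(g) & g > gof_threshold
  recentered$lof <- !is.na(g) & g < 0
  recentered$diff_class <- ifelse(is.na(g), NA_character_,
                                  ifelse(g > gof_threshold, "GOF",
                                         ifelse(g < 0, "LOF", "neutral")))
  recentered
}

#' Resistance hotspots aggregated by inhibitor type
#'
#' Sums resistance (mutation, inhibitor) calls per position over all
#' inhibitors of each type, and partitions resistance variants by the set
#' of inhibitor types they resist (Venn partition), where a variant counts
#' for a type if it is a resistance mutation for >= 1 inhibitor of that
#' type.
#'
#' @param calls stacked call table over all inhibitors.
#' @param conditions condition metadata (maps inhibitor to type).
#' @return list with `counts` (`position`, `inhibitor_type`, `count`) and
#'   `shared_sets` (named list keyed by `+`-joined sorted type combination,
#'   each a character vector of variant ids).
#' @export
hotspot_counts <- function(calls, conditions) {
  ty <- conditions$inhibitor_type[match(calls$inhibitor, conditions$condition)]
  if (any(is.na(ty))) {
    stop_input("inhibitor(s) missing from conditions metadata: %s",
               paste(unique(calls$inhibitor[is.na(ty)]), collapse = ", "))
  }
  res <- calls[!is.na(calls$is_resistance) & calls$is_resistance, , drop = FALSE]
  res_ty <- ty[!is.na(calls$is_resistance) & calls$is_resistance]
  types <- sort_types(setdiff(unique(ty), "DMSO"))
  positions <- sort(unique(calls$position))
  grid <- expand.grid(position = positions, inhibitor_type = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(res$position, res_ty)
  tab <- table(key)
  grid$count <- as.integer(tab[paste(grid$position, grid$inhibitor_type)])
  grid$count[is.na(grid$count)] <- 0L

  shared <- list()
  if (nrow(res)) {
    vid <- variant_id(res)
    combo <- tapply(res_ty, vid,
                    function(x) paste(sort_types(unique(x)), collapse = "+"))
    shared <- lapply(split(names(combo), as.character(combo)), sort)
  }
  list(counts = grid, shared_sets = shared)
}

#' Divergent mutations between two inhibitors
#'
#' Identifies mutations that are gain-of-function under one inhibitor but
#' loss-of-function under the other — candidate levers for sequential or
#' combination dosing. By default the GOF side must also pass the
#' resistance statistical filter (`is_resistance`).
#'
#' @param calls_a,calls_b call tables for the two inhibitors (contain
#'   `gamma` and `is_resistance`).
#' @param gof_threshold recentered-score threshold (default 0.75).
#' @param require_resistance require the statistical resistance call on the
#'   GOF side (default TRUE).
#' @return list with `gof_a_lof_b` and `gof_b_lof_a` variant-id vectors.
#' @export
differential_pairs <- function(calls_a, calls_b, gof_threshold = 0.75,
                               require_resistance = TRUE) {
  va <- variant_id(calls_a)
  vb <- variant_id(calls_b)
  shared <- intersect(va, vb)
  a <- calls_a[match(shared, va), ]
  b <- calls_b[match(shared, vb), ]
  gof_side <- function(x) {
    g <- !is.na(x$gamma) & x$gamma > gof_threshold
    if (require_resistance) g <- g & !is.na(x$is_resistance) & x$is_resistance
    g
  }
  lof_side <- function(x) !is.na(x$gamma) & x$gamma < 0
  list(gof_a_lof_b = sort(shared[gof_side(a) & lof_side(b)]),
       gof_b_lof_a = sort(shared[gof_side(b) & lof_side(a)]))
}

#' Type-exclusive resistance variants
#'
#' Variants resistant to at least one inhibitor of a given type and to no
#' inhibitor of any other type.
#'
#' @param calls stacked call table over all inhibitors.
#' @param conditions condition metadata.
#' @return named list mapping inhibitor type to a character vector of
#'   variant ids.
#' @export
type_exclusive_resistance <- function(calls, conditions) {
  ty <- conditions$inhibitor_type[match(calls$inhibitor, conditions$condition)]
  types <- sort_types(setdiff(unique(ty), "DMSO"))
  if (length(types) < 2) stop_input("need >= 2 inhibitor types")
  res <- calls[!is.na(calls$is_resistance) & calls$is_resistance, , drop = FALSE]
  res_ty <- ty[!is.na(calls$is_resistance) & calls$is_resistance]
  out <- stats::setNames(vector("list", length(types)), types)
  if (!nrow(res)) return(lapply(out, function(x) character(0)))
  vid <- variant_id(res)
  combo <- tapply(res_ty, vid, function(x) sort_types(unique(x)))
  for (t in types) {
    out[[t]] <- sort(names(combo)[vapply(combo, function(x) identical(x, t),
                                         logical(1))])
  }
  out
}
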