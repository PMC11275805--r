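#' Default ground-truth effect-size parameters
#'
#' The DMSO fitness landscape is a two-component mixture: a neutral
#' component centred at 0 (tolerated substitutions) and a deleterious
#' component centred at -2 (on the doubling-rate scale, -2 means the cells
#' stop growing while wild type doubles twice per interval). Nonsense
#' variants are forced below the deleterious mean. Under an inhibitor,
#' neutral-component variants are shifted down by `inhibitor_shift`
#' (growth-rate penalty at IC50) except designated resistance pairs, which
#' gain `resistance_effect` over wild type.
#'
#' @param neutral_weight mixture weight of the neutral component.
#' @param neutral_mean,neutral_sd neutral component parameters.
#' @param deleterious_mean,deleterious_sd deleterious component parameters.
#' @param nonsense_offset nonsense scores sit this far below
#'   `deleterious_mean` (minus half-normal jitter).
#' @param inhibitor_shift growth-rate shift applied to neutral-component
#'   variants under inhibitor selection (negative = sensitive).
#' @param resistance_effect range (or single value) of the true score given
#'   to a planted resistance pair under a matching-type inhibitor.
#' @return named list of parameters.
#' @export
default_effect_params <- function(neutral_weight = 0.6,
                                  neutral_mean = 0, neutral_sd = 0.15,
                                  deleterious_mean = -2, deleterious_sd = 0.4,
                                  nonsense_offset = -1,
                                  inhibitor_shift = -1.5,
                                  resistance_effect = c(0.75, 1.5)) {
  list(neutral_weight = neutral_weight, neutral_mean = neutral_mean,
       neutral_sd = neutral_sd, deleterious_mean = deleterious_mean,
       deleterious_sd = deleterious_sd, nonsense_offset = nonsense_offset,
       inhibitor_shift = inhibitor_shift,
       resistance_effect = resistance_effect)
}

#' Assign ground-truth fitness scores to a variant library
#'
#' Draws per-variant true scores (log2 growth-rate offset from wild type per
#' sampling interval) for every condition. Synonymous variants are 0
#' everywhere; missense variants fall into a neutral or deleterious DMSO
#' component; nonsense variants are strongly negative. Under inhibitors,
#' planted resistance pairs of the matching inhibitor type receive a
#' positive score while their DMSO score is forced strictly negative, so
#' the resistance behaviour is inhibitor-specific by construction.
#'
#' @param library variant library from [build_library()].
#' @param conditions condition metadata from [make_conditions()].
#' @param resistance_spec named list mapping an inhibitor type (e.g. `"I_a"`)
#'   to a data frame with columns `position`, `mut_aa` of planted resistance
#'   pairs. May be `NULL`.
#' @param effect_params list from [default_effect_params()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return data frame (one row per variant x condition): library columns
#'   plus `condition`, `true_score`, and the generator-internal `component`
#'   label (`synonymous`, `neutral`, `deleterious`, `nonsense`,
#'   `resistant`) retained as ground-truth metadata for benchmarking.
#' @export
assign_true_scores <- function(library, conditions, resistance_spec = NULL,
                               effect_params = default_effect_params(),
                               seed = 1) {
  p <- effect_params
  known_types <- unique(conditions$inhibitor_type)
  if (!is.null(resistance_spec)) {
    bad <- setdiff(names(resistance_spec), known_types)
    if (length(bad)) stop_input("resistance_spec names unknown inhibitor type(s): %s",
                                paste(bad, collapse = ", "))
    for (ty in names(resistance_spec)) {
      rs <- resistance_spec[[ty]]
      out <- !(rs$position %in% library$position)
      if (any(out)) stop_input("resistance_spec position(s) outside library: %s",
                               paste(unique(rs$position[out]), collapse = ", "))
    }
  }
  n <- nrow(library)
  vid <- variant_id(library)
  res_key <- character(0)
  res_type <- character(0)
  if (!is.null(resistance_spec)) {
    for (ty in names(resistance_spec)) {
      rs <- resistance_spec[[ty]]
      wt <- library$wt_aa[match(rs$position, library$position)]
      res_key <- c(res_key, paste0(wt, rs$position, rs$mut_aa))
      res_type <- c(res_type, rep(ty, nrow(rs)))
    }
  }

  with_seed(seed, {
    component <- character(n)
    dmso <- numeric(n)
    is_syn <- library$var_class == "synonymous"
    is_non <- library$var_class == "nonsense"
    is_mis <- library$var_class == "missense"
    component[is_syn] <- "synonymous"
    dmso[is_syn] <- 0
    component[is_non] <- "nonsense"
    dmso[is_non] <- p$deleterious_mean + p$nonsense_offset -
      abs(stats::rnorm(sum(is_non), 0, 0.1))
    neut <- is_mis & (stats::runif(n) < p$neutral_weight)
    dele <- is_mis & !neut
    component[neut] <- "neutral"
    dmso[neut] <- stats::rnorm(sum(neut), p$neutral_mean, p$neutral_sd)
    component[dele] <- "deleterious"
    dmso[dele] <- stats::rnorm(sum(dele), p$deleterious_mean, p$deleterious_sd)
    # planted resistance pairs: DMSO strictly <= 0 so the call rule's
    # effect-size condition is satisfiable by their true behaviour
    planted <- match(vid, res_key)
    is_res <- !is.na(planted)
    component[is_res] <- "resistant"
    dmso[is_res] <- -0.05 - abs(stats::rnorm(sum(is_res), 0, 0.15))

    eff <- if (length(p$resistance_effect) == 1) {
      rep(p$resistance_effect, sum(is_res))
    } else {
      stats::runif(sum(is_res), p$resistance_effect[1], p$resistance_effect[2])
    }

    out <- vector("list", nrow(conditions))
    for (i in seq_len(nrow(conditions))) {
      cond <- conditions$condition[i]
      ty <- conditions$inhibitor_type[i]
      sc <- dmso
      if (ty != "DMSO") {
        shifted <- component %in% c("neutral", "resistant")
        sc[shifted] <- sc[shifted] + p$inhibitor_shift
        # resistant pairs of the matching type override the shift
        match_ty <- is_res
        match_ty[is_res] <- res_type[planted[is_res]] == ty
        sc[match_ty] <- eff[res_type[planted[is_res]] == ty]
      }
      out[[i]] <- data.frame(library, condition = cond, true_score = sc,
                             component = component, stringsAsFactors = FALSE)
    }
    eff_tab <- do.call(rbind, out)
    rownames(eff_tab) <- NULL
    eff_tab
  })
}

#' Simulation design
#'
#' @param n_replicates biological replicates per condition (default 3).
#' @param n_timepoints sampling time points including T0 (default 4).
#' @param depth sequencing reads per (replicate, timepoint) sample.
#' @param noise_mode `"none"` for real-valued expected counts or
#'   `"multinomial"` for integer sampled counts.
#' @param seed integer seed for the multinomial draws.
#' @return named list.
#' @export
sim_design <- function(n_replicates = 3, n_timepoints = 4, depth = 1e6,
                       noise_mode = c("multinomial", "none"), seed = 1) {
  noise_mode <- match.arg(noise_mode)
  if (n_timepoints < 2) stop_input("n_timepoints must be >= 2")
  if (n_replicates < 1) stop_input("n_replicates must be >= 1")
  if (depth <= 0) stop_input("depth must be positive")
  list(n_replicates = as.integer(n_replicates),
       n_timepoints = as.integer(n_timepoints),
       depth = depth, noise_mode = noise_mode, seed = seed)
}

#' Simulate pooled-selection sequencing counts for one condition
#'
#' Cells carrying variant v grow at `2^(g_wt + true_score(v))` per sampling
#' interval, where `g_wt` is the wild-type doublings per interval (2 in the
#' screen design). The expected relative abundance at time index t
#' (t = 0..T-1) is proportional to `freq0(v) * 2^((g_wt + s_v) * t)`;
#' sequencing draws `depth` reads per (replicate, timepoint) sample, either
#' as exact depth-scaled expectations (`noise_mode = "none"`) or as one
#' multinomial draw per sample.
#'
#' @param effects true-score table from [assign_true_scores()].
#' @param condition condition name (must appear in `effects$condition`).
#' @param design list from [sim_design()].
#' @param conditions condition metadata (for `wt_doublings_per_interval`).
#' @param initial_freqs optional numeric vector of starting frequencies
#'   named by [variant_id()]; defaults to uniform.
#' @return long count table: `position`, `wt_aa`, `mut_aa`, `var_class`,
#'   `condition`, `replicate` (1-based), `timepoint` (0-based), `count`.
#' @export
simulate_counts <- function(effects, condition, design, conditions,
                            initial_freqs = NULL) {
  eff <- effects[effects$condition == condition, , drop = FALSE]
  if (!nrow(eff)) stop_input("condition '%s' not present in effects", condition)
  ci <- match(condition, conditions$condition)
  if (is.na(ci)) stop_input("condition '%s' not in conditions metadata", condition)
  g_wt <- conditions$wt_doublings_per_interval[ci]
  nv <- nrow(eff)
  vid <- variant_id(eff)
  f0 <- if (is.null(initial_freqs)) rep(1 / nv, nv) else {
    miss <- setdiff(vid, names(initial_freqs))
    if (length(miss)) stop_input("initial_freqs missing %d variant(s), e.g. %s",
                                 length(miss), miss[1])
    unname(initial_freqs[vid])
  }
  Tn <- design$n_timepoints
  R <- design$n_replicates
  tidx <- 0:(Tn - 1)
  # expected abundance per variant x timepoint
  ab <- outer(g_wt + eff$true_score, tidx, function(s, t) 2^(s * t)) * f0
  prob <- sweep(ab, 2, colSums(ab), "/")

  grid <- expand.grid(row = seq_len(nv), replicate = seq_len(R),
                      timepoint = tidx, KEEP.OUT.ATTRS = FALSE)
  counts <- if (design$noise_mode == "none") {
    design$depth * prob[cbind(grid$row, grid$timepoint + 1)]
  } else {
    draws <- with_seed(design$seed, {
      d <- array(0, dim = c(nv, R, Tn))
      for (r in seq_len(R)) for (t in seq_len(Tn)) {
        d[, r, t] <- stats::rmultinom(1, size = design$depth, prob = prob[, t])
      }
      d
    })
    draws[cbind(grid$row, grid$replicate, grid$timepoint + 1)]
  }
  out <- data.frame(eff[grid$row, c("position", "wt_aa", "mut_aa", "var_class")],
                    condition = condition,
                    replicate = grid$replicate,
                    timepoint = grid$timepoint,
                    count = counts,
                    stringsAsFactors = FALSE)
  ord <- order(out$replicate, out$timepoint, out$position, out$mut_aa)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Amino-acid side-chain volumes (A^3), used for the delta-volume feature.
AA_VOLUME <- c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
               G = 60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
               M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
               S = 89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6)

#' The 14-feature catalogue of the fitness predictor
#'
#' `llr` (protein-language-model log-likelihood ratio) is always present;
#' the other 13 are optional model inputs spanning inhibitor chemistry,
#' stability, distance, conformation and pocket descriptors.
#'
#' @return character vector of 14 feature names, `llr` first.
#' @export
feature_catalog <- function() {
  c("llr", optional_features())
}

#' @rdname feature_catalog
#' @export
optional_features <- function() {
  c("inhibitor_mw", "ligand_rmsd", "dddG", "ddG", "residue_atp_distance",
    "inhibitor_distance", "crystal_rmsf", "residue_rmsd", "rf_score",
    "pocket_volume", "hydrophobicity_score", "polarity_score",
    "delta_volume")
}

#' Simulate a per-(variant, inhibitor) feature table
#'
#' Stands in for the structural/chemical feature pipelines (language-model
#' scoring, stability prediction, docking, pocket analysis) with synthetic
#' values that preserve the relationships the predictor exploits: `llr`
#' correlates positively and `ddG` negatively with DMSO fitness;
#' position-level features (`residue_atp_distance`, `crystal_rmsf`) are
#' identical across mutations at a position; `inhibitor_mw` depends only on
#' the inhibitor; `delta_volume` is the mutant-minus-wild-type side-chain
#' volume difference. Missense variants only.
#'
#' @param library variant library.
#' @param inhibitors condition metadata rows for the inhibitors (no DMSO).
#' @param effects true-score table (provides the DMSO anchor for `llr`/`ddG`).
#' @param seed integer seed.
#' @param llr_noise,ddg_noise gaussian noise SDs on the fitness-linked
#'   features.
#' @return data frame: `position`, `wt_aa`, `mut_aa`, `inhibitor`, then the
#'   14 catalogue features.
#' @export
simulate_feature_table <- function(library, inhibitors, effects, seed = 1,
                                   llr_noise = 0.8, ddg_noise = 0.6) {
  if (any(inhibitors$inhibitor_type == "DMSO")) {
    stop_input("inhibitors must exclude the DMSO condition")
  }
  lib <- library[library$var_class == "missense", , drop = FALSE]
  vid <- variant_id(lib)
  dmso <- effects[effects$condition == "DMSO", , drop = FALSE]
  if (!nrow(dmso)) stop_input("effects must contain a DMSO condition")
  s_dmso <- dmso$true_score[match(vid, variant_id(dmso))]

  positions <- sort(unique(lib$position))
  with_seed(seed, {
    pos_feat <- data.frame(
      position = positions,
      residue_atp_distance = stats::runif(length(positions), 5, 30),
      crystal_rmsf = stats::runif(length(positions), 0.3, 2.0)
    )
    llr <- 1.5 * s_dmso + stats::rnorm(nrow(lib), 0, llr_noise)
    ddG <- -1.2 * s_dmso + stats::rnorm(nrow(lib), 0, ddg_noise)
    dddG <- stats::rnorm(nrow(lib), 0, 0.8)
    residue_rmsd <- abs(stats::rnorm(nrow(lib), 0.5, 0.4))
    delta_volume <- unname(AA_VOLUME[lib$mut_aa] - AA_VOLUME[lib$wt_aa])
    mw <- stats::runif(nrow(inhibitors), 300, 600)
    out <- vector("list", nrow(inhibitors))
    for (i in seq_len(nrow(inhibitors))) {
      out[[i]] <- data.frame(
        lib[, c("position", "wt_aa", "mut_aa")],
        inhibitor = inhibitors$condition[i],
        llr = llr,
        inhibitor_mw = mw[i],
        ligand_rmsd = abs(stats::rnorm(nrow(lib), 1, 0.7)),
        dddG = dddG,
        ddG = ddG,
        residue_atp_distance = pos_feat$residue_atp_distance[
          match(lib$position, pos_feat$position)],
        inhibitor_distance = stats::runif(nrow(lib), 3, 25),
        crystal_rmsf = pos_feat$crystal_rmsf[
          match(lib$position, pos_feat$position)],
        residue_rmsd = residue_rmsd,
        rf_score = stats::rnorm(nrow(lib), 6, 1),
        pocket_volume = stats::rnorm(nrow(lib), 500, 80),
        hydrophobicity_score = stats::rnorm(nrow(lib), 30, 10),
        polarity_score = stats::rnorm(nrow(lib), 8, 3),
        delta_volume = delta_volume,
        stringsAsFactors = FALSE
      )
    }
    ft <- do.call(rbind, out)
    rownames(ft) <- NULL
    ft
  })
}
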