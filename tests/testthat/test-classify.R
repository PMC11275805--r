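test_that("resistance calls implement the two-condition rule", {
  inh <- score_row(1:4, c("C", "D", "E", "F"),
                   beta = c(1.2, 0.4, 1.2, 1.2), se = 0.05, df = 30,
                   condition = "inh")
  dmso <- score_row(1:4, c("C", "D", "E", "F"),
                    beta = c(-0.1, -0.1, 0.3, -0.1), se = 0.05, df = 30,
                    condition = "DMSO")
  inh$beta[4] <- NA; inh$se[4] <- NA  # missing inhibitor score -> NA call
  calls <- call_resistance(inh, dmso)

  # oracle: Student-t tail at (0.5 - beta) / se
  expect_equal(calls$tail_prob_resist[1], pt((0.5 - 1.2) / 0.05, 30))
  expect_true(calls$is_resistance[1])          # strong beta, DMSO below 0
  expect_false(calls$is_resistance[2])         # estimate below threshold
  expect_gt(calls$tail_prob_resist[2], 0.5)
  expect_false(calls$is_resistance[3])         # fails the DMSO cutoff
  expect_true(is.na(calls$is_resistance[4]))
  expect_equal(calls$gamma, c(1.3, 0.5, 0.9, NA))
})

test_that("synonymous variants are never called resistant", {
  syn <- score_row(1, "A", beta = 1.5, se = 0.01, df = 30,
                   var_class = "synonymous")
  dmso <- score_row(1, "A", beta = -0.2, se = 0.01, df = 30,
                    var_class = "synonymous", condition = "DMSO")
  expect_false(call_resistance(syn, dmso)$is_resistance)
})

test_that("resistance positions deduplicate mutations per position", {
  calls <- data.frame(position = c(5, 5, 9, 9), wt_aa = "A",
                      mut_aa = c("C", "D", "E", "F"),
                      var_class = "missense",
                      inhibitor = c("i1", "i1", "i1", "i2"),
                      is_resistance = c(TRUE, TRUE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  rp <- resistance_positions(calls)
  expect_equal(rp$i1, 5)        # two mutations, one position
  expect_equal(rp$i2, 9)
  none <- calls; none$is_resistance <- FALSE
  expect_length(resistance_positions(none), 0)
})

test_that("GOF/LOF classification follows the gamma thresholds", {
  rc <- data.frame(position = 1:4, wt_aa = "A", mut_aa = c("C", "D", "E", "F"),
                   var_class = "missense", inhibitor = "inh",
                   beta_inh = 0, beta_dmso = 0,
                   gamma = c(0.9, -0.4, 0.3, NA), stringsAsFactors = FALSE)
  out <- classify_gof_lof(rc)
  expect_equal(out$diff_class, c("GOF", "LOF", "neutral", NA))
  expect_false(any(out$gof & out$lof))
  # boundary: exactly 0.75 and exactly 0 are neither GOF nor LOF
  rc$gamma <- c(0.75, 0, 0.7500001, -1e-9)
  out <- classify_gof_lof(rc)
  expect_equal(out$diff_class, c("neutral", "neutral", "GOF", "LOF"))
})

test_that("hotspot counts sum per (mutation, inhibitor) pair by type", {
  cond <- make_conditions(c("DMSO", "i1", "i2", "i3"),
                          c("DMSO", "I_a", "I_a", "II"))
  # variant A5C resistant to 2 of the type I inhibitors at position 5;
  # A9E resistant under one type I and one type II inhibitor
  calls <- expand.grid(mut_aa = c("C", "E"), inhibitor = c("i1", "i2", "i3"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  calls$position <- ifelse(calls$mut_aa == "C", 5, 9)
  calls$wt_aa <- "A"
  calls$var_class <- "missense"
  calls$is_resistance <- with(calls,
    (mut_aa == "C" & inhibitor %in% c("i1", "i2")) |
    (mut_aa == "E" & inhibitor %in% c("i2", "i3")))
  hs <- hotspot_counts(calls, cond)
  cnt <- hs$counts
  get <- function(p, ty) cnt$count[cnt$position == p & cnt$inhibitor_type == ty]
  expect_equal(get(5, "I_a"), 2)
  expect_equal(get(5, "II"), 0)
  expect_equal(get(9, "I_a"), 1)
  expect_equal(get(9, "II"), 1)
  # totals equal the number of TRUE calls of that type
  expect_equal(sum(cnt$count[cnt$inhibitor_type == "I_a"]),
               sum(calls$is_resistance[calls$inhibitor %in% c("i1", "i2")]))

  # shared sets: A9E spans both types, A5C is type-I-only
  expect_equal(hs$shared_sets[["I_a+II"]], "A9E")
  expect_equal(hs$shared_sets[["I_a"]], "A5C")

  # degenerate: no calls
  none <- calls; none$is_resistance <- FALSE
  hs0 <- hotspot_counts(none, cond)
  expect_true(all(hs0$counts$count == 0))
  expect_length(hs0$shared_sets, 0)
})

test_that("divergent-pair sets match brute-force enumeration", {
  mk <- function(gamma, res, inhibitor) {
    data.frame(position = seq_along(gamma), wt_aa = "A",
               mut_aa = metdms:::AA_STANDARD[seq_along(gamma) + 1],
               var_class = "missense", inhibitor = inhibitor,
               beta_inh = gamma, beta_dmso = 0, gamma = gamma,
               is_resistance = res, stringsAsFactors = FALSE)
  }
  g_a <- c(1.0, 1.0, 0.9, -0.6, 0.2, -1, 0.8, 1.2, NA, 0.76)
  r_a <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  g_b <- c(-0.6, 0.2, -0.5, 1.0, -0.3, 0.9, -0.1, NA, -0.4, -0.2)
  r_b <- c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  a <- mk(g_a, r_a, "a"); b <- mk(g_b, r_b, "b")
  dp <- differential_pairs(a, b)
  # brute force over all 10 variants
  exp_ab <- variant_id(a)[!is.na(g_a) & g_a > 0.75 & r_a &
                            !is.na(g_b) & g_b < 0]
  exp_ba <- variant_id(a)[!is.na(g_b) & g_b > 0.75 & r_b &
                            !is.na(g_a) & g_a < 0]
  expect_setequal(dp$gof_a_lof_b, exp_ab)
  expect_setequal(dp$gof_b_lof_a, exp_ba)
  expect_true("A1C" %in% dp$gof_a_lof_b)     # gamma_a 1.0 resistant, gamma_b -0.6
  expect_false("A2D" %in% dp$gof_a_lof_b)    # gamma_b 0.2: not LOF in b

  # laxer gamma-only mode adds the non-filtered GOF variant
  dp2 <- differential_pairs(a, b, require_resistance = FALSE)
  expect_true("A3E" %in% dp2$gof_a_lof_b)
})

test_that("type-exclusive sets partition resistance variants by type", {
  cond <- make_conditions(c("DMSO", "i1", "i2", "j1", "k1"),
                          c("DMSO", "I_a", "I_a", "II", "I_half"))
  vids <- c("A1C", "A2D", "A3E", "A4F")
  grid <- expand.grid(v = vids, inhibitor = c("i1", "i2", "j1", "k1"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$position <- match(grid$v, vids)
  grid$wt_aa <- "A"
  grid$mut_aa <- substr(grid$v, 3, 3)
  grid$var_class <- "missense"
  # A1C: II-only (two II? j1 only); A2D: I_a + II; A3E: I_a only; A4F: none
  grid$is_resistance <- with(grid,
    (v == "A1C" & inhibitor == "j1") |
    (v == "A2D" & inhibitor %in% c("i1", "j1")) |
    (v == "A3E" & inhibitor %in% c("i1", "i2")))
  ex <- type_exclusive_resistance(grid, cond)
  expect_equal(ex$II, "A1C")
  expect_equal(ex$I_a, "A3E")
  expect_equal(ex$I_half, character(0))
  # exclusive sets are disjoint and exclude the cross-type variant
  expect_length(intersect(ex$I_a, ex$II), 0)
  expect_false("A2D" %in% unlist(ex))

  expect_error(type_exclusive_resistance(
    grid[grid$inhibitor == "i1", ], cond[cond$condition %in% c("DMSO", "i1"), ]),
    "types")
})

test_that("planted resistance is recovered with high sensitivity and low FPR", {
  lib <- small_library(11, seed = 33)
  cond <- make_conditions(c("DMSO", "inh1"), c("DMSO", "I_a"))
  pos <- sort(unique(lib$position))
  # 12 planted resistance pairs at effect +1.0
  spec <- list(I_a = data.frame(
    position = rep(pos[c(2, 4, 6, 8)], each = 3),
    mut_aa = rep(c("R", "K", "W"), 4)))
  p <- default_effect_params(resistance_effect = 1.0)
  eff <- assign_true_scores(lib, cond, spec, p, seed = 34)
  d <- sim_design(depth = 1e6, noise_mode = "multinomial", seed = 35)
  sc <- lapply(c(DMSO = "DMSO", inh1 = "inh1"), function(cn) {
    score_condition(normalize_counts(simulate_counts(eff, cn, d, cond)))
  })
  calls <- call_resistance(sc$inh1, sc$DMSO)
  truth <- eff[eff$condition == "inh1", ]
  planted <- variant_id(truth)[truth$component == "resistant"]
  neutral <- variant_id(truth)[truth$component %in% c("neutral", "deleterious")]
  cv <- variant_id(calls)
  sens <- mean(calls$is_resistance[match(planted, cv)])
  fpr <- mean(calls$is_resistance[match(neutral, cv)], na.rm = TRUE)
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
})
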