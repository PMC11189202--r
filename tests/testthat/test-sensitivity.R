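# Sensitivity analyses use fast toy kinetics where only structure matters;
# sign/shape claims about the fitted system use the published constants with
# reduced grids.

test_that("zero perturbation gives zero sensitivity everywhere", {
  tab <- local_sensitivity(toy_rates(), perturbation = 0, horizon_s = 500)
  expect_true(all(tab$sensitivity == 0))
  expect_identical(nrow(tab), 2L * 9L)  # 6 rates + 3 concentrations, 2 metrics
})

test_that("raising dissociation rates cannot increase total bound AUC", {
  tab <- local_sensitivity(best_fit_rates())
  koff_rows <- tab$parameter %in% c("koff_6R", "koff_8R") &
    tab$output_metric == "AUC_total_bound"
  expect_true(all(tab$sensitivity[koff_rows] <= 0))
  # association to either receptor increases total binding at 2 h
  kon_rows <- tab$parameter %in% c("kon_6R", "kon_8R") &
    tab$output_metric == "AUC_total_bound"
  expect_true(all(tab$sensitivity[kon_rows] > 0))
})

test_that("swapping receptor roles swaps the paired sensitivities", {
  # frozen-constraint mode: propagation is asymmetric by construction
  # (kon_8R_star is the derived element on both sides of the swap)
  rc <- toy_rates()
  a <- local_sensitivity(rc, horizon_s = 1000, constraint = "frozen")
  b <- local_sensitivity(swap_receptor_roles(rc), horizon_s = 1000,
                         constraint = "frozen")
  pick <- function(tab, par, metric)
    tab$sensitivity[tab$parameter == par & tab$output_metric == metric]
  for (metric in c("AUC_ternary", "AUC_total_bound")) {
    expect_equal(pick(a, "kon_6R", metric), pick(b, "kon_8R", metric),
                 tolerance = 1e-6)
    expect_equal(pick(a, "koff_6R", metric), pick(b, "koff_8R", metric),
                 tolerance = 1e-6)
    expect_equal(pick(a, "conc_IL6R", metric), pick(b, "conc_IL8R", metric),
                 tolerance = 1e-6)
  }
})

test_that("AUC converges under time-grid refinement", {
  rc <- toy_rates()
  prot <- assay_protocol(doses = 10, washout = FALSE, horizon_s = 2000,
                         detection_s = 0)
  auc_n <- function(n) {
    sim <- simulate_assay("BS1", cell_line("s", 5e4, 5e4), 10, rc, prot,
                          model_options(n_out = n))
    bsabkin:::.auc_trapz(sim$time, 2 * sim$states[, "ternary"])
  }
  expect_equal(auc_n(400), auc_n(200), tolerance = 1e-3)
})

test_that("global sensitivity baseline offset reproduces the base run", {
  rc <- toy_rates()
  tab <- global_sensitivity(rc, doses = 10, n_offsets = 3, span = 1,
                            horizon_s = 2000)
  base <- tab[tab$offset_log10 == 0, ]
  occ <- summarize_occupancy(simulate_assay(
    "BS1", cell_line("sensitivity", 5e4, 5e4), 10, rc,
    assay_protocol(doses = 10, washout = FALSE, horizon_s = 2000,
                   detection_s = 0)))
  expect_equal(unique(base$frac_ternary), occ$frac_ternary, tolerance = 1e-10)
  expect_equal(unique(base$frac_total), occ$frac_total, tolerance = 1e-10)
})

test_that("global scan shows the autoinhibition regimes", {
  rc <- best_fit_rates()
  tab <- global_sensitivity(rc, doses = c(1, 1000), n_offsets = 9,
                            horizon_s = 86400)
  k6 <- tab[tab$parameter == "kon_6R", ]
  lo <- k6[k6$dose == 1, ]; lo <- lo[order(lo$offset_log10), ]
  hi <- k6[k6$dose == 1000, ]; hi <- hi[order(hi$offset_log10), ]
  # ternary occupancy vs kon_6R is non-monotone (rises then falls) at a
  # sub-saturating dose, and monotone-decreasing once the antibody is in
  # large excess (binary complexes consume the receptor)
  d <- diff(lo$frac_ternary)
  expect_true(any(d > 1e-6) && any(d < -1e-6))
  expect_true(all(diff(hi$frac_ternary) < 0))
  # slowing the first binding step two decades below baseline always costs
  # total binding (note: total occupancy is NOT globally monotone in
  # kon_6R -- fast first-step binding trades stable ternary complexes for
  # binary ones)
  for (dd in c(1, 1000)) {
    cur <- k6[k6$dose == dd, ]; cur <- cur[order(cur$offset_log10), ]
    expect_lt(cur$frac_total[1], cur$frac_total[cur$offset_log10 == 0])
  }
})

test_that("constraint propagation modes differ only through kon_8R_star", {
  rc <- toy_rates()
  p1 <- bsabkin:::.perturb_rates(rc, "kon_6R", 1.1, "propagate")
  p2 <- bsabkin:::.perturb_rates(rc, "kon_6R", 1.1, "frozen")
  expect_equal(cycle_product(p1), 1, tolerance = 1e-12)
  expect_equal(p2$kon_8R_star, rc$kon_8R_star)
  expect_false(isTRUE(all.equal(p1$kon_8R_star, p2$kon_8R_star)))
  # local and global analyses agree in sign at small offsets
  loc <- local_sensitivity(best_fit_rates())
  glob <- global_sensitivity(best_fit_rates(), doses = 10, n_offsets = 3,
                             span = 0.05, horizon_s = 7200)
  for (par in c("kon_6R", "kon_8R")) {
    s_loc <- loc$sensitivity[loc$parameter == par &
                               loc$output_metric == "AUC_total_bound"]
    g <- glob[glob$parameter == par, ]
    s_glob <- diff(g$frac_total[order(g$offset_log10)])[1]
    expect_equal(sign(s_loc), sign(s_glob))
  }
})
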