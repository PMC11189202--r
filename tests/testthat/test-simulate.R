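test_that("non-cognate and receptor-free combinations stay unbound", {
  rc <- toy_rates()
  prot <- assay_protocol(doses = 10, washout = FALSE, horizon_s = 1000,
                         detection_s = 0)
  # double-negative line: nothing binds
  s0 <- simulate_assay("BS1", "negative", 10, rc, prot)
  expect_true(all(s0$states[, c("binary_ab_r1", "binary_ab_r2", "ternary")] == 0))
  expect_equal(total_bound_antibody(s0), 0)
  # tocilizumab on the IL-8R-only line: no cognate receptor
  s1 <- simulate_assay("tocilizumab", "IL8R+", 10, rc, prot)
  expect_equal(total_bound_antibody(s1), 0)
  expect_equal(max(s1$states[, "free_ab"]), 10)
})

test_that("conservation sums hold to integrator tolerance across networks", {
  set.seed(21)
  prot <- assay_protocol(doses = 1, washout = TRUE, washout_time_s = 500,
                         detection_s = 0, horizon_s = 1000)
  for (ab in c("BS1", "tocilizumab", "10H2")) {
    for (i in 1:3) {
      rc <- toy_rates(kon_6R = 10^runif(1, -4, -3), kon_8R = 10^runif(1, -4, -3),
                      kon_6R_star = 10^runif(1, -6, -4))
      sim <- simulate_assay(ab, "IL6R+IL8R+", 10^runif(1, -1, 2), rc, prot)
      expect_lt(conservation_error(sim), 1e-6)
    }
  }
})

test_that("equilibrium satisfies all four detailed-balance relations", {
  rc <- toy_rates()
  cl <- cell_line("db", 1e4, 2e4)
  prot <- assay_protocol(doses = 5, washout = FALSE, horizon_s = 2e4,
                         detection_s = 0)
  st <- terminal_state(simulate_assay("BS1", cl, 5, rc, prot))
  Ab <- st[["free_ab"]]; R1 <- st[["free_r1"]]; R2 <- st[["free_r2"]]
  C1 <- st[["binary_ab_r1"]]; C2 <- st[["binary_ab_r2"]]; Tn <- st[["ternary"]]
  expect_equal(Ab * R1 / C1, rc$koff_6R / rc$kon_6R, tolerance = 1e-4)
  expect_equal(Ab * R2 / C2, rc$koff_8R / rc$kon_8R, tolerance = 1e-4)
  expect_equal(C2 * R1 / Tn, rc$koff_6R / rc$kon_6R_star, tolerance = 1e-4)
  expect_equal(C1 * R2 / Tn, rc$koff_8R / rc$kon_8R_star, tolerance = 1e-4)
})

test_that("monovalent equilibrium matches the closed-form hyperbola", {
  # cross-linking disabled, tiny receptor pool so depletion is negligible,
  # fast toy kinetics reach equilibrium well within the horizon
  KD <- 10
  rc <- restrict_monovalent(toy_rates(kon_6R = 1e-3, koff_6R = 1e-2,
                                      kon_8R = 1e-3, koff_8R = 1e-2,
                                      kon_6R_star = 1e-30))
  cl <- cell_line("langmuir", 10, 0)
  for (d in default_doses()) {
    prot <- assay_protocol(doses = d, washout = FALSE, horizon_s = 2e4,
                           detection_s = 0)
    occ <- summarize_occupancy(simulate_assay("BS1", cl, d, rc, prot))
    expect_equal(occ$occ_il6r, d / (d + KD), tolerance = 1e-3)
    expect_equal(occ$bound_ternary, 0)
  }
})

test_that("integration sharpens with tolerance (order sanity)", {
  rc <- toy_rates()
  run <- function(rtol) {
    opts <- model_options(rtol = rtol, n_out = 11)
    prot <- assay_protocol(doses = 10, washout = FALSE, horizon_s = 3000,
                           detection_s = 0)
    terminal_state(simulate_assay("BS1", "IL6R+IL8R+", 10, rc, prot, opts))
  }
  ref <- run(1e-11)
  err6 <- max(abs(run(1e-6) - ref) / pmax(abs(ref), 1))
  err9 <- max(abs(run(1e-9) - ref) / pmax(abs(ref), 1))
  expect_lt(err6, 1e-5)
  expect_lt(err9, 1e-8)
})

test_that("washout resets free antibody and lets ternary complexes grow", {
  rc <- best_fit_rates()
  sim <- simulate_assay("BS1", "IL6R+IL8R+", 100, rc, fitting_protocol())
  after <- sim$time > sim$protocol$washout_time_s
  expect_lt(max(sim$states[after, "free_ab"]), 100 * 1e-3)
  i2h <- max(which(sim$time <= 7200))
  expect_gte(sim$states[nrow(sim$states), "ternary"],
             sim$states[i2h, "ternary"])
  # total bound antibody is non-increasing after washout
  tb <- sim$states[after, "binary_ab_r1"] + sim$states[after, "binary_ab_r2"] +
    sim$states[after, "ternary"]
  expect_true(all(diff(tb) <= 1e-6 * max(tb)))
})

test_that("clamped washout removes released antibody from the free pool", {
  rc <- toy_rates()
  prot_free <- assay_protocol(doses = 10, washout = TRUE, washout_time_s = 500,
                              detection_s = 0, horizon_s = 5000)
  prot_clamp <- assay_protocol(doses = 10, washout = TRUE, washout_time_s = 500,
                               detection_s = 0, horizon_s = 5000,
                               clamp_washout = TRUE)
  free <- simulate_assay("BS1", "IL6R+", 10, rc, prot_free)
  clamp <- simulate_assay("BS1", "IL6R+", 10, rc, prot_clamp)
  after <- free$time > 500
  expect_lt(max(abs(clamp$states[after, "free_ab"])), 1e-12)
  expect_gt(max(free$states[after, "free_ab"]), 0)
  # with rebinding suppressed, at least as much antibody leaves the surface
  expect_lte(total_bound_antibody(clamp), total_bound_antibody(free))
})

test_that("occupancy summary applies the binary/ternary accounting", {
  st <- c(free_ab = 1, free_r1 = 10, free_r2 = 20, binary_ab_r1 = 3,
          binary_ab_r2 = 4, ternary = 5)
  cl <- cell_line("toy", 10 + 3 + 5, 20 + 4 + 5)
  occ <- summarize_occupancy(st, cl)
  expect_equal(occ$bound_binary, 7)
  expect_equal(occ$bound_ternary, 10)
  expect_equal(occ$bound_total, 17)
  expect_equal(occ$frac_total, 17 / (18 + 29))
  expect_equal(occ$occ_il6r, (3 + 5) / 18)
  expect_equal(occ$occ_il8r, (4 + 5) / 29)
  expect_equal(total_bound_antibody(st), 12)

  # all-free state
  st0 <- c(free_ab = 1, free_r1 = 10, free_r2 = 20, binary_ab_r1 = 0,
           binary_ab_r2 = 0, ternary = 0)
  occ0 <- summarize_occupancy(st0, cl)
  expect_equal(occ0$bound_total, 0)
  expect_equal(occ0$frac_total, 0)

  # fully ternary-saturated symmetric state
  stT <- c(free_ab = 0, free_r1 = 0, free_r2 = 0, binary_ab_r1 = 0,
           binary_ab_r2 = 0, ternary = 100)
  occT <- summarize_occupancy(stT, cell_line("sym", 100, 100))
  expect_equal(occT$frac_total, 1)

  # zero-receptor flag
  occZ <- summarize_occupancy(st0, cell_line("none", 0, 0))
  expect_true(occZ$zero_receptor)
  expect_equal(occZ$frac_total, 0)
})

test_that("homobivalent ternary complexes count two cognate receptors", {
  rc <- toy_rates()
  prot <- assay_protocol(doses = 10, washout = FALSE, horizon_s = 5000,
                         detection_s = 0)
  sim <- simulate_assay("tocilizumab", "IL6R+", 10, rc, prot)
  st <- terminal_state(sim)
  expect_gt(st[["ternary"]], 0)
  occ <- summarize_occupancy(sim)
  # all bound receptor is IL-6R; IL-8R occupancy must be 0
  expect_equal(occ$occ_il8r, 0)
  expect_equal(occ$occ_il6r * sim$cell_line$il6r_per_cell,
               st[["binary_ab_r1"]] + 2 * st[["ternary"]])
})

test_that("pre-washout bound antibody equals depleted dose via alpha", {
  rc <- toy_rates()
  prot <- assay_protocol(doses = 1, washout = FALSE, horizon_s = 2000,
                         detection_s = 0)
  sim <- simulate_assay("BS1", "IL6R+IL8R+", 1, rc, prot)
  st <- terminal_state(sim)
  expect_equal(total_bound_antibody(st),
               (sim$dose - st[["free_ab"]]) / rc$alpha, tolerance = 1e-8)
})

test_that("statistical factor 2 doubles initial homobivalent uptake", {
  rc <- toy_rates()
  prot <- assay_protocol(doses = 1, washout = FALSE, horizon_s = 10,
                         detection_s = 0)
  b2 <- total_bound_antibody(simulate_assay("tocilizumab", "IL6R+", 1, rc,
                                            prot, model_options(stat_factor = 2)))
  b1 <- total_bound_antibody(simulate_assay("tocilizumab", "IL6R+", 1, rc,
                                            prot, model_options(stat_factor = 1)))
  # over a short window binding is rate-limited: factor ~2
  expect_equal(b2 / b1, 2, tolerance = 0.05)
})

test_that("integrator failure surfaces as a diagnostic error", {
  rc <- toy_rates()
  opts <- model_options(max_steps = 5L)
  prot <- assay_protocol(doses = 10, washout = FALSE, horizon_s = 7200,
                         detection_s = 0)
  expect_error(simulate_assay("BS1", "IL6R+IL8R+", 10, rc, prot, opts),
               "integrator failure")
})
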