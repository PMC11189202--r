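# Fitting-module tests run on reduced designs (fewer doses) for speed; the
# full 77-point identifiability campaign lives in test-acceptance.R.

test_that("normalization: saturation self-normalizes and scale cancels", {
  d <- default_design(doses = default_doses(6))
  rc <- toy_rates()
  dat <- generate_dataset(d, rc, noise_model("none"), scale = 1000)
  norm <- normalize_dataset(dat)
  sat <- attr(norm, "saturation_doses")
  for (cl in unique(norm$cell_line)) {
    sel <- norm$antibody == "BS1" & norm$cell_line == cl &
      norm$dose_nM %in% sat[[cl]]
    expect_equal(mean(norm$value[sel]), 1, tolerance = 1e-12)
  }
  # scaling all MFI by a constant leaves the table unchanged
  dat2 <- dat
  dat2$mfi <- dat2$mfi * 123.4
  expect_equal(normalize_dataset(dat2)$value, norm$value, tolerance = 1e-12)
})

test_that("normalization preconditions: BS1 rows and nonzero denominator", {
  d <- default_design(doses = default_doses(3))
  dat <- generate_dataset(d, toy_rates(), noise_model("none"))
  no_bs1 <- dat[dat$antibody != "BS1", ]
  expect_error(normalize_dataset(no_bs1), "BS1")
  zero <- dat
  zero$mfi[zero$antibody == "BS1"] <- 0
  expect_error(normalize_dataset(zero), "zero|undefined")
})

test_that("cost is zero at truth and the residual layout matches the data", {
  d <- default_design()
  rc <- best_fit_rates()
  dat <- generate_dataset(d, rc, noise_model("none"), seed = 1)
  norm <- normalize_dataset(dat)
  fn <- cost_function(norm)
  r <- fn(table_fit_truth_log10())
  expect_length(r, 77L)
  expect_lt(attr(r, "sse"), 1e-12)
})

test_that("cost grows monotonically as koff values are scaled from truth", {
  d <- default_design(doses = default_doses(5))
  rc <- toy_rates()
  dat <- generate_dataset(d, rc, noise_model("none"))
  norm <- normalize_dataset(dat)
  fn <- cost_function(norm)
  truth <- log10(c(rc$kon_6R, rc$kon_8R, rc$kon_6R_star, rc$koff_6R,
                   rc$koff_8R))
  sse <- sapply(c(0, 0.15, 0.3, 0.6), function(s)
    attr(fn(truth + c(0, 0, 0, s, s)), "sse"))
  expect_true(all(diff(sse) > 0))
  expect_lt(sse[1], 1e-12)
})

test_that("the four normalization schemes produce distinct denominators", {
  d <- default_design(doses = default_doses(5))
  rc <- toy_rates()
  dat <- generate_dataset(d, rc, noise_model("none"))
  norm <- normalize_dataset(dat)
  truth <- log10(c(rc$kon_6R, rc$kon_8R, rc$kon_6R_star, rc$koff_6R,
                   rc$koff_8R))
  sses <- sapply(list(norm_scheme("BS1", "data"), norm_scheme("BS1", "max"),
                      norm_scheme("Ab", "data"), norm_scheme("Ab", "max")),
                 function(s) attr(cost_function(norm, s)(truth), "sse"))
  # the data are BS1/saturation normalized, so only that scheme nulls at truth
  expect_lt(sses[1], 1e-12)
  expect_gt(sses[3], 1e-6)
})

test_that("LHS guesses are stratified log-uniformly and reproducible", {
  rng <- default_guess_ranges()
  g <- lhs_initial_guesses(rng, n = 40, seed = 9)
  expect_identical(dim(g), c(40L, 5L))
  expect_true(all(t(g) >= rng[1, ] & t(g) <= rng[2, ]))
  # exactly one sample per log-width stratum, every column
  for (j in 1:5) {
    u <- (log10(g[, j]) - log10(rng[1, j])) /
      (log10(rng[2, j]) - log10(rng[1, j]))
    expect_identical(as.vector(table(findInterval(u, seq(0, 1, by = 1 / 40),
                                                  rightmost.closed = TRUE))),
                     rep(1L, 40))
  }
  expect_identical(lhs_initial_guesses(rng, n = 40, seed = 9), g)
  expect_identical(nrow(lhs_initial_guesses(rng, n = 1, seed = 1)), 1L)
  expect_error(lhs_initial_guesses(rbind(c(-1, 1), c(1, 2)), 5), "positive")
})

test_that("multistart recovers truth from nearby guesses (noise-free)", {
  d <- default_design(doses = default_doses(7))
  rc <- best_fit_rates()
  dat <- generate_dataset(d, rc, noise_model("none"))
  norm <- normalize_dataset(dat)
  truth <- table_fit_truth_log10()
  set.seed(31)
  guesses <- 10^t(replicate(3, truth + runif(5, -0.5, 0.5)))
  colnames(guesses) <- fit_param_names()
  fits <- run_multistart(norm, guesses)
  sel <- filter_and_select(fits)
  expect_true(all(abs(sel$best$log10_par - truth) < 0.05))
  expect_lt(sel$best$cost, 1e-10)
  # derived constant carried through the constraint
  expect_equal(cycle_product(sel$best$params), 1, tolerance = 1e-10)
})

test_that("bound-violating starts are rejected up front", {
  d <- default_design(doses = default_doses(3))
  dat <- generate_dataset(d, toy_rates(), noise_model("none"))
  norm <- normalize_dataset(dat)
  bad <- matrix(10^c(0.5, -5, -7, -3, -3), nrow = 1)  # kon_6R above bound
  expect_error(run_multistart(norm, bad), "bounds")
})

test_that("filter_and_select applies the discard rules and tie-breaks", {
  mk <- function(idx, cost, conv, moved) {
    structure(list(params = toy_rates(), cost = cost, converged = conv,
                   moved_from_guess = moved, initial_guess = rep(-5, 5),
                   log10_par = stats::setNames(rep(-5, 5), fit_param_names()),
                   scheme = norm_scheme(), index = as.integer(idx)),
              class = "fit_result")
  }
  res <- structure(list(mk(1, 5, TRUE, TRUE), mk(2, 1, FALSE, TRUE),
                        mk(3, 1, TRUE, FALSE), mk(4, 2, TRUE, TRUE),
                        mk(5, 2, TRUE, TRUE)),
                   class = "multistart_fits")
  sel <- filter_and_select(res)
  expect_identical(sel$n_retained, 3L)
  expect_identical(sel$best$index, 4L)  # cost tie at 2 -> lowest index
  expect_equal(sel$discard_rate, 2 / 5)
  expect_identical(nrow(sel$summary), 5L)
  # single converged result is best; all-discarded errors
  expect_identical(filter_and_select(structure(list(mk(1, 9, TRUE, TRUE)),
                                               class = "multistart_fits"))$best$index, 1L)
  expect_error(filter_and_select(structure(list(mk(1, 9, FALSE, TRUE)),
                                           class = "multistart_fits")),
               "more starts")
})

test_that("fits are invariant to the synthetic MFI scale factor", {
  d <- default_design(doses = default_doses(5))
  rc <- toy_rates()
  truth <- log10(c(rc$kon_6R, rc$kon_8R, rc$kon_6R_star, rc$koff_6R,
                   rc$koff_8R))
  g <- matrix(10^(truth + 0.3), nrow = 1)
  fit_at_scale <- function(scale) {
    dat <- generate_dataset(d, rc, noise_model("none"), scale = scale)
    run_multistart(normalize_dataset(dat), g)[[1]]$log10_par
  }
  expect_equal(fit_at_scale(1), fit_at_scale(8.5e3), tolerance = 1e-6)
})
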