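# Shared fixtures. Toy rate sets use fast kinetics so equilibrium is reached
# in short simulated times, keeping property tests cheap; the published
# best-fit set is used where the test is about those specific values.

toy_rates <- function(kon_6R = 1e-3, kon_8R = 2e-3, kon_6R_star = 5e-4,
                      koff_6R = 1e-2, koff_8R = 2e-2, alpha = 8.3e-7) {
  rate_constants(kon_6R = kon_6R, kon_8R = kon_8R, kon_6R_star = kon_6R_star,
                 koff_6R = koff_6R, koff_8R = koff_8R, alpha = alpha)
}

random_rates <- function() {
  rate_constants(kon_6R = 10^runif(1, -7, -4), kon_8R = 10^runif(1, -7, -4),
                 kon_6R_star = 10^runif(1, -9, -6),
                 koff_6R = 10^runif(1, -5, -3), koff_8R = 10^runif(1, -5, -3))
}

table_fit_truth_log10 <- function() {
  rc <- best_fit_rates()
  log10(c(rc$kon_6R, rc$kon_8R, rc$kon_6R_star, rc$koff_6R, rc$koff_8R))
}

# occupancy-fraction deviation between two grid tables
max_frac_diff <- function(a, b) {
  max(abs(a$frac_total - b$frac_total), abs(a$frac_binary - b$frac_binary),
      abs(a$frac_ternary - b$frac_ternary))
}
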