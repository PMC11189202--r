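#' Occupancy over a dose x receptor-expression grid
#'
#' Runs one simulation per grid cell (by default the 24 h no-washout
#' analysis protocol) and reports the occupancy summary for each. The
#' simulated species can be a single antibody construct (`"BS1"`,
#' `"tocilizumab"`, `"10H2"`) or `"mabs"`, the 1:1 combination of
#' tocilizumab and 10H2 at the stated total dose.
#'
#' @param spec antibody name, [antibody_construct()], or `"mabs"`
#' @param doses vector of total antibody doses, nM
#' @param receptor_levels a data.frame (or 2-column matrix) with columns
#'   `il6r`, `il8r` in #/cell, one row per receptor condition
#' @param rates a [rate_constants()] object
#' @param protocol an [assay_protocol()]; defaults to 24 h, no washout
#' @param ratio tocilizumab fraction of the total dose in `"mabs"` mode
#' @param options a [model_options()] list
#' @return a long data.frame: `dose`, `il6r`, `il8r`, the occupancy-summary
#'   columns, and `error` (NA unless the integration failed in that cell,
#'   in which case the message is recorded and the grid continues)
#' @export
dose_receptor_grid <- function(spec, doses, receptor_levels,
                               rates = best_fit_rates(),
                               protocol = analysis_protocol(),
                               ratio = 0.5, options = model_options()) {
  stopifnot(length(doses) >= 1)
  rl <- as.data.frame(receptor_levels)
  names(rl) <- c("il6r", "il8r")
  stopifnot(nrow(rl) >= 1)
  combo <- is.character(spec) && identical(spec, "mabs")
  rows <- vector("list", length(doses) * nrow(rl))
  k <- 0L
  for (i in seq_len(nrow(rl))) {
    cl <- cell_line(sprintf("grid_%g_%g", rl$il6r[i], rl$il8r[i]),
                    rl$il6r[i], rl$il8r[i])
    for (d in doses) {
      k <- k + 1L
      res <- tryCatch({
        sim <- if (combo)
          simulate_mab_combo(cl, d, rates, protocol, ratio, options)
        else
          simulate_assay(spec, cl, d, rates, protocol, options)
        cbind(data.frame(dose = d, il6r = rl$il6r[i], il8r = rl$il8r[i]),
              summarize_occupancy(sim), data.frame(error = NA_character_))
      }, error = function(e) {
        cbind(data.frame(dose = d, il6r = rl$il6r[i], il8r = rl$il8r[i],
                         bound_binary = NA_real_, bound_ternary = NA_real_,
                         bound_total = NA_real_, frac_binary = NA_real_,
                         frac_ternary = NA_real_, frac_total = NA_real_,
                         occ_il6r = NA_real_, occ_il8r = NA_real_,
                         zero_receptor = NA),
              data.frame(error = conditionMessage(e)))
      })
      rows[[k]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log-spaced grid axis helper
#' @param lo,hi endpoints
#' @param per_decade points per decade (default 25)
#' @return numeric vector
#' @export
log_axis <- function(lo, hi, per_decade = 25) {
  n <- max(2L, ceiling(log10(hi / lo) * per_decade) + 1L)
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Relative binding of the bispecific versus the monoclonal combination
#'
#' Element-wise ratio of fractional occupancies (BsAb / mAb combination) for
#' summaries computed on the same cell line, protocol, and total dose.
#' A 0/0 ratio is reported as 1 with `indeterminate = TRUE`; a positive
#' numerator over a zero denominator is `Inf`.
#'
#' @param bsab occupancy summary row for the bispecific ([summarize_occupancy()])
#' @param mabs occupancy summary row for the monoclonal combination
#' @return a one-row data.frame of ratios `rel_total`, `rel_binary`,
#'   `rel_ternary`, `rel_il6r`, `rel_il8r` and the `indeterminate` flag
#' @export
relative_binding <- function(bsab, mabs) {
  ratio1 <- function(num, den) {
    if (den == 0 && num == 0) return(c(1, TRUE))
    c(num / den, FALSE)
  }
  rt <- ratio1(bsab$frac_total, mabs$frac_total)
  rb <- ratio1(bsab$frac_binary, mabs$frac_binary)
  rn <- ratio1(bsab$frac_ternary, mabs$frac_ternary)
  r6 <- ratio1(bsab$occ_il6r, mabs$occ_il6r)
  r8 <- ratio1(bsab$occ_il8r, mabs$occ_il8r)
  data.frame(rel_total = rt[1], rel_binary = rb[1], rel_ternary = rn[1],
             rel_il6r = r6[1], rel_il8r = r8[1],
             indeterminate = any(c(rt[2], rb[2], rn[2], r6[2], r8[2]) == 1))
}
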