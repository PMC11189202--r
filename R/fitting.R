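#' Free parameters of the binding model fit
#'
#' Five rate constants are estimated from dose-response data (`kon_6R`,
#' `kon_8R`, `kon_6R_star`, `koff_6R`, `koff_8R`); `kon_8R_star` is always
#' derived from the thermodynamic cycle constraint. `default_guess_ranges()`
#' gives the log-uniform Latin hypercube sampling box (centered on
#' literature values for other bispecific antibodies) and
#' `default_fit_bounds()` the optimization bounds.
#'
#' @return a 2-row matrix (`lo`, `hi`) with one column per free parameter
#' @export
default_guess_ranges <- function() {
  m <- rbind(lo = c(1e-9, 1e-9, 1e-13, 1e-7, 1e-7),
             hi = c(1e-2, 1e-2, 1e-5, 1e-2, 1e-2))
  colnames(m) <- fit_param_names()
  m
}

#' @rdname default_guess_ranges
#' @export
default_fit_bounds <- function() {
  m <- rbind(lo = c(1e-11, 1e-11, 1e-15, 1e-9, 1e-9),
             hi = c(1, 1, 1e-3, 1, 1))
  colnames(m) <- fit_param_names()
  m
}

#' @rdname default_guess_ranges
#' @export
fit_param_names <- function() {
  c("kon_6R", "kon_8R", "kon_6R_star", "koff_6R", "koff_8R")
}

#' Normalization scheme for the cost function
#'
#' Simulated bound antibody is normalized before comparison with the
#' normalized assay data. `basis = "BS1"` divides every antibody's simulated
#' signal in a cell line by the simulated BS1 signal there; `basis = "Ab"`
#' divides each antibody by its own signal. `reference = "data"` evaluates
#' the denominator at the saturation doses used to normalize the
#' experimental data; `reference = "max"` uses the maximum dose only.
#' The scheme used for the published parameter estimates is `"BS1"` /
#' `"data"` (the default).
#'
#' @param basis `"BS1"` or `"Ab"`
#' @param reference `"data"` or `"max"`
#' @return a list of class `norm_scheme`
#' @export
norm_scheme <- function(basis = c("BS1", "Ab"), reference = c("data", "max")) {
  basis <- match.arg(basis)
  reference <- match.arg(reference)
  structure(list(basis = basis, reference = reference), class = "norm_scheme")
}

#' Identify the BS1 saturation doses of a dataset
#'
#' Saturation doses are, per cell line, the doses at which the mean BS1
#' signal lies within `window` of its maximum over the dose grid; if fewer
#' than two qualify, the top two doses are used.
#'
#' @param data dose-response table with columns `antibody`, `cell_line`,
#'   `dose_nM`, `mfi` (replicates allowed)
#' @param window relative closeness to the maximum (default 0.05)
#' @return named list of dose vectors, one entry per cell line
#' @export
saturation_doses <- function(data, window = 0.05) {
  bs1 <- data[data$antibody == "BS1", , drop = FALSE]
  if (nrow(bs1) == 0) stop("dataset contains no BS1 rows")
  out <- list()
  for (cl in unique(bs1$cell_line)) {
    d <- bs1[bs1$cell_line == cl, , drop = FALSE]
    m <- tapply(d$mfi, d$dose_nM, mean)
    doses <- as.numeric(names(m))
    sat <- doses[m >= (1 - window) * max(m)]
    if (length(sat) < 2) sat <- sort(doses, decreasing = TRUE)[1:2]
    out[[cl]] <- sort(sat)
  }
  out
}

#' Normalize a dose-response dataset
#'
#' Replicates are averaged (unless `average_replicates = FALSE`), then every
#' value is divided by the mean BS1 signal at the saturation doses of its
#' cell line, so the normalized data are invariant to the arbitrary MFI
#' scale. Each cell line is normalized separately.
#'
#' @param data table with columns `antibody`, `cell_line`, `dose_nM`,
#'   `replicate`, `mfi`
#' @param sat_doses optional named list of saturation doses per cell line;
#'   determined by [saturation_doses()] when `NULL`
#' @param average_replicates average replicates before normalizing?
#' @param window passed to [saturation_doses()]
#' @return a data.frame `antibody`, `cell_line`, `dose_nM`, `value` with the
#'   saturation doses attached as attribute `"saturation_doses"`
#' @export
normalize_dataset <- function(data, sat_doses = NULL,
                              average_replicates = TRUE, window = 0.05) {
  need <- c("antibody", "cell_line", "dose_nM", "mfi")
  if (!all(need %in% names(data)))
    stop("dataset must have columns ", paste(need, collapse = ", "))
  if (is.null(sat_doses)) sat_doses <- saturation_doses(data, window)
  missing_cl <- setdiff(unique(data$cell_line), names(sat_doses))
  if (length(missing_cl))
    stop("no BS1 rows to normalize cell line(s): ",
         paste(missing_cl, collapse = ", "))
  if (average_replicates) {
    agg <- stats::aggregate(mfi ~ antibody + cell_line + dose_nM,
                            data = data, FUN = mean)
  } else {
    agg <- data[, c("antibody", "cell_line", "dose_nM", "mfi")]
  }
  agg$value <- NA_real_
  for (cl in unique(agg$cell_line)) {
    bs1 <- data$antibody == "BS1" & data$cell_line == cl &
      data$dose_nM %in% sat_doses[[cl]]
    denom <- mean(data$mfi[bs1])
    if (!is.finite(denom) || denom == 0)
      stop("zero or undefined BS1 saturation signal for cell line ", cl)
    sel <- agg$cell_line == cl
    agg$value[sel] <- agg$mfi[sel] / denom
  }
  out <- agg[order(agg$antibody, agg$cell_line, agg$dose_nM),
             c("antibody", "cell_line", "dose_nM", "value")]
  rownames(out) <- NULL
  attr(out, "saturation_doses") <- sat_doses
  out
}

# Terminal bound antibody (#/cell) for one design point; fast terminal-only
# integration.
.terminal_bound <- function(antibody, cl, dose, rc, protocol, options) {
  spec <- .network_spec(as_antibody(antibody), cl, dose, rc, options)
  res <- .integrate_phases(spec, protocol, options, terminal_only = TRUE)
  y <- res$y[nrow(res$y), ]
  if (spec$type == 0L) sum(y[4:6]) else sum(y[3:4])
}

# Precompute the per-point matrices consumed by the batched C++ design
# evaluator. `code` selects the parameter template per row: 1 = hetero (BS1),
# 2 = homo on IL-6R (tocilizumab), 3 = homo on IL-8R (10H2).
.design_matrices <- function(points, cell_lines, options) {
  m <- nrow(points)
  type <- integer(m); code <- integer(m)
  y0 <- matrix(0, m, 6); atol <- matrix(0, m, 6)
  for (i in seq_len(m)) {
    nm <- points$cell_line[i]
    cl <- if (nm %in% names(cell_lines)) cell_lines[[nm]] else as_cell_line(nm)
    ab <- as_antibody(points$antibody[i])
    dose <- points$dose_nM[i]
    if (ab$bispecific) {
      type[i] <- 0L; code[i] <- 1L
      y0[i, 1:3] <- c(dose, cl$il6r_per_cell, cl$il8r_per_cell)
      atol[i, ] <- options$atol_scale *
        c(max(dose, 1), rep(max(cl$il6r_per_cell, cl$il8r_per_cell, 1), 5))
    } else if (ab$arm_targets[1] == "IL6R") {
      type[i] <- 1L; code[i] <- 2L
      y0[i, 1:2] <- c(dose, cl$il6r_per_cell)
      atol[i, 1:4] <- options$atol_scale *
        c(max(dose, 1), rep(max(cl$il6r_per_cell, 1), 3))
    } else {
      type[i] <- 1L; code[i] <- 3L
      y0[i, 1:2] <- c(dose, cl$il8r_per_cell)
      atol[i, 1:4] <- options$atol_scale *
        c(max(dose, 1), rep(max(cl$il8r_per_cell, 1), 3))
    }
  }
  list(type = type, code = code, y0 = y0, atol = atol)
}

# Evaluate terminal bound antibody for all points of a precomputed design.
.design_bound <- function(dm, rc, protocol, options) {
  templates <- rbind(
    c(rc$kon_6R, rc$kon_8R, rc$kon_6R_star, rc$kon_8R_star, rc$koff_6R,
      rc$koff_8R, rc$alpha, 0),
    c(rc$kon_6R, rc$kon_6R_star, rc$koff_6R, rc$alpha, options$stat_factor,
      0, 0, 0),
    c(rc$kon_8R, rc$kon_8R_star, rc$koff_8R, rc$alpha, options$stat_factor,
      0, 0, 0))
  .design_bound_cpp(dm$type, templates[dm$code, , drop = FALSE], dm$y0,
                    dm$atol, protocol$washout_time_s, protocol$horizon_s,
                    options$rtol, protocol$washout, protocol$clamp_washout,
                    options$max_steps)
}

#' Simulate the bound-antibody signal for a whole design
#'
#' Runs the fitting protocol for every (antibody, cell line, dose) point and
#' returns the terminal total bound antibody per cell.
#'
#' @param points data.frame with columns `antibody`, `cell_line`, `dose_nM`
#' @param rates a [rate_constants()] object
#' @param protocol an [assay_protocol()]
#' @param cell_lines named list of [cell_line()] objects for lookup
#' @param options a [model_options()] list
#' @return `points` with a `bound` column (#/cell)
#' @export
simulate_design <- function(points, rates = best_fit_rates(),
                            protocol = fitting_protocol(),
                            cell_lines = hek_panel(),
                            options = model_options()) {
  dm <- .design_matrices(points, cell_lines, options)
  points$bound <- as.numeric(.design_bound(dm, rates, protocol, options))
  points
}

# Scheme denominators per (antibody, cell line) for a simulated design.
.scheme_denoms <- function(simmed, scheme, sat_doses) {
  key <- paste(simmed$antibody, simmed$cell_line, sep = "\r")
  denom <- numeric(nrow(simmed))
  for (cl in unique(simmed$cell_line)) {
    ref_doses <- if (scheme$reference == "data") sat_doses[[cl]]
                 else max(simmed$dose_nM[simmed$cell_line == cl])
    sel_cl <- simmed$cell_line == cl
    if (scheme$basis == "BS1") {
      ref <- sel_cl & simmed$antibody == "BS1" & simmed$dose_nM %in% ref_doses
      if (!any(ref)) stop("no BS1 reference points for cell line ", cl)
      denom[sel_cl] <- mean(simmed$bound[ref])
    } else {
      for (ab in unique(simmed$antibody[sel_cl])) {
        sel <- sel_cl & simmed$antibody == ab
        ref <- sel & simmed$dose_nM %in% ref_doses
        denom[sel] <- mean(simmed$bound[ref])
      }
    }
  }
  denom
}

#' Cost function for the binding-model fit
#'
#' Builds a residual function over the five free parameters in log10 space.
#' For a candidate parameter vector the fitting protocol (association,
#' washout, detection) is simulated at every data point, the simulated bound
#' antibody is normalized per the scheme, and residuals against the
#' normalized data are returned. A failed integration at any point
#' contributes a large penalty residual (with a warning) instead of
#' aborting.
#'
#' @param data_norm normalized dataset from [normalize_dataset()]
#' @param scheme a [norm_scheme()]
#' @param protocol an [assay_protocol()]; the fitting protocol by default
#' @param cell_lines named list of [cell_line()] objects
#' @param alpha unit-conversion constant fixed during fitting
#' @param options a [model_options()] list
#' @param penalty residual value assigned to failed simulations
#' @return a function `f(log10_params)` returning the residual vector with
#'   attribute `"sse"`
#' @export
cost_function <- function(data_norm, scheme = norm_scheme(),
                          protocol = fitting_protocol(),
                          cell_lines = hek_panel(), alpha = 8.3e-7,
                          options = model_options(), penalty = 1e3) {
  sat_doses <- attr(data_norm, "saturation_doses")
  if (is.null(sat_doses))
    stop("data_norm must come from normalize_dataset()")
  points <- data_norm[, c("antibody", "cell_line", "dose_nM")]
  dm <- .design_matrices(points, cell_lines, options)
  target <- data_norm$value

  function(logp) {
    stopifnot(length(logp) == 5)
    p <- 10^logp
    rc <- rate_constants(kon_6R = p[1], kon_8R = p[2], kon_6R_star = p[3],
                         koff_6R = p[4], koff_8R = p[5], alpha = alpha)
    bound <- tryCatch(
      as.numeric(.design_bound(dm, rc, protocol, options)),
      error = function(e) {
        warning("integration failed; penalty residuals used: ",
                conditionMessage(e), call. = FALSE)
        rep(NA_real_, nrow(points))
      })
    if (anyNA(bound))
      warning("integration failed for some design points; penalty residuals used",
              call. = FALSE)
    simmed <- cbind(points, bound = bound)
    denom <- tryCatch(.scheme_denoms(simmed, scheme, sat_doses),
                      error = function(e) rep(NA_real_, nrow(simmed)))
    r <- simmed$bound / denom - target
    r[!is.finite(r)] <- penalty
    attr(r, "sse") <- sum(r^2)
    r
  }
}

#' Log-uniform Latin hypercube initial guesses
#'
#' Each parameter axis is divided into `n` equal log-width strata and
#' exactly one sample is drawn per stratum, with strata permuted
#' independently per parameter.
#'
#' @param ranges 2-row matrix (`lo`, `hi`) as from [default_guess_ranges()]
#' @param n number of guesses
#' @param seed optional integer seed for reproducibility
#' @return `n` x 5 matrix of parameter values (linear scale)
#' @export
lhs_initial_guesses <- function(ranges = default_guess_ranges(), n = 300,
                                seed = NULL) {
  stopifnot(n >= 1, nrow(ranges) == 2)
  if (any(ranges <= 0)) stop("LHS ranges must be positive (log-space sampling)")
  if (any(ranges[1, ] >= ranges[2, ])) stop("each range must have lo < hi")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  k <- ncol(ranges)
  out <- matrix(NA_real_, n, k, dimnames = list(NULL, colnames(ranges)))
  for (j in seq_len(k)) {
    lo <- log10(ranges[1, j]); hi <- log10(ranges[2, j])
    strata <- (sample.int(n) - 1 + stats::runif(n)) / n
    out[, j] <- 10^(lo + strata * (hi - lo))
  }
  out
}

# Bound-projected Levenberg-Marquardt on a residual function, with forward-
# difference Jacobian. Operates on the (log10) parameter vector directly.
.lm_bounded <- function(res_fn, x0, lo, hi, max_iter = 80, ftol = 1e-12,
                        xtol = 1e-10, gtol = 1e-8, fd_h = 1e-6) {
  x <- pmin(pmax(x0, lo), hi)
  r <- res_fn(x)
  sse <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  n <- length(x)
  for (iter in seq_len(max_iter)) {
    J <- matrix(0, length(r), n)
    for (j in seq_len(n)) {
      xh <- x
      h <- fd_h * max(1, abs(x[j]))
      if (xh[j] + h > hi[j]) h <- -h
      xh[j] <- xh[j] + h
      J[, j] <- (res_fn(xh) - r) / h
    }
    g <- drop(crossprod(J, r))
    # projected gradient: ignore components pushing past an active bound
    gp <- g
    gp[x <= lo + 1e-12 & g > 0] <- 0
    gp[x >= hi - 1e-12 & g < 0] <- 0
    if (max(abs(gp)) < gtol * max(1, sse)) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    improved <- FALSE
    for (tries in 1:12) {
      A <- JtJ + lambda * diag(pmax(diag(JtJ), 1e-12), n)
      step <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      xn <- pmin(pmax(x + step, lo), hi)
      rn <- res_fn(xn)
      ssen <- sum(rn^2)
      if (is.finite(ssen) && ssen < sse) {
        moved <- max(abs(xn - x))
        rel_drop <- (sse - ssen) / max(sse, .Machine$double.eps)
        x <- xn; r <- rn; sse <- ssen
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        if (moved < xtol || rel_drop < ftol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }  # no descent direction left
    if (converged) break
  }
  list(par = x, sse = sse, converged = converged, iterations = iter)
}

#' Multi-start bounded least-squares fit
#'
#' One bounded least-squares solve per initial guess, optimizing the five
#' free rate constants in log10 space with `kon_8R_star` derived from the
#' cycle constraint at every evaluation. The default optimizer is a
#' bound-projected Levenberg-Marquardt on the residual vector;
#' `method = "nlminb"` minimizes the sum of squares with [stats::nlminb()].
#'
#' @param data_norm normalized dataset from [normalize_dataset()]
#' @param guesses matrix of initial guesses (linear scale), e.g. from
#'   [lhs_initial_guesses()]; all rows must lie within `bounds`
#' @param bounds 2-row matrix of optimization bounds (linear scale)
#' @param scheme a [norm_scheme()]
#' @param protocol an [assay_protocol()]
#' @param cell_lines named list of [cell_line()] objects
#' @param alpha unit-conversion constant, fixed
#' @param options a [model_options()] list
#' @param method `"lm"` or `"nlminb"`
#' @param moved_tol log10 displacement below which a result counts as "did
#'   not vary from its initial guess"
#' @return a list of `fit_result` objects (class `multistart_fits`), each
#'   with optimized [rate_constants()], `cost` (SSE), `converged`,
#'   `moved_from_guess`, `initial_guess` (log10), `log10_par`, `scheme`,
#'   and the start `index`
#' @export
run_multistart <- function(data_norm, guesses, bounds = default_fit_bounds(),
                           scheme = norm_scheme(),
                           protocol = fitting_protocol(),
                           cell_lines = hek_panel(), alpha = 8.3e-7,
                           options = model_options(),
                           method = c("lm", "nlminb"), moved_tol = 1e-6) {
  method <- match.arg(method)
  guesses <- as.matrix(guesses)
  lo <- log10(bounds[1, ]); hi <- log10(bounds[2, ])
  glog <- log10(guesses)
  if (any(t(glog) < lo - 1e-12) || any(t(glog) > hi + 1e-12))
    stop("initial guesses must lie within the optimization bounds")
  fn <- cost_function(data_norm, scheme, protocol, cell_lines, alpha, options)
  fits <- vector("list", nrow(guesses))
  for (i in seq_len(nrow(guesses))) {
    x0 <- glog[i, ]
    res <- tryCatch({
      if (method == "lm") {
        .lm_bounded(fn, x0, lo, hi)
      } else {
        o <- stats::nlminb(x0, function(x) sum(fn(x)^2), lower = lo,
                           upper = hi)
        list(par = o$par, sse = o$objective, converged = o$convergence == 0,
             iterations = o$iterations)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fits[[i]] <- structure(list(params = NULL, cost = Inf,
                                  converged = FALSE, moved_from_guess = FALSE,
                                  initial_guess = x0, log10_par = x0,
                                  scheme = scheme, index = i,
                                  error = conditionMessage(res)),
                             class = "fit_result")
      next
    }
    p <- 10^res$par
    rc <- rate_constants(kon_6R = p[1], kon_8R = p[2], kon_6R_star = p[3],
                         koff_6R = p[4], koff_8R = p[5], alpha = alpha)
    fits[[i]] <- structure(list(params = rc, cost = res$sse,
                                converged = isTRUE(res$converged),
                                moved_from_guess = max(abs(res$par - x0)) >= moved_tol,
                                initial_guess = x0,
                                log10_par = stats::setNames(res$par, fit_param_names()),
                                scheme = scheme, index = i, error = NULL),
                           class = "fit_result")
  }
  structure(fits, class = "multistart_fits")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit %d: cost %.4g, converged %s, moved %s\n", x$index, x$cost,
              x$converged, x$moved_from_guess))
  invisible(x)
}

#' Filter multi-start results and select the best fit
#'
#' Discards starts that did not converge or that did not move from their
#' initial guesses, then selects the minimum-cost retained fit (ties broken
#' by lowest start index). The summary reports the distribution of each
#' optimized parameter and the standard deviation of its log10-transformed
#' values across retained starts.
#'
#' @param results a `multistart_fits` list from [run_multistart()]
#' @return list with `retained` (list of fits), `best` (a `fit_result`),
#'   and `summary` (data.frame: per-parameter best-fit value, median and
#'   S.D. of log10 values, counts)
#' @export
filter_and_select <- function(results) {
  stopifnot(length(results) >= 1)
  keep <- vapply(results, function(f) isTRUE(f$converged) &&
                   isTRUE(f$moved_from_guess), logical(1))
  retained <- results[keep]
  if (length(retained) == 0)
    stop("all starts were discarded (non-converged or did not move); ",
         "run more starts or widen the guess ranges")
  costs <- vapply(retained, function(f) f$cost, numeric(1))
  best <- retained[[which.min(costs)]]  # which.min takes the first = lowest index
  logmat <- do.call(rbind, lapply(retained, function(f) f$log10_par))
  summ <- data.frame(parameter = fit_param_names(),
                     best_fit = 10^best$log10_par,
                     median_log10 = apply(logmat, 2, stats::median),
                     sd_log10 = apply(logmat, 2, stats::sd),
                     row.names = NULL)
  list(retained = retained, best = best, summary = summ,
       n_total = length(results), n_retained = length(retained),
       discard_rate = 1 - length(retained) / length(results))
}
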