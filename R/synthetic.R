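#' Default assay design
#'
#' The binding-competent design of the flow-cytometry experiment: 11
#' log-spaced doses from 1e-2 to 1e3 nM, the seven antibody x cell-line
#' combinations where at least one arm has its receptor (tocilizumab on the
#' IL-6R+ and double-positive lines; 10H2 on the IL-8R+ and double-positive
#' lines; BS1 on all three receptor-positive lines), and three technical
#' replicates, on the quantified HEK 293T receptor expressions.
#'
#' @param doses dose vector, nM
#' @param replicates number of technical replicates
#' @return list of class `assay_design` with `points` (one row per
#'   antibody x cell line x dose), `combinations`, `doses`, `replicates`,
#'   and `cell_lines`
#' @export
default_design <- function(doses = default_doses(), replicates = 3) {
  panel <- hek_panel()[c("IL6R+", "IL8R+", "IL6R+IL8R+")]
  abs <- antibody_panel()
  combos <- expand.grid(antibody = names(abs), cell_line = names(panel),
                        stringsAsFactors = FALSE)
  ok <- mapply(function(a, c) binding_competent(abs[[a]], panel[[c]]),
               combos$antibody, combos$cell_line)
  combos <- combos[ok, , drop = FALSE]
  rownames(combos) <- NULL
  points <- merge(combos, data.frame(dose_nM = doses), by = NULL)
  points <- points[order(points$antibody, points$cell_line, points$dose_nM), ]
  rownames(points) <- NULL
  structure(list(points = points, combinations = combos, doses = doses,
                 replicates = replicates, cell_lines = hek_panel()),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("Assay design: %d combinations x %d doses = %d points, %d replicates\n",
              nrow(x$combinations), length(x$doses), nrow(x$points),
              x$replicates))
  invisible(x)
}

#' Measurement noise model for synthetic data
#'
#' @param kind `"none"`, `"multiplicative-gaussian"` (value scaled by
#'   `max(0, 1 + N(0, sigma))`), or `"multiplicative-lognormal"`
#' @param sigma coefficient of variation (dimensionless)
#' @return a list of class `noise_model`
#' @export
noise_model <- function(kind = c("multiplicative-gaussian", "none",
                                 "multiplicative-lognormal"),
                        sigma = 0.05) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be non-negative")
  if (kind == "none") sigma <- 0
  structure(list(kind = kind, sigma = sigma), class = "noise_model")
}

.noise_multipliers <- function(noise, n) {
  switch(noise$kind,
         none = rep(1, n),
         `multiplicative-gaussian` = pmax(0, 1 + stats::rnorm(n, 0, noise$sigma)),
         `multiplicative-lognormal` = stats::rlnorm(n, -noise$sigma^2 / 2,
                                                    noise$sigma))
}

#' Generate a synthetic dose-response dataset
#'
#' Forward-simulates the fitting protocol (2 h association, washout, 15 min
#' detection) for every design point with known ground-truth rate constants,
#' scales the terminal bound antibody by an arbitrary MFI scale factor, and
#' applies independent multiplicative noise per replicate.
#'
#' @param design an [default_design()] object
#' @param ground_truth a [rate_constants()] object
#' @param noise a [noise_model()]
#' @param scale MFI units per bound antibody per cell (arbitrary; fits must
#'   be invariant to it)
#' @param seed optional integer seed
#' @param protocol an [assay_protocol()]; the fitting protocol by default
#' @param options a [model_options()] list
#' @return a data.frame of class `synthetic_dataset` with columns
#'   `antibody`, `cell_line`, `dose_nM`, `replicate`, `mfi`; ground truth,
#'   noise, scale, and seed are attached as attributes
#' @export
generate_dataset <- function(design = default_design(),
                             ground_truth = best_fit_rates(),
                             noise = noise_model(), scale = 1e3,
                             seed = NULL, protocol = fitting_protocol(),
                             options = model_options()) {
  stopifnot(inherits(design, "assay_design"),
            inherits(ground_truth, "rate_constants"), scale > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  simmed <- simulate_design(design$points, ground_truth, protocol,
                            design$cell_lines, options)
  reps <- design$replicates
  out <- simmed[rep(seq_len(nrow(simmed)), each = reps), ]
  out$replicate <- rep(seq_len(reps), times = nrow(simmed))
  out$mfi <- scale * out$bound * .noise_multipliers(noise, nrow(out))
  out$bound <- NULL
  rownames(out) <- NULL
  structure(out, class = c("synthetic_dataset", "data.frame"),
            ground_truth = ground_truth, noise = noise, scale = scale,
            seed = seed)
}

#' Write / read a dose-response dataset as CSV
#'
#' `write_dataset` writes the delimited table the fitting module reads and,
#' for synthetic data, a JSON sidecar (`<path>.meta.json`) embedding the
#' ground-truth parameters, noise model, scale and seed.
#'
#' @param data a dataset (e.g. from [generate_dataset()])
#' @param path CSV file path
#' @return `write_dataset`: the path, invisibly; `read_dose_response`: a
#'   data.frame
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  gt <- attr(data, "ground_truth")
  if (!is.null(gt)) {
    meta <- list(ground_truth = unclass(gt)[c(fit_param_names(),
                                              "kon_8R_star", "alpha")],
                 noise = unclass(attr(data, "noise")),
                 scale = attr(data, "scale"),
                 seed = attr(data, "seed"))
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dose_response <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("antibody", "cell_line", "dose_nM", "replicate", "mfi")
  if (!all(need %in% names(data)))
    stop("dose-response file must have columns ", paste(need, collapse = ", "))
  data
}
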