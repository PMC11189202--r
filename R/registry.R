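#' Antibody constructs
#'
#' An antibody construct is defined by its two arm specificities. The three
#' constructs of the IL-6R/IL-8R system are the homobivalent monoclonals
#' tocilizumab (anti-IL-6R x2) and 10H2 (anti-IL-8R x2) and the
#' heterobivalent bispecific BS1 (anti-IL-6R / anti-IL-8R).
#'
#' @param name construct identifier
#' @param arm_targets character vector of length 2; each element one of
#'   `"IL6R"`, `"IL8R"`
#' @return an object of class `antibody_construct`
#' @examples
#' antibody_construct("BS1", c("IL6R", "IL8R"))
#' @export
antibody_construct <- function(name, arm_targets) {
  if (length(arm_targets) != 2L)
    stop("an antibody construct has exactly two arms")
  if (!all(arm_targets %in% c("IL6R", "IL8R")))
    stop("unknown receptor identifier; arms must target IL6R or IL8R")
  structure(list(name = name, arm_targets = as.character(arm_targets),
                 bispecific = arm_targets[1] != arm_targets[2]),
            class = "antibody_construct")
}

#' @export
print.antibody_construct <- function(x, ...) {
  cat(sprintf("Antibody %s: %s / %s (%s)\n", x$name, x$arm_targets[1],
              x$arm_targets[2],
              if (x$bispecific) "heterobivalent" else "homobivalent"))
  invisible(x)
}

#' @rdname antibody_construct
#' @export
antibody_panel <- function() {
  list(tocilizumab = antibody_construct("tocilizumab", c("IL6R", "IL6R")),
       `10H2` = antibody_construct("10H2", c("IL8R", "IL8R")),
       BS1 = antibody_construct("BS1", c("IL6R", "IL8R")))
}

#' Look up an antibody construct by name
#' @param x an `antibody_construct` or the name of one in [antibody_panel()]
#' @return an `antibody_construct`
#' @export
as_antibody <- function(x) {
  if (inherits(x, "antibody_construct")) return(x)
  panel <- antibody_panel()
  if (is.character(x) && x %in% names(panel)) return(panel[[x]])
  stop("unknown antibody: ", x)
}

#' Cell lines
#'
#' A cell line is defined by its IL-6R and IL-8R surface expression in
#' receptors per cell. [hek_panel()] returns the four transduced HEK 293T
#' fixture lines quantified by flow cytometry: IL-6R+ (5.08e5 IL-6R),
#' IL-8R+ (1.30e6 IL-8R), IL-6R+/IL-8R+ (3.16e5 / 6.18e5), and the
#' double-negative parental line.
#'
#' @param name cell line identifier
#' @param il6r_per_cell IL-6R count, #/cell (0 if absent)
#' @param il8r_per_cell IL-8R count, #/cell (0 if absent)
#' @return an object of class `cell_line`
#' @export
cell_line <- function(name, il6r_per_cell, il8r_per_cell) {
  if (il6r_per_cell < 0 || il8r_per_cell < 0)
    stop("receptor counts must be non-negative")
  structure(list(name = name, il6r_per_cell = il6r_per_cell,
                 il8r_per_cell = il8r_per_cell),
            class = "cell_line")
}

#' @export
print.cell_line <- function(x, ...) {
  cat(sprintf("Cell line %s: IL-6R %.3g /cell, IL-8R %.3g /cell\n",
              x$name, x$il6r_per_cell, x$il8r_per_cell))
  invisible(x)
}

#' @rdname cell_line
#' @export
hek_panel <- function() {
  list(`IL6R+` = cell_line("IL6R+", 5.08e5, 0),
       `IL8R+` = cell_line("IL8R+", 0, 1.30e6),
       `IL6R+IL8R+` = cell_line("IL6R+IL8R+", 3.16e5, 6.18e5),
       `negative` = cell_line("negative", 0, 0))
}

#' Look up a cell line by name
#' @param x a `cell_line` or the name of one in [hek_panel()]
#' @return a `cell_line`
#' @export
as_cell_line <- function(x) {
  if (inherits(x, "cell_line")) return(x)
  panel <- hek_panel()
  if (is.character(x) && x %in% names(panel)) return(panel[[x]])
  stop("unknown cell line: ", x)
}

#' Does an antibody have an arm for any receptor on a cell line?
#' @param antibody antibody construct or name
#' @param cell cell line or name
#' @return logical
#' @export
binding_competent <- function(antibody, cell) {
  ab <- as_antibody(antibody); cl <- as_cell_line(cell)
  counts <- c(IL6R = cl$il6r_per_cell, IL8R = cl$il8r_per_cell)
  any(counts[unique(ab$arm_targets)] > 0)
}
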