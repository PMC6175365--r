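#' Allometric-equation registry
#'
#' The registry maps inventory habitats to the set of published allometric
#' equations averaged by [tree_biomass_ensemble()] and
#' [liana_plot_biomass()]. Three functional forms are supported, all
#' returning kg dry biomass for DBH `D` in cm and wood specific gravity
#' `rho` in g/cm3:
#' * `power`: `B = a * (rho * D^2)^b`
#' * `log_poly`: `ln B = c0 + c1*ln D + c2*(ln D)^2 + c3*ln rho`
#' * `liana_power`: `B = a * D^b` (lianas carry no density term)
#'
#' Coefficients live in an editable CSV (columns `id`, `source`, `habitat`,
#' `form`, `a`, `b`, `c0`..`c3`, `provenance`), not in code: height-based
#' equations are excluded by design, and the default file mixes transcribed
#' public coefficients with clearly labelled synthetic stand-ins (see the
#' `provenance` column and the methods vignette). At load time every
#' equation is checked to return finite positive biomass across a grid of
#' D in (1, 300) cm and rho in (0.1, 1.2) g/cm3.
#'
#' @param path CSV path; default is the registry shipped with the package.
#' @return A data frame of class `equation_registry`.
#' @export
read_equation_registry <- function(path = system.file(
    "extdata", "allometric_equations.csv", package = "swidcarbon")) {
  reg <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "source", "habitat", "form", "a", "b", "c0", "c1", "c2", "c3")
  missing <- setdiff(need, names(reg))
  if (length(missing) > 0)
    stop("equation registry ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad_hab <- !reg$habitat %in% c("old_growth", "secondary", "liana")
  if (any(bad_hab))
    stop("equation registry: unknown habitat ", reg$habitat[bad_hab][1],
         call. = FALSE)
  bad_form <- !reg$form %in% c("power", "log_poly", "liana_power")
  if (any(bad_form))
    stop("equation registry: unknown form ", reg$form[bad_form][1],
         call. = FALSE)
  d_grid <- c(1.1, 5, 20, 80, 299)
  rho_grid <- c(0.11, 0.5, 1.19)
  for (i in seq_len(nrow(reg))) {
    vals <- outer(d_grid, rho_grid,
                  function(d, r) evaluate_equation(reg[i, ], d, r))
    if (!all(is.finite(vals)) || any(vals <= 0))
      stop(sprintf("equation %s is not finite-positive over D in (1,300), rho in (0.1,1.2)",
                   reg$id[i]), call. = FALSE)
  }
  class(reg) <- c("equation_registry", "data.frame")
  reg
}

# Evaluate one registry row at vectors of DBH (cm) and wsg (g/cm3) -> kg.
evaluate_equation <- function(eq, dbh, wsg) {
  switch(eq$form,
    power = eq$a * (wsg * dbh^2)^eq$b,
    log_poly = {
      # a zero density exponent must not propagate NA from absent wsg (lianas)
      rho_term <- if (eq$c3 == 0) 0 else eq$c3 * log(wsg)
      exp(eq$c0 + eq$c1 * log(dbh) + eq$c2 * log(dbh)^2 + rho_term)
    },
    liana_power = eq$a * dbh^eq$b,
    stop("unknown equation form: ", eq$form))
}

#' Deadwood decay-class density table
#'
#' Maps the five-class deadwood decomposition scale (1 = recently dead,
#' intact wood; 5 = almost decomposed) to wood density in g/cm3. Densities
#' must be strictly positive and non-increasing from class 1 to class 5.
#' Values are literature-style defaults and config-overridable; class-1
#' pieces normally carry a field-measured core density instead.
#'
#' @param path CSV path (columns `decay_class`, `density`); default is the
#'   table shipped with the package.
#' @return A named numeric vector of length 5 (names "1".."5"), class
#'   `decay_density_table`.
#' @export
read_decay_density <- function(path = system.file(
    "extdata", "decay_density.csv", package = "swidcarbon")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("decay_class", "density") %in% names(df)))
    stop("decay table needs columns decay_class, density", call. = FALSE)
  df <- df[order(df$decay_class), ]
  if (!identical(as.integer(df$decay_class), 1:5))
    stop("decay table must cover classes 1-5 exactly once", call. = FALSE)
  if (any(!(df$density > 0)))
    stop("decay densities must be strictly positive", call. = FALSE)
  if (any(diff(df$density) > 0))
    stop("decay densities must be non-increasing from class 1 to 5",
         call. = FALSE)
  structure(setNames(df$density, df$decay_class),
            class = "decay_density_table")
}
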