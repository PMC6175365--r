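# Shared fixtures: everything is built in code at test time.

default_registry <- read_equation_registry()
default_decay <- read_decay_density()

# single-equation registries with hand-checkable coefficients
toy_registry <- function() {
  reg <- data.frame(
    id = c("pow_tree", "li1"),
    source = c("toy", "toy"),
    habitat = c("secondary", "liana"),
    form = c("power", "liana_power"),
    a = c(0.1, 0.05), b = c(1, 2),
    c0 = NA_real_, c1 = NA_real_, c2 = NA_real_, c3 = NA_real_,
    stringsAsFactors = FALSE)
  class(reg) <- c("equation_registry", "data.frame")
  reg
}

# small synthetic designs used across files
small_params <- function(...) {
  synthetic_params(n_landscapes = 1, squares_per_landscape = 4,
                   plots_per_square = 3,
                   habitat_mix = c(farmland = 2, secondary = 6,
                                   old_growth = 4) / 12, ...)
}

# a minimal single-plot field dataset built directly from records
one_plot_dataset <- function(habitat = "secondary", fallow_age = 10,
                             stems = NULL, lianas = NULL, deadwood = NULL,
                             litter = NULL) {
  plots <- data.frame(plot = "p1", square = "s1", landscape = "l1",
                      habitat = habitat,
                      fallow_age = if (habitat == "secondary") fallow_age
                                   else NA_real_,
                      elevation = 2000, stringsAsFactors = FALSE)
  field_dataset(plots, stems = stems, lianas = lianas, deadwood = deadwood,
                litter = litter)
}

stem_rows <- function(plot = "p1", dbh, size_class = "large", wsg = 0.5) {
  large <- size_class == "large"
  data.frame(plot = plot, size_class = size_class, dbh = dbh,
             core_dry_mass = if (all(large)) wsg * 10 else NA_real_,
             core_green_volume = if (all(large)) 10 else NA_real_,
             stringsAsFactors = FALSE)
}

litter_rows <- function(plot = "p1", subplot = "L1", compressed = 8,
                        dry_mass = 50) {
  data.frame(plot = plot, subplot = subplot, compressed_volume = compressed,
             subsample_volume = 1, subsample_dry_mass = dry_mass,
             stringsAsFactors = FALSE)
}

deadwood_row <- function(plot = "p1", posture = "fallen", base = 12,
                         top = 6, length = 100, class = 1, density = 0.5) {
  data.frame(plot = plot, posture = posture, base_diameter = base,
             top_diameter = top, length = length, decay_class = class,
             measured_density = density, stringsAsFactors = FALSE)
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("swidcarbon-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# quadrature oracle for the volume of a solid of revolution with linearly
# tapering radius r(x) from r0 at x = 0 to r1 at x = h
taper_volume_quadrature <- function(h, r0, r1) {
  integrate(function(x) pi * (r0 + (r1 - r0) * x / h)^2, 0, h,
            rel.tol = 1e-12)$value
}
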