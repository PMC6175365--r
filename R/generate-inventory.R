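#' Generate a synthetic field inventory matching target plot carbon
#'
#' Inverts the allometry module: for each plot of a synthetic
#' [generate_plot_carbon()] table it emits stem, liana, deadwood and litter
#' records such that [plot_carbon()] applied to them recovers the plot's
#' target total carbon within `tolerance`. Farmland plots receive litter
#' and deadwood records only (their live pools are zero by construction);
#' lianas appear only with DBH >= 2 cm.
#'
#' The inversion draws large-stem DBH from a truncated power law and adds
#' stems until the target live biomass is bracketed, then root-solves the
#' last stem's DBH; deadwood pieces are added the same way with the last
#' piece's length rescaled (volume is linear in length), and litter
#' subsample dry masses are set analytically. A plot whose target cannot be
#' met within a bounded number of records raises an error naming the plot.
#'
#' @param params a [synthetic_params()] object.
#' @param seed integer seed; same `(params, seed)` give identical datasets.
#' @param registry an [read_equation_registry()] object.
#' @param decay_table a [read_decay_density()] table.
#' @param tolerance relative closure tolerance per plot (default 0.05).
#' @return A list with elements `dataset` (a [field_dataset()]) and
#'   `targets` (the generating `plot_table`).
#' @export
generate_inventory <- function(params, seed = params$seed,
                               registry = read_equation_registry(),
                               decay_table = read_decay_density(),
                               tolerance = 0.05) {
  stopifnot(inherits(params, "synthetic_params"))
  targets <- generate_plot_carbon(params, seed = seed)
  with_seed(child_seed(seed, 2), {
    stems <- list(); lianas <- list(); deadwood <- list(); litter <- list()
    for (i in seq_len(nrow(targets))) {
      tg <- targets[i, ]
      live_kg <- tg$live_carbon * PLOT_AREA_HA / CARBON_FRACTION * 1000
      dead_kg <- tg$dead_carbon * PLOT_AREA_HA / CARBON_FRACTION * 1000
      eq_hab <- if (tg$habitat == "old_growth") "old_growth" else "secondary"

      if (tg$habitat != "farmland" && live_kg > 0) {
        li <- invert_lianas(tg$plot, live_kg, registry)
        lianas[[length(lianas) + 1]] <- li$records
        st <- invert_stems(tg$plot, live_kg - li$kg, eq_hab, registry)
        stems[[length(stems) + 1]] <- st
      }
      litter_frac <- if (tg$habitat == "farmland") 0.5 else 0.3
      deadwood[[length(deadwood) + 1]] <-
        invert_deadwood(tg$plot, dead_kg * (1 - litter_frac), decay_table)
      litter[[length(litter) + 1]] <-
        invert_litter(tg$plot, dead_kg * litter_frac)
    }
    plots <- targets[, c("plot", "square", "landscape", "habitat",
                         "fallow_age", "elevation")]
    ds <- field_dataset(plots,
                        stems = rbind_or_null(stems),
                        lianas = rbind_or_null(lianas),
                        deadwood = rbind_or_null(deadwood),
                        litter = rbind_or_null(litter))
    check_closure(ds, targets, registry, decay_table, tolerance)
    list(dataset = ds, targets = targets)
  })
}

rbind_or_null <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) NULL else do.call(rbind, lst)
}

# 0-2 lianas in V1/V2 contributing at most a quarter of the live pool;
# returns the plot-level kg they account for (subplot mean x area factor 5).
invert_lianas <- function(plot_id, live_kg, registry) {
  n <- sample(0:2, 1)
  if (n == 0) return(list(records = NULL, kg = 0))
  rec <- data.frame(plot = plot_id,
                    subplot = sample(c("V1", "V2"), n, replace = TRUE),
                    dbh = runif(n, 2, 6), stringsAsFactors = FALSE)
  kg <- AREA_FACTOR[["liana"]] * liana_plot_biomass(rec, registry)
  if (kg > 0.25 * live_kg) return(list(records = NULL, kg = 0))
  list(records = rec, kg = kg)
}

# truncated Pareto (alpha = 2) DBH draw on [dmin, dmax]
rdbh <- function(n, dmin, dmax) {
  u <- runif(n)
  1 / (1 / dmin - u * (1 / dmin - 1 / dmax))
}

invert_stems <- function(plot_id, target_kg, habitat, registry,
                         max_stems = 5000) {
  if (target_kg <= 0) return(NULL)
  dmax <- if (habitat == "old_growth") 200 else 80
  # draw in batches until the cumulative ensemble biomass brackets the target
  cum_prev <- 0
  dbh <- numeric(0); wsg <- numeric(0)
  repeat {
    if (length(dbh) >= max_stems)
      stop(sprintf("plot %s: live-biomass target not reached within %d stems",
                   plot_id, max_stems), call. = FALSE)
    m <- 32
    d <- rdbh(m, 5, dmax)
    w <- pmin(pmax(rnorm(m, 0.55, 0.1), 0.3), 0.9)
    b <- tree_biomass_ensemble(d, w, habitat, registry)
    cs <- cum_prev + cumsum(b)
    hit <- which(cs >= target_kg)
    if (length(hit) == 0) {
      dbh <- c(dbh, d); wsg <- c(wsg, w); cum_prev <- cs[m]
      next
    }
    j <- hit[1]
    dbh <- c(dbh, d[seq_len(j)]); wsg <- c(wsg, w[seq_len(j)])
    cum_before <- if (j == 1) cum_prev else cs[j - 1]
    remainder <- target_kg - cum_before
    k <- length(dbh)
    b5 <- tree_biomass_ensemble(5, wsg[k], habitat, registry)
    if (remainder >= b5) {
      # shrink the crossing stem to land exactly on the target
      dbh[k] <- uniroot(function(x)
        tree_biomass_ensemble(x, wsg[k], habitat, registry) - remainder,
        lower = 5, upper = dbh[k], tol = 1e-9)$root
    } else if (k > 1) {
      # remainder smaller than the smallest admissible stem: drop the
      # crossing stem and grow the previous one to absorb the remainder
      need <- remainder +
        tree_biomass_ensemble(dbh[k - 1], wsg[k - 1], habitat, registry)
      dbh <- dbh[-k]; wsg <- wsg[-k]
      dbh[k - 1] <- uniroot(function(x)
        tree_biomass_ensemble(x, wsg[k - 1], habitat, registry) - need,
        lower = dbh[k - 1], upper = 300, tol = 1e-9)$root
    } else {
      # tiny plot: a single 5 cm stem already overshoots; accept the floor
      # (the closure check catches it if out of tolerance)
      dbh[k] <- 5
    }
    break
  }
  core_vol <- 8
  data.frame(plot = plot_id, size_class = "large", dbh = dbh,
             core_dry_mass = wsg * core_vol, core_green_volume = core_vol,
             stringsAsFactors = FALSE)
}

invert_deadwood <- function(plot_id, target_kg, decay_table,
                            max_pieces = 5000) {
  if (target_kg <= 0) return(NULL)
  piece_kg <- function(base, top, len, dens) {
    vol <- ifelse(is.na(top), cone_volume(len, base / 2),
                  pi * len / 3 * ((base / 2)^2 + (top / 2)^2 +
                                    (base / 2) * (top / 2)))
    vol * dens / 1000
  }
  cum_prev <- 0
  rec <- NULL
  repeat {
    if (!is.null(rec) && nrow(rec) >= max_pieces)
      stop(sprintf("plot %s: deadwood target not reached within %d pieces",
                   plot_id, max_pieces), call. = FALSE)
    m <- 32
    batch <- data.frame(
      plot = plot_id,
      posture = sample(c("standing", "fallen"), m, replace = TRUE,
                       prob = c(0.15, 0.85)),
      base_diameter = runif(m, 8, 45),
      top_diameter = NA_real_,
      length = runif(m, 100, 500),
      decay_class = sample(1:5, m, replace = TRUE),
      measured_density = NA_real_, stringsAsFactors = FALSE)
    has_top <- runif(m) < 0.7
    batch$top_diameter[has_top] <-
      batch$base_diameter[has_top] * runif(sum(has_top), 0.3, 0.8)
    cls1 <- batch$decay_class == 1
    batch$measured_density[cls1] <-
      decay_table[["1"]] * runif(sum(cls1), 0.9, 1.1)
    dens <- ifelse(cls1, batch$measured_density,
                   unname(decay_table[as.character(batch$decay_class)]))
    b <- piece_kg(batch$base_diameter, batch$top_diameter, batch$length, dens)
    cs <- cum_prev + cumsum(b)
    hit <- which(cs >= target_kg)
    if (length(hit) == 0) {
      rec <- rbind(rec, batch); cum_prev <- cs[m]
      next
    }
    j <- hit[1]
    batch <- batch[seq_len(j), , drop = FALSE]
    cum_before <- if (j == 1) cum_prev else cs[j - 1]
    # biomass is linear in length for both volume formulas
    batch$length[j] <- batch$length[j] * (target_kg - cum_before) / b[j]
    rec <- rbind(rec, batch)
    break
  }
  rec
}

invert_litter <- function(plot_id, target_kg) {
  # plot pool = mean over 3 quadrats x area factor 100
  per_quadrat_g <- target_kg / AREA_FACTOR[["litter"]] * 1000
  data.frame(plot = plot_id, subplot = c("L1", "L2", "L3"),
             compressed_volume = 8, subsample_volume = 1,
             subsample_dry_mass = per_quadrat_g / 8 * 1,
             stringsAsFactors = FALSE)
}

check_closure <- function(ds, targets, registry, decay_table, tolerance) {
  got <- plot_carbon_table(ds, registry, decay_table)
  got <- got[match(targets$plot, got$plot), ]
  rel <- abs(got$total_carbon - targets$total_carbon) / targets$total_carbon
  bad <- which(rel > tolerance)
  if (length(bad) > 0)
    stop(sprintf("inventory inversion failed closure for plot(s): %s (max rel. error %.3f)",
                 paste(targets$plot[bad], collapse = ", "), max(rel[bad])),
         call. = FALSE)
  invisible(TRUE)
}
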