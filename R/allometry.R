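#' Wood specific gravity from an increment core
#'
#' Oven-dry mass divided by green (water-saturated) volume.
#'
#' @param dry_mass oven-dry core mass, g; must be > 0.
#' @param green_volume green core volume, cm3; must be > 0.
#' @return Wood specific gravity, g/cm3.
#' @export
#' @examples
#' wood_specific_gravity(0.75, 1.5)  # 0.5
wood_specific_gravity <- function(dry_mass, green_volume) {
  if (any(!(dry_mass > 0)) || any(!(green_volume > 0)))
    stop("dry mass and green volume must both be > 0", call. = FALSE)
  dry_mass / green_volume
}

#' Assign wood specific gravity to small stems
#'
#' Cores cannot be extracted from 1-5 cm stems, so each small stem receives
#' the arithmetic mean wood specific gravity of the large (>= 5 cm) stems in
#' its own plot. When a plot holds no large stems the configured `fallback`
#' is used (with a warning); without a fallback this is an error naming the
#' plot.
#'
#' @param stems stem table for one or more plots (schema of
#'   [field_dataset()]), with a `wsg` column or core measurements from which
#'   it is derived.
#' @param fallback optional g/cm3 value used for plots lacking large stems.
#' @return The stem table with a filled `wsg` column.
#' @export
assign_small_stem_wsg <- function(stems, fallback = NULL) {
  if (is.null(stems$wsg))
    stems$wsg <- ifelse(
      !is.na(stems$core_dry_mass) & !is.na(stems$core_green_volume),
      stems$core_dry_mass / stems$core_green_volume, NA_real_)
  for (pid in unique(stems$plot)) {
    in_plot <- stems$plot == pid
    large <- in_plot & stems$size_class == "large" & !is.na(stems$wsg)
    small <- in_plot & stems$size_class == "small"
    if (!any(small)) next
    if (any(large)) {
      stems$wsg[small & is.na(stems$wsg)] <- mean(stems$wsg[large])
    } else if (!is.null(fallback)) {
      warning(sprintf("plot %s has no large stems with cores; using fallback wsg %.3f",
                      pid, fallback), call. = FALSE)
      stems$wsg[small & is.na(stems$wsg)] <- fallback
    } else {
      stop(sprintf("cannot estimate small-stem wood specific gravity in plot %s: no large stems and no fallback",
                   pid), call. = FALSE)
    }
  }
  stems
}

#' Ensemble tree biomass from DBH and wood specific gravity
#'
#' Evaluates every registry equation applicable to `habitat` at
#' `(dbh, wsg)` and returns their arithmetic mean. The same equations are
#' applied to small (1-5 cm) stems as to large ones.
#'
#' @param dbh DBH, cm (>= 1); vectorized.
#' @param wsg wood specific gravity, g/cm3; recycled against `dbh`.
#' @param habitat `"old_growth"` or `"secondary"`.
#' @param registry an [read_equation_registry()] object.
#' @return Dry biomass, kg.
#' @export
tree_biomass_ensemble <- function(dbh, wsg, habitat, registry) {
  if (any(dbh < 1)) stop("dbh must be >= 1 cm", call. = FALSE)
  eqs <- registry[registry$habitat == habitat, , drop = FALSE]
  if (nrow(eqs) == 0)
    stop("equation registry holds no equations for habitat ", habitat,
         call. = FALSE)
  vals <- vapply(seq_len(nrow(eqs)),
                 function(i) evaluate_equation(eqs[i, ], dbh, wsg),
                 numeric(length(dbh)))
  if (length(dbh) == 1) mean(vals) else rowMeans(matrix(vals, nrow = length(dbh)))
}

#' Plot-level liana biomass
#'
#' Each liana's biomass is the mean over the registered liana equations;
#' each 1 x 30 m subplot's biomass is the sum over its lianas; the plot
#' value is the mean of the two subplot sums. A subplot with no records
#' contributes zero only because the protocol surveys both subplots in
#' every plot (`surveyed` documents that convention).
#'
#' @param records liana records for one plot (columns `subplot`, `dbh`).
#' @param registry an [read_equation_registry()] object.
#' @param surveyed character vector of surveyed subplot ids.
#' @return Biomass, kg per plot (on the 2 x 30 m2 sampled area; area
#'   scaling happens in [plot_carbon()]).
#' @export
liana_plot_biomass <- function(records, registry, surveyed = c("V1", "V2")) {
  if (nrow(records) > 0 && any(!records$subplot %in% c("V1", "V2")))
    stop("liana subplot ids must be V1 or V2", call. = FALSE)
  eqs <- registry[registry$habitat == "liana", , drop = FALSE]
  if (nrow(eqs) == 0)
    stop("equation registry holds no liana equations", call. = FALSE)
  per_sub <- vapply(surveyed, function(sp) {
    d <- records$dbh[records$subplot == sp]
    if (length(d) == 0) return(0)
    sum(vapply(d, function(dd)
      mean(vapply(seq_len(nrow(eqs)),
                  function(i) evaluate_equation(eqs[i, ], dd, NA_real_),
                  numeric(1))), numeric(1)))
  }, numeric(1))
  mean(per_sub)
}

#' Volume of a frustum (truncated cone)
#'
#' `V = pi * length / 3 * (R^2 + r^2 + R*r)` with base and top *radii*
#' `R`, `r`. Field deadwood records store diameters; [deadwood_biomass()]
#' halves them before calling this.
#'
#' @param length length/height, cm (> 0).
#' @param base_radius,top_radius radii, cm (> 0).
#' @return Volume, cm3.
#' @export
#' @examples
#' frustum_volume(100, 6, 3)  # 2100 * pi
frustum_volume <- function(length, base_radius, top_radius) {
  if (any(!(length > 0)) || any(!(base_radius > 0)) || any(!(top_radius > 0)))
    stop("frustum dimensions must all be > 0", call. = FALSE)
  pi * length / 3 * (base_radius^2 + top_radius^2 + base_radius * top_radius)
}

#' Volume of a cone
#'
#' `V = pi * R^2 * length / 3`; used for standing deadwood whose top
#' diameter could not be measured.
#'
#' @param length height, cm (> 0).
#' @param base_radius base radius, cm (> 0).
#' @return Volume, cm3.
#' @export
cone_volume <- function(length, base_radius) {
  if (any(!(length > 0)) || any(!(base_radius > 0)))
    stop("cone dimensions must be > 0", call. = FALSE)
  pi * base_radius^2 * length / 3
}

#' Biomass of one deadwood piece
#'
#' Volume via the frustum formula when a top diameter is recorded, else the
#' cone formula; recorded *diameters* are halved to radii first. Density is
#' the piece's measured core density for decay class 1, otherwise the
#' decay-class table value.
#'
#' @param record one deadwood record (a one-row data frame or list).
#' @param table a [read_decay_density()] table.
#' @param use_table_fallback when `TRUE` (default) a class-1 piece without a
#'   measured density falls back to the table; when `FALSE` that is an
#'   error.
#' @return Dry biomass, kg.
#' @export
deadwood_biomass <- function(record, table, use_table_fallback = TRUE) {
  top <- record$top_diameter
  vol <- if (!is.null(top) && length(top) == 1 && !is.na(top))
    frustum_volume(record$length, record$base_diameter / 2, top / 2)
  else cone_volume(record$length, record$base_diameter / 2)
  dens <- record$measured_density
  if (is.null(dens) || is.na(dens)) {
    if (record$decay_class == 1 && !use_table_fallback)
      stop("class-1 deadwood record lacks a measured density and table fallback is disabled",
           call. = FALSE)
    dens <- unname(table[[as.character(record$decay_class)]])
  }
  vol * dens / 1000
}

#' Plot-level leaf-litter biomass
#'
#' Each 1 m2 quadrat's dry biomass scales the compressed litter volume by
#' the dry-mass concentration of its 1 L subsample; the plot value is the
#' mean over surveyed quadrats.
#'
#' @param records litter records for one plot (1-3 rows).
#' @return Dry biomass, kg per quadrat-mean (area scaling happens in
#'   [plot_carbon()]).
#' @export
#' @examples
#' litter_plot_biomass(data.frame(plot = "p", subplot = "L1",
#'   compressed_volume = 8, subsample_volume = 1, subsample_dry_mass = 50))
litter_plot_biomass <- function(records) {
  if (nrow(records) < 1 || nrow(records) > 3)
    stop("a plot has 1-3 litter quadrat records", call. = FALSE)
  if (any(records$subsample_volume == 0))
    stop("litter subsample volume must be > 0", call. = FALSE)
  g <- records$compressed_volume *
    (records$subsample_dry_mass / records$subsample_volume)
  mean(g) / 1000
}

#' Carbon pools of one plot
#'
#' Converts every record type of a plot into biomass, scales each pool from
#' its sampled area to the full 300 m2 plot (large stems and deadwood x1,
#' small stems x25, lianas x5, litter x100), sums to total biomass, applies
#' the 0.474 carbon fraction, and reports both Mg per plot (0.03 ha) and
#' Mg per hectare.
#'
#' @param ds a [field_dataset()].
#' @param plot_id plot id present in `ds$plots`.
#' @param registry an [read_equation_registry()] object.
#' @param table a [read_decay_density()] table.
#' @param wsg_fallback optional small-stem wood-specific-gravity fallback
#'   passed to [assign_small_stem_wsg()].
#' @return A one-row data frame of class `carbon_pools`: per-plot biomass
#'   pools (`live_tree`, `liana`, `deadwood`, `litter`, Mg), `biomass_total`
#'   (Mg/plot), `carbon_plot`/`live_carbon_plot`/`dead_carbon_plot`
#'   (Mg C/plot) and the same on the per-ha scale.
#' @export
plot_carbon <- function(ds, plot_id, registry, table, wsg_fallback = NULL) {
  stopifnot(inherits(ds, "field_dataset"))
  meta <- ds$plots[ds$plots$plot == plot_id, , drop = FALSE]
  if (nrow(meta) != 1)
    stop("plot id not found in dataset: ", plot_id, call. = FALSE)
  habitat <- meta$habitat
  eq_habitat <- if (habitat == "old_growth") "old_growth" else "secondary"

  wrap <- function(expr) tryCatch(expr, error = function(e)
    stop(sprintf("plot %s: %s", plot_id, conditionMessage(e)), call. = FALSE))

  stems <- ds$stems[ds$stems$plot == plot_id, , drop = FALSE]
  live_tree_kg <- 0
  if (nrow(stems) > 0) {
    stems <- wrap(assign_small_stem_wsg(stems, fallback = wsg_fallback))
    large <- stems$size_class == "large"
    if (any(large))
      live_tree_kg <- live_tree_kg + AREA_FACTOR[["large_stem"]] *
        sum(wrap(tree_biomass_ensemble(stems$dbh[large], stems$wsg[large],
                                       eq_habitat, registry)))
    if (any(!large))
      live_tree_kg <- live_tree_kg + AREA_FACTOR[["small_stem"]] *
        sum(wrap(tree_biomass_ensemble(stems$dbh[!large], stems$wsg[!large],
                                       eq_habitat, registry)))
  }

  lianas <- ds$lianas[ds$lianas$plot == plot_id, , drop = FALSE]
  liana_kg <- AREA_FACTOR[["liana"]] * wrap(liana_plot_biomass(lianas, registry))

  dw <- ds$deadwood[ds$deadwood$plot == plot_id, , drop = FALSE]
  deadwood_kg <- if (nrow(dw) == 0) 0 else AREA_FACTOR[["deadwood"]] *
    sum(vapply(seq_len(nrow(dw)),
               function(i) wrap(deadwood_biomass(dw[i, ], table)),
               numeric(1)))

  lit <- ds$litter[ds$litter$plot == plot_id, , drop = FALSE]
  litter_kg <- if (nrow(lit) == 0) 0 else AREA_FACTOR[["litter"]] *
    wrap(litter_plot_biomass(lit))

  pools_mg <- c(live_tree = live_tree_kg, liana = liana_kg,
                deadwood = deadwood_kg, litter = litter_kg) / 1000
  biomass_total <- sum(pools_mg)
  live_bio <- pools_mg[["live_tree"]] + pools_mg[["liana"]]
  dead_bio <- pools_mg[["deadwood"]] + pools_mg[["litter"]]
  out <- data.frame(
    plot = plot_id, square = meta$square, landscape = meta$landscape,
    habitat = habitat, fallow_age = meta$fallow_age, elevation = meta$elevation,
    live_tree = pools_mg[["live_tree"]], liana = pools_mg[["liana"]],
    deadwood = pools_mg[["deadwood"]], litter = pools_mg[["litter"]],
    biomass_total = biomass_total,
    carbon_plot = biomass_total * CARBON_FRACTION,
    live_carbon_plot = live_bio * CARBON_FRACTION,
    dead_carbon_plot = dead_bio * CARBON_FRACTION,
    stringsAsFactors = FALSE)
  out$total_carbon <- out$carbon_plot / PLOT_AREA_HA
  out$live_carbon <- out$live_carbon_plot / PLOT_AREA_HA
  out$dead_carbon <- out$dead_carbon_plot / PLOT_AREA_HA
  class(out) <- c("carbon_pools", "data.frame")
  out
}

#' Carbon pools for every plot of a dataset
#'
#' Applies [plot_carbon()] to each plot and row-binds the results into a
#' table suitable for [write_plot_carbon_table()] and [fit_model()].
#'
#' @inheritParams plot_carbon
#' @return A data frame of class `plot_table` with one row per plot.
#' @export
plot_carbon_table <- function(ds, registry, table, wsg_fallback = NULL) {
  rows <- lapply(ds$plots$plot, function(pid)
    plot_carbon(ds, pid, registry, table, wsg_fallback = wsg_fallback))
  out <- do.call(rbind, rows)
  class(out) <- c("plot_table", "data.frame")
  out
}
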