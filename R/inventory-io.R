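#' Field-inventory dataset container and CSV I/O
#'
#' A `field_dataset` bundles five tables keyed by plot id: plot metadata
#' plus stem, liana, deadwood and leaf-litter records, in the fixed units of
#' the schema (DBH cm, core mass g, core volume cm3, deadwood dimensions cm,
#' litter volumes L, dry mass g, elevation m). All tables are plain
#' comma-separated UTF-8 text with one header row.
#'
#' Schemas (mandatory columns):
#' * `plots.csv`: plot, square, landscape, habitat, fallow_age, elevation
#' * `stems.csv`: plot, size_class (`large`/`small`), dbh, core_dry_mass,
#'   core_green_volume
#' * `lianas.csv`: plot, subplot (`V1`/`V2`), dbh
#' * `deadwood.csv`: plot, posture (`standing`/`fallen`), base_diameter,
#'   top_diameter (empty = cone-formula fallback), length, decay_class,
#'   measured_density (class 1 only)
#' * `litter.csv`: plot, subplot (`L1`-`L3`), compressed_volume,
#'   subsample_volume, subsample_dry_mass
#'
#' @param plots,stems,lianas,deadwood,litter data frames following the
#'   schemas above; record tables may be empty but must carry the columns.
#' @return An object of class `field_dataset`.
#' @export
field_dataset <- function(plots, stems = NULL, lianas = NULL,
                          deadwood = NULL, litter = NULL) {
  empty <- function(cols) {
    as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  }
  ds <- structure(list(
    plots = plots,
    stems = stems %||% empty(schema_cols("stems")),
    lianas = lianas %||% empty(schema_cols("lianas")),
    deadwood = deadwood %||% empty(schema_cols("deadwood")),
    litter = litter %||% empty(schema_cols("litter"))
  ), class = "field_dataset")
  for (tb in c("stems", "lianas", "deadwood", "litter")) {
    orphans <- setdiff(unique(ds[[tb]]$plot), ds$plots$plot)
    if (length(orphans) > 0)
      stop(sprintf("referential error: %s rows reference unknown plot id(s): %s",
                   tb, paste(orphans, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(ds$plots$plot))
    stop("referential error: duplicated plot ids in plot metadata",
         call. = FALSE)
  ds
}

schema_cols <- function(table) {
  switch(table,
    plots = c("plot", "square", "landscape", "habitat", "fallow_age",
              "elevation"),
    stems = c("plot", "size_class", "dbh", "core_dry_mass",
              "core_green_volume"),
    lianas = c("plot", "subplot", "dbh"),
    deadwood = c("plot", "posture", "base_diameter", "top_diameter",
                 "length", "decay_class", "measured_density"),
    litter = c("plot", "subplot", "compressed_volume", "subsample_volume",
               "subsample_dry_mass"),
    stop("unknown table: ", table))
}

#' Read a field-inventory dataset from CSV files
#'
#' Reads the five schema files, checks mandatory columns, builds a
#' [field_dataset()] and stops if validation finds any invariant breach.
#' Unknown columns are kept but flagged with a warning; row order is
#' preserved.
#'
#' @param paths named character vector or list with entries `plots`,
#'   `stems`, `lianas`, `deadwood`, `litter`; alternatively a directory
#'   containing files with those names plus `.csv`.
#' @return A validated `field_dataset`.
#' @export
read_field_dataset <- function(paths) {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    paths <- file.path(paths, paste0(c("plots", "stems", "lianas",
                                       "deadwood", "litter"), ".csv"))
    names(paths) <- c("plots", "stems", "lianas", "deadwood", "litter")
  }
  need <- c("plots", "stems", "lianas", "deadwood", "litter")
  if (!all(need %in% names(paths)))
    stop("`paths` must name files for: ", paste(need, collapse = ", "),
         call. = FALSE)
  tabs <- lapply(need, function(tb) {
    path <- paths[[tb]]
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(schema_cols(tb), names(df))
    if (length(missing) > 0)
      stop(sprintf("schema error in %s: missing mandatory column(s) %s",
                   path, paste(missing, collapse = ", ")), call. = FALSE)
    extra <- setdiff(names(df), schema_cols(tb))
    if (length(extra) > 0)
      warning(sprintf("%s: ignoring unknown column(s) %s", basename(path),
                      paste(extra, collapse = ", ")), call. = FALSE)
    df
  })
  names(tabs) <- need
  ds <- field_dataset(tabs$plots, tabs$stems, tabs$lianas, tabs$deadwood,
                      tabs$litter)
  rep <- validate_field_dataset(ds)
  if (nrow(rep) > 0)
    stop("validation failure:\n", paste(format_breach(rep), collapse = "\n"),
         call. = FALSE)
  ds
}

#' Write a field-inventory dataset to a directory of CSV files
#'
#' Inverse of [read_field_dataset()]; writes `plots.csv`, `stems.csv`,
#' `lianas.csv`, `deadwood.csv`, `litter.csv`.
#'
#' @param ds a `field_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_field_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "field_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(c("plots", "stems", "lianas", "deadwood", "litter"),
                  function(tb) {
    path <- file.path(dir, paste0(tb, ".csv"))
    write.csv(ds[[tb]], path, row.names = FALSE, quote = FALSE, na = "")
    path
  }, character(1))
  invisible(paths)
}

#' Validate a field-inventory dataset
#'
#' Pure check of every schema invariant: stem DBH >= 1 cm (large stems
#' >= 5 cm), wood specific gravity inside (0.05, 1.5) when present, liana
#' DBH >= 2 cm and subplot in V1/V2, deadwood base diameter >= 5 cm with
#' positive length, decay class 1-5 and measured density only for class 1,
#' litter quantities >= 0 with subsample <= compressed volume, habitat
#' levels, fallow age present iff secondary, positive elevation, and absence
#' of stems/lianas in farmland plots. The dataset is not modified.
#'
#' @param ds a `field_dataset`.
#' @return A `validation_report` data frame (`table`, `row`, `field`,
#'   `message`); zero rows means a clean dataset.
#' @export
validate_field_dataset <- function(ds) {
  stopifnot(inherits(ds, "field_dataset"))
  out <- list()
  add <- function(table, rows, field, message) {
    if (length(rows) > 0)
      out[[length(out) + 1]] <<- data.frame(
        table = table, row = rows, field = field, message = message,
        stringsAsFactors = FALSE)
  }

  p <- ds$plots
  add("plots", which(!p$habitat %in% c("farmland", "secondary", "old_growth")),
      "habitat", "habitat must be farmland/secondary/old_growth")
  fa <- suppressWarnings(as.numeric(p$fallow_age))
  add("plots", which(p$habitat == "secondary" & is.na(fa)),
      "fallow_age", "secondary plots require a fallow age")
  add("plots", which(p$habitat != "secondary" & !is.na(fa)),
      "fallow_age", "fallow age only allowed for secondary plots")
  add("plots", which(!(p$elevation > 0)), "elevation",
      "elevation must be > 0")

  s <- ds$stems
  if (nrow(s) > 0) {
    add("stems", which(!(s$dbh >= 1)), "dbh", "stem dbh must be >= 1 cm")
    add("stems", which(s$size_class == "large" & s$dbh < 5), "dbh",
        "large stems must have dbh >= 5 cm")
    add("stems", which(!s$size_class %in% c("large", "small")), "size_class",
        "size_class must be large/small")
    wsg <- with(s, ifelse(!is.na(core_dry_mass) & !is.na(core_green_volume) &
                            core_green_volume > 0,
                          core_dry_mass / core_green_volume, NA_real_))
    add("stems", which(!is.na(wsg) & (wsg <= 0.05 | wsg >= 1.5)),
        "core_dry_mass", "implied wood specific gravity outside (0.05, 1.5)")
    farm <- ds$plots$plot[ds$plots$habitat == "farmland"]
    add("stems", which(s$plot %in% farm), "plot",
        "stems recorded in a farmland plot")
  }

  l <- ds$lianas
  if (nrow(l) > 0) {
    add("lianas", which(!(l$dbh >= 2)), "dbh",
        "liana dbh must be >= 2 cm (survey protocol minimum)")
    add("lianas", which(!l$subplot %in% c("V1", "V2")), "subplot",
        "liana subplot must be V1 or V2")
    farm <- ds$plots$plot[ds$plots$habitat == "farmland"]
    add("lianas", which(l$plot %in% farm), "plot",
        "lianas recorded in a farmland plot")
  }

  d <- ds$deadwood
  if (nrow(d) > 0) {
    add("deadwood", which(!(d$base_diameter >= 5)), "base_diameter",
        "deadwood base diameter must be >= 5 cm")
    add("deadwood", which(!(d$length > 0)), "length",
        "deadwood length must be > 0")
    add("deadwood", which(!d$decay_class %in% 1:5), "decay_class",
        "decay class must be an integer 1-5")
    add("deadwood", which(!is.na(d$measured_density) & d$decay_class != 1),
        "measured_density", "measured density only allowed for decay class 1")
    add("deadwood", which(!d$posture %in% c("standing", "fallen")), "posture",
        "posture must be standing/fallen")
    add("deadwood",
        which(!is.na(d$top_diameter) & d$top_diameter > d$base_diameter),
        "top_diameter", "top diameter exceeds base diameter")
  }

  t <- ds$litter
  if (nrow(t) > 0) {
    add("litter", which(!t$subplot %in% c("L1", "L2", "L3")), "subplot",
        "litter subplot must be L1/L2/L3")
    for (field in c("compressed_volume", "subsample_volume",
                    "subsample_dry_mass"))
      add("litter", which(!(t[[field]] >= 0)), field,
          paste(field, "must be >= 0"))
    add("litter", which(!is.na(t$subsample_volume) &
                          !is.na(t$compressed_volume) &
                          t$compressed_volume > 0 &
                          t$subsample_volume > t$compressed_volume),
        "subsample_volume", "subsample volume exceeds compressed volume")
  }

  rep <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(table = character(0), row = integer(0), field = character(0),
               message = character(0), stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

format_breach <- function(rep) {
  sprintf("  %s row %d [%s]: %s", rep$table, rep$row, rep$field, rep$message)
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) cat("validation report: clean (0 breaches)\n")
  else {
    cat(sprintf("validation report: %d breach(es)\n", nrow(x)))
    cat(format_breach(x), sep = "\n")
  }
  invisible(x)
}

#' Write / read a plot-carbon table
#'
#' `write_plot_carbon_table()` writes the per-plot carbon-pool table as CSV
#' with full precision (re-reading reproduces the numbers exactly);
#' `read_plot_carbon_table()` reads one back.
#'
#' @param rows non-empty data frame of plot carbon pools (as produced by
#'   [plot_carbon_table()] or [generate_plot_carbon()]).
#' @param path output CSV path.
#' @return `write_plot_carbon_table()` returns `path` invisibly;
#'   `read_plot_carbon_table()` returns a data frame.
#' @export
write_plot_carbon_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0)
    stop("refusing to write an empty plot-carbon table", call. = FALSE)
  df <- as.data.frame(rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  tryCatch(write.csv(df, path, row.names = FALSE, quote = FALSE, na = ""),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname write_plot_carbon_table
#' @export
read_plot_carbon_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("plot_table", "data.frame")
  df
}

#' @export
print.field_dataset <- function(x, ...) {
  cat(sprintf(
    "field dataset: %d plots | %d stems | %d lianas | %d deadwood | %d litter\n",
    nrow(x$plots), nrow(x$stems), nrow(x$lianas), nrow(x$deadwood),
    nrow(x$litter)))
  invisible(x)
}
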