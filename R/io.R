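# Canonical numeric formatting for all CSV writers: %.9g round-trips
# through parsing (9 significant digits < double precision), so
# write(read(f)) is byte-identical to f for files this package wrote.
.fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.9g", as.numeric(v)))

.write_formatted_csv <- function(df, path, num_cols) {
  out <- df
  for (cn in intersect(num_cols, names(out))) out[[cn]] <- .fmt_num(out[[cn]])
  for (cn in names(out)) if (is.logical(out[[cn]])) out[[cn]] <- ifelse(out[[cn]], "TRUE", "FALSE")
  data.table::fwrite(out, path, quote = FALSE, na = "", sep = ",",
                     eol = "\n", scipen = 0)
  invisible(path)
}

.cohort_base_cols <- c("pair_id", "zygosity", "sex1", "sex2", "age",
                       "y1", "y2", "x", "y")

#' Read a twin cohort CSV
#'
#' Dialect: one row per twin pair with columns `pair_id`, `zygosity`
#' (`MZ`/`DZss`/`DZos`), `sex1`, `sex2` (`M`/`F`), `age`, `y1`, `y2`
#' (empty cell = missing phenotype), planar `x`, `y`, optional `region_id`
#' and optional historical snapshot columns `x_<label>`, `y_<label>`.
#' Structural problems (missing columns, zygosity outside the vocabulary)
#' are errors; rows violating pair invariants (both phenotypes missing, MZ
#' with discordant sexes, non-finite coordinates) are dropped with a
#' warning that lists their line numbers.
#'
#' @param path CSV file path.
#' @param crs coordinate reference of `x`, `y`: `"planar"` (default) or
#'   `"lonlat"` (must then be projected with [project_coordinates()] before
#'   any weighting).
#' @return a `twin_cohort` data frame.
#' @export
read_cohort_csv <- function(path, crs = "planar") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  crs <- match.arg(crs, c("planar", "lonlat"))
  dt <- data.table::fread(path, sep = ",", header = TRUE, na.strings = "",
                          colClasses = list(character = c("pair_id", "zygosity",
                                                          "sex1", "sex2")),
                          data.table = FALSE, showProgress = FALSE)
  .assert_cols(dt, .cohort_base_cols, sprintf("cohort file %s", path))
  dt$zygosity <- .normalize_zygosity(dt$zygosity)   # errors on bad vocabulary
  for (cn in c("age", "y1", "y2", "x", "y")) dt[[cn]] <- as.numeric(dt[[cn]])
  line_no <- seq_len(nrow(dt)) + 1L  # header is line 1
  bad_y <- is.na(dt$y1) & is.na(dt$y2)
  bad_sex <- dt$zygosity == "MZ" & dt$sex1 != dt$sex2
  bad_xy <- !is.finite(dt$x) | !is.finite(dt$y)
  bad <- bad_y | bad_sex | bad_xy
  if (any(bad)) {
    why <- ifelse(bad_y, "both phenotypes missing",
           ifelse(bad_sex, "MZ pair with discordant sexes", "non-finite coordinates"))
    warnf("dropping %d malformed row(s):\n  %s", sum(bad),
          paste(sprintf("line %d: %s", line_no[bad], why[bad])[seq_len(min(10L, sum(bad)))],
                collapse = "\n  "))
    dt <- dt[!bad, , drop = FALSE]
    rownames(dt) <- NULL
  }
  .sex_code(dt$sex1); .sex_code(dt$sex2)  # vocabulary check
  attr(dt, "crs") <- crs
  class(dt) <- c("twin_cohort", "data.frame")
  dt
}

#' Write a twin cohort CSV
#'
#' Writes the canonical cohort dialect (see [read_cohort_csv()]); numeric
#' cells use a fixed 9-significant-digit format so a read/write round trip
#' is byte-identical.
#'
#' @param pairs twin cohort data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cohort_csv <- function(pairs, path) {
  .assert_cols(pairs, .cohort_base_cols, "twin cohort")
  extra <- setdiff(names(pairs), .cohort_base_cols)
  out <- as.data.frame(pairs)[, c(.cohort_base_cols, extra), drop = FALSE]
  num_cols <- c("age", "y1", "y2", "x", "y",
                grep("^[xy]_", extra, value = TRUE))
  .write_formatted_csv(out, path, num_cols)
}

#' Read / write a target-location CSV
#'
#' Columns `target_id`, `x`, `y` and optional `source`.
#'
#' @param path CSV file path.
#' @return data frame of target locations.
#' @export
read_targets_csv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, na.strings = "",
                          data.table = FALSE, showProgress = FALSE)
  .assert_cols(dt, c("target_id", "x", "y"), sprintf("targets file %s", path))
  dt$target_id <- as.character(dt$target_id)
  dt$x <- as.numeric(dt$x); dt$y <- as.numeric(dt$y)
  if (any(!is.finite(dt$x)) || any(!is.finite(dt$y)))
    stopf("non-finite target coordinates in %s", path)
  if (!"source" %in% names(dt)) dt$source <- "user"
  dt
}

#' @rdname read_targets_csv
#' @param targets target data frame.
#' @export
write_targets_csv <- function(targets, path) {
  .assert_cols(targets, c("target_id", "x", "y"), "targets")
  if (!"source" %in% names(targets)) targets$source <- "user"
  .write_formatted_csv(targets[, c("target_id", "x", "y", "source")], path,
                       c("x", "y"))
}

.space_num_cols <- c("x", "y", "a2_raw", "c2_or_d2_raw", "e2_raw",
                     "a2_std", "c2_or_d2_std", "e2_std", "total_variance",
                     "a2_lo", "a2_hi", "c2_or_d2_lo", "c2_or_d2_hi",
                     "e2_lo", "e2_hi", "ess_mz", "ess_dz",
                     "weighted_mean_trait")

#' Write / read a spatial-analysis result table
#'
#' One row per target location with raw and proportional components, CI
#' bounds, effective sample sizes, convergence flag and weighted mean
#' trait. The writer is deterministic (fixed numeric format), so repeated
#' runs with the same seed produce byte-identical files.
#'
#' @param space_result a [run_space()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_space_csv <- function(space_result, path) {
  .write_formatted_csv(as.data.frame(space_result), path, .space_num_cols)
}

#' @rdname write_space_csv
#' @export
read_space_csv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, na.strings = "",
                          data.table = FALSE, showProgress = FALSE)
  dt$target_id <- as.character(dt$target_id)
  if ("converged" %in% names(dt)) dt$converged <- as.logical(dt$converged)
  class(dt) <- c("space_result", "data.frame")
  dt
}

#' Write a spatial-analysis result as a GeoJSON point collection
#'
#' @param space_result a [run_space()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_space_geojson <- function(space_result, path) {
  df <- as.data.frame(space_result)
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, setdiff(names(df), c("x", "y")), drop = FALSE])
    props <- lapply(props, function(v) if (is.numeric(v)) round(v, 9) else v)
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(round(df$x[i], 9), round(df$y[i], 9))),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = FALSE)
  invisible(path)
}

#' Project cohort coordinates to a planar system
#'
#' Distance weighting requires planar (Euclidean) coordinates. Supported
#' transforms: `"planar" -> "planar"` (identity) and `"lonlat" ->
#' "local_planar"`, an equirectangular projection in metres about a
#' reference point (default: the cohort centroid) on a sphere of radius
#' 6371008.8 m — accurate to well under 1% over spans of 100 km, which is
#' ample for inverse-distance weights. Arbitrary EPSG transforms are out
#' of scope (no PROJ library is assumed).
#'
#' @param records twin cohort (or any data frame with `x`, `y`; `x` =
#'   longitude, `y` = latitude for `"lonlat"` input).
#' @param source_crs `"planar"` or `"lonlat"`.
#' @param target_crs `"planar"` or `"local_planar"`.
#' @param origin optional `c(lon0, lat0)` reference for the projection.
#' @return the records with planar `x`, `y` (metres for lon/lat input) and
#'   attribute `crs = "planar"`.
#' @export
project_coordinates <- function(records, source_crs = "planar",
                                target_crs = "planar", origin = NULL) {
  source_crs <- match.arg(source_crs, c("planar", "lonlat"))
  target_crs <- match.arg(target_crs, c("planar", "local_planar"))
  .assert_cols(records, c("x", "y"), "records")
  if (source_crs == "planar") {
    attr(records, "crs") <- "planar"
    return(records)
  }
  lon <- as.numeric(records$x); lat <- as.numeric(records$y)
  if (any(abs(lat) > 90) || any(abs(lon) > 360))
    stopf("lon/lat input out of range")
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  R <- 6371008.8
  rad <- pi / 180
  records$x <- R * cos(origin[2] * rad) * (lon - origin[1]) * rad
  records$y <- R * (lat - origin[2]) * rad
  attr(records, "crs") <- "planar"
  attr(records, "projection_origin") <- origin
  records
}

# --- run configuration ----------------------------------------------------

.config_schema <- list(
  cohort = "character", targets = "character", output = "character",
  results = "character",
  field = "character", model = "character", sex_limitation = "character",
  ci_method = "character", component = "character", snapshots = "character",
  covariates = "character",
  p = "numeric", d_floor = "numeric", q = "numeric",
  n_pairs = "integer", k_targets = "integer", seed = "integer",
  n_bins = "integer", log_level = "character")

.config_defaults <- function() {
  list(p = 0.5, d_floor = 1e-6, q = 0.04, n_bins = 256L,
       model = "ACE", sex_limitation = "equated", ci_method = "information",
       covariates = "sex", k_targets = 100L, seed = 1L, log_level = "info")
}

#' Read a plain-text run configuration
#'
#' One `key = value` (or `key: value`) entry per line; `#` starts a
#' comment. Unknown keys are rejected with an explicit message; values are
#' coerced and validated against the schema. Unset keys take the package
#' defaults (`p = 0.5`, `d_floor = 1e-6`, `q = 0.04`, `model = ACE`,
#' `ci_method = information`, `k_targets = 100`, `seed = 1`).
#'
#' @param path config file path (NULL for pure defaults).
#' @param overrides named list applied on top of the file.
#' @return named list of validated settings.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("no such config file: %s", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) stopf("cannot parse config line: '%s'", ln)
      cfg[[m[2]]] <- trimws(m[3])
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stopf("unknown config key(s): %s (valid: %s)", paste(unknown, collapse = ", "),
          paste(names(.config_schema), collapse = ", "))
  for (k in names(cfg)) {
    ty <- .config_schema[[k]]
    v <- cfg[[k]]
    cfg[[k]] <- switch(ty,
      numeric = { x <- suppressWarnings(as.numeric(v))
                  if (is.na(x)) stopf("config key '%s' must be numeric, got '%s'", k, v); x },
      integer = { x <- suppressWarnings(as.integer(v))
                  if (is.na(x)) stopf("config key '%s' must be an integer, got '%s'", k, v); x },
      as.character(v))
  }
  if (!cfg$model %in% c("ACE", "ADE", "AE", "CE", "E"))
    stopf("config key 'model' must be one of ACE, ADE, AE, CE, E")
  if (!cfg$ci_method %in% c("information", "profile", "none"))
    stopf("config key 'ci_method' must be information, profile or none")
  if (cfg$p < 0) stopf("config key 'p' must be >= 0")
  if (cfg$d_floor <= 0) stopf("config key 'd_floor' must be > 0")
  cfg
}
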