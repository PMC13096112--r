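#' Default kinematic feature catalog
#'
#' The catalog names the 23 kinematic parameters extracted from a repetitive
#' hand opening-closing aperture trace, groups them into five families
#' (amplitude, speed, rhythm, variability, decrement), and records each
#' feature's clinical orientation: `higher_better` features improve when they
#' increase (amplitude, speed, frequency), `lower_better` features improve
#' when they decrease (durations, variability ratios, hesitations, decay
#' slopes). Orientation is the only catalog property the downstream scoring
#' machinery uses; the catalog is plain data and can be replaced wholesale
#' (e.g. to match an alternative feature battery) without code changes.
#'
#' @return A data frame with columns `name`, `family`, `orientation`,
#'   `definition_id` and exactly 23 rows.
#' @export
#' @examples
#' cat23 <- default_catalog()
#' table(cat23$family)
default_catalog <- function() {
  entry <- function(name, family, orientation) {
    data.frame(name = name, family = family, orientation = orientation,
               definition_id = name, stringsAsFactors = FALSE)
  }
  catalog <- rbind(
    entry("mean_amplitude",              "amplitude",   "higher_better"),
    entry("max_amplitude",               "amplitude",   "higher_better"),
    entry("cv_amplitude",                "amplitude",   "lower_better"),
    entry("amplitude_decay",             "decrement",   "lower_better"),
    entry("mean_speed",                  "speed",       "higher_better"),
    entry("mean_rms_velocity",           "speed",       "higher_better"),
    entry("mean_opening_speed",          "speed",       "higher_better"),
    entry("mean_closing_speed",          "speed",       "higher_better"),
    entry("max_speed",                   "speed",       "higher_better"),
    entry("opening_speed_decay",         "decrement",   "lower_better"),
    entry("closing_speed_decay",         "decrement",   "lower_better"),
    entry("velocity_decay",              "decrement",   "lower_better"),
    entry("frequency",                   "rhythm",      "higher_better"),
    entry("mean_cycle_duration",         "rhythm",      "lower_better"),
    entry("mean_opening_duration",       "rhythm",      "lower_better"),
    entry("mean_closing_duration",       "rhythm",      "lower_better"),
    entry("opening_closing_ratio",       "rhythm",      "lower_better"),
    entry("frequency_decay",             "decrement",   "lower_better"),
    entry("cv_cycle_duration",           "variability", "lower_better"),
    entry("cv_peak_speed",               "variability", "lower_better"),
    entry("jerkiness",                   "variability", "lower_better"),
    entry("n_hesitations",               "variability", "lower_better"),
    entry("amplitude_range_consistency", "variability", "lower_better")
  )
  validate_catalog(catalog)
}

#' Validate a feature catalog
#'
#' @param catalog A data frame with columns `name`, `family`, `orientation`.
#' @param n_required Required number of entries (default 23; pass `NA` to
#'   allow any size, e.g. for reduced overlapping feature sets).
#' @return The catalog, invisibly unchanged, or an error.
#' @export
validate_catalog <- function(catalog, n_required = 23L) {
  stopifnot(is.data.frame(catalog),
            all(c("name", "family", "orientation") %in% names(catalog)))
  if (!is.na(n_required) && nrow(catalog) != n_required) {
    stop_stimvision("catalog must have exactly ", n_required, " entries, got ",
                    nrow(catalog), class = "stimvision_catalog_error")
  }
  if (anyDuplicated(catalog$name)) {
    stop_stimvision("catalog feature names must be unique",
                    class = "stimvision_catalog_error")
  }
  families <- c("amplitude", "speed", "rhythm", "variability", "decrement")
  if (!all(catalog$family %in% families)) {
    stop_stimvision("unknown feature family: ",
                    paste(setdiff(catalog$family, families), collapse = ", "),
                    class = "stimvision_catalog_error")
  }
  if (!all(catalog$orientation %in% c("higher_better", "lower_better"))) {
    stop_stimvision("orientation must be higher_better or lower_better",
                    class = "stimvision_catalog_error")
  }
  catalog
}

#' Orientation signs for a catalog
#'
#' @param catalog A feature catalog.
#' @return Named numeric vector: +1 for `higher_better`, -1 for `lower_better`.
#' @export
orientation_signs <- function(catalog) {
  setNames(ifelse(catalog$orientation == "higher_better", 1, -1), catalog$name)
}

#' Read / write a feature catalog as JSON
#'
#' @param path File path.
#' @param catalog Catalog to serialize.
#' @param n_required See [validate_catalog()].
#' @return `read_catalog` returns the validated catalog data frame.
#' @export
read_catalog <- function(path, n_required = 23L) {
  obj <- jsonlite::fromJSON(path)
  validate_catalog(as.data.frame(obj, stringsAsFactors = FALSE), n_required)
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(validate_catalog(catalog, NA), path,
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
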