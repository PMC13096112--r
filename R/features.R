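#' Compute the 23-parameter kinematic feature set for one trace
#'
#' Features are computed from the smoothed signal and its central-difference
#' derivative, restricted to the active task span (first to last detected
#' extremum) so that leading or trailing rest periods do not dilute
#' whole-trace statistics. Binding definitions for the headline features:
#'
#' * `mean_speed` — time average of |ds/dt| (1/s);
#' * `mean_rms_velocity` — root-mean-square of ds/dt (1/s);
#' * `mean_closing_speed` — mean over cycles of the peak |ds/dt| during the
#'   closing phase (1/s);
#' * `frequency` — number of complete cycles divided by the time they span
#'   (Hz);
#' * `frequency_decay` — OLS slope of the instantaneous cycle rate
#'   (1/cycle_duration) against cycle index, as percent of the mean rate per
#'   cycle.
#'
#' All decay slopes use ordinary least squares over the cycle index and are
#' expressed as percent of the per-trace mean per cycle; they, together with
#' the coefficient-of-variation and consistency features, require at least
#' three complete cycles and are reported as `NA` (missing) otherwise.
#'
#' @param trace An [aperture_trace()].
#' @param catalog A feature catalog (default [default_catalog()]).
#' @param config A [smoothing_config()].
#' @return A named list of class `feature_vector` with elements `values`
#'   (named numeric, names exactly the catalog's), and provenance fields
#'   `patient_id`, `hand`, `condition`, `n_cycles`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1/60)
#' tr <- aperture_trace(0.5 + 0.4 * sin(2 * pi * 1.5 * t))
#' fv <- compute_features(tr)
#' round(fv$values[c("frequency", "mean_speed", "mean_rms_velocity")], 3)
compute_features <- function(trace, catalog = default_catalog(),
                             config = smoothing_config()) {
  validate_catalog(catalog, NA)
  seg <- segment_cycles(trace, config)
  cyc <- seg$cycles
  n_cyc <- nrow(cyc)
  fs <- seg$sampling_rate
  v <- seg$velocity

  # Active span: first to last extremum in the alternating sequence.
  span <- range(c(seg$peak_indices, seg$valley_indices))
  idx <- span[1]:span[2]
  va <- v[idx]
  acc <- derivative(v, fs)[idx]

  have3 <- n_cyc >= 3
  rate <- 1 / cyc$cycle_duration

  vals <- c(
    mean_amplitude    = mean(cyc$amplitude),
    max_amplitude     = max(cyc$amplitude),
    cv_amplitude      = if (have3) cv(cyc$amplitude) else NA_real_,
    amplitude_decay   = if (have3) pct_slope_per_cycle(cyc$amplitude) else NA_real_,
    mean_speed        = mean(abs(va)),
    mean_rms_velocity = sqrt(mean(va^2)),
    mean_opening_speed = mean(cyc$opening_peak_speed),
    mean_closing_speed = mean(cyc$closing_peak_speed),
    max_speed         = max(abs(va)),
    opening_speed_decay = if (have3) pct_slope_per_cycle(cyc$opening_peak_speed) else NA_real_,
    closing_speed_decay = if (have3) pct_slope_per_cycle(cyc$closing_peak_speed) else NA_real_,
    velocity_decay    = if (have3) pct_slope_per_cycle(cycle_rms_velocity(seg)) else NA_real_,
    frequency         = n_cyc / sum(cyc$cycle_duration),
    mean_cycle_duration = mean(cyc$cycle_duration),
    mean_opening_duration = mean(cyc$opening_duration),
    mean_closing_duration = mean(cyc$closing_duration),
    opening_closing_ratio = mean(cyc$opening_duration) / mean(cyc$closing_duration),
    frequency_decay   = if (have3) pct_slope_per_cycle(rate) else NA_real_,
    cv_cycle_duration = if (have3) cv(cyc$cycle_duration) else NA_real_,
    cv_peak_speed     = if (have3) cv(cyc$peak_speed) else NA_real_,
    jerkiness         = mean(abs(acc)) / mean(abs(va)),
    n_hesitations     = count_hesitations(seg) / n_cyc,
    amplitude_range_consistency =
      if (have3) IQR(cyc$amplitude) / median(cyc$amplitude) else NA_real_
  )

  missing <- setdiff(catalog$name, names(vals))
  if (length(missing)) {
    stop_stimvision("catalog requests feature(s) this extractor does not ",
                    "define: ", paste(missing, collapse = ", "),
                    class = "stimvision_catalog_error")
  }
  structure(list(values = vals[catalog$name],
                 patient_id = trace$patient_id, hand = trace$hand,
                 condition = trace$condition, n_cycles = n_cyc),
            class = "feature_vector")
}

# Per-cycle RMS of ds/dt over the valley-to-valley window.
cycle_rms_velocity <- function(seg) {
  vapply(seq_len(nrow(seg$cycles)), function(i) {
    w <- seg$cycles$valley_start[i]:seg$cycles$valley_end[i]
    sqrt(mean(seg$velocity[w]^2))
  }, numeric(1))
}

# Hesitations: interior local minima of |ds/dt| that dip below 10% of the
# cycle's peak speed within an opening or closing phase. Endpoints of each
# phase are excluded because |ds/dt| vanishes there by construction.
count_hesitations <- function(seg, threshold_frac = 0.1) {
  total <- 0L
  absv <- abs(seg$velocity)
  for (i in seq_len(nrow(seg$cycles))) {
    thr <- threshold_frac * seg$cycles$peak_speed[i]
    for (phase in list(seg$cycles$valley_start[i]:seg$cycles$peak[i],
                       seg$cycles$peak[i]:seg$cycles$valley_end[i])) {
      # Trim 10% off each phase end: |ds/dt| vanishes at the extrema by
      # construction, so dips there are geometry, not hesitation.
      margin <- max(1L, ceiling(0.1 * length(phase)))
      if (length(phase) < 2 * margin + 3) next
      x <- absv[phase[(margin + 1):(length(phase) - margin)]]
      k <- 2:(length(x) - 1)
      dips <- x[k] < x[k - 1] & x[k] <= x[k + 1] & x[k] < thr
      total <- total + sum(dips)
    }
  }
  total
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s/%s/%s (%d cycles)\n", x$patient_id,
              x$hand, x$condition, x$n_cycles))
  print(round(x$values, 4))
  invisible(x)
}

#' Extract features for a collection of traces
#'
#' Produces one feature-table row per trace. Traces that fail segmentation
#' (e.g. too few cycles) are reported in the `errors` element rather than
#' silently dropped.
#'
#' @param traces A list of [aperture_trace()] objects.
#' @param catalog,config Passed to [compute_features()].
#' @return A list with `features` (data frame: `patient_id`, `hand`,
#'   `condition`, then one column per catalog feature) and `errors`
#'   (data frame: `patient_id`, `hand`, `condition`, `message`).
#' @export
batch_extract <- function(traces, catalog = default_catalog(),
                          config = smoothing_config()) {
  validate_catalog(catalog, NA)
  keys <- vapply(traces, trace_id, character(1))
  if (anyDuplicated(keys)) {
    stop_stimvision("duplicate (patient, hand, condition) keys: ",
                    paste(unique(keys[duplicated(keys)]), collapse = ", "),
                    class = "stimvision_io_error")
  }
  rows <- list(); errs <- list()
  for (tr in traces) {
    res <- tryCatch(compute_features(tr, catalog, config),
                    stimvision_error = function(e) e)
    if (inherits(res, "feature_vector")) {
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(patient_id = tr$patient_id, hand = tr$hand,
                   condition = tr$condition, stringsAsFactors = FALSE),
        as.data.frame(as.list(res$values)))
    } else {
      errs[[length(errs) + 1L]] <- data.frame(
        patient_id = tr$patient_id, hand = tr$hand, condition = tr$condition,
        message = conditionMessage(res), stringsAsFactors = FALSE)
    }
  }
  empty_feat <- as.data.frame(setNames(
    c(rep(list(character(0)), 3L), rep(list(numeric(0)), nrow(catalog))),
    c("patient_id", "hand", "condition", catalog$name)))
  list(
    features = if (length(rows)) do.call(rbind, rows) else empty_feat,
    errors = if (length(errs)) do.call(rbind, errs) else
      data.frame(patient_id = character(0), hand = character(0),
                 condition = character(0), message = character(0)))
}
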