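#' Construct an aperture trace
#'
#' An aperture trace is a uniformly sampled, dimensionless hand-aperture
#' signal (distance between third-digit tip and wrist, normalized by hand
#' length) recorded while a patient performs repetitive hand opening-closing
#' under one experimental condition (the stimulation-off baseline or one
#' candidate stimulation program).
#'
#' @param samples Numeric vector of aperture values; all finite.
#' @param sampling_rate Sampling rate in Hz (default 60, the video frame rate).
#' @param patient_id,hand,condition Identifying labels; `hand` is `"left"` or
#'   `"right"`.
#' @return An object of class `aperture_trace`.
#' @export
#' @examples
#' tr <- aperture_trace(0.5 + 0.4 * sin(2 * pi * 1.5 * seq(0, 10, by = 1/60)),
#'                      sampling_rate = 60, patient_id = "P01",
#'                      hand = "right", condition = "OFF")
#' tr$duration
aperture_trace <- function(samples, sampling_rate = 60,
                           patient_id = "unknown", hand = "right",
                           condition = "OFF") {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop_stimvision("aperture samples must all be finite",
                    class = "stimvision_trace_error")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_stimvision("sampling_rate must be a positive number",
                    class = "stimvision_trace_error")
  }
  hand <- match.arg(hand, c("left", "right"))
  structure(
    list(samples = samples,
         sampling_rate = as.numeric(sampling_rate),
         patient_id = as.character(patient_id),
         hand = hand,
         condition = as.character(condition),
         duration = length(samples) / sampling_rate),
    class = "aperture_trace")
}

#' @export
print.aperture_trace <- function(x, ...) {
  cat(sprintf("<aperture_trace> %s/%s/%s: %d samples @ %g Hz (%.2f s)\n",
              x$patient_id, x$hand, x$condition, length(x$samples),
              x$sampling_rate, x$duration))
  invisible(x)
}

trace_id <- function(trace) {
  paste(trace$patient_id, trace$hand, trace$condition, sep = "/")
}

# A trace must cover at least 2 s of signal before feature extraction makes
# sense (shorter snippets cannot hold two full cycles of the task band).
check_trace_length <- function(trace) {
  if (length(trace$samples) < 2 * trace$sampling_rate) {
    stop_stimvision("trace ", trace_id(trace), " is shorter than 2 s (",
                    length(trace$samples), " samples @ ", trace$sampling_rate,
                    " Hz)", class = "stimvision_trace_error")
  }
  invisible(trace)
}

#' Read an aperture trace from disk
#'
#' Two plain-text formats are supported: a CSV with columns `time_s` and
#' `aperture` (one file per trial; the sampling rate is inferred from the
#' median time step), or a JSON bundle
#' `{patient_id, hand, condition, fs, samples}`.
#'
#' @param path File path (`.csv` or `.json`).
#' @param patient_id,hand,condition Labels used for CSV input (JSON input
#'   carries its own).
#' @return An [aperture_trace()].
#' @export
read_trace <- function(path, patient_id = "unknown", hand = "right",
                       condition = "OFF") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    need <- c("patient_id", "hand", "condition", "fs", "samples")
    missing <- setdiff(need, names(obj))
    if (length(missing)) {
      stop_stimvision("trace JSON ", path, " is missing field(s): ",
                      paste(missing, collapse = ", "),
                      class = "stimvision_io_error")
    }
    return(aperture_trace(obj$samples, obj$fs, obj$patient_id, obj$hand,
                          obj$condition))
  }
  df <- read.csv(path)
  if (!all(c("time_s", "aperture") %in% names(df))) {
    stop_stimvision("trace CSV ", path, " must have columns time_s, aperture",
                    class = "stimvision_io_error")
  }
  dt <- median(diff(df$time_s))
  if (!is.finite(dt) || dt <= 0) {
    stop_stimvision("trace CSV ", path, " has a non-increasing time column",
                    class = "stimvision_io_error")
  }
  aperture_trace(df$aperture, 1 / dt, patient_id, hand, condition)
}

#' Write an aperture trace
#'
#' @param trace An [aperture_trace()].
#' @param path Destination; `.csv` writes `time_s, aperture`, `.json` the
#'   full bundle.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(patient_id = trace$patient_id, hand = trace$hand,
           condition = trace$condition, fs = trace$sampling_rate,
           samples = trace$samples),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    t <- (seq_along(trace$samples) - 1) / trace$sampling_rate
    write.csv(data.frame(time_s = t, aperture = trace$samples), path,
              row.names = FALSE)
  }
  invisible(path)
}
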