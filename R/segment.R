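#' Smoothing configuration for aperture traces
#'
#' Derivative-based features dominate the kinematic set, so the raw aperture
#' signal is low-pass filtered before differentiation. The default is a
#' zero-phase (forward-backward) 4th-order Butterworth filter with an 8 Hz
#' cutoff: comfortably above the hand opening-closing task band
#' (roughly 0.5-4 Hz) and well below the 60 Hz sampling noise.
#'
#' @param cutoff_hz Low-pass cutoff in Hz.
#' @param order Butterworth filter order.
#' @return A list of class `smoothing_config`.
#' @export
smoothing_config <- function(cutoff_hz = 8, order = 4) {
  stopifnot(cutoff_hz > 0, order >= 1)
  structure(list(cutoff_hz = cutoff_hz, order = order),
            class = "smoothing_config")
}

# Zero-phase low-pass of the sample vector. A cutoff at or above Nyquist
# leaves the signal untouched. The signal is extended by odd reflection at
# both ends before filtering so that filter start-up transients fall in the
# discarded padding, not in the trace.
smooth_samples <- function(samples, sampling_rate, config = smoothing_config()) {
  w <- config$cutoff_hz / (sampling_rate / 2)
  if (w >= 1) return(samples)
  n <- length(samples)
  np <- min(n - 1, ceiling(sampling_rate))
  left <- 2 * samples[1] - samples[(np + 1):2]
  right <- 2 * samples[n] - samples[(n - 1):(n - np)]
  bf <- signal::butter(config$order, w, type = "low")
  out <- as.numeric(signal::filtfilt(bf, c(left, samples, right)))
  out[(np + 1):(np + n)]
}

# Central-difference derivative (one-sided at the ends), in signal units / s.
derivative <- function(samples, sampling_rate) {
  n <- length(samples)
  v <- numeric(n)
  if (n >= 3) v[2:(n - 1)] <- (samples[3:n] - samples[1:(n - 2)]) * sampling_rate / 2
  v[1] <- (samples[2] - samples[1]) * sampling_rate
  v[n] <- (samples[n] - samples[n - 1]) * sampling_rate
  v
}

# Local maxima indices with prominence- and distance-based pruning.
# Ties on flat tops resolve toward the earlier sample (strict rise into the
# peak, non-strict fall out of it). Prominence is the classical definition:
# peak height minus the higher of the two bracketing minima, where each
# bracket runs to the nearest higher peak or the signal edge.
find_peaks <- function(x, min_prominence, min_distance) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))

  prominence <- vapply(cand, function(i) {
    left <- i; lmin <- x[i]
    while (left > 1 && x[left] <= x[i]) {
      left <- left - 1L
      if (x[left] < lmin) lmin <- x[left]
    }
    if (x[left] <= x[i]) lmin <- min(lmin, x[left])
    right <- i; rmin <- x[i]
    while (right < n && x[right] <= x[i]) {
      right <- right + 1L
      if (x[right] < rmin) rmin <- x[right]
    }
    if (x[right] <= x[i]) rmin <- min(rmin, x[right])
    x[i] - max(lmin, rmin)
  }, numeric(1))

  keep <- cand[prominence >= min_prominence]
  if (length(keep) <= 1) return(keep)

  # Enforce minimum separation: visit by height (earlier index wins ties),
  # discard any candidate within min_distance of an already accepted peak.
  ord <- order(-x[keep], keep)
  accepted <- integer(0)
  for (i in keep[ord]) {
    if (!length(accepted) || all(abs(accepted - i) >= min_distance)) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted)
}

# A trace that starts or ends at valley level hides its outermost valleys at
# the signal edges, where interior local-minimum detection cannot see them.
# If the region outside the outermost peak reaches down to valley level,
# place a valley at the last (first) quiet sample before (after) the rise
# (fall), so edge cycles are kept without swallowing leading/trailing rest.
rescue_boundary_valleys <- function(s, ev) {
  if (!nrow(ev) || !any(ev$type == "peak")) return(ev)
  interior_v <- ev$idx[ev$type == "valley"]
  p_idx <- ev$idx[ev$type == "peak"]
  ref_level <- if (length(interior_v)) median(s[interior_v]) else NA_real_
  amp_ref <- median(s[p_idx]) - if (length(interior_v)) ref_level else NA_real_

  add_boundary <- function(reg, leading) {
    vlevel <- min(s[reg])
    peak_val <- s[if (leading) ev$idx[1] else ev$idx[nrow(ev)]]
    ref <- if (is.na(ref_level)) vlevel else ref_level
    amp <- if (is.na(amp_ref)) peak_val - vlevel else amp_ref
    if (amp <= 0 || vlevel > ref + 0.25 * amp) return(NULL)
    thr <- vlevel + 0.02 * (peak_val - vlevel)
    quiet <- reg[s[reg] <= thr]
    if (!length(quiet)) return(NULL)
    if (leading) max(quiet) else min(quiet)
  }

  if (ev$type[1] == "peak" && ev$idx[1] > 1) {
    idx <- add_boundary(1:(ev$idx[1] - 1), leading = TRUE)
    if (!is.null(idx)) {
      ev <- rbind(data.frame(idx = idx, type = "valley"), ev)
    }
  }
  n <- nrow(ev)
  if (ev$type[n] == "peak" && ev$idx[n] < length(s)) {
    idx <- add_boundary((ev$idx[n] + 1):length(s), leading = FALSE)
    if (!is.null(idx)) {
      ev <- rbind(ev, data.frame(idx = idx, type = "valley"))
    }
  }
  ev
}

# Merge peak and valley indices into a strictly alternating sequence,
# collapsing runs of the same type to their most extreme member.
alternate_extrema <- function(x, peaks, valleys) {
  ev <- rbind(data.frame(idx = peaks, type = rep("peak", length(peaks))),
              data.frame(idx = valleys, type = rep("valley", length(valleys))))
  ev <- ev[order(ev$idx), , drop = FALSE]
  if (!nrow(ev)) return(ev)
  out <- ev[1, , drop = FALSE]
  for (r in seq_len(nrow(ev))[-1]) {
    last <- nrow(out)
    if (ev$type[r] == out$type[last]) {
      better <- if (ev$type[r] == "peak") x[ev$idx[r]] > x[out$idx[last]]
                else x[ev$idx[r]] < x[out$idx[last]]
      if (better) out[last, ] <- ev[r, ]
    } else {
      out <- rbind(out, ev[r, ])
    }
  }
  out
}

#' Segment open-close cycles from an aperture trace
#'
#' Detects alternating peaks (maximum aperture) and valleys (hand closed) on
#' the smoothed signal and assembles per-cycle records. A cycle is a
#' valley-peak-valley triple: the opening phase runs valley to peak, the
#' closing phase peak to the next valley. Peak detection requires a
#' prominence of at least 20% of the trace's 5th-95th percentile range and a
#' separation of at least 0.2 s.
#'
#' @param trace An [aperture_trace()].
#' @param config A [smoothing_config()].
#' @return A list of class `cycle_segmentation` with elements
#'   `peak_indices`, `valley_indices` (1-based sample indices into the
#'   trace), `cycles` (data frame of per-cycle records), `smoothed`,
#'   `velocity` and `sampling_rate`.
#' @export
segment_cycles <- function(trace, config = smoothing_config()) {
  stopifnot(inherits(trace, "aperture_trace"))
  check_trace_length(trace)
  fs <- trace$sampling_rate
  s <- smooth_samples(trace$samples, fs, config)
  v <- derivative(s, fs)

  rng <- diff(quantile(s, c(0.05, 0.95), names = FALSE))
  # absolute floor guards against numerically flat traces, where filter edge
  # ripple would otherwise masquerade as oscillation
  min_prom <- max(0.2 * rng, 1e-6)
  min_dist <- max(1, round(0.2 * fs))
  peaks <- find_peaks(s, min_prom, min_dist)
  valleys <- find_peaks(-s, min_prom, min_dist)
  ev <- alternate_extrema(s, peaks, valleys)
  ev <- rescue_boundary_valleys(s, ev)

  p_idx <- ev$idx[ev$type == "peak"]
  v_idx <- ev$idx[ev$type == "valley"]

  # Cycles: every peak flanked by a valley on both sides.
  cycles <- NULL
  if (length(p_idx) && length(v_idx) >= 2) {
    rows <- lapply(p_idx, function(p) {
      pv <- v_idx[v_idx < p]
      nv <- v_idx[v_idx > p]
      if (!length(pv) || !length(nv)) return(NULL)
      v0 <- max(pv); v1 <- min(nv)
      seg_open <- v0:p; seg_close <- p:v1
      # amplitude is read off the raw samples at the detected indices: the
      # low-pass smoothing flattens sharp apexes and would bias it downward
      data.frame(
        valley_start = v0, peak = p, valley_end = v1,
        amplitude = trace$samples[p] - trace$samples[v0],
        opening_duration = (p - v0) / fs,
        closing_duration = (v1 - p) / fs,
        cycle_duration = (v1 - v0) / fs,
        opening_peak_speed = max(v[seg_open]),
        closing_peak_speed = max(-v[seg_close]),
        peak_speed = max(abs(v[v0:v1])))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) cycles <- do.call(rbind, rows)
  }
  if (!is.null(cycles) && nrow(cycles) > 1) {
    # Drop degenerate edge cycles (e.g. a trace cut right after a peak gets
    # an instant "closing" against the boundary valley).
    med <- median(cycles$cycle_duration)
    ok <- cycles$opening_duration >= 0.15 * med &
      cycles$closing_duration >= 0.15 * med
    cycles <- cycles[ok, , drop = FALSE]
  }

  if (is.null(cycles) || nrow(cycles) < 2) {
    stop_stimvision("insufficient cycles in trace ", trace_id(trace),
                    " (need at least 2 complete open-close cycles)",
                    class = "stimvision_segmentation_error")
  }
  if (nrow(cycles) < 4) {
    warning("trace ", trace_id(trace), " has only ", nrow(cycles),
            " complete cycles; cycle-level statistics will be unstable",
            call. = FALSE)
  }
  structure(list(peak_indices = p_idx, valley_indices = v_idx,
                 cycles = cycles, smoothed = s, velocity = v,
                 sampling_rate = fs),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d cycles (%d peaks, %d valleys)\n",
              nrow(x$cycles), length(x$peak_indices), length(x$valley_indices)))
  invisible(x)
}
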