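# Shared fixtures: analytic signals and tiny feature tables, built in code.

sinusoid_trace <- function(freq = 1.5, amplitude = 0.4, offset = 0.5,
                           duration = 10, fs = 60, ...) {
  t <- seq(0, duration, by = 1 / fs)
  aperture_trace(offset + amplitude * sin(2 * pi * freq * t),
                 sampling_rate = fs, ...)
}

# Triangle-wave trace with prescribed per-cycle peak-to-valley amplitudes.
triangle_trace <- function(amplitudes, period = 1, fs = 60, offset = 0.1) {
  half <- round(period * fs / 2)
  s <- offset
  for (a in amplitudes) {
    up <- seq(offset, offset + a, length.out = half + 1)[-1]
    down <- seq(offset + a, offset, length.out = half + 1)[-1]
    s <- c(s, up, down)
  }
  aperture_trace(s, sampling_rate = fs)
}

# A 2-program x 2-feature feature table with an OFF baseline row.
tiny_feature_table <- function() {
  data.frame(
    patient_id = "P1", hand = "right",
    condition = c("OFF", "PrA", "PrB"),
    f_up = c(10, 13, 11),    # higher_better
    f_down = c(2.0, 1.5, 2.2))  # lower_better
}

tiny_catalog <- function() {
  data.frame(name = c("f_up", "f_down"),
             family = c("speed", "variability"),
             orientation = c("higher_better", "lower_better"),
             definition_id = c("f_up", "f_down"))
}

# Independent brute-force DWIS oracle: expands every sum with explicit
# loops, no vectorized shortcuts shared with the implementation.
brute_force_dwis <- function(values, r, lambda) {
  responsive <- which(r > 0)
  w <- numeric(length(r))
  if (length(responsive) == 0) {
    w[] <- 1 / length(r)
  } else {
    total_r <- 0
    for (j in responsive) total_r <- total_r + r[j]
    for (j in responsive) {
      w[j] <- (1 - lambda) * r[j] / total_r + lambda / length(responsive)
    }
  }
  scores <- numeric(nrow(values))
  for (p in seq_len(nrow(values))) {
    num <- 0; den <- 0
    for (j in seq_len(ncol(values))) {
      if (!is.na(values[p, j]) && w[j] > 0) {
        num <- num + w[j] * values[p, j]
        den <- den + w[j]
      }
    }
    scores[p] <- if (den > 0) num / den else 0
  }
  scores
}

# Brute-force sample SD oracle for responsiveness.
brute_force_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Exact one-sided signed-rank p by full 2^n enumeration (no zeros, no ties).
enumerate_wilcoxon_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  rk <- rank(abs(x))
  w_obs <- sum(rk[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% rk)
  mean(w_all >= w_obs)
}

# Hand application of the Benjamini-Hochberg step-up rule.
step_up_bh <- function(p, m = length(p)) {
  ord <- order(p)
  q <- numeric(length(p))
  prev <- 1
  for (i in rev(seq_along(p))) {
    j <- ord[i]
    q[j] <- min(prev, p[j] * m / i)
    prev <- q[j]
  }
  q
}
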