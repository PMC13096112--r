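#' Specification of a synthetic aperture trace
#'
#' Describes a quasi-periodic open-close aperture signal: cycle `k`
#' (0-based) has amplitude `base_amplitude * (1 + amplitude_decay/100 * k)`
#' and nominal rate `base_frequency * (1 + frequency_decay/100 * k)`, with
#' multiplicative cycle-to-cycle period jitter and additive Gaussian sample
#' noise. The defaults emulate a bradykinetic medication-off baseline:
#' modest amplitude, slowed rate, a few percent per-cycle decrement, mild
#' timing jitter.
#'
#' @param base_amplitude Peak-to-valley aperture of the first cycle
#'   (dimensionless; aperture is normalized by hand length).
#' @param base_frequency First-cycle rate in Hz.
#' @param amplitude_decay,frequency_decay Per-cycle drift in percent per
#'   cycle (negative = decrement, the parkinsonian sequence effect).
#' @param cycle_jitter_cv Coefficient of variation of multiplicative period
#'   jitter.
#' @param noise_sd Additive Gaussian noise SD on each sample.
#' @param duration Trace length in s (task protocol: roughly 10-15 s).
#' @param sampling_rate Hz (smartphone video: 60).
#' @param seed RNG seed.
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(base_amplitude = 0.5, base_frequency = 1.2,
                       amplitude_decay = -3, frequency_decay = -2,
                       cycle_jitter_cv = 0.06, noise_sd = 0.01,
                       duration = 12, sampling_rate = 60, seed = 0L) {
  spec <- list(base_amplitude = base_amplitude,
               base_frequency = base_frequency,
               amplitude_decay = amplitude_decay,
               frequency_decay = frequency_decay,
               cycle_jitter_cv = cycle_jitter_cv,
               noise_sd = noise_sd, duration = duration,
               sampling_rate = sampling_rate, seed = seed)
  stopifnot(base_amplitude > 0, base_frequency > 0, cycle_jitter_cv >= 0,
            noise_sd >= 0, sampling_rate > 0)
  if (duration * base_frequency < 2) {
    stop_stimvision("spec must allow at least 2 cycles ",
                    "(duration x base_frequency >= 2)",
                    class = "stimvision_synth_error")
  }
  structure(spec, class = "trace_spec")
}

#' Generate a synthetic aperture trace
#'
#' The signal is a per-cycle-parameterized raised cosine: cycle `k` spans a
#' period `T_k` and traces `offset + A_k/2 * (1 - cos(2*pi*t/T_k))`, so it
#' starts and ends at a valley with the peak mid-cycle. Output is a pure
#' function of the spec (including its seed).
#'
#' @param spec A [trace_spec()].
#' @param patient_id,hand,condition Labels for the resulting trace.
#' @param offset Valley aperture level (default 0.2).
#' @return An [aperture_trace()].
#' @export
#' @examples
#' tr <- generate_aperture_trace(trace_spec(noise_sd = 0, cycle_jitter_cv = 0))
#' compute_features(tr)$values[["frequency"]]
generate_aperture_trace <- function(spec, patient_id = "synthetic",
                                    hand = "right", condition = "OFF",
                                    offset = 0.2) {
  stopifnot(inherits(spec, "trace_spec"))
  with_seed(spec$seed, {
    # Lay down cycles until they cover the trace duration.
    amp <- numeric(0); period <- numeric(0); starts <- numeric(0)
    t_now <- 0; k <- 0L
    while (t_now <= spec$duration) {
      f_k <- spec$base_frequency * (1 + spec$frequency_decay / 100 * k)
      if (f_k <= 0) {
        stop_stimvision("frequency_decay drives the cycle rate non-positive ",
                        "within the trace duration",
                        class = "stimvision_synth_error")
      }
      T_k <- (1 / f_k) * max(1 + rnorm(1, 0, spec$cycle_jitter_cv), 0.1)
      amp <- c(amp, max(spec$base_amplitude *
                          (1 + spec$amplitude_decay / 100 * k), 0))
      period <- c(period, T_k)
      starts <- c(starts, t_now)
      t_now <- t_now + T_k
      k <- k + 1L
    }
    t <- seq(0, spec$duration, by = 1 / spec$sampling_rate)
    cyc_of <- findInterval(t, starts)
    tau <- (t - starts[cyc_of]) / period[cyc_of]
    s <- offset + amp[cyc_of] / 2 * (1 - cos(2 * pi * tau)) +
      rnorm(length(t), 0, spec$noise_sd)
    aperture_trace(s, spec$sampling_rate, patient_id, hand, condition)
  })
}

#' Specification of a synthetic patient programming session
#'
#' A session is a stimulation-off baseline trace plus `n_programs` candidate
#' programs, each applying a multiplicative effect vector to the baseline
#' spec's generative parameters. Exactly one designated best program
#' dominates: largest amplitude and frequency gains, strongest reduction of
#' decrement and jitter.
#'
#' @param base A [trace_spec()] for the stimulation-off baseline.
#' @param n_programs Number of DBS-on programs (cohort protocol: 10).
#' @param best_program Index of the planted best program.
#' @param effects Optional list of per-program named multiplier vectors over
#'   `base_amplitude`, `base_frequency`, `amplitude_decay`,
#'   `frequency_decay`, `cycle_jitter_cv`; generated if `NULL`.
#' @param patient_id,hand Labels.
#' @param seed Session seed (drives effect generation and per-trial seeds).
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(base = trace_spec(), n_programs = 10L,
                         best_program = 1L, effects = NULL,
                         patient_id = "synthetic", hand = "right",
                         seed = 0L) {
  stopifnot(inherits(base, "trace_spec"), n_programs >= 1L,
            best_program >= 1L, best_program <= n_programs)
  if (is.null(effects)) {
    effects <- with_seed(seed + 104729L, {
      lapply(seq_len(n_programs), function(i) {
        if (i == best_program) {
          c(base_amplitude = 1.45, base_frequency = 1.35,
            amplitude_decay = 0.4, frequency_decay = 0.4,
            cycle_jitter_cv = 0.6)
        } else {
          c(base_amplitude = runif(1, 0.85, 1.25),
            base_frequency = runif(1, 0.9, 1.2),
            amplitude_decay = runif(1, 0.6, 1.1),
            frequency_decay = runif(1, 0.6, 1.1),
            cycle_jitter_cv = runif(1, 0.7, 1.1))
        }
      })
    })
  }
  stopifnot(length(effects) == n_programs)
  structure(list(base = base, n_programs = as.integer(n_programs),
                 best_program = as.integer(best_program), effects = effects,
                 patient_id = patient_id, hand = hand, seed = seed),
            class = "session_spec")
}

#' Generate the traces of a synthetic programming session
#'
#' @param spec A [session_spec()].
#' @return List with `traces` (the baseline plus one trace per program, in
#'   chronological order), `best_program` (the planted optimal label), and
#'   `program_labels`.
#' @export
generate_patient_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  trial_seed <- function(i) (spec$seed + i * 10007L) %% 2147483647L
  base <- spec$base
  base$seed <- trial_seed(0L)
  traces <- list(generate_aperture_trace(base, spec$patient_id, spec$hand,
                                         "OFF"))
  labels <- sprintf("Pr%02d", seq_len(spec$n_programs))
  for (i in seq_len(spec$n_programs)) {
    s <- base
    eff <- spec$effects[[i]]
    for (field in names(eff)) s[[field]] <- s[[field]] * eff[[field]]
    s$seed <- trial_seed(i)
    class(s) <- "trace_spec"
    traces[[i + 1L]] <- generate_aperture_trace(s, spec$patient_id,
                                                spec$hand, labels[i])
  }
  list(traces = traces, best_program = labels[spec$best_program],
       program_labels = labels)
}

#' Default planted sparse domain loadings
#'
#' Three non-overlapping feature blocks (a speed-like, a consistency-like
#' and a timing-like domain) with seeded loading magnitudes, each column
#' scaled to unit norm — the ground truth for sparse-recovery simulations.
#'
#' @param p Number of features (default 23).
#' @param seed RNG seed.
#' @return A `p x 3` matrix with unit-norm sparse columns.
#' @export
planted_domain_loadings <- function(p = 23L, seed = 0L) {
  stopifnot(p >= 9L)
  cuts <- round(p * c(1, 2) / 3)
  blocks <- list(1:cuts[1], (cuts[1] + 1):cuts[2], (cuts[2] + 1):p)
  with_seed(seed + 7919L, {
    L <- matrix(0, p, 3)
    for (k in 1:3) {
      v <- runif(length(blocks[[k]]), 0.5, 1) *
        sample(c(1, 1, 1, -1), length(blocks[[k]]), replace = TRUE)
      L[blocks[[k]], k] <- v / sqrt(sum(v^2))
    }
    rownames(L) <- paste0("f", seq_len(p))
    colnames(L) <- paste0("PC", 1:3)
    L
  })
}

#' Specification of a domain-structured synthetic cohort
#'
#' @param n_patients Cohort size (default 150, the scale of the reference
#'   levodopa-style cohort).
#' @param loadings True sparse loadings (`p x 3`); default
#'   [planted_domain_loadings()].
#' @param score_sd Component score SDs (length 3, decreasing).
#' @param noise_sd Additive noise SD as a fraction of the signal SD.
#' @param seed RNG seed.
#' @return A list of class `planted_domain_spec`.
#' @export
planted_domain_spec <- function(n_patients = 150L, loadings = NULL,
                                score_sd = c(3, 2, 1.2), noise_sd = 0.1,
                                seed = 0L) {
  if (is.null(loadings)) loadings <- planted_domain_loadings(seed = seed)
  stopifnot(ncol(loadings) == length(score_sd), noise_sd >= 0,
            n_patients >= ncol(loadings) + 2L)
  if (any(colSums(loadings^2) == 0)) {
    stop_stimvision("planted loading columns must be non-zero",
                    class = "stimvision_synth_error")
  }
  structure(list(n_patients = as.integer(n_patients), loadings = loadings,
                 score_sd = score_sd, noise_sd = noise_sd, seed = seed),
            class = "planted_domain_spec")
}

#' Generate an improvement matrix with planted low-rank sparse structure
#'
#' `X = S L' + E` with component scores `S` drawn i.i.d. normal with the
#' spec's SDs and noise `E` scaled to `noise_sd` times the SD of the signal
#' part. Returns the planted loadings alongside the matrix so recovery can
#' be scored.
#'
#' @param spec A [planted_domain_spec()].
#' @return List with `matrix` (patients x features) and `loadings` (truth).
#' @export
generate_domain_structured_cohort <- function(spec) {
  stopifnot(inherits(spec, "planted_domain_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    k <- ncol(spec$loadings)
    S <- matrix(rnorm(n * k), n, k) %*% diag(spec$score_sd, k)
    signal <- S %*% t(spec$loadings)
    E <- matrix(rnorm(n * nrow(spec$loadings)), n) *
      (spec$noise_sd * sd(as.numeric(signal)))
    X <- signal + E
    colnames(X) <- rownames(spec$loadings)
    rownames(X) <- paste0("patient_", seq_len(n))
    list(matrix = X, loadings = spec$loadings)
  })
}

#' Generate a synthetic clinician-concordance dataset
#'
#' Clinical improvement is generated on a latent continuous scale,
#' `improvement = intercept_cluster + beta * delta_dwis + residual`, then
#' mapped to MDS-UPDRS item scores: the program score is the baseline score
#' minus the improvement, rounded and clipped to the 0-4 item range (set
#' `discretize = FALSE` for the continuous latent version).
#'
#' @param beta True fixed-effect slope.
#' @param cluster_sd SD of the per-patient-hand random intercept.
#' @param residual_sd SD of the residual noise.
#' @param n_clusters,n_per_cluster Design size.
#' @param seed RNG seed.
#' @param discretize Round and clip program scores to the 0-4 item scale.
#' @param dwis_mean,dwis_sd Distribution of `delta_dwis` values.
#' @return Data frame: `patient_hand`, `program`, `delta_dwis`,
#'   `updrs_baseline`, `updrs_program`, plus the latent `improvement_latent`.
#' @export
generate_concordance_dataset <- function(beta = 0.70, cluster_sd = 0.4,
                                         residual_sd = 0.6,
                                         n_clusters = 15L,
                                         n_per_cluster = 10L, seed = 0L,
                                         discretize = TRUE,
                                         dwis_mean = 0.4, dwis_sd = 0.8) {
  stopifnot(cluster_sd >= 0, residual_sd >= 0)
  with_seed(seed, {
    rows <- lapply(seq_len(n_clusters), function(cl) {
      icpt <- rnorm(1, 0, cluster_sd)
      dd <- rnorm(n_per_cluster, dwis_mean, dwis_sd)
      latent <- icpt + beta * dd + rnorm(n_per_cluster, 0, residual_sd)
      base <- sample(2:3, 1)
      prog_score <- base - latent
      if (discretize) prog_score <- pmin(4, pmax(0, round(prog_score)))
      data.frame(patient_hand = sprintf("PH%02d", cl),
                 program = sprintf("Pr%02d", seq_len(n_per_cluster)),
                 delta_dwis = dd,
                 updrs_baseline = base,
                 updrs_program = prog_score,
                 improvement_latent = latent,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
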