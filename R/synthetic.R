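#' Specification of a synthetic resting-state EEG cohort
#'
#' Describes the signal model used by the synthetic generators: a 1/f^gamma
#' background plus independent band-limited oscillations in each of the five
#' canonical bands, on a 32-electrode 10/10 montage. Amplitudes are in
#' arbitrary microvolt-scale units; only relative band power matters
#' downstream, but absolute spectral densities are kept consistent.
#'
#' Defaults emulate five minutes of open-eyes resting EEG on a 32-channel
#' cap. `band_gain_mean` sets the flat in-band amplitude spectral density of
#' each band's oscillation; the defaults yield a realistic adult eyes-open
#' relative-power profile (delta-dominant with clear alpha). Between-subject
#' variability is log-normal on band amplitude with coefficient of variation
#' `band_gain_cv`.
#'
#' @param montage Character vector of unique electrode labels.
#' @param fs Sampling rate in Hz (typically 5000 or 500).
#' @param duration_s Recording length in seconds.
#' @param noise_exponent Spectral slope gamma of the 1/f^gamma background.
#' @param noise_amp Amplitude scale of the background (0 disables it).
#' @param band_gain_mean Named numeric vector, mean oscillation amplitude
#'   per band (names must be the five canonical bands).
#' @param band_gain_cv Coefficient of variation of band amplitude across
#'   subjects (>= 0).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(montage = default_montage(),
                        fs = 500,
                        duration_s = 300,
                        noise_exponent = 1.0,
                        noise_amp = 5,
                        band_gain_mean = c(delta = 2, theta = 2, alpha1 = 3,
                                           alpha2 = 2.5, beta = 1),
                        band_gain_cv = 0.3) {
  if (anyDuplicated(montage)) stop("montage labels must be unique", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (band_gain_cv < 0) stop("band_gain_cv must be >= 0", call. = FALSE)
  bands <- band_scheme()$band
  if (!setequal(names(band_gain_mean), bands))
    stop("band_gain_mean must be named with the five canonical bands",
         call. = FALSE)
  if (any(band_gain_mean < 0) || noise_amp < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  structure(list(montage = as.character(montage), fs = fs,
                 duration_s = duration_s,
                 noise_exponent = noise_exponent, noise_amp = noise_amp,
                 band_gain_mean = band_gain_mean[bands],
                 band_gain_cv = band_gain_cv),
            class = "cohort_spec")
}

#' Specification of a planted spectral anomaly
#'
#' Multiplies the amplitude of one band's oscillation at a set of target
#' electrodes, emulating a focal band-power excess (e.g. theta excess over
#' the left motor area) when `gain_factor > 1`.
#'
#' @param target_band One of the five canonical band names.
#' @param target_electrodes Electrode labels (must be in the montage used).
#' @param gain_factor Positive multiplicative amplitude factor.
#' @return An object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(target_band, target_electrodes, gain_factor) {
  target_band <- tolower(target_band)
  if (!target_band %in% band_scheme()$band)
    stop("unknown band: ", target_band, call. = FALSE)
  if (gain_factor <= 0) stop("gain_factor must be positive", call. = FALSE)
  structure(list(target_band = target_band,
                 target_electrodes = as.character(target_electrodes),
                 gain_factor = gain_factor),
            class = "anomaly_spec")
}

# Frequency-domain synthesis shared by all recording generators.
# band_gains: named per-band amplitudes for this subject.
synth_recording <- function(spec, band_gains, anomaly, seed, reference) {
  n <- round(spec$fs * spec$duration_s)
  nk <- floor((n - 1) / 2)                 # positive-frequency bins, no Nyquist
  f <- seq_len(nk) * spec$fs / n
  scheme <- band_scheme()

  anom_idx <- integer(0)
  if (!is.null(anomaly)) {
    stopifnot(inherits(anomaly, "anomaly_spec"))
    anom_idx <- match_labels(anomaly$target_electrodes, spec$montage)
  }

  # amplitude spectral density of the background; cut below 0.5 Hz to avoid
  # a divergent DC region (everything below 1 Hz is discarded downstream)
  a_bg <- ifelse(f >= 0.5, spec$noise_amp * f^(-spec$noise_exponent / 2), 0)
  band_bins <- lapply(seq_len(nrow(scheme)), function(b)
    which(f >= scheme$lo[b] - 1e-9 & f <= scheme$hi[b] + 1e-9))
  scale <- sqrt(n * spec$fs / 2)

  with_seed(seed, {
    data <- matrix(0, length(spec$montage), n)
    for (ch in seq_along(spec$montage)) {
      spec_ch <- a_bg * exp(1i * stats::runif(nk, 0, 2 * pi))
      for (b in seq_len(nrow(scheme))) {
        idx <- band_bins[[b]]
        if (!length(idx)) next
        g <- band_gains[[scheme$band[b]]]
        if (!is.null(anomaly) && scheme$band[b] == anomaly$target_band &&
            ch %in% anom_idx)
          g <- g * anomaly$gain_factor
        spec_ch[idx] <- spec_ch[idx] +
          g * exp(1i * stats::runif(length(idx), 0, 2 * pi))
      }
      xk <- complex(n)
      xk[2:(nk + 1)] <- scale * spec_ch
      xk[n:(n - nk + 1)] <- Conj(xk[2:(nk + 1)])
      data[ch, ] <- Re(stats::fft(xk, inverse = TRUE)) / n
    }
    recording(data, fs = spec$fs, labels = spec$montage,
              reference = reference)
  })
}

#' Generate one synthetic resting-state EEG recording
#'
#' Synthesizes the signal in the frequency domain (power proportional to
#' 1/f^gamma background plus flat-top band-limited oscillations, with
#' independent random phases), giving exact control over the expected power
#' spectrum. An optional anomaly multiplies the target band's amplitude at
#' the target electrodes. The output is a pure function of (spec, anomaly,
#' seed): the same seed reproduces the recording bitwise.
#'
#' @param spec A [cohort_spec()].
#' @param anomaly An [anomaly_spec()] or `NULL`.
#' @param seed Integer seed.
#' @return An `eeg_recording`.
#' @export
generate_recording <- function(spec, anomaly = NULL, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  synth_recording(spec, spec$band_gain_mean, anomaly, seed,
                  reference = "synthetic")
}

# Per-subject log-normal band gains with mean band_gain_mean and CV
# band_gain_cv (CV 0 degenerates to the mean).
draw_band_gains <- function(spec, n) {
  bands <- names(spec$band_gain_mean)
  sdlog <- sqrt(log1p(spec$band_gain_cv^2))
  out <- lapply(seq_len(n), function(i) {
    m <- stats::rlnorm(length(bands),
                       meanlog = log(spec$band_gain_mean) - sdlog^2 / 2,
                       sdlog = sdlog)
    names(m) <- bands
    m
  })
  out
}

#' Generate a synthetic healthy-control cohort
#'
#' Draws `n` subjects whose band amplitudes vary log-normally around the
#' spec means (coefficient of variation `band_gain_cv`) and synthesizes one
#' recording per subject. At least two controls are required, since the
#' downstream normative model needs a between-subject standard deviation.
#'
#' @param n Number of control subjects (>= 2).
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A list of `eeg_recording` objects named `ctrl01`, `ctrl02`, ...
#' @export
generate_control_cohort <- function(n, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n < 2)
    stop("a control cohort needs n >= 2 (normative SD undefined otherwise)",
         call. = FALSE)
  gains <- with_seed(seed, draw_band_gains(spec, n))
  seeds <- child_seeds(seed + 1L, n)
  recs <- lapply(seq_len(n), function(i)
    synth_recording(spec, gains[[i]], NULL, seeds[i],
                    reference = sprintf("synthetic control %d", i)))
  names(recs) <- sprintf("ctrl%02d", seq_len(n))
  recs
}

#' Generate a synthetic patient with a planted spectral anomaly
#'
#' Like one subject of [generate_control_cohort()] (band gains drawn from
#' the same between-subject distribution), with the anomaly applied on top,
#' so patients differ from controls only by the planted excess plus normal
#' inter-individual variability.
#'
#' @param spec A [cohort_spec()].
#' @param anomaly An [anomaly_spec()] or `NULL`.
#' @param seed Integer seed.
#' @return An `eeg_recording`.
#' @export
generate_patient <- function(spec, anomaly = NULL, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  gains <- with_seed(seed, draw_band_gains(spec, 1))[[1L]]
  synth_recording(spec, gains, anomaly, seed + 1L,
                  reference = "synthetic patient")
}

#' Specification of synthetic crossover outcome tables
#'
#' Describes a two-condition (tACS vs random-noise stimulation) crossover
#' measurement schedule with baseline T0, post-cycle T1/T1' and
#' post-wash-out T2/T2' assessments. Effects are additive location shifts on
#' a measure at a given condition and timepoint; noise is Gaussian before
#' clamping to the measure's score range.
#'
#' @param n_subjects Number of subjects.
#' @param measures Data frame with columns `measure`, `min`, `max`,
#'   `baseline` (score units). Default: a 0--10 pain visual-analogue scale
#'   with baseline 6.
#' @param effects Data frame with columns `measure`, `condition`
#'   (`"tACS"`/`"RNS"`), `timepoint` (`"T1"`/`"T2"`), `shift` (score units
#'   added at that cell). Default: no effects.
#' @param noise_sd Gaussian noise SD in score units.
#' @param missing_rate Probability in [0, 1) that a post-baseline
#'   observation is missing.
#' @return An object of class `outcome_spec`.
#' @export
outcome_spec <- function(n_subjects = 14,
                         measures = data.frame(measure = "VAS", min = 0,
                                               max = 10, baseline = 6),
                         effects = NULL,
                         noise_sd = 1,
                         missing_rate = 0) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(all(c("measure", "min", "max", "baseline") %in% names(measures)))
  if (is.null(effects))
    effects <- data.frame(measure = character(), condition = character(),
                          timepoint = character(), shift = numeric())
  stopifnot(all(c("measure", "condition", "timepoint", "shift") %in%
                  names(effects)))
  structure(list(n_subjects = n_subjects, measures = measures,
                 effects = effects, noise_sd = noise_sd,
                 missing_rate = missing_rate),
            class = "outcome_spec")
}

#' Generate a synthetic crossover outcome table
#'
#' Subjects are randomized 1:1 to a tACS-first or RNS-first sequence. Each
#' subject contributes one baseline row (T0, no condition) and, per
#' measure, post-cycle and post-wash-out rows for each condition: T1/T2 in
#' the first arm and T1'/T2' in the second. Values are
#' `baseline + shift + noise`, clamped to the measure's range; the shift for
#' T1'/T2' is looked up under T1/T2 of the corresponding condition.
#'
#' @param spec An [outcome_spec()].
#' @param seed Integer seed.
#' @return A long-format data frame with columns `subject`, `sequence`,
#'   `timepoint`, `condition`, `measure`, `value`.
#' @export
generate_outcomes <- function(spec, seed) {
  stopifnot(inherits(spec, "outcome_spec"))
  n <- spec$n_subjects
  with_seed(seed, {
    n_first <- floor(n / 2) + stats::rbinom(1, 1, 0.5) * (n %% 2)
    seqs <- sample(c(rep("tACS-first", n_first), rep("RNS-first", n - n_first)))
    rows <- vector("list", n)
    for (s in seq_len(n)) {
      first <- if (seqs[s] == "tACS-first") "tACS" else "RNS"
      second <- setdiff(c("tACS", "RNS"), first)
      sched <- data.frame(
        timepoint = c("T0", "T1", "T2", "T1'", "T2'"),
        condition = c(NA, first, first, second, second),
        eff_time  = c(NA, "T1", "T2", "T1", "T2"),
        stringsAsFactors = FALSE
      )
      out <- merge(sched, spec$measures, by = NULL)
      shift <- rep(0, nrow(out))
      if (nrow(spec$effects)) {
        key <- paste(out$measure, out$condition, out$eff_time)
        ekey <- paste(spec$effects$measure, spec$effects$condition,
                      spec$effects$timepoint)
        hit <- match(key, ekey)
        shift[!is.na(hit)] <- spec$effects$shift[hit[!is.na(hit)]]
      }
      val <- out$baseline + shift + stats::rnorm(nrow(out), 0, spec$noise_sd)
      out$value <- pmin(pmax(val, out$min), out$max)
      out$subject <- sprintf("S%02d", s)
      out$sequence <- seqs[s]
      rows[[s]] <- out[, c("subject", "sequence", "timepoint", "condition",
                           "measure", "value")]
    }
    tab <- do.call(rbind, rows)
    if (spec$missing_rate > 0) {
      post <- tab$timepoint != "T0"
      drop <- post & stats::runif(nrow(tab)) < spec$missing_rate
      tab <- tab[!drop, , drop = FALSE]
    }
    rownames(tab) <- NULL
    tab
  })
}

#' Discrete probability distribution on a numeric support
#'
#' Used for the signed-rank power simulation of score differences (e.g.
#' pain-scale change scores on the integers -1 to 6).
#'
#' @param support Strictly increasing numeric values.
#' @param probabilities Non-negative weights summing to 1 (within 1e-12).
#' @return An object of class `discrete_distribution`.
#' @export
discrete_distribution <- function(support, probabilities) {
  support <- as.numeric(support)
  probabilities <- as.numeric(probabilities)
  if (length(support) != length(probabilities))
    stop("support and probabilities must have equal length", call. = FALSE)
  if (any(diff(support) <= 0))
    stop("support must be strictly increasing", call. = FALSE)
  if (any(probabilities < 0))
    stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(probabilities) - 1) > 1e-12)
    stop("probabilities must sum to 1 (within 1e-12)", call. = FALSE)
  structure(list(support = support, probabilities = probabilities),
            class = "discrete_distribution")
}

#' @export
print.discrete_distribution <- function(x, ...) {
  cat("<discrete_distribution>\n")
  print(stats::setNames(x$probabilities, format(x$support)))
  invisible(x)
}

#' Draw i.i.d. samples from a discrete distribution
#'
#' @param dist A [discrete_distribution()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_differences <- function(dist, n, seed) {
  stopifnot(inherits(dist, "discrete_distribution"))
  # index-based draw: sample(x, ...) would misread a length-1 support
  with_seed(seed, dist$support[sample.int(length(dist$support), n,
                                          replace = TRUE,
                                          prob = dist$probabilities)])
}

#' Read a discrete-distribution config file
#'
#' The config is YAML with keys `support` and `probabilities`.
#'
#' @param path Path to the YAML file.
#' @return A [discrete_distribution()].
#' @export
read_distribution_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  discrete_distribution(cfg$support, cfg$probabilities)
}

#' Illustrative pain-score difference distribution
#'
#' A discrete distribution of baseline-to-post-treatment pain visual
#' analogue scale differences on the integers -1 to 6 with median 1.5
#' (under the midpoint convention), shipped for power-analysis examples.
#' The probabilities are illustrative, chosen to respect the published
#' support, median and approximate test power of the motivating trial; they
#' are not that study's unpublished empirical frequencies.
#'
#' @return A [discrete_distribution()].
#' @export
#' @examples
#' distribution_median(example_vas_difference_distribution())
example_vas_difference_distribution <- function() {
  discrete_distribution(
    support = -1:6,
    probabilities = c(0.20, 0.10, 0.20, 0.15, 0.12, 0.10, 0.08, 0.05)
  )
}
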