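#' Fit a normative band-power model from a control cohort
#'
#' Cell-wise (channel x band) sample mean and sample standard deviation
#' (n - 1 denominator) of relative power across control subjects. The model
#' is the reference against which individual patients are z-scored; a zero
#' SD in any cell would make that z undefined and is rejected.
#'
#' @param controls List of `band_power_table` objects on identical montages
#'   and band schemes (>= 2).
#' @return An object of class `normative_model` with `mean` and `sd`
#'   matrices (channels x bands) and `n_controls`.
#' @export
fit_normative <- function(controls) {
  if (length(controls) < 2)
    stop("need >= 2 control tables", call. = FALSE)
  ref <- controls[[1L]]
  for (tab in controls[-1L]) {
    if (!identical(dim(tab), dim(ref)) ||
        !identical(rownames(tab), rownames(ref)) ||
        !identical(colnames(tab), colnames(ref)))
      stop("control tables have mismatched montage or band scheme",
           call. = FALSE)
  }
  arr <- simplify2array(lapply(controls, unclass))
  mu <- apply(arr, c(1, 2), mean)
  sdev <- apply(arr, c(1, 2), stats::sd)
  if (any(sdev <= 0)) {
    bad <- which(sdev <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("zero control SD at channel %s, band %s",
                 rownames(mu)[bad[1L]], colnames(mu)[bad[2L]]),
         call. = FALSE)
  }
  structure(list(mean = mu, sd = sdev, n_controls = length(controls)),
            class = "normative_model")
}

#' Z-statistic topographic map of a subject versus controls
#'
#' Per channel and band, `z = (subject - control mean) / control SD`; cells
#' with `|z| >= 1.959964` (two-sided normal 5% quantile by default) are
#' flagged significant. This is the statistical map used to locate the
#' scalp area where a subject's spectrum deviates from the healthy cohort.
#'
#' @param subject A `band_power_table`.
#' @param model A `normative_model` on the same montage and bands.
#' @param threshold Absolute z threshold for the significance flag.
#' @return An object of class `zmap` with matrices `z` and `significant`.
#' @export
compute_zmap <- function(subject, model, threshold = stats::qnorm(0.975)) {
  stopifnot(inherits(model, "normative_model"))
  if (!identical(dim(unclass(subject)), dim(model$mean)) ||
      !identical(rownames(subject), rownames(model$mean)) ||
      !identical(colnames(subject), colnames(model$mean)))
    stop("subject table does not match the normative model's montage/bands",
         call. = FALSE)
  z <- (unclass(subject) - model$mean) / model$sd
  structure(list(z = z, significant = abs(z) >= threshold,
                 threshold = threshold),
            class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat(sprintf("<zmap> %d x %d, |z| threshold %.6f, %d significant cell(s)\n",
              nrow(x$z), ncol(x$z), x$threshold, sum(x$significant)))
  invisible(x)
}

#' Prevailing rhythm: the strongest significant band-power excess
#'
#' Returns the band and electrode of the maximum positive significant z in
#' the map. Ties are broken deterministically: first by band order (delta
#' to beta), then by montage order. When no cell shows a significant
#' positive excess the result is an explicit "no target" outcome, not an
#' error.
#'
#' @param zmap A `zmap`.
#' @return An object of class `prevailing_rhythm` with fields `found`,
#'   `band`, `electrode`, `z`.
#' @export
prevailing_rhythm <- function(zmap) {
  stopifnot(inherits(zmap, "zmap"))
  cand <- zmap$significant & zmap$z > 0
  if (!any(cand)) {
    return(structure(list(found = FALSE, band = NA_character_,
                          electrode = NA_character_, z = NA_real_),
                     class = "prevailing_rhythm"))
  }
  zv <- zmap$z
  zv[!cand] <- -Inf
  best <- max(zv)
  hits <- which(zv >= best - 1e-12, arr.ind = TRUE)
  # tie-break: band order (columns follow the canonical delta..beta order),
  # then montage (row) order
  hits <- hits[order(hits[, 2L], hits[, 1L]), , drop = FALSE]
  structure(list(found = TRUE,
                 band = colnames(zv)[hits[1L, 2L]],
                 electrode = rownames(zv)[hits[1L, 1L]],
                 z = zmap$z[hits[1L, 1L], hits[1L, 2L]]),
            class = "prevailing_rhythm")
}

#' @export
print.prevailing_rhythm <- function(x, ...) {
  if (x$found)
    cat(sprintf("<prevailing_rhythm> %s excess at %s (z = %.2f)\n",
                x$band, x$electrode, x$z))
  else cat("<prevailing_rhythm> no significant positive excess (no target)\n")
  invisible(x)
}

# Cathode site for a given anode: ipsilateral mastoid for lateral
# electrodes (odd terminal digit = left, even = right); for midline
# ("z"-suffixed) anodes, the adjacent midline electrode (anterior neighbour
# in the Fpz-Fz-Cz-Pz-Oz chain when available, else posterior).
cathode_for <- function(anode) {
  lab <- toupper(anode)
  if (grepl("Z$", lab)) {
    chain <- c("FPZ", "FZ", "CZ", "PZ", "OZ")
    pretty <- c("Fpz", "Fz", "Cz", "Pz", "Oz")
    i <- match(lab, chain)
    if (is.na(i)) stop("unknown midline electrode: ", anode, call. = FALSE)
    return(if (i > 1L) pretty[i - 1L] else pretty[i + 1L])
  }
  digits <- gsub("\\D", "", lab)
  if (!nzchar(digits))
    stop("cannot determine laterality of electrode: ", anode, call. = FALSE)
  last <- as.integer(substr(digits, nchar(digits), nchar(digits)))
  if (last %% 2L == 1L) "M1" else "M2"
}

#' Derive the individualized stimulation plan from a prevailing rhythm
#'
#' Applies the frequency decision rule: an excess in a slow band (delta,
#' theta, alpha1) is countered with 30 Hz beta-tACS, an excess in a fast
#' band (alpha2, beta) with 4 Hz theta-tACS. The anode goes over the peak
#' electrode; the cathode over the ipsilateral mastoid (M1 left / M2 right),
#' or the adjacent midline electrode for midline anodes. Amplitude range is
#' 1--2 mA. A "no target" rhythm yields a plan with `mode = "none"`.
#'
#' @param prev A `prevailing_rhythm`.
#' @param mode `"tACS"` (default) or `"RNS"` (active sham: same montage,
#'   randomized amplitude and frequency).
#' @param cathode Optional manual override of the cathode site.
#' @return An object of class `stimulation_plan`.
#' @export
plan_stimulation <- function(prev, mode = c("tACS", "RNS"), cathode = NULL) {
  stopifnot(inherits(prev, "prevailing_rhythm"))
  mode <- match.arg(mode)
  if (!prev$found) {
    return(structure(list(mode = "none", band_class = NA_character_,
                          frequency_hz = NA_real_, anode = NA_character_,
                          cathode = NA_character_,
                          amplitude_ma = c(1, 2)),
                     class = "stimulation_plan"))
  }
  cls <- band_class(prev$band)
  structure(list(
    mode = mode,
    band_class = paste0(cls, "-excess"),
    frequency_hz = if (cls == "slow") 30 else 4,
    anode = prev$electrode,
    cathode = cathode %||% cathode_for(prev$electrode),
    amplitude_ma = c(1, 2)
  ), class = "stimulation_plan")
}

#' @export
print.stimulation_plan <- function(x, ...) {
  if (x$mode == "none") {
    cat("<stimulation_plan> no target (no significant excess)\n")
  } else {
    cat(sprintf("<stimulation_plan> %s at %g Hz, anode %s, cathode %s, %g-%g mA (%s)\n",
                x$mode, x$frequency_hz, x$anode, x$cathode,
                x$amplitude_ma[1], x$amplitude_ma[2], x$band_class))
  }
  invisible(x)
}

#' Write a stimulation plan as a JSON file
#'
#' @param plan A `stimulation_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "stimulation_plan"))
  jsonlite::write_json(list(mode = plan$mode,
                            band_class = plan$band_class,
                            frequency_hz = plan$frequency_hz,
                            anode = plan$anode, cathode = plan$cathode,
                            amplitude_ma_min = plan$amplitude_ma[1],
                            amplitude_ma_max = plan$amplitude_ma[2]),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Synthesize a stimulation current waveform
#'
#' tACS mode produces a fixed-frequency sinusoid at the plan frequency;
#' random-noise stimulation (RNS) produces piecewise sinusoidal segments
#' (50 ms each, phase-continuous) whose amplitude and frequency are drawn
#' uniformly from 1--2 mA and 0--100 Hz. All samples are bounded by 2 mA.
#'
#' @param plan A `stimulation_plan`.
#' @param duration_s Waveform duration in seconds.
#' @param fs Sampling rate in Hz; must exceed twice the maximum frequency.
#' @param seed Integer seed (used by RNS mode).
#' @param amplitude_ma tACS amplitude in mA (default: midpoint of the
#'   plan's range; must lie within it).
#' @return Numeric vector of current samples in mA.
#' @export
synthesize_waveform <- function(plan, duration_s, fs, seed = 1L,
                                amplitude_ma = NULL) {
  stopifnot(inherits(plan, "stimulation_plan"))
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (plan$mode == "none")
    stop("cannot synthesize a waveform for a 'no target' plan", call. = FALSE)
  n <- round(duration_s * fs)
  if (plan$mode == "tACS") {
    if (fs <= 2 * plan$frequency_hz)
      stop("fs must exceed twice the stimulation frequency", call. = FALSE)
    amp <- amplitude_ma %||% mean(plan$amplitude_ma)
    if (amp < plan$amplitude_ma[1] || amp > plan$amplitude_ma[2])
      stop("amplitude outside the plan's range", call. = FALSE)
    return(amp * sin(2 * pi * plan$frequency_hz * (seq_len(n) - 1L) / fs))
  }
  # RNS
  if (fs <= 2 * 100)
    stop("fs must exceed 200 Hz for 0-100 Hz random-noise stimulation",
         call. = FALSE)
  seg <- max(1L, round(0.05 * fs))
  n_seg <- ceiling(n / seg)
  with_seed(seed, {
    freqs <- stats::runif(n_seg, 0, 100)
    amps <- stats::runif(n_seg, plan$amplitude_ma[1], plan$amplitude_ma[2])
    phase <- 0
    out <- numeric(0)
    for (s in seq_len(n_seg)) {
      k <- seq_len(seg)
      ph <- phase + 2 * pi * freqs[s] * k / fs
      out <- c(out, amps[s] * sin(ph))
      phase <- ph[seg] %% (2 * pi)
    }
    out[seq_len(n)]
  })
}
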