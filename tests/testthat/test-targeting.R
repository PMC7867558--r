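make_table <- function(m, labels = c("C3", "C4"),
                       bands = band_scheme()$band) {
  dimnames(m) <- list(labels, bands)
  structure(m, class = "band_power_table")
}

test_that("normative models are cell-wise mean and n-1 SD", {
  a <- make_table(matrix(10, 2, 5))
  b <- make_table(matrix(20, 2, 5))
  m <- fit_normative(list(a, b))
  expect_equal(unname(m$mean[1, 1]), 15)
  expect_equal(unname(m$sd[1, 1]), 7.0711, tolerance = 1e-4)
  expect_equal(m$n_controls, 2)
})

test_that("degenerate and mismatched control sets are rejected", {
  a <- make_table(matrix(10, 2, 5))
  expect_error(fit_normative(list(a)), ">= 2")
  expect_error(fit_normative(list(a, a)), "zero control SD at channel C3")
  b <- make_table(matrix(12, 2, 5), labels = c("F3", "F4"))
  expect_error(fit_normative(list(a, b)), "mismatched")
})

test_that("normative cells match an independent mean/SD recomputation", {
  set.seed(31)
  for (rep in 1:20) {
    tabs <- lapply(1:21, function(i) make_table(matrix(runif(10, 5, 40), 2, 5)))
    m <- fit_normative(tabs)
    arr <- simplify2array(lapply(tabs, unclass))
    # oracle: explicit sums, not stats::sd
    mu <- apply(arr, c(1, 2), function(x) sum(x) / length(x))
    sdev <- apply(arr, c(1, 2), function(x)
      sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1)))
    expect_equal(m$mean, mu, tolerance = 1e-12)
    expect_equal(m$sd, sdev, tolerance = 1e-12)
  }
})

test_that("z-maps standardize against the normative model", {
  ctrl <- list(make_table(matrix(10, 2, 5)), make_table(matrix(20, 2, 5)))
  m <- fit_normative(ctrl)
  at_mean <- make_table(matrix(15, 2, 5))
  zm <- compute_zmap(at_mean, m)
  expect_equal(max(abs(zm$z)), 0)
  expect_false(any(zm$significant))

  m$mean[] <- 15; m$sd[] <- 5
  subj <- make_table(matrix(15, 2, 5))
  subj[1, "theta"] <- 25
  zm2 <- compute_zmap(subj, m)
  expect_equal(unname(zm2$z["C3", "theta"]), 2)
  expect_true(zm2$significant["C3", "theta"])
  expect_equal(sum(zm2$significant), 1)

  wrong <- make_table(matrix(15, 2, 5), labels = c("F3", "F4"))
  expect_error(compute_zmap(wrong, m), "montage")
})

test_that("negating the deviation from the mean negates every z", {
  set.seed(12)
  m <- fit_normative(lapply(1:5, function(i)
    make_table(matrix(runif(10, 10, 30), 2, 5))))
  dev <- matrix(rnorm(10), 2, 5)
  zp <- compute_zmap(make_table(m$mean + dev), m)$z
  zn <- compute_zmap(make_table(m$mean - dev), m)$z
  expect_equal(zp, -zn, tolerance = 1e-12)
})

test_that("the prevailing rhythm is the maximal significant excess", {
  m <- fit_normative(list(make_table(matrix(10, 2, 5)),
                          make_table(matrix(20, 2, 5))))
  m$mean[] <- 15; m$sd[] <- 5
  subj <- make_table(matrix(15, 2, 5))
  subj[1, "theta"] <- 30
  pr <- prevailing_rhythm(compute_zmap(subj, m))
  expect_true(pr$found)
  expect_equal(pr$band, "theta")
  expect_equal(pr$electrode, "C3")
  expect_equal(pr$z, 3)

  none <- prevailing_rhythm(compute_zmap(make_table(matrix(15, 2, 5)), m))
  expect_false(none$found)
  # a strong *deficit* is not a target
  deficit <- make_table(matrix(15, 2, 5)); deficit[1, "beta"] <- 0
  expect_false(prevailing_rhythm(compute_zmap(deficit, m))$found)
})

test_that("prevailing-rhythm ties break by band order then montage order", {
  m <- fit_normative(list(make_table(matrix(10, 2, 5)),
                          make_table(matrix(20, 2, 5))))
  m$mean[] <- 15; m$sd[] <- 5
  subj <- make_table(matrix(15, 2, 5))
  subj[1, "beta"] <- 30; subj[2, "delta"] <- 30   # equal z = 3
  pr <- prevailing_rhythm(compute_zmap(subj, m))
  expect_equal(pr$band, "delta")                  # delta precedes beta
  subj2 <- make_table(matrix(15, 2, 5))
  subj2[, "theta"] <- 30                          # tie within one band
  expect_equal(prevailing_rhythm(compute_zmap(subj2, m))$electrode, "C3")
})

test_that("the frequency rule is total over bands and sites map to mastoids", {
  mk <- function(band, el) structure(list(found = TRUE, band = band,
                                          electrode = el, z = 3),
                                     class = "prevailing_rhythm")
  for (b in c("delta", "theta", "alpha1"))
    expect_equal(plan_stimulation(mk(b, "C3"))$frequency_hz, 30)
  for (b in c("alpha2", "beta"))
    expect_equal(plan_stimulation(mk(b, "C3"))$frequency_hz, 4)

  p <- plan_stimulation(mk("theta", "F3"))
  expect_equal(p$anode, "F3"); expect_equal(p$cathode, "M1")
  expect_equal(p$band_class, "slow-excess")
  expect_equal(plan_stimulation(mk("alpha1", "C4"))$cathode, "M2")
  expect_equal(plan_stimulation(mk("beta", "Cz"))$cathode, "Fz")
  expect_equal(plan_stimulation(mk("alpha2", "Pz"))$cathode, "Cz")
  expect_equal(plan_stimulation(mk("theta", "CP5"))$cathode, "M1")
  expect_equal(plan_stimulation(mk("theta", "P8"))$cathode, "M2")
  # manual override
  expect_equal(plan_stimulation(mk("theta", "C3"), cathode = "CP5")$cathode,
               "CP5")
  expect_equal(p$amplitude_ma, c(1, 2))
})

test_that("a no-target rhythm yields an explicit idle plan", {
  none <- structure(list(found = FALSE, band = NA_character_,
                         electrode = NA_character_, z = NA_real_),
                    class = "prevailing_rhythm")
  plan <- plan_stimulation(none)
  expect_equal(plan$mode, "none")
  path <- tempfile(fileext = ".json")
  write_plan_json(plan, path)
  expect_equal(jsonlite::read_json(path)$mode, "none")
})

test_that("published tailoring assignments follow the decision rule", {
  tab <- tailoring_table()
  expect_equal(nrow(tab), 15)
  expect_equal(tab$derived_frequency_hz, tab$stim_frequency_hz)
  expect_equal(tab$derived_frequency_hz[tab$prevailing_band == "theta"],
               rep(30, sum(tab$prevailing_band == "theta")))
  expect_equal(tab$derived_frequency_hz[c(8, 9, 14, 15)], rep(4, 4))
})

test_that("tACS waveforms are clean sinusoids at the planned frequency", {
  mk <- structure(list(found = TRUE, band = "theta", electrode = "C3", z = 3),
                  class = "prevailing_rhythm")
  plan <- plan_stimulation(mk)
  w <- synthesize_waveform(plan, duration_s = 1, fs = 1000, amplitude_ma = 1)
  ups <- sum(w[-1] > 0 & w[-length(w)] <= 0)
  expect_equal(ups, 30)
  expect_lte(max(abs(w)), 1)
  expect_error(synthesize_waveform(plan, 1, fs = 50), "twice")
  expect_error(synthesize_waveform(plan, 1, fs = 1000, amplitude_ma = 3),
               "range")
})

test_that("random-noise stimulation is bounded and spectrally spread", {
  mk <- structure(list(found = TRUE, band = "theta", electrode = "C3", z = 3),
                  class = "prevailing_rhythm")
  plan <- plan_stimulation(mk, mode = "RNS")
  w <- synthesize_waveform(plan, duration_s = 30, fs = 500, seed = 4)
  expect_lte(max(abs(w)), 2)
  expect_identical(w, synthesize_waveform(plan, 30, 500, seed = 4))
  ps <- epoch_psd(segment_epochs(recording(rbind(w, w), 500, c("a", "b"))))
  frac <- ps$psd[1, ] / sum(ps$psd[1, ])
  expect_lt(max(frac), 0.10)
  expect_error(synthesize_waveform(plan, 1, fs = 150), "200 Hz")
})

test_that("the full pipeline recovers a strong planted anomaly", {
  spec <- short_spec(duration_s = 40)
  ctrl <- generate_control_cohort(8, spec, seed = 60)
  model <- fit_normative(lapply(ctrl, band_power))
  rec <- generate_recording(spec, anomaly_spec("alpha2", "Pz", 3), seed = 61)
  pr <- prevailing_rhythm(compute_zmap(band_power(rec), model))
  plan <- plan_stimulation(pr)
  expect_equal(pr$band, "alpha2")
  expect_equal(pr$electrode, "Pz")
  expect_equal(plan$frequency_hz, 4)
  expect_equal(plan$cathode, "Cz")
})
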