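test_that("ROI power is the mean of member electrodes, per band", {
  labels <- default_montage()
  m <- matrix(0, length(labels), 5,
              dimnames = list(labels, band_scheme()$band))
  m[, ] <- 10
  m["Fp2", 1] <- 10; m["F8", 1] <- 20; m["F4", 1] <- 30
  tab <- structure(m, class = "band_power_table")
  rp <- roi_band_power(tab)
  expect_equal(unname(rp["right_frontal", "delta"]), 20)

  uni <- structure(matrix(7, length(labels), 5,
                          dimnames = dimnames(m)),
                   class = "band_power_table")
  expect_true(all(roi_band_power(uni) == 7))
})

test_that("ROI power matches a brute-force recomputation on random tables", {
  labels <- default_montage()
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(runif(length(labels) * 5, 0, 40), length(labels), 5,
                dimnames = list(labels, band_scheme()$band))
    rp <- roi_band_power(structure(m, class = "band_power_table"))
    for (roi in names(roi_scheme())) {
      els <- roi_scheme()[[roi]]
      manual <- sapply(seq_len(5), function(b) {
        s <- 0
        for (e in els) s <- s + m[e, b]
        s / length(els)
      })
      expect_equal(unname(rp[roi, ]), manual, tolerance = 1e-12)
    }
  }
})

test_that("missing ROI electrodes are reported by name", {
  m <- matrix(1, 2, 5, dimnames = list(c("C3", "C4"), band_scheme()$band))
  expect_error(roi_band_power(structure(m, class = "band_power_table")),
               "Fp1|FC1")
})

test_that("identical samples give the degenerate signed-rank result", {
  x <- c(3, 5, 2, 8)
  res <- paired_wilcoxon(x, x)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
  expect_equal(res$n_used, 0)
})

test_that("all-positive differences of 1..6 give exact p = 0.03125", {
  res <- paired_wilcoxon(c(1, 2, 3, 4, 5, 6), rep(0, 6))
  expect_equal(res$p, 0.03125, tolerance = 1e-12)
  expect_equal(res$statistic, 21)
  expect_equal(res$method, "exact")
})

test_that("exact p equals full sign-pattern enumeration for n <= 10", {
  set.seed(77)
  for (n in c(3, 5, 7, 10)) {
    for (rep in 1:8) {
      d <- round(rnorm(n, 0.3, 1), 6)
      while (anyDuplicated(abs(d)) || any(d == 0))
        d <- round(rnorm(n, 0.3, 1), 6)
      res <- paired_wilcoxon(d, rep(0, n))
      expect_equal(res$p, enumerate_signed_rank_p(d), tolerance = 1e-12)
    }
  }
})

test_that("the test agrees with the reference implementation when tie-free", {
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- paired_wilcoxon(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE,
                              conf.int = TRUE)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-9)
    expect_equal(ours$ci_low, unname(ref$conf.int[1]), tolerance = 1e-9)
    expect_equal(ours$ci_high, unname(ref$conf.int[2]), tolerance = 1e-9)
  }
})

test_that("ties fall back to the corrected normal approximation", {
  x <- c(2, 2, 3, 3, 5, 6, 7, 7)
  res <- paired_wilcoxon(x, rep(0, 8))
  expect_equal(res$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, exact = FALSE,
                                             correct = TRUE))
  expect_equal(res$p, unname(ref$p.value), tolerance = 1e-9)
})

test_that("the p-value is symmetric in the order of the samples", {
  set.seed(4)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(paired_wilcoxon(x, y)$p, paired_wilcoxon(y, x)$p,
               tolerance = 1e-12)
})

test_that("shifting all differences moves the estimate, not the ranks", {
  set.seed(6)
  d <- rnorm(10)
  base <- paired_wilcoxon(d, rep(0, 10))
  shifted <- paired_wilcoxon(d + 5, rep(0, 10))
  expect_equal(shifted$estimate, base$estimate + 5, tolerance = 1e-9)
  # one-sided evidence in the positive direction can only grow
  expect_gte(base$statistic + 1e-9, 0)
  expect_gte(shifted$statistic, base$statistic)
})

test_that("Hodges-Lehmann point estimates are Walsh-average medians", {
  hl <- hodges_lehmann_ci(c(1, 3))
  expect_equal(hl$estimate, 2)           # Walsh averages {1, 2, 3}
  hlc <- hodges_lehmann_ci(rep(4, 5))
  expect_equal(hlc$estimate, 4)
  expect_equal(hlc$lower, 4); expect_equal(hlc$upper, 4)
  expect_error(hodges_lehmann_ci(1), "2 differences")

  set.seed(9)
  for (rep in 1:10) {
    d <- rnorm(8)
    w <- c()
    for (i in 1:8) for (j in i:8) w <- c(w, (d[i] + d[j]) / 2)
    expect_length(w, 36)
    expect_equal(hodges_lehmann_ci(d)$estimate, median(w),
                 tolerance = 1e-12)
  }
})

test_that("confidence intervals bracket the estimate and respect order", {
  set.seed(10)
  for (rep in 1:10) {
    d <- rnorm(12, 1)
    hl <- hodges_lehmann_ci(d)
    expect_lte(hl$lower, hl$estimate)
    expect_lte(hl$estimate, hl$upper)
    wide <- hodges_lehmann_ci(d, level = 0.99)
    expect_lte(wide$lower, hl$lower)
    expect_gte(wide$upper, hl$upper)
  }
})

test_that("crossover analysis runs all default contrasts per measure", {
  spec <- outcome_spec(n_subjects = 12)
  tab <- generate_outcomes(spec, seed = 8)
  res <- crossover_analysis(tab)
  expect_equal(nrow(res), 8)
  expect_setequal(res$contrast,
                  sapply(tacstailor:::default_contrasts(), `[[`, "label"))
  expect_true(all(res$n_pairs == 12))
})

test_that("contrasts without enough complete pairs are skipped with a warning", {
  spec <- outcome_spec(n_subjects = 6)
  tab <- generate_outcomes(spec, seed = 9)
  only_t0 <- tab[tab$timepoint == "T0", ]
  only_t0$measure <- "MoCA"
  tab2 <- rbind(tab, only_t0)
  w <- capture_warnings(res <- crossover_analysis(tab2))
  expect_length(w, 8)                     # one per skipped contrast
  expect_true(all(grepl("MoCA", w)))
  expect_equal(sum(res$measure == "MoCA"), 0)
  expect_equal(sum(res$measure == "VAS"), 8)
})

test_that("a planted tACS effect is detected with high power at n = 14", {
  eff <- data.frame(measure = "VAS", condition = "tACS", timepoint = "T1",
                    shift = -2)
  spec <- outcome_spec(n_subjects = 14, effects = eff, noise_sd = 1)
  hits <- 0; n_rep <- 200
  for (i in seq_len(n_rep)) {
    res <- crossover_analysis(generate_outcomes(spec, seed = 20000 + i))
    hits <- hits + (res$p[res$contrast == "tACS: T0 vs T1"] < 0.05)
  }
  expect_gte(hits / n_rep, 0.80)
})
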