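tm <- c(0, 60, 120, 180, 240, 270, 300, 360)

test_that("the product slope recovers an exact line and a constant", {
  s <- enrichment_series("a", "blood_gsh", tm, 1.15e-4 * tm)
  expect_equal(fit_product_slope(s)$K, 1.15e-4, tolerance = 1e-12)
  expect_equal(fit_product_slope(s, force_zero_intercept = TRUE)$K,
               1.15e-4, tolerance = 1e-12)
  s1 <- enrichment_series("a", "blood_gsh", c(60, 120, 180), rep(0.01, 3))
  expect_equal(fit_product_slope(s1)$K, 0, tolerance = 1e-15)
})

test_that("below-LOQ points are excluded but the baseline is kept", {
  vals <- 1.15e-4 * tm
  vals[2] <- 0.001                       # corrupt the 60-min point
  s <- apply_loq_filter(enrichment_series("a", "blood_gsh", tm, vals), 0.003)
  expect_true(s$below_loq[2])
  K <- fit_product_slope(s)$K
  expect_equal(K, 1.15e-4, tolerance = 1e-10)  # fit unaffected by the bad point
  few <- apply_loq_filter(
    enrichment_series("a", "blood_gsh", c(0, 60, 120),
                      c(0, 0.001, 0.002)), 0.003)
  expect_error(fit_product_slope(few), "at least 3 usable")
})

test_that("OLS slope is unbiased on a noisy line (Monte Carlo)", {
  set.seed(42)
  Ks <- replicate(1000, {
    y <- 1.15e-4 * tm + c(0, stats::rnorm(7, 0, 0.005))
    y <- pmax(y, -0.05)
    fit_product_slope(enrichment_series("a", "blood_gsh", tm, y))$K
  })
  expect_lt(abs(mean(Ks) / 1.15e-4 - 1), 0.02)
})

test_that("a negative slope is reported with a warning", {
  s <- enrichment_series("a", "blood_gsh", c(60, 120, 180, 240),
                         c(0.03, 0.02, 0.01, 0.005))
  expect_warning(out <- fit_product_slope(s), "negative")
  expect_lt(out$K, 0)
})

test_that("FSR = 1440 K / Ep reproduces the printed group values", {
  # burned group: printed slope and inverted plateau give the printed FSR
  expect_equal(round(fsr_whole_blood(K = 1.15e-4, Ep = 0.4330), 2), 0.38)
  # sham analogue lands within 2% of the printed 0.46 (group-mean rounding)
  fsr_sham <- fsr_whole_blood(K = 2.09e-4, Ep = 0.6653)
  expect_equal(round(fsr_sham, 3), 0.452)
  expect_lt(abs(fsr_sham - 0.46) / 0.46, 0.02)
  expect_identical(fsr_whole_blood(0, 0.5), 0)
  expect_error(fsr_whole_blood(1e-4, 0), "Ep")
})

test_that("blood ASR is the exact per-animal product FSR x concentration", {
  expect_equal(asr_whole_blood(0.38, 1263.8), 480.244)
  expect_identical(asr_whole_blood(0, 1500), 0)
  expect_identical(asr_whole_blood(1, 1), 1)
  expect_error(asr_whole_blood(0.4, -5), ">= 0")
})

test_that("noiseless simulated animals return the true FSR to 1e-9", {
  for (g in c("sham", "burn")) {
    truth_fsr <- default_truth_from_tables()[[g]]$fsr_blood
    r <- analyze_animal(noiseless_animal(g))
    expect_equal(r$FSR_blood, truth_fsr, tolerance = 1e-9)
  }
})
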