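# build a scan whose M+1 fraction is exactly `frac` (M0 intensity 1)
scan_with_fraction <- function(frac, time, scale = 1) {
  sim_scan(m0 = scale, m1 = scale * frac / (1 - frac), sample_time = time)
}

test_that("compute_mre inverts forward-constructed intensities", {
  r0 <- 0.012                          # natural-abundance baseline fraction
  truth <- c(0, 0.05, 0.1, 0.2, 0.4)
  times <- c(0, 60, 120, 240, 360)
  baseline <- scan_with_fraction(r0, 0)
  scans <- Map(function(e, t) scan_with_fraction(e + r0, t), truth, times)
  s <- compute_mre(scans, baseline, tracer_channel = 1, animal_id = "a")
  expect_equal(s$values, truth, tolerance = 1e-12)
  expect_identical(s$values[1], 0)     # baseline subtraction identity
})

test_that("compute_mre does simple baseline-subtracted ratio arithmetic", {
  b <- scan_with_fraction(0.010, 0)
  s <- compute_mre(list(scan_with_fraction(0.060, 120)), b)
  expect_equal(s$values, 0.050, tolerance = 1e-12)
})

test_that("enrichment is invariant to uniform intensity scaling within a scan", {
  b <- scan_with_fraction(0.01, 0)
  for (scale in c(1e-3, 1, 1e6)) {
    s <- compute_mre(list(scan_with_fraction(0.2, 60, scale = scale)), b)
    expect_equal(s$values, 0.19, tolerance = 1e-12)
  }
})

test_that("a zero M0 intensity is rejected", {
  expect_error(sim_scan(m0 = 0, m1 = 5), "M0")
  expect_error(sim_scan(m0 = 1, m1 = -1), ">= 0")
})

test_that("LOQ flagging marks sub-LOQ points, preserves values, exempts baseline", {
  s <- enrichment_series("a", "blood_gsh", c(0, 60, 120, 180),
                         c(0, 0.001, 0.004, 0.02))
  f <- apply_loq_filter(s, loq = 0.003)
  expect_identical(f$below_loq, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(f$values, s$values)
  expect_identical(apply_loq_filter(s, loq = 0)$below_loq, rep(FALSE, 4))
  z <- enrichment_series("a", "blood_gsh", c(0, 60, 120), rep(0, 3))
  expect_identical(apply_loq_filter(z, 0.003)$below_loq,
                   c(FALSE, TRUE, TRUE))
  expect_error(apply_loq_filter(s, loq = -0.001), ">= 0")
})

test_that("isotope-dilution quantification follows the internal-standard ratio", {
  # equal signals: concentration is is_amount / volume
  expect_equal(quantify_gsh_concentration(1, 1, 0.05, sample_volume = 50e-6),
               1000)
  # ratio chosen to land on a realistic whole-blood value
  expect_equal(quantify_gsh_concentration(1.486, 1, 0.05,
                                          sample_volume = 50e-6), 1486)
  expect_equal(quantify_gsh_concentration(2, 1, 0.3, sample_mass = 0.3), 2)
  expect_error(quantify_gsh_concentration(1, 0, 0.05, sample_volume = 1e-3),
               "internal-standard")
  expect_error(quantify_gsh_concentration(1, 1, 0.05), "exactly one")
})

test_that("quantification is linear in signal and amount, inverse in sample size", {
  base <- quantify_gsh_concentration(1.2, 1, 0.05, sample_volume = 50e-6)
  expect_equal(quantify_gsh_concentration(2.4, 1, 0.05,
                                          sample_volume = 50e-6), 2 * base)
  expect_equal(quantify_gsh_concentration(1.2, 1, 0.10,
                                          sample_volume = 50e-6), 2 * base)
  expect_equal(quantify_gsh_concentration(1.2, 1, 0.05,
                                          sample_volume = 25e-6), 2 * base)
})
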