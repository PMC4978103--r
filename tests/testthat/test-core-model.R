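test_that("constructors enforce the domain invariants", {
  expect_error(infusion_protocol(isotopic_abundance = 0), "Ei")
  expect_error(infusion_protocol(isotopic_abundance = 1.2), "Ei")
  expect_error(infusion_protocol(infusion_rate = -1), "infusion_rate")
  expect_error(infusion_protocol(sampling_times = c(0, 60, 60)),
               "strictly increasing")
  expect_error(infusion_protocol(sampling_times = c(0, 400), duration = 360),
               "within")

  expect_error(enrichment_series("a", "plasma_cysteine", 1:3, 1:2),
               "same length")
  expect_error(enrichment_series("a", "plasma_cysteine", c(0, 60),
                                 c(0.1, 0.2)),
               "baseline")
  expect_error(enrichment_series("a", "plasma_cysteine", c(0, 60),
                                 c(0, 1.5)),
               "mole-fraction")
  # small negatives from baseline subtraction are legal
  s <- enrichment_series("a", "blood_gsh", c(0, 60), c(0, -0.01))
  expect_s3_class(s, "enrichment_series")

  expect_error(organ_sample("spleen", 0.4, 0.2, 1.0), "should be one of")
  expect_error(organ_sample("liver", 0.4, 0.2, -1), "gsh_concentration")
  expect_error(organ_sample("liver", 0.4, 0.2, 1.0, t_end = 0), "t_end")
})

test_that("animal_dataset requires series on the protocol's schedule", {
  p <- infusion_protocol()
  t <- p$sampling_times
  mk <- function(analyte, tt = t) {
    enrichment_series("a1", analyte, tt, rep(0, length(tt)))
  }
  expect_s3_class(
    animal_dataset("a1", "sham", 2.7, p, mk("plasma_cysteine"),
                   mk("blood_gsh"), 1486),
    "animal_dataset")
  off <- enrichment_series("a1", "blood_gsh", c(0, 30, 90), rep(0, 3))
  expect_error(
    animal_dataset("a1", "sham", 2.7, p, mk("plasma_cysteine"), off, 1486),
    "sampling times")
  expect_error(
    animal_dataset("a1", "other", 2.7, p, mk("plasma_cysteine"),
                   mk("blood_gsh"), 1486),
    "should be one of")
})

test_that("cohort_dataset rejects duplicate animal ids", {
  a <- noiseless_animal("sham")
  expect_error(cohort_dataset(list(a, a)), "duplicate")
})

test_that("rate unit conversions round-trip exactly", {
  x <- c(1e-4, 0.38, 5.86, 29.3)
  expect_equal(per_day_to_per_min(per_min_to_per_day(x)), x,
               tolerance = 1e-15)
  expect_equal(per_hour_to_per_min(per_min_to_per_hour(x)), x,
               tolerance = 1e-15)
  expect_equal(per_min_to_per_day(1), 1440)
  expect_equal(per_min_to_per_hour(1), 60)
})
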