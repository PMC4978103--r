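test_that("noiseless sham plasma plateau matches the dilution equation and a one-pool ODE oracle", {
  a <- noiseless_animal("sham")
  win <- a$plasma_series$values[a$plasma_series$times >= 120]
  Ep_expected <- 0.99 / (29.3 / 60 + 1)   # invert Q = 60 i (Ei/Ep - 1)
  expect_equal(unique(win), Ep_expected, tolerance = 1e-12)
  expect_equal(Ep_expected, 0.6652, tolerance = 1e-4)
  # independent check: numerically integrate the primed one-pool system
  ode <- plasma_ode_oracle(Q = 29.3, i = 1.0, Ei = 0.99, t = 120,
                           lambda = log(100) / 60, prime_fraction = 1)
  expect_equal(ode, Ep_expected, tolerance = 1e-4)
})

test_that("an underprimed infusion follows the rising exponential, checked against the ODE oracle", {
  tr <- sham_truth()
  a <- simulate_animal("s", "sham", tr, sham_protocol(),
                       prime_fraction = 0.5)
  Ep <- 0.99 / (29.3 / 60 + 1)
  lam <- log(100) / 60
  tm <- a$plasma_series$times[-1]
  expect_equal(a$plasma_series$values[-1],
               Ep * (1 - 0.5 * exp(-lam * tm)), tolerance = 1e-12)
  ode <- plasma_ode_oracle(29.3, 1.0, 0.99, t = 60, lambda = lam,
                           prime_fraction = 0.5)
  expect_equal(ode, Ep * (1 - 0.5 * exp(-lam * 60)), tolerance = 1e-3)
})

test_that("zero blood FSR gives an identically zero product series", {
  tr <- sham_truth()
  tr$fsr_blood <- 0
  a <- simulate_animal("s", "sham", tr, sham_protocol())
  expect_identical(unique(a$blood_gsh_series$values), 0)
})

test_that("organ labeling follows single-exponential kinetics (closed form and numerical integration)", {
  tr <- burn_truth()
  a <- simulate_animal("b", "burn", tr, burn_protocol())
  liver <- a$organ_samples[[which(vapply(a$organ_samples, `[[`,
                                         character(1), "tissue") == "liver")]]
  # burned liver k = 3.76/day over 360 min = 0.25 day
  expect_equal(liver$Et / liver$Eo, 1 - exp(-3.76 * 0.25), tolerance = 1e-12)
  expect_equal(round(liver$Et / liver$Eo, 4), 0.6094)
  ode <- organ_ode_oracle(3.76, liver$Eo, 360)
  expect_equal(liver$Et, ode, tolerance = 1e-3)
})

test_that("invalid truth parameters are rejected", {
  tr <- sham_truth()
  tr$Q <- -1
  expect_error(simulate_animal("s", "sham", tr, sham_protocol()), "positive")
  tr <- sham_truth()
  expect_error(simulate_animal("s", "sham", tr, sham_protocol(),
                               prime_fraction = 0), "prime_fraction")
})

test_that("default truth reproduces the published group means", {
  tr <- default_truth_from_tables()
  expect_equal(tr$burn$fsr_blood, 0.38)
  expect_equal(tr$sham$Q, 29.3)
  expect_equal(tr$burn$Q, 65.6)
  org <- function(g, t) tr[[g]]$organs[tr[[g]]$organs$tissue == t, ]
  expect_equal(org("sham", "liver")$conc, 2.00)
  expect_equal(org("sham", "kidney")$k, 3.58)
  expect_equal(org("burn", "liver")$k, 3.76)
  expect_true(is.na(org("burn", "muscle")$k))
})

test_that("simulation is deterministic given the seed", {
  c1 <- simulate_cohort(seed = 11)
  c2 <- simulate_cohort(seed = 11)
  attr(c1, "truth") <- attr(c2, "truth") <- NULL
  expect_identical(c1, c2)
  c3 <- simulate_cohort(seed = 12)
  expect_false(identical(c1$animals[[1]]$plasma_series$values,
                         c3$animals[[1]]$plasma_series$values))
})

test_that("burned muscle carries no reliable determination and is excluded downstream", {
  co <- simulate_cohort(seed = 3)
  burn <- Filter(function(a) a$group == "burn", co$animals)
  for (a in burn) {
    mus <- Filter(function(s) s$tissue == "muscle", a$organ_samples)[[1]]
    expect_true(is.na(mus$Et))
    expect_true(is.na(mus$gsh_concentration))
  }
  cmp <- run_pipeline(co)$comparisons
  mus_k <- cmp[cmp$variable == "muscle_k", ]
  expect_equal(mus_k$burn_n, 0)
  expect_true(is.na(mus_k$burn_mean))
})

test_that("noiseless simulate -> estimate round-trips over a grid of truths", {
  for (Q in c(10, 29.3, 65.6, 120)) {
    for (fsr in c(0.1, 0.38, 2)) {
      tr <- sham_truth()
      tr$Q <- Q; tr$fsr_blood <- fsr
      tr$organs$k <- c(0.2, 1.54, 5, 9.5)
      a <- simulate_animal("s", "sham", tr, sham_protocol())
      r <- analyze_animal(a)
      expect_equal(r$Q_cys, Q, tolerance = 1e-9)
      expect_equal(r$FSR_blood, fsr, tolerance = 1e-9)
      expect_equal(r$organs$k, tr$organs$k, tolerance = 1e-9)
    }
  }
})

test_that("moderate-noise cohorts keep group means near the generating truth", {
  set.seed(99)
  fsr_sham <- replicate(20, {
    b <- run_pipeline(simulate_cohort(seed = sample.int(1e6, 1)))
    b$comparisons[b$comparisons$variable == "fsr_blood", "sham_mean"]
  })
  # cohort-mean sd ~ 0.46 * 0.25 / sqrt(7); 20 cohorts pin the mean to ~2%
  expect_lt(abs(mean(fsr_sham) - 0.46) / 0.46, 0.06)
})

test_that("simulated plasma series pass the plateau check in nearly all animals", {
  set.seed(7)
  pass <- 0L; n <- 0L
  for (i in 1:10) {
    co <- simulate_cohort(seed = 200 + i)
    for (a in co$animals) {
      n <- n + 1L
      if (check_plateau(a$plasma_series)$is_plateau) pass <- pass + 1L
    }
  }
  expect_gte(pass / n, 0.9)
})
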