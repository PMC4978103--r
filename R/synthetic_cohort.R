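#' Group-level true parameters for the simulated experiment
#'
#' The simulator is parameterised by the group means of the sham-burn/burn
#' rabbit study: plasma cysteine flux, targeted tracer infusion rate,
#' whole-blood GSH fractional synthesis rate and concentration, and per-organ
#' GSH fractional synthesis rate and concentration. [default_truth_from_tables()]
#' returns the published group means; burned skeletal muscle carries `NA`
#' truth because no reliable determination exists for it — the simulator
#' emits an unlabeled, unquantifiable sample that downstream stages flag
#' and exclude.
#'
#' @param sham,burn Per-group lists with elements `Q` (umol/kg/h),
#'   `infusion_rate` (umol/kg/min), `fsr_blood` (per day), `c_blood`
#'   (umol/l), `body_weight` (kg), and `organs`, a data frame with columns
#'   `tissue`, `k` (per day), `conc` (umol/g).
#' @return Object of class `group_truth_params`.
#' @export
group_truth_params <- function(sham, burn) {
  for (g in list(sham, burn)) {
    stopifnot(is.list(g), is.data.frame(g$organs),
              all(c("tissue", "k", "conc") %in% names(g$organs)))
    pos <- c(g$Q, g$infusion_rate, g$fsr_blood, g$c_blood, g$body_weight)
    if (any(pos <= 0, na.rm = TRUE)) {
      stop("truth parameters must be positive", call. = FALSE)
    }
    if (any(c(g$organs$k, g$organs$conc) <= 0, na.rm = TRUE)) {
      stop("organ truth parameters must be positive", call. = FALSE)
    }
    if (!all(g$organs$tissue %in% TISSUES)) {
      stop("unknown tissue in organ truth table", call. = FALSE)
    }
  }
  structure(list(sham = sham, burn = burn), class = "group_truth_params")
}

#' Published group means as simulation truth
#'
#' @return A [group_truth_params()] whose values are the printed group means
#'   of the tracer study: sham flux 29.3 and burned 65.6 umol/kg/h at
#'   targeted infusion rates 1.0 and 0.85 umol/kg/min; blood FSR 0.46 vs
#'   0.38 per day at 1486.0 vs 1263.8 umol/l; per-organ (liver, lung,
#'   kidney, muscle) FSR and concentration, with burned muscle `NA`.
#' @export
default_truth_from_tables <- function() {
  group_truth_params(
    sham = list(
      Q = 29.3, infusion_rate = 1.0, fsr_blood = 0.46, c_blood = 1486.0,
      body_weight = 2.7,
      organs = data.frame(
        tissue = c("liver", "lung", "kidney", "muscle"),
        k = c(5.86, 1.54, 3.58, 2.00),
        conc = c(2.00, 1.15, 0.20, 1.00),
        stringsAsFactors = FALSE)),
    burn = list(
      Q = 65.6, infusion_rate = 0.85, fsr_blood = 0.38, c_blood = 1263.8,
      body_weight = 2.5,
      organs = data.frame(
        tissue = c("liver", "lung", "kidney", "muscle"),
        k = c(3.76, 0.51, 4.06, NA_real_),
        conc = c(0.61, 0.79, 0.25, NA_real_),
        stringsAsFactors = FALSE)))
}

#' Measurement and between-animal noise model
#'
#' @param ms_read_sd Absolute standard deviation of a mass-spectrometric
#'   enrichment read, mole-fraction excess. Default 0.005 (a stated
#'   assumption of the simulator; within-replicate variance is not
#'   published).
#' @param animal_cv Coefficient of variation of per-animal true rates
#'   (flux, FSRs), applied as mean-one lognormal factors so rates stay
#'   positive. Default 0.25.
#' @param concentration_cv CV of per-animal GSH concentrations, same
#'   lognormal scheme. Default 0.20.
#' @param seed Optional integer seed recorded with the model; used by
#'   [simulate_cohort()] when no explicit seed is given.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(ms_read_sd = 0.005, animal_cv = 0.25,
                        concentration_cv = 0.20, seed = NULL) {
  if (ms_read_sd < 0 || animal_cv < 0 || concentration_cv < 0) {
    stop("noise sds/cvs must be >= 0", call. = FALSE)
  }
  structure(list(ms_read_sd = ms_read_sd, animal_cv = animal_cv,
                 concentration_cv = concentration_cv, seed = seed),
            class = "noise_model")
}

#' Zero-noise model (exact forward simulation)
#' @return A [noise_model()] with all sds/cvs 0.
#' @export
noise_free <- function() noise_model(0, 0, 0)

# mean-one lognormal multiplicative factor(s) with coefficient of variation cv
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# tissue free-cysteine enrichment sits below the plasma plateau; these
# dilution factors scale Ep to the organ precursor pools
DEFAULT_TISSUE_FACTORS <- c(liver = 0.60, lung = 0.55, kidney = 0.70,
                            muscle = 0.45)

#' Simulate one animal's tracer study
#'
#' Forward model of the primed constant infusion:
#' \itemize{
#'   \item Plasma precursor: one-pool kinetics. The plateau is
#'     `Ep = Ei / (Q/(60 i) + 1)` (steady-state dilution). The priming bolus
#'     covers a fraction `prime_fraction` of the ideal prime; the enrichment
#'     approaches plateau as
#'     `E(t) = Ep (1 - (1 - prime_fraction) exp(-lambda t))`. The default
#'     `prime_fraction = 1` is the ideally primed pool — flat at Ep from the
#'     first post-baseline sample — so noiseless data invert exactly to the
#'     truth; smaller values reproduce the rising approach curve, with
#'     `lambda` defaulting to `log(100)/60` (99% of plateau attained 60 min
#'     into an unprimed infusion).
#'   \item Whole-blood GSH: linear rise `K t` with
#'     `K = FSR x Ep / 1440`.
#'   \item Organs: single-exponential labeling
#'     `Et = Eo (1 - exp(-k t_end / 1440))` with precursor
#'     `Eo = Ep x tissue_factor`. An organ with `NA` truth (burned muscle)
#'     yields a failed determination — `NA` product enrichment and
#'     concentration — which downstream stages flag and exclude.
#' }
#' Gaussian read noise (`ms_read_sd`) is added to every measured enrichment
#' except the t = 0 baseline, which is 0 by construction.
#'
#' @param animal_id Identifier.
#' @param group `"sham"` or `"burn"`.
#' @param truth Per-animal truth: list with `Q`, `fsr_blood`, `c_blood`,
#'   `body_weight` and `organs` (data frame `tissue`, `k`, `conc`).
#' @param protocol An [infusion_protocol()]; its `infusion_rate` is the
#'   animal's tracer rate.
#' @param noise A [noise_model()]. Default [noise_free()].
#' @param prime_fraction Fraction of the ideal priming dose delivered,
#'   in (0, 1]. Default 1.
#' @param lambda Plasma pool rate constant for the unprimed component,
#'   per min. Default `log(100)/60`.
#' @param tissue_factors Named dilution factors mapping plasma plateau to
#'   organ precursor enrichment, in \[0.4, 0.9\].
#' @return An [animal_dataset()].
#' @export
simulate_animal <- function(animal_id, group, truth, protocol,
                            noise = noise_free(),
                            prime_fraction = 1,
                            lambda = log(100) / 60,
                            tissue_factors = DEFAULT_TISSUE_FACTORS) {
  stopifnot(inherits(protocol, "infusion_protocol"),
            inherits(noise, "noise_model"))
  if (any(c(truth$Q, truth$c_blood) <= 0, na.rm = TRUE) ||
      isTRUE(truth$fsr_blood < 0)) {
    stop("truth rates must be positive (blood FSR may be 0: no synthesis, no labeling)",
         call. = FALSE)
  }
  if (prime_fraction <= 0 || prime_fraction > 1) {
    stop("prime_fraction must lie in (0, 1]", call. = FALSE)
  }
  tm <- protocol$sampling_times
  Ei <- protocol$isotopic_abundance
  i  <- protocol$infusion_rate
  Ep <- plateau_from_flux(truth$Q, i, Ei)

  read_noise <- function(n) {
    if (noise$ms_read_sd == 0) rep(0, n) else stats::rnorm(n, 0, noise$ms_read_sd)
  }

  plasma <- Ep * (1 - (1 - prime_fraction) * exp(-lambda * tm))
  plasma[tm == 0] <- 0                      # pre-infusion baseline sample
  plasma <- plasma + ifelse(tm == 0, 0, read_noise(length(tm)))

  K_true <- truth$fsr_blood * Ep / MIN_PER_DAY
  gsh <- K_true * tm
  gsh <- gsh + ifelse(tm == 0, 0, read_noise(length(tm)))

  organs <- lapply(seq_len(nrow(truth$organs)), function(r) {
    row <- truth$organs[r, ]
    fac <- tissue_factors[[row$tissue]]
    Eo_true <- Ep * fac
    if (is.na(row$k)) {
      # failed determination: no reliable product enrichment or pool size
      organ_sample(row$tissue, Eo = Eo_true + read_noise(1), Et = NA_real_,
                   gsh_concentration = NA_real_,
                   t_end = protocol$duration)
    } else {
      Et_true <- Eo_true * (1 - exp(-row$k * protocol$duration / MIN_PER_DAY))
      organ_sample(row$tissue,
                   Eo = Eo_true + read_noise(1),
                   Et = Et_true + read_noise(1),
                   gsh_concentration = row$conc,
                   t_end = protocol$duration)
    }
  })

  animal_dataset(
    animal_id = animal_id, group = group,
    body_weight = truth$body_weight, protocol = protocol,
    plasma_series = enrichment_series(animal_id, "plasma_cysteine", tm,
                                      pmin(pmax(plasma, -0.05), 1)),
    blood_gsh_series = enrichment_series(animal_id, "blood_gsh", tm,
                                         pmin(pmax(gsh, -0.05), 1)),
    blood_gsh_concentration = truth$c_blood,
    organ_samples = organs)
}

# draw one animal's truth from the group means under the noise model
draw_animal_truth <- function(g, noise) {
  org <- g$organs
  org$k <- org$k * lognormal_factor(nrow(org), noise$animal_cv)
  org$conc <- org$conc * lognormal_factor(nrow(org), noise$concentration_cv)
  list(Q = g$Q * lognormal_factor(1, noise$animal_cv),
       fsr_blood = g$fsr_blood * lognormal_factor(1, noise$animal_cv),
       c_blood = g$c_blood * lognormal_factor(1, noise$concentration_cv),
       body_weight = g$body_weight *
         lognormal_factor(1, noise$concentration_cv / 4),
       organs = org)
}

#' Simulate a sham/burn cohort
#'
#' Draws per-animal true parameters around the group means (mean-one
#' lognormal factors, see [noise_model()]) and forward-simulates every
#' animal with [simulate_animal()]. Deterministic given `seed`.
#'
#' @param n_sham,n_burn Group sizes, each >= 2. Defaults 7 sham, 6 burn.
#' @param truth A [group_truth_params()]. Default
#'   [default_truth_from_tables()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; falls back to `noise$seed`; `NULL` leaves the
#'   RNG state untouched.
#' @param protocol_template An [infusion_protocol()] whose fields other
#'   than `infusion_rate` are shared by both groups; each group's targeted
#'   rate comes from `truth`.
#' @param prime_fraction,lambda,tissue_factors Passed to
#'   [simulate_animal()].
#' @return A [cohort_dataset()]; animal truths are attached as attribute
#'   `"truth"` (list keyed by animal id) for simulation studies.
#' @export
simulate_cohort <- function(n_sham = 7, n_burn = 6,
                            truth = default_truth_from_tables(),
                            noise = noise_model(),
                            seed = NULL,
                            protocol_template = infusion_protocol(),
                            prime_fraction = 1,
                            lambda = log(100) / 60,
                            tissue_factors = DEFAULT_TISSUE_FACTORS) {
  stopifnot(inherits(truth, "group_truth_params"))
  if (n_sham < 2 || n_burn < 2) {
    stop("group sizes must be >= 2 for downstream statistics", call. = FALSE)
  }
  seed <- if (is.null(seed)) noise$seed else seed
  if (!is.null(seed)) set.seed(seed)

  make_group <- function(gname, n) {
    g <- truth[[gname]]
    proto <- protocol_template
    proto$infusion_rate <- g$infusion_rate
    lapply(seq_len(n), function(j) {
      at <- draw_animal_truth(g, noise)
      a <- simulate_animal(sprintf("%s_%02d", gname, j), gname, at, proto,
                           noise = noise, prime_fraction = prime_fraction,
                           lambda = lambda, tissue_factors = tissue_factors)
      attr(a, "truth") <- at
      a
    })
  }
  animals <- c(make_group("sham", n_sham), make_group("burn", n_burn))
  cohort <- cohort_dataset(animals)
  truths <- lapply(animals, attr, "truth")
  names(truths) <- vapply(animals, `[[`, character(1), "animal_id")
  attr(cohort, "truth") <- truths
  cohort
}
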