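#' gshkin: stable-isotope tracer kinetics of glutathione synthesis
#'
#' Core domain objects shared by every stage of the pipeline: the infusion
#' protocol, timestamped enrichment series, endpoint organ samples, and the
#' per-animal container that holds them together with its group label.
#'
#' Unit conventions used throughout:
#' \itemize{
#'   \item enrichment: mole-fraction excess above the pre-infusion baseline,
#'     i.e. tracer/(tracer + tracee) minus its baseline value, dimensionless
#'     in \[0, 1\] (small negatives tolerated from baseline-subtraction noise);
#'   \item time: minutes internally; fractional synthesis rates reported per
#'     day (x 1440), fluxes per hour (x 60);
#'   \item concentration: umol/l for whole blood, umol/g wet tissue for organs.
#' }
#' @name gshkin-package
#' @keywords internal
"_PACKAGE"

# minutes per hour / per day: the only unit conversions in the package
MIN_PER_HOUR <- 60
MIN_PER_DAY  <- 1440

#' Analytes and tissues recognised by the pipeline
#' @keywords internal
#' @noRd
ANALYTES <- c("plasma_cysteine", "blood_gsh", "tissue_cysteine", "tissue_gsh")
TISSUES  <- c("liver", "lung", "kidney", "muscle")

#' Infusion protocol for a primed constant tracer infusion
#'
#' Describes the tracer delivery: isotopic abundance of the tracer, constant
#' infusion rate, the priming bolus expressed as minutes of infusion given
#' up-front, total duration, and the blood-sampling schedule.
#'
#' @param tracer_name Character label, e.g. `"[1-13C]cysteine"`.
#' @param isotopic_abundance Tracer isotopic abundance Ei, mole fraction in
#'   (0, 1]. Default 0.99.
#' @param infusion_rate Constant infusion rate i, umol/kg/min. Must be > 0.
#' @param prime_equivalent Priming bolus expressed as minutes of infusion
#'   delivered as a bolus at t = 0. Default 60 min.
#' @param duration Infusion duration, min. Default 360.
#' @param sampling_times Strictly increasing sampling times (min since start
#'   of infusion), all within `[0, duration]`. Default the standard schedule
#'   0, 60, 120, 180, 240, 270, 300, 360 min.
#' @return An object of class `infusion_protocol`.
#' @examples
#' p <- infusion_protocol(infusion_rate = 1.0)
#' p$sampling_times
#' @export
infusion_protocol <- function(tracer_name = "[1-13C]cysteine",
                              isotopic_abundance = 0.99,
                              infusion_rate = 1.0,
                              prime_equivalent = 60,
                              duration = 360,
                              sampling_times = c(0, 60, 120, 180, 240, 270, 300, 360)) {
  stopifnot(is.numeric(isotopic_abundance), length(isotopic_abundance) == 1L)
  if (!(isotopic_abundance > 0 && isotopic_abundance <= 1)) {
    stop("isotopic_abundance (Ei) must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(infusion_rate) || infusion_rate <= 0) {
    stop("infusion_rate must be > 0 umol/kg/min", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be > 0 min", call. = FALSE)
  }
  if (prime_equivalent < 0) stop("prime_equivalent must be >= 0", call. = FALSE)
  sampling_times <- as.numeric(sampling_times)
  if (any(diff(sampling_times) <= 0)) {
    stop("sampling_times must be strictly increasing", call. = FALSE)
  }
  if (any(sampling_times < 0) || any(sampling_times > duration)) {
    stop("sampling_times must lie within [0, duration]", call. = FALSE)
  }
  structure(
    list(tracer_name = tracer_name,
         isotopic_abundance = isotopic_abundance,
         infusion_rate = infusion_rate,
         prime_equivalent = prime_equivalent,
         duration = duration,
         sampling_times = sampling_times),
    class = "infusion_protocol")
}

#' Timestamped enrichment series for one analyte in one animal
#'
#' Values are mole-fraction excess above the pre-infusion baseline; the
#' baseline point (t = 0), when present, is 0 by construction. Small negative
#' values are tolerated (baseline-subtraction noise) down to -0.05.
#'
#' @param animal_id Identifier.
#' @param analyte One of `"plasma_cysteine"`, `"blood_gsh"`,
#'   `"tissue_cysteine"`, `"tissue_gsh"`.
#' @param times Sampling times, min.
#' @param values Mole-fraction excess enrichments, same length as `times`.
#' @param below_loq Logical flags, one per point, marking values below the
#'   limit of quantitation. Default all `FALSE`.
#' @return An object of class `enrichment_series`.
#' @export
enrichment_series <- function(animal_id, analyte, times, values,
                              below_loq = rep(FALSE, length(times))) {
  analyte <- match.arg(analyte, ANALYTES)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) != length(below_loq)) {
    stop("times, values and below_loq must have the same length", call. = FALSE)
  }
  if (any(values < -0.05 | values > 1, na.rm = TRUE)) {
    stop("enrichment values must lie in [-0.05, 1] (mole-fraction excess)",
         call. = FALSE)
  }
  if (any(times == 0) && !isTRUE(all.equal(values[times == 0], 0))) {
    stop("baseline point (t = 0) must have enrichment 0 by construction",
         call. = FALSE)
  }
  structure(
    list(animal_id = animal_id, analyte = analyte,
         times = times, values = values, below_loq = as.logical(below_loq)),
    class = "enrichment_series")
}

#' Endpoint organ sample
#'
#' Single end-of-infusion tissue record: free-precursor enrichment `Eo`
#' ([1-13C]cysteine in the tissue free amino-acid pool), product enrichment
#' `Et` ([13C-cysteine]GSH), GSH concentration per g wet tissue, and the
#' labeling duration.
#'
#' `Et` and `gsh_concentration` may be `NA` for samples where a reliable
#' determination was not possible; such samples are carried through the
#' pipeline flagged and excluded from kinetics and group summaries.
#'
#' @param tissue One of `"liver"`, `"lung"`, `"kidney"`, `"muscle"`.
#' @param Eo Precursor enrichment (mole-fraction excess), > 0 for kinetics.
#' @param Et Product enrichment at the end of infusion (mole-fraction excess).
#' @param gsh_concentration GSH concentration, umol/g wet tissue.
#' @param t_end Labeling duration, min. Default 360.
#' @param wet_weight Sample wet weight, g (recorded, not used in kinetics).
#' @return An object of class `organ_sample`.
#' @export
organ_sample <- function(tissue, Eo, Et, gsh_concentration,
                         t_end = 360, wet_weight = NA_real_) {
  tissue <- match.arg(tissue, TISSUES)
  if (!is.na(Eo) && Eo < 0) stop("Eo must be >= 0", call. = FALSE)
  if (!is.na(Et) && Et < -0.05) stop("Et must be >= 0 (noise tolerance -0.05)",
                                     call. = FALSE)
  if (!is.na(gsh_concentration) && gsh_concentration < 0) {
    stop("gsh_concentration must be >= 0", call. = FALSE)
  }
  if (t_end <= 0) stop("t_end must be > 0 min", call. = FALSE)
  structure(
    list(tissue = tissue, Eo = Eo, Et = Et,
         gsh_concentration = gsh_concentration,
         t_end = t_end, wet_weight = wet_weight),
    class = "organ_sample")
}

#' One animal's complete tracer-study measurements
#'
#' @param animal_id Identifier.
#' @param group `"sham"` or `"burn"`.
#' @param body_weight kg.
#' @param protocol An [infusion_protocol()].
#' @param plasma_series [enrichment_series()] of plasma `[1-13C]`cysteine.
#' @param blood_gsh_series [enrichment_series()] of whole-blood
#'   `[13C-cysteine]`GSH.
#' @param blood_gsh_concentration Whole-blood GSH concentration, umol/l.
#' @param organ_samples List of [organ_sample()] objects (possibly empty).
#' @return An object of class `animal_dataset`.
#' @export
animal_dataset <- function(animal_id, group, body_weight, protocol,
                           plasma_series, blood_gsh_series,
                           blood_gsh_concentration,
                           organ_samples = list()) {
  group <- match.arg(group, c("sham", "burn"))
  stopifnot(inherits(protocol, "infusion_protocol"),
            inherits(plasma_series, "enrichment_series"),
            inherits(blood_gsh_series, "enrichment_series"))
  if (!isTRUE(all.equal(plasma_series$times, protocol$sampling_times)) ||
      !isTRUE(all.equal(blood_gsh_series$times, protocol$sampling_times))) {
    stop("plasma and blood series must share the protocol's sampling times",
         call. = FALSE)
  }
  if (!all(vapply(organ_samples, inherits, logical(1), "organ_sample"))) {
    stop("organ_samples must be a list of organ_sample objects", call. = FALSE)
  }
  structure(
    list(animal_id = animal_id, group = group, body_weight = body_weight,
         protocol = protocol, plasma_series = plasma_series,
         blood_gsh_series = blood_gsh_series,
         blood_gsh_concentration = blood_gsh_concentration,
         organ_samples = organ_samples),
    class = "animal_dataset")
}

#' A cohort of animals
#'
#' @param animals List of [animal_dataset()] objects.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(animals) {
  if (!all(vapply(animals, inherits, logical(1), "animal_dataset"))) {
    stop("animals must be a list of animal_dataset objects", call. = FALSE)
  }
  ids <- vapply(animals, `[[`, character(1), "animal_id")
  if (anyDuplicated(ids)) stop("duplicate animal_id in cohort", call. = FALSE)
  structure(list(animals = animals), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  groups <- vapply(x$animals, `[[`, character(1), "group")
  cat(sprintf("<cohort_dataset> %d animals (%d sham, %d burn)\n",
              length(x$animals), sum(groups == "sham"), sum(groups == "burn")))
  invisible(x)
}

#' @export
print.enrichment_series <- function(x, ...) {
  cat(sprintf("<enrichment_series> %s / %s, %d points, t in [%g, %g] min\n",
              x$animal_id, x$analyte, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

# ---- unit conversions ------------------------------------------------------

#' Rate unit conversions
#'
#' Exact conversions between per-minute, per-hour and per-day rates
#' (factors 60 and 1440).
#'
#' @param x Numeric rate(s).
#' @return Converted rate(s).
#' @export
per_min_to_per_day <- function(x) x * MIN_PER_DAY

#' @rdname per_min_to_per_day
#' @export
per_min_to_per_hour <- function(x) x * MIN_PER_HOUR

#' @rdname per_min_to_per_day
#' @export
per_day_to_per_min <- function(x) x / MIN_PER_DAY

#' @rdname per_min_to_per_day
#' @export
per_hour_to_per_min <- function(x) x / MIN_PER_HOUR
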