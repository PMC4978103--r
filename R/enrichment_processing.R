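#' A selected-ion-monitoring scan
#'
#' Channel intensities at the nominal masses M0..M3 of the monitored
#' near-parent ion cluster (for the GSH derivative: m/z 477.1-480.1).
#'
#' @param m0,m1,m2,m3 Non-negative channel intensities; `m0` must be > 0
#'   so ratios can be formed.
#' @param sample_time Sampling time, min.
#' @return An object of class `sim_scan`.
#' @export
sim_scan <- function(m0, m1, m2 = 0, m3 = 0, sample_time = NA_real_) {
  ints <- c(m0, m1, m2, m3)
  if (any(ints < 0)) stop("channel intensities must be >= 0", call. = FALSE)
  if (m0 <= 0) stop("M0 intensity must be > 0 to form ratios", call. = FALSE)
  structure(list(m0 = m0, m1 = m1, m2 = m2, m3 = m3,
                 sample_time = sample_time),
            class = "sim_scan")
}

# tracer-channel fraction R = I(M+offset) / (I(M0) + I(M+offset));
# the mole-fraction convention adopted package-wide
scan_fraction <- function(scan, tracer_channel) {
  it <- scan[[paste0("m", tracer_channel)]]
  it / (scan$m0 + it)
}

#' Baseline-subtracted enrichment from SIM scans
#'
#' Converts raw ion intensities to mole-fraction excess: for each scan the
#' tracer-channel fraction `R = I(M+n) / (I(M0) + I(M+n))` is computed and
#' the pre-infusion baseline fraction subtracted, so the baseline scan maps
#' to 0 exactly. The tracer channel for the [1-13C]cysteine label is M+1
#' (m/z 478.1 for the GSH derivative); the doubly labeled internal standard
#' occupies M+2 and does not enter the enrichment ratio. Isotopomer overlap
#' beyond baseline subtraction is not corrected.
#'
#' @param scans List of [sim_scan()] objects, each with a `sample_time`.
#' @param baseline_scan A [sim_scan()] acquired pre-infusion.
#' @param tracer_channel Mass offset of the tracer channel (1, 2 or 3).
#'   Default 1.
#' @param animal_id,analyte Passed through to the returned series.
#' @return An [enrichment_series()] with one point per scan.
#' @export
compute_mre <- function(scans, baseline_scan, tracer_channel = 1,
                        animal_id = "unknown", analyte = "blood_gsh") {
  stopifnot(inherits(baseline_scan, "sim_scan"))
  if (!all(vapply(scans, inherits, logical(1), "sim_scan"))) {
    stop("scans must be a list of sim_scan objects", call. = FALSE)
  }
  if (!tracer_channel %in% 1:3) stop("tracer_channel must be 1, 2 or 3",
                                     call. = FALSE)
  r0 <- scan_fraction(baseline_scan, tracer_channel)
  times <- vapply(scans, `[[`, numeric(1), "sample_time")
  values <- vapply(scans, scan_fraction, numeric(1),
                   tracer_channel = tracer_channel) - r0
  enrichment_series(animal_id, analyte, times, values)
}

#' Flag enrichment points below the limit of quantitation
#'
#' The GC/MS method quantitates enrichments reliably down to 0.3-0.5 mol%
#' excess (0.003-0.005 as mole fraction). Points below the chosen LOQ are
#' flagged, not removed: values (including small negatives from baseline
#' subtraction) are preserved so downstream regression stays unbiased,
#' while flagged points are excluded from fits and summaries. The t = 0
#' baseline point is exempt — it is 0 by construction, not a measurement
#' below the limit.
#'
#' @param series An [enrichment_series()].
#' @param loq Limit of quantitation, mole-fraction excess, >= 0.
#'   Default 0.003 (0.3 mol% excess, the method's lower bound).
#' @return The series with `below_loq` flags set where `value < loq`.
#' @export
apply_loq_filter <- function(series, loq = 0.003) {
  stopifnot(inherits(series, "enrichment_series"))
  if (loq < 0) stop("loq must be >= 0", call. = FALSE)
  flags <- series$values < loq
  flags[series$times == 0] <- FALSE
  series$below_loq <- flags
  series
}

#' Isotope-dilution concentration from an internal standard
#'
#' Concentration by the internal-standard ratio method: a known amount of an
#' isotopically distinct standard (here [1,2-13C2-glycyl]GSH, two mass units
#' above the analyte) is spiked into the sample and
#' \deqn{C = (S_{analyte}/S_{IS}) \times n_{IS} / \mathrm{size}.}
#'
#' @param analyte_signal,is_signal Integrated analyte and internal-standard
#'   signals (same arbitrary units); `is_signal` must be > 0.
#' @param is_amount Amount of internal standard spiked, umol, > 0.
#' @param sample_volume Sample volume in litres (blood), or
#' @param sample_mass sample mass in grams (tissue); exactly one of the two.
#' @return Concentration, umol/l (volume given) or umol/g (mass given).
#' @examples
#' quantify_gsh_concentration(1.486, 1, is_amount = 0.05,
#'                            sample_volume = 50e-6)  # 1486 umol/l
#' @export
quantify_gsh_concentration <- function(analyte_signal, is_signal, is_amount,
                                       sample_volume = NULL,
                                       sample_mass = NULL) {
  if (is_signal <= 0) stop("internal-standard signal must be > 0", call. = FALSE)
  if (is_amount <= 0) stop("internal-standard amount must be > 0", call. = FALSE)
  if (analyte_signal < 0) stop("analyte signal must be >= 0", call. = FALSE)
  if (is.null(sample_volume) == is.null(sample_mass)) {
    stop("give exactly one of sample_volume (l) or sample_mass (g)",
         call. = FALSE)
  }
  size <- if (is.null(sample_volume)) sample_mass else sample_volume
  if (size <= 0) stop("sample size must be > 0", call. = FALSE)
  (analyte_signal / is_signal) * is_amount / size
}
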