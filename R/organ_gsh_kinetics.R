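#' Organ GSH fractional synthesis rate from a single endpoint
#'
#' Tracer incorporation into an organ GSH pool held at constant size with
#' precursor enrichment Eo follows single-exponential kinetics,
#' \deqn{E_t = E_o (1 - e^{-k t}),}
#' so a single end-of-infusion measurement inverts algebraically to
#' \deqn{k = -\ln(1 - E_t/E_o) / t,}
#' here converted to per day (t in minutes, x 1440/t). The precursor is the
#' tissue free-cysteine enrichment measured in the same homogenate, not the
#' plasma plateau.
#'
#' `Et >= Eo` (possible under measurement noise) violates the model — the
#' product cannot out-label its precursor — and raises an error rather than
#' being clamped to a finite rate; callers flag and exclude such samples.
#'
#' @param Et Product ([13C-cysteine]GSH) enrichment at time `t`,
#'   mole-fraction excess, `0 <= Et < Eo`.
#' @param Eo Precursor (free [1-13C]cysteine) enrichment in the tissue,
#'   mole-fraction excess, > 0.
#' @param t Labeling duration, min, > 0. Default 360 (6-h infusion).
#' @return k, per day.
#' @examples
#' organ_fsr(Et = 0.6094 * 0.5, Eo = 0.5, t = 360)  # ~3.76 per day
#' @export
organ_fsr <- function(Et, Eo, t = 360) {
  if (is.na(Et) || is.na(Eo)) return(NA_real_)
  if (Eo <= 0) stop("precursor enrichment Eo must be > 0", call. = FALSE)
  if (Et < 0) stop("product enrichment Et must be >= 0", call. = FALSE)
  if (t <= 0) stop("labeling time t must be > 0 min", call. = FALSE)
  if (Et >= Eo) {
    stop("Et >= Eo: product labeling cannot exceed precursor enrichment ",
         "under single-exponential kinetics", call. = FALSE)
  }
  -log(1 - Et / Eo) * MIN_PER_DAY / t
}

#' Organ GSH absolute synthesis rate
#'
#' @param k Fractional synthesis rate, per day.
#' @param conc GSH concentration, umol/g wet tissue, >= 0.
#' @return ASR = k x conc, umol/g wet tissue/day (exact product).
#' @export
organ_asr <- function(k, conc) {
  if (is.na(k) || is.na(conc)) return(NA_real_)
  if (conc < 0) stop("conc must be >= 0", call. = FALSE)
  k * conc
}
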