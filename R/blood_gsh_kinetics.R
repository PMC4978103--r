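#' Slope of whole-blood GSH product enrichment
#'
#' Ordinary least-squares slope (free intercept) of product enrichment on
#' time over the fit window. Under a precursor at isotopic steady state the
#' product enrichment rises linearly; the slope K (mole-fraction excess/min)
#' is the tracer incorporation rate. Points flagged below the limit of
#' quantitation are excluded; the free intercept tolerates any
#' tracer-equilibration lag and is exact on the linear model either way.
#'
#' @param series An [enrichment_series()] of whole-blood GSH enrichment.
#' @param fit_window Two-element numeric window in minutes. Default
#'   `c(0, 360)`.
#' @param force_zero_intercept Fit through the origin instead. Default
#'   `FALSE`.
#' @return List with `K` (per min), `intercept`, `n_points`. A negative K
#'   is returned with a warning (expected K >= 0 under the model).
#' @export
fit_product_slope <- function(series, fit_window = c(0, 360),
                              force_zero_intercept = FALSE) {
  stopifnot(inherits(series, "enrichment_series"), length(fit_window) == 2L)
  sel <- series$times >= fit_window[1] & series$times <= fit_window[2] &
    !series$below_loq & !is.na(series$values)
  # the t = 0 baseline is 0 by construction, never below LOQ
  sel <- sel | (series$times == 0 & series$times >= fit_window[1])
  if (sum(sel) < 3L) {
    stop("product-slope fit needs at least 3 usable (non-LOQ) points",
         call. = FALSE)
  }
  t <- series$times[sel]
  y <- series$values[sel]
  fit <- if (force_zero_intercept) stats::lm(y ~ t + 0) else stats::lm(y ~ t)
  K <- unname(stats::coef(fit)[["t"]])
  if (abs(K) < 1e-15) K <- 0      # constant series: slope is floating noise
  if (K < 0) {
    warning("negative product-enrichment slope K = ", signif(K, 4),
            "; inconsistent with net tracer incorporation", call. = FALSE)
  }
  list(K = K,
       intercept = if (force_zero_intercept) 0
                   else unname(stats::coef(fit)[["(Intercept)"]]),
       n_points = sum(sel))
}

#' Fractional synthesis rate of whole-blood GSH
#'
#' Precursor-product equation: the fraction of the whole-blood GSH pool
#' renewed per day is the product labeling rate divided by the precursor
#' plateau enrichment,
#' \deqn{FSR = 1440 \, K / Ep \quad [\mathrm{day}^{-1}],}
#' with K in (mole-fraction excess)/min and Ep the plasma precursor
#' plateau enrichment.
#'
#' @param K Product enrichment slope, per min.
#' @param Ep Plasma precursor plateau enrichment, mole-fraction excess, > 0.
#' @return FSR, per day.
#' @examples
#' fsr_whole_blood(K = 1.15e-4, Ep = 0.4330)  # ~0.38 per day
#' @export
fsr_whole_blood <- function(K, Ep) {
  if (Ep <= 0) stop("Ep must be > 0", call. = FALSE)
  MIN_PER_DAY * K / Ep
}

#' Absolute synthesis rate of whole-blood GSH
#'
#' @param FSR Fractional synthesis rate, per day.
#' @param C_gsh Whole-blood GSH concentration, umol/l, >= 0.
#' @return ASR = FSR x C_gsh, umol/l/day (exact product).
#' @export
asr_whole_blood <- function(FSR, C_gsh) {
  if (is.na(C_gsh)) return(NA_real_)
  if (C_gsh < 0) stop("C_gsh must be >= 0", call. = FALSE)
  FSR * C_gsh
}
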