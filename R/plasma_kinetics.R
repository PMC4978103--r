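#' Check that plasma precursor enrichment has reached an isotopic plateau
#'
#' Fits an ordinary least-squares regression of enrichment on time over the
#' plateau window and tests the slope against zero (two-sided t-test). A
#' plateau is accepted when the slope is not significantly different from
#' zero (p > alpha). The plateau enrichment Ep is the arithmetic mean of the
#' in-window values, not the regression intercept: the regression serves only
#' as a flatness check.
#'
#' @param series An [enrichment_series()] of plasma precursor enrichment.
#' @param window Two-element numeric, plateau window in minutes
#'   (inclusive). Default `c(120, 360)`.
#' @param alpha Significance level for the slope test. Default 0.05.
#' @return A list of class `plateau_result` with elements `Ep` (mole-fraction
#'   excess), `slope` (per min), `slope_p_value`, `window`, `is_plateau`
#'   and `n_points`.
#' @examples
#' s <- enrichment_series("r1", "plasma_cysteine",
#'                        times = c(0, 60, 120, 180, 240, 300, 360),
#'                        values = c(0, .66, .665, .665, .665, .665, .665))
#' check_plateau(s)$is_plateau
#' @export
check_plateau <- function(series, window = c(120, 360), alpha = 0.05) {
  stopifnot(inherits(series, "enrichment_series"), length(window) == 2L)
  sel <- series$times >= window[1] & series$times <= window[2] &
    !is.na(series$values)
  if (sum(sel) < 3L) {
    stop("plateau check needs at least 3 points in the window [",
         window[1], ", ", window[2], "] min", call. = FALSE)
  }
  t <- series$times[sel]
  y <- series$values[sel]
  fit <- stats::lm(y ~ t)
  # an exactly flat series triggers summary.lm's perfect-fit warning
  cf <- stats::coef(suppressWarnings(summary(fit)))
  slope <- unname(cf["t", "Estimate"])
  # guard: an exactly constant series gives slope 0 with NaN p; treat as flat
  p <- unname(cf["t", "Pr(>|t|)"])
  if (is.nan(p)) p <- 1
  structure(
    list(Ep = mean(y), slope = slope, slope_p_value = p,
         window = window, is_plateau = (p > alpha), n_points = sum(sel)),
    class = "plateau_result")
}

#' Plasma cysteine flux by steady-state isotope dilution
#'
#' The conventional steady-state (primed constant infusion) dilution
#' equation: with tracer infused at rate i (umol/kg/min) at isotopic
#' abundance Ei and plasma precursor enrichment at plateau Ep,
#' \deqn{Q = 60 \, i \, (Ei/Ep - 1) \quad [\mu mol/kg/h].}
#' Q is the total rate of appearance of cysteine in plasma.
#'
#' @param i Tracer infusion rate, umol/kg/min.
#' @param Ei Tracer isotopic abundance, mole fraction in (0, 1].
#' @param Ep Plateau plasma enrichment, mole-fraction excess; requires
#'   `0 < Ep < Ei`.
#' @return Flux Q, umol/kg/h.
#' @examples
#' cysteine_flux(i = 1.0, Ei = 0.99, Ep = 0.6653)  # ~29.3
#' @export
cysteine_flux <- function(i, Ei, Ep) {
  if (i <= 0) stop("infusion rate i must be > 0", call. = FALSE)
  if (Ei <= 0 || Ei > 1) stop("Ei must lie in (0, 1]", call. = FALSE)
  if (Ep <= 0) stop("Ep must be > 0", call. = FALSE)
  if (Ep >= Ei) {
    stop("Ep >= Ei implies non-positive flux; plateau enrichment cannot ",
         "reach the infusate abundance under endogenous dilution", call. = FALSE)
  }
  MIN_PER_HOUR * i * (Ei / Ep - 1)
}

#' Plateau enrichment implied by a given flux
#'
#' Algebraic inverse of [cysteine_flux()]: the plateau enrichment a primed
#' constant infusion at rate i and abundance Ei settles at when the
#' endogenous rate of appearance is Q (umol/kg/h),
#' \deqn{Ep = Ei / (Q/(60 i) + 1).}
#' Used by the simulator's forward model and for worked-example inversions.
#'
#' @inheritParams cysteine_flux
#' @param Q Plasma flux, umol/kg/h, > 0.
#' @return Ep, mole-fraction excess.
#' @export
plateau_from_flux <- function(Q, i, Ei = 0.99) {
  if (Q <= 0) stop("Q must be > 0", call. = FALSE)
  if (i <= 0) stop("infusion rate i must be > 0", call. = FALSE)
  Ei / (Q / (MIN_PER_HOUR * i) + 1)
}
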