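#' Composition of the rabbit diet
#'
#' Per-100 g contents of the standard high-fiber rabbit chow used in the
#' tracer studies: protein, individual amino acids, fat, fiber, minerals
#' (all g/100 g) and total energy (kcal/100 g). Defaults are the
#' manufacturer-analysis values for the study diet.
#'
#' @param ... Name-value overrides of the defaults, e.g. `cystine = 0.25`.
#' @return Named numeric vector of class `diet_composition`.
#' @examples
#' diet_composition()[["cystine"]]
#' @export
diet_composition <- function(...) {
  d <- c(protein = 16.5,
         arginine = 0.79, cystine = 0.19, glycine = 0.52, histidine = 0.48,
         isoleucine = 0.82, leucine = 1.12, lysine = 0.98, methionine = 0.18,
         phenylalanine = 0.95, tyrosine = 0.77, threonine = 0.61,
         tryptophan = 0.25, valine = 1.07, serine = 0.87,
         aspartic_acid = 1.93, glutamic_acid = 3.21, alanine = 0.77,
         proline = 1.17,
         fat = 5.0, fiber = 21.9, minerals = 8.6, energy_kcal = 209)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) stop("unknown diet components: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    d[names(over)] <- as.numeric(over)
  }
  if (any(d < 0)) stop("diet contents must be >= 0", call. = FALSE)
  # amino acids cannot sum to more than crude protein (rounding slack 5%)
  aa <- setdiff(names(d), c("protein", "fat", "fiber", "minerals", "energy_kcal"))
  if (sum(d[aa]) > d[["protein"]] * 1.05) {
    stop("amino-acid sum exceeds protein content", call. = FALSE)
  }
  structure(d, class = c("diet_composition", "numeric"))
}

#' Nutrient intakes from diet composition and food intake
#'
#' Each nutrient intake is `intake x content / 100`, linear in intake:
#' g (or kcal) per kg body weight per day for an intake in g/kg/day.
#'
#' @param diet A [diet_composition()].
#' @param intake Food intake, g/kg/day, >= 0.
#' @return Named numeric vector of per-nutrient intakes (g/kg/day;
#'   `energy_kcal` in kcal/kg/day).
#' @examples
#' nutrient_intake(diet_composition(), 43.0)[["energy_kcal"]]  # ~90
#' @export
nutrient_intake <- function(diet, intake) {
  stopifnot(inherits(diet, "diet_composition"))
  if (intake < 0) stop("intake must be >= 0", call. = FALSE)
  out <- unclass(diet) * intake / 100
  out
}

# Molar masses of the free amino acids, g/mol (average atomic weights):
# L-methionine C5H11NO2S, L-cystine C6H12N2O4S2.
MOLAR_MASS <- c(methionine = 149.21, cystine = 240.30)

#' Convert a mass in mg to micromoles
#'
#' @param mass_mg Mass, mg, >= 0.
#' @param molar_mass Molar mass, g/mol, > 0. For convenience
#'   `molar_mass_of()` returns the embedded constants for methionine
#'   (149.21) and cystine (240.30).
#' @return Amount, umol (`1000 x mass / molar_mass`).
#' @examples
#' to_micromoles(82, molar_mass_of("cystine"))  # ~341
#' @export
to_micromoles <- function(mass_mg, molar_mass) {
  if (molar_mass <= 0) stop("molar_mass must be > 0", call. = FALSE)
  if (any(mass_mg < 0)) stop("mass must be >= 0", call. = FALSE)
  1000 * mass_mg / molar_mass
}

#' @rdname to_micromoles
#' @param compound `"methionine"` or `"cystine"`.
#' @export
molar_mass_of <- function(compound) {
  compound <- match.arg(compound, names(MOLAR_MASS))
  unname(MOLAR_MASS[compound])
}

#' Sulfur-amino-acid precursor intake report
#'
#' Computes the intakes relevant to GSH precursor supply at a given food
#' intake: energy, protein, and the sulfur amino acids methionine and
#' cystine in mg and umol per kg per day. Unrounded values are reported
#' alongside a presentation-rounded column matching conventional precision
#' (nearest integer for kcal/mg/umol, one decimal for g); the umol column
#' is derived from the rounded mg value, the usual presentation path.
#'
#' @param intake Food intake, g/kg/day.
#' @param diet A [diet_composition()].
#' @return Data frame with columns `quantity`, `unit`, `value` (unrounded)
#'   and `rounded`.
#' @examples
#' diet_report(43.0)
#' @export
diet_report <- function(intake, diet = diet_composition()) {
  ni <- nutrient_intake(diet, intake)
  met_mg <- ni[["methionine"]] * 1000
  cys_mg <- ni[["cystine"]] * 1000
  met_umol <- to_micromoles(round(met_mg), molar_mass_of("methionine"))
  cys_umol <- to_micromoles(round(cys_mg), molar_mass_of("cystine"))
  data.frame(
    quantity = c("energy", "protein", "methionine", "methionine",
                 "cystine", "cystine"),
    unit = c("kcal/kg/day", "g/kg/day", "mg/kg/day", "umol/kg/day",
             "mg/kg/day", "umol/kg/day"),
    value = c(ni[["energy_kcal"]], ni[["protein"]], met_mg, met_umol,
              cys_mg, cys_umol),
    rounded = c(round(ni[["energy_kcal"]]), round(ni[["protein"]], 1),
                round(met_mg), round(met_umol), round(cys_mg),
                round(cys_umol)),
    stringsAsFactors = FALSE)
}
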