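#' Pipeline configuration
#'
#' @param plateau_window Plasma plateau window, min. Default `c(120, 360)`.
#' @param plateau_alpha Slope-test level. Default 0.05.
#' @param blood_fit_window Product-slope fit window, min. Default
#'   `c(0, 360)`.
#' @param force_zero_intercept Force the product-slope fit through the
#'   origin. Default `FALSE`.
#' @param loq Enrichment limit of quantitation, mole-fraction excess.
#'   Default 0.003.
#' @param alpha Significance level for group comparisons. Default 0.05.
#' @param alpha_norm Level for the normality screen. Default 0.05.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(plateau_window = c(120, 360),
                            plateau_alpha = 0.05,
                            blood_fit_window = c(0, 360),
                            force_zero_intercept = FALSE,
                            loq = 0.003,
                            alpha = 0.05, alpha_norm = 0.05) {
  if (loq < 0) stop("loq must be >= 0", call. = FALSE)
  structure(list(plateau_window = plateau_window,
                 plateau_alpha = plateau_alpha,
                 blood_fit_window = blood_fit_window,
                 force_zero_intercept = force_zero_intercept,
                 loq = loq, alpha = alpha, alpha_norm = alpha_norm),
            class = "pipeline_config")
}

#' Estimate all kinetic quantities for one animal
#'
#' Runs the full estimation chain: LOQ flagging, plateau check and plateau
#' enrichment Ep, plasma cysteine flux, whole-blood product slope K, blood
#' FSR and ASR, and per-organ k and ASR. Diagnostics (failed plateau, LOQ
#' exclusions, model violations Et >= Eo) are collected in `warnings`
#' rather than aborting: every animal is reported, flagged.
#'
#' @param animal An [animal_dataset()].
#' @param config A [pipeline_config()].
#' @return List of class `kinetics_result`: `animal_id`, `group`,
#'   `plateau` ([check_plateau()] result), `Ep`, `Q_cys` (umol/kg/h),
#'   `K` (per min), `FSR_blood` (per day), `C_blood` (umol/l),
#'   `ASR_blood` (umol/l/day), `organs` (data frame with per-tissue
#'   `Eo`, `Et`, `conc`, `k`, `ASR`, `below_loq`, `model_violation`),
#'   `warnings` (character).
#' @export
analyze_animal <- function(animal, config = pipeline_config()) {
  stopifnot(inherits(animal, "animal_dataset"),
            inherits(config, "pipeline_config"))
  warns <- character()
  proto <- animal$protocol

  plasma <- apply_loq_filter(animal$plasma_series, config$loq)
  plat <- check_plateau(plasma, window = config$plateau_window,
                        alpha = config$plateau_alpha)
  if (!plat$is_plateau) {
    warns <- c(warns, sprintf(
      "plasma enrichment slope significant in window (p = %.3g); flux computed from window mean anyway",
      plat$slope_p_value))
  }
  Q <- cysteine_flux(proto$infusion_rate, proto$isotopic_abundance, plat$Ep)

  blood <- apply_loq_filter(animal$blood_gsh_series, config$loq)
  n_excl <- sum(blood$below_loq)
  if (n_excl > 0) {
    warns <- c(warns, sprintf("%d blood GSH point(s) below LOQ excluded",
                              n_excl))
  }
  sl <- withCallingHandlers(
    fit_product_slope(blood, fit_window = config$blood_fit_window,
                      force_zero_intercept = config$force_zero_intercept),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  FSR <- fsr_whole_blood(sl$K, plat$Ep)
  ASR <- asr_whole_blood(FSR, animal$blood_gsh_concentration)

  org_rows <- lapply(animal$organ_samples, function(s) {
    below <- is.na(s$Et) || s$Et < config$loq ||
      is.na(s$Eo) || s$Eo < config$loq
    violation <- !below && s$Et >= s$Eo
    k <- NA_real_
    if (!below && !violation) k <- organ_fsr(s$Et, s$Eo, s$t_end)
    data.frame(tissue = s$tissue, Eo = s$Eo, Et = s$Et,
               conc = s$gsh_concentration, k = k,
               ASR = organ_asr(k, s$gsh_concentration),
               below_loq = below, model_violation = violation,
               stringsAsFactors = FALSE)
  })
  organs <- if (length(org_rows)) do.call(rbind, org_rows) else
    data.frame(tissue = character(), Eo = numeric(), Et = numeric(),
               conc = numeric(), k = numeric(), ASR = numeric(),
               below_loq = logical(), model_violation = logical())
  for (r in seq_len(nrow(organs))) {
    if (organs$below_loq[r]) {
      warns <- c(warns, sprintf("%s: enrichment below LOQ, excluded",
                                organs$tissue[r]))
    } else if (organs$model_violation[r]) {
      warns <- c(warns, sprintf("%s: Et >= Eo, single-exponential model violated, excluded",
                                organs$tissue[r]))
    }
  }

  structure(
    list(animal_id = animal$animal_id, group = animal$group,
         plateau = plat, Ep = plat$Ep, Q_cys = Q, K = sl$K,
         FSR_blood = FSR, C_blood = animal$blood_gsh_concentration,
         ASR_blood = ASR, organs = organs, warnings = warns),
    class = "kinetics_result")
}

# flatten one kinetics_result into a single-row data frame (blood block)
result_row <- function(res) {
  data.frame(animal_id = res$animal_id, group = res$group,
             Ep = res$Ep, plateau_p = res$plateau$slope_p_value,
             is_plateau = res$plateau$is_plateau,
             Q_cys = res$Q_cys, K = res$K,
             FSR_blood = res$FSR_blood, C_blood = res$C_blood,
             ASR_blood = res$ASR_blood, stringsAsFactors = FALSE)
}

#' Run the full estimation and comparison pipeline on a cohort
#'
#' Per-animal kinetics via [analyze_animal()], then group summaries
#' (mean +/- SEM) and sham-vs-burn comparisons via [compare_groups()] for
#' every reported variable: body-analogous blood measures (cysteine flux,
#' product slope K, blood FSR/concentration/ASR) and per-organ
#' concentration, FSR and ASR. Variables with fewer than 2 usable values
#' in a group (e.g. burned muscle, excluded below the LOQ) are summarised
#' for the other group only, with no test.
#'
#' @param cohort A [cohort_dataset()].
#' @param config A [pipeline_config()].
#' @return List of class `result_bundle`: `per_animal` (data frame, one
#'   row per animal), `per_organ` (data frame, one row per animal x
#'   tissue), `comparisons` (data frame: variable, sham/burn mean, SEM, n,
#'   test, p, significant), `results` (list of `kinetics_result`), `log`
#'   (data frame of warnings keyed by animal).
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  results <- lapply(cohort$animals, analyze_animal, config = config)

  per_animal <- do.call(rbind, lapply(results, result_row))
  per_organ <- do.call(rbind, lapply(results, function(r) {
    if (!nrow(r$organs)) return(NULL)
    cbind(data.frame(animal_id = r$animal_id, group = r$group,
                     stringsAsFactors = FALSE), r$organs)
  }))

  log_df <- do.call(rbind, lapply(results, function(r) {
    if (!length(r$warnings)) return(NULL)
    data.frame(animal_id = r$animal_id, message = r$warnings,
               stringsAsFactors = FALSE)
  }))
  if (is.null(log_df)) {
    log_df <- data.frame(animal_id = character(), message = character())
  }

  vars <- list(
    cysteine_flux = function(df) df$Q_cys,
    gsh_enrichment_slope_K = function(df) df$K,
    fsr_blood = function(df) df$FSR_blood,
    blood_gsh_concentration = function(df) df$C_blood,
    asr_blood = function(df) df$ASR_blood)

  comp_rows <- list()
  add_comparison <- function(name, sham_vals, burn_vals) {
    sham_vals <- sham_vals[!is.na(sham_vals)]
    burn_vals <- burn_vals[!is.na(burn_vals)]
    summ <- function(v) {
      if (length(v) >= 2) summarize_values(v)
      else list(mean = NA_real_, sem = NA_real_, n = length(v))
    }
    ss <- summ(sham_vals); sb <- summ(burn_vals)
    if (length(sham_vals) >= 3 && length(burn_vals) >= 3) {
      cr <- compare_groups(sham_vals, burn_vals,
                           alpha = config$alpha,
                           alpha_norm = config$alpha_norm)
      test <- cr$test_used; p <- cr$p_value; sig <- cr$significant
    } else {
      test <- NA_character_; p <- NA_real_; sig <- NA
    }
    comp_rows[[length(comp_rows) + 1L]] <<- data.frame(
      variable = name,
      sham_mean = ss$mean, sham_sem = ss$sem, sham_n = ss$n,
      burn_mean = sb$mean, burn_sem = sb$sem, burn_n = sb$n,
      test = test, p = p, significant = sig, stringsAsFactors = FALSE)
  }

  sham_df <- per_animal[per_animal$group == "sham", ]
  burn_df <- per_animal[per_animal$group == "burn", ]
  for (v in names(vars)) {
    add_comparison(v, vars[[v]](sham_df), vars[[v]](burn_df))
  }
  if (!is.null(per_organ) && nrow(per_organ)) {
    usable <- per_organ[!per_organ$below_loq & !per_organ$model_violation, ]
    for (tis in intersect(TISSUES, unique(per_organ$tissue))) {
      for (meas in c("conc", "k", "ASR")) {
        u <- usable[usable$tissue == tis, ]
        add_comparison(paste(tis, meas, sep = "_"),
                       u[[meas]][u$group == "sham"],
                       u[[meas]][u$group == "burn"])
      }
    }
  }

  structure(
    list(per_animal = per_animal, per_organ = per_organ,
         comparisons = do.call(rbind, comp_rows),
         results = results, log = log_df),
    class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable report of a pipeline run
#'
#' Renders the comparison table as text with mean +/- SEM formatting;
#' unavailable cells (e.g. burned muscle) print as `n.d.` (not determined).
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  fmt_cell <- function(m, s, n) {
    if (is.na(m)) return("n.d.")
    sprintf("%s +/- %s (n=%d)", signif(m, 3), signif(s, 2), n)
  }
  cmp <- bundle$comparisons
  lines <- c("Group comparison (sham vs burn), mean +/- SEM",
             sprintf("%-28s %-24s %-24s %-14s %s",
                     "variable", "sham", "burn", "test", "p"))
  for (r in seq_len(nrow(cmp))) {
    lines <- c(lines, sprintf(
      "%-28s %-24s %-24s %-14s %s%s",
      cmp$variable[r],
      fmt_cell(cmp$sham_mean[r], cmp$sham_sem[r], cmp$sham_n[r]),
      fmt_cell(cmp$burn_mean[r], cmp$burn_sem[r], cmp$burn_n[r]),
      ifelse(is.na(cmp$test[r]), "-", cmp$test[r]),
      ifelse(is.na(cmp$p[r]), "-", format(signif(cmp$p[r], 3))),
      ifelse(!is.na(cmp$significant[r]) && cmp$significant[r], " *", "")))
  }
  if (nrow(bundle$log)) {
    lines <- c(lines, "", "Diagnostics:",
               sprintf("  %s: %s", bundle$log$animal_id, bundle$log$message))
  }
  lines
}
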