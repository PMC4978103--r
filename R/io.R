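#' Write a cohort to tidy CSV/JSON files
#'
#' Writes four files to `dir`:
#' \describe{
#'   \item{animals.csv}{animal_id, group, body_weight_kg,
#'     blood_gsh_umol_per_l, infusion_rate_umol_per_kg_min}
#'   \item{series.csv}{animal_id, group, analyte, time_min, enrichment,
#'     below_loq}
#'   \item{organs.csv}{animal_id, tissue, Eo, Et, conc_umol_per_g,
#'     wet_weight_g, t_end_min}
#'   \item{protocol.json}{tracer_name, isotopic_abundance,
#'     prime_equivalent, duration, sampling_times (shared across animals;
#'     per-animal infusion rates live in animals.csv)}
#' }
#' Numeric fields are written at full double precision so write/read
#' round-trips are lossless.
#'
#' @param cohort A [cohort_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  an <- cohort$animals

  animals <- do.call(rbind, lapply(an, function(a) data.frame(
    animal_id = a$animal_id, group = a$group,
    body_weight_kg = a$body_weight,
    blood_gsh_umol_per_l = a$blood_gsh_concentration,
    infusion_rate_umol_per_kg_min = a$protocol$infusion_rate,
    stringsAsFactors = FALSE)))

  series <- do.call(rbind, lapply(an, function(a) {
    do.call(rbind, lapply(list(a$plasma_series, a$blood_gsh_series),
      function(s) data.frame(
        animal_id = a$animal_id, group = a$group, analyte = s$analyte,
        time_min = s$times, enrichment = s$values,
        below_loq = s$below_loq, stringsAsFactors = FALSE)))
  }))

  organs <- do.call(rbind, lapply(an, function(a) {
    if (!length(a$organ_samples)) return(NULL)
    do.call(rbind, lapply(a$organ_samples, function(s) data.frame(
      animal_id = a$animal_id, tissue = s$tissue, Eo = s$Eo, Et = s$Et,
      conc_umol_per_g = s$gsh_concentration, wet_weight_g = s$wet_weight,
      t_end_min = s$t_end, stringsAsFactors = FALSE)))
  }))

  p <- an[[1]]$protocol
  proto <- list(tracer_name = p$tracer_name,
                isotopic_abundance = p$isotopic_abundance,
                prime_equivalent = p$prime_equivalent,
                duration = p$duration,
                sampling_times = p$sampling_times)

  write_full <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                  scientific = TRUE,
                                                  trim = TRUE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_full(animals, file.path(dir, "animals.csv"))
  write_full(series, file.path(dir, "series.csv"))
  if (!is.null(organs)) write_full(organs, file.path(dir, "organs.csv"))
  jsonlite::write_json(proto, file.path(dir, "protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

stop_schema <- function(file, msg) {
  stop(sprintf("schema error in %s: %s", file, msg), call. = FALSE)
}

require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_schema(file, paste("missing column(s):", paste(miss, collapse = ", ")))
  }
}

#' Read a cohort from tidy CSV/JSON files
#'
#' Inverse of [write_cohort()]; validates schemas and labels, naming the
#' offending file/row in errors.
#'
#' @param dir Directory containing `animals.csv`, `series.csv`,
#'   `protocol.json` and optionally `organs.csv`.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("animals.csv", "series.csv", "protocol.json"))
  for (f in need) if (!file.exists(f)) stop("missing input file: ", f,
                                            call. = FALSE)
  animals <- utils::read.csv(file.path(dir, "animals.csv"),
                             stringsAsFactors = FALSE)
  series <- utils::read.csv(file.path(dir, "series.csv"),
                            stringsAsFactors = FALSE)
  organs_path <- file.path(dir, "organs.csv")
  organs <- if (file.exists(organs_path)) {
    utils::read.csv(organs_path, stringsAsFactors = FALSE)
  } else NULL
  proto_json <- jsonlite::read_json(file.path(dir, "protocol.json"),
                                    simplifyVector = TRUE)

  require_cols(animals, c("animal_id", "group", "body_weight_kg",
                          "blood_gsh_umol_per_l",
                          "infusion_rate_umol_per_kg_min"), "animals.csv")
  require_cols(series, c("animal_id", "group", "analyte", "time_min",
                         "enrichment", "below_loq"), "series.csv")
  if (!is.null(organs)) {
    require_cols(organs, c("animal_id", "tissue", "Eo", "Et",
                           "conc_umol_per_g"), "organs.csv")
    bad <- which(!organs$tissue %in% TISSUES)
    if (length(bad)) {
      stop_schema("organs.csv", sprintf("unknown tissue '%s' in row %d",
                                        organs$tissue[bad[1]], bad[1]))
    }
  }
  bad <- which(!series$analyte %in% ANALYTES)
  if (length(bad)) {
    stop_schema("series.csv", sprintf("unknown analyte '%s' in row %d",
                                      series$analyte[bad[1]], bad[1]))
  }
  bad <- which(!animals$group %in% c("sham", "burn"))
  if (length(bad)) {
    stop_schema("animals.csv", sprintf("unknown group '%s' in row %d",
                                       animals$group[bad[1]], bad[1]))
  }

  build_animal <- function(r) {
    id <- animals$animal_id[r]
    proto <- infusion_protocol(
      tracer_name = proto_json$tracer_name,
      isotopic_abundance = proto_json$isotopic_abundance,
      infusion_rate = animals$infusion_rate_umol_per_kg_min[r],
      prime_equivalent = proto_json$prime_equivalent,
      duration = proto_json$duration,
      sampling_times = proto_json$sampling_times)
    get_series <- function(analyte) {
      s <- series[series$animal_id == id & series$analyte == analyte, ]
      if (!nrow(s)) {
        stop(sprintf("insufficient data: no %s series for animal '%s'",
                     analyte, id), call. = FALSE)
      }
      s <- s[order(s$time_min), ]
      enrichment_series(id, analyte, s$time_min, s$enrichment, s$below_loq)
    }
    org_list <- list()
    if (!is.null(organs)) {
      o <- organs[organs$animal_id == id, ]
      org_list <- lapply(seq_len(nrow(o)), function(j) {
        organ_sample(o$tissue[j], Eo = o$Eo[j], Et = o$Et[j],
                     gsh_concentration = o$conc_umol_per_g[j],
                     t_end = if ("t_end_min" %in% names(o)) o$t_end_min[j]
                             else proto$duration,
                     wet_weight = if ("wet_weight_g" %in% names(o))
                       o$wet_weight_g[j] else NA_real_)
      })
    }
    animal_dataset(id, animals$group[r], animals$body_weight_kg[r], proto,
                   get_series("plasma_cysteine"), get_series("blood_gsh"),
                   animals$blood_gsh_umol_per_l[r], org_list)
  }
  cohort_dataset(lapply(seq_len(nrow(animals)), build_animal))
}

#' Write pipeline results to a directory
#'
#' Emits `per_animal.csv`, `per_organ.csv`, `comparisons.csv`, a
#' `report.txt` text rendering, and `log.csv` of estimation diagnostics.
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(bundle$per_animal, file.path(dir, "per_animal.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$per_organ)) {
    utils::write.csv(bundle$per_organ, file.path(dir, "per_organ.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  writeLines(render_report(bundle), file.path(dir, "report.txt"))
  utils::write.csv(bundle$log, file.path(dir, "log.csv"), row.names = FALSE)
  invisible(dir)
}
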