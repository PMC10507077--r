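## End-to-end pipeline orchestration, descriptive table, run manifest.

# Shared stage: profile wards on the full population, prune procedure
# wards, classify the included cohort's transfers and count exposures.
derive_exposures <- function(cohort, mode = "last", min_deposits = 10,
                             threshold_hours = 6) {
  profiles <- profile_wards(cohort, mode = mode,
                            min_deposits = min_deposits)
  exempt <- prune_procedure_wards(cohort, threshold_hours = threshold_hours)
  transfers <- extract_transfers(cohort)
  inc <- apply_inclusion(cohort, transfers)
  if (nrow(inc$cohort$spells) == 0) {
    stop("no spells meet the inclusion criteria; pipeline stopped")
  }
  classified <- classify_transfers(inc$transfers, profiles,
                                   exempt_wards = exempt)
  exposures <- count_exposures(classified)
  list(profiles = profiles, exempt = exempt, included = inc$cohort,
       transfers = classified, exposures = exposures,
       exclusion_log = inc$exclusion_log)
}

#' Run the full transfer-outcome pipeline
#'
#' Chains spell construction, ward profiling, transfer classification,
#' readmission index construction, the three outcome models and the
#' descriptive table, and returns everything with a stage-by-stage row
#' manifest.
#'
#' @param cohort a `transfer_cohort` (full profiling population).
#' @param mode TFC selection mode for ward profiling.
#' @param min_deposits low-evidence threshold for ward profiles.
#' @param threshold_hours procedure-ward pruning threshold (hours).
#' @param covariates optional covariate override for all models.
#' @param sensitivity run the six LOS sensitivity variants too.
#' @return list of class `wardflow_results`: `profiles`, `exempt_wards`,
#'   `transfers`, `exposures`, `exclusion_log`, `analysis`,
#'   `pair_stats`, `models` (los/readmission/mortality `transfer_model`s),
#'   `descriptive`, `sensitivity` (or NULL), `manifest`.
#' @export
run_pipeline <- function(cohort, mode = "last", min_deposits = 10,
                         threshold_hours = 6, covariates = NULL,
                         sensitivity = FALSE) {
  stage <- derive_exposures(cohort, mode = mode,
                            min_deposits = min_deposits,
                            threshold_hours = threshold_hours)
  if (nrow(stage$included$spells) == 0) {
    stop("no spells meet the inclusion criteria; pipeline stopped")
  }
  readmission_index <- build_readmission_index(
    cohort$spells, included_ids = stage$included$spells$spell_id)
  analysis <- build_analysis_table(stage$included, stage$exposures,
                                   readmission_index)
  models <- list(
    los = fit_outcome_model(analysis, "los", covariates = covariates),
    readmission = fit_outcome_model(analysis, "readmission",
                                    covariates = covariates),
    mortality = fit_outcome_model(analysis, "mortality",
                                  covariates = covariates)
  )
  pair_stats <- atypical_pair_stats(stage$transfers)
  descriptive <- build_descriptive_table(analysis)
  sens <- if (sensitivity) {
    run_sensitivity_suite(cohort, min_deposits = min_deposits,
                          threshold_hours = threshold_hours,
                          covariates = covariates)
  }
  manifest <- list(
    stages = data.frame(
      stage = c("spells", "included", "transfers", "classified",
                "analysis_rows", "readmission_rows", "mortality_rows"),
      rows = c(nrow(cohort$spells), nrow(stage$included$spells),
               nrow(stage$transfers), nrow(stage$transfers),
               nrow(analysis), models$readmission$n_obs,
               models$mortality$n_obs),
      stringsAsFactors = FALSE),
    n_dropped_missing = attr(analysis, "n_dropped_missing"),
    settings = list(mode = mode, min_deposits = min_deposits,
                    threshold_hours = threshold_hours)
  )
  structure(c(stage[c("profiles", "transfers", "exposures",
                      "exclusion_log")],
              list(exempt_wards = stage$exempt, analysis = analysis,
                   readmission_index = readmission_index,
                   pair_stats = pair_stats, models = models,
                   descriptive = descriptive, sensitivity = sens,
                   manifest = manifest)),
            class = "wardflow_results")
}

#' @export
print.wardflow_results <- function(x, ...) {
  cat("<wardflow_results>\n")
  print(x$manifest$stages, row.names = FALSE)
  cat("\nLength of stay (gamma GLM, AME in days):\n")
  print(average_marginal_effect(x$models$los), row.names = FALSE)
  cat("\nUnique atypical ward pairs:", x$pair_stats$n_unique_pairs, "\n")
  invisible(x)
}

#' Descriptive characteristics stratified by atypical exposure
#'
#' Compares spells with no atypical transfers against spells with at least
#' one: continuous variables as median (Q1, Q3) with Kruskal-Wallis
#' p-values, categorical variables as counts (%) with chi-square tests
#' (without continuity correction). Constant variables or empty strata are
#' flagged and their tests skipped.
#'
#' @param analysis analysis table from [build_analysis_table()].
#' @param continuous,categorical variable names; sensible defaults.
#' @return data.frame, one row per variable (continuous) or per level
#'   (categorical), with a `p_value` on the first row of each variable.
#' @export
build_descriptive_table <- function(analysis,
    continuous = c("n_regular", "n_site", "los_days",
                   "primary_diagnosis_count", "imaging_count",
                   "elixhauser_count"),
    categorical = c("age_band", "gender", "icu_flag", "weekend_admission",
                    "out_of_hours_admission", "discharge_destination",
                    "died")) {
  continuous <- intersect(continuous, names(analysis))
  categorical <- intersect(categorical, names(analysis))
  strata <- factor(ifelse(analysis$n_atypical > 0, "atypical", "none"),
                   levels = c("none", "atypical"))
  empty_stratum <- any(table(strata) == 0)
  rows <- list()
  fmt_q <- function(x) {
    sprintf("%.1f (%.1f, %.1f)", median(x), quantile(x, 0.25),
            quantile(x, 0.75))
  }
  for (v in continuous) {
    x <- analysis[[v]]
    p <- if (empty_stratum || length(unique(x)) < 2) {
      NA_real_
    } else {
      kruskal.test(x, strata)$p.value
    }
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "median (Q1, Q3)",
      none = fmt_q(x[strata == "none"]),
      atypical = fmt_q(x[strata == "atypical"]),
      p_value = p,
      test = if (is.na(p)) "skipped" else "kruskal-wallis",
      stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- factor(analysis[[v]])
    tab <- table(x, strata)
    p <- if (empty_stratum || nlevels(x) < 2) {
      NA_real_
    } else {
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    pct <- prop.table(tab, margin = 2) * 100
    for (j in seq_len(nlevels(x))) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = levels(x)[j],
        none = sprintf("%d (%.1f%%)", tab[j, "none"], pct[j, "none"]),
        atypical = sprintf("%d (%.1f%%)", tab[j, "atypical"],
                           pct[j, "atypical"]),
        p_value = if (j == 1) p else NA_real_,
        test = if (j > 1) "" else if (is.na(p)) "skipped" else "chi-square",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write pipeline results to a directory of CSV/text files
#'
#' Emits the ward profile table and long share table, classified transfer
#' and exposure tables, exclusion log, pair statistics, per-model
#' coefficient and AME/OR tables, per-site chord matrices, the descriptive
#' table and a JSON manifest (requires `jsonlite`; skipped otherwise).
#'
#' @param results a `wardflow_results` from [run_pipeline()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  wcsv(results$profiles$profiles, "ward_profiles.csv")
  wcsv(results$profiles$shares, "ward_shares.csv")
  tr <- results$transfers
  tr$transfer_ts <- format_ts(tr$transfer_ts)
  wcsv(tr, "transfers_classified.csv")
  wcsv(results$exposures, "exposures.csv")
  wcsv(results$exclusion_log, "exclusion_log.csv")
  wcsv(results$pair_stats$pairs, "atypical_pairs.csv")
  wcsv(results$descriptive, "descriptive_table.csv")
  for (nm in names(results$models)) {
    m <- results$models[[nm]]
    co <- data.frame(term = names(m$coefficients),
                     estimate = unname(m$coefficients),
                     se = sqrt(diag(m$vcov)), stringsAsFactors = FALSE)
    wcsv(co, paste0("model_", nm, "_coefficients.csv"))
    if (nm == "los") {
      wcsv(average_marginal_effect(m), "model_los_ame.csv")
    } else {
      wcsv(odds_ratios(m), paste0("model_", nm, "_or.csv"))
    }
  }
  for (s in unique(results$transfers$from_site)) {
    cm <- chord_matrix(results$transfers, results$profiles, s)
    if (nrow(cm) > 0) {
      write.csv(cm, file.path(dir, paste0("chord_matrix_", s, ".csv")))
    }
  }
  if (!is.null(results$sensitivity)) {
    wcsv(results$sensitivity$summary, "sensitivity_summary.csv")
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(results$manifest,
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Simulate a cohort and write it to disk (CLI entry point)
#'
#' @param out output directory.
#' @param seed integer seed.
#' @param n_patients cohort size.
#' @param ... further [sim_config()] overrides.
#' @return the `wardflow_sim`, invisibly.
#' @export
simulate_cohort <- function(out, seed = 1L, n_patients = 20000, ...) {
  sim <- generate_cohort(sim_config(seed = seed, n_patients = n_patients,
                                    ...))
  write_sim(sim, out)
  message("wrote ", nrow(sim$cohort$spells), " spells (",
          nrow(sim$cohort$stays), " stays) to ", out)
  invisible(sim)
}
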