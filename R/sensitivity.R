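## The six sensitivity analyses around the length-of-stay model.

#' Run the sensitivity analysis suite
#'
#' Re-estimates the length-of-stay model (the headline analysis) under six
#' variants:
#' \enumerate{
#'   \item exclude spells ending in in-hospital death;
#'   \item exclude spells with a positive infection/colonisation flag;
#'   \item add a 12-level approximate-month dummy (admission date binned
#'         every 30 days, cycling over 12 categories);
#'   \item swap the surgical severity counts for the alternative
#'         categorisation columns (`alt_minor_proc_count` etc.);
#'   \item redefine the exposures using first-TFC ward profiles
#'         (re-profile, re-classify, re-count);
#'   \item refit after dropping observations with absolute standardised
#'         Pearson residual above `std_resid_cutoff`.
#' }
#'
#' @param cohort the full `transfer_cohort` (profiling population).
#' @param variants which variants to run (subset of 1:6).
#' @param covariates covariates for the LOS model; default set.
#' @param cluster cluster id column.
#' @param min_deposits,threshold_hours profiling/classification settings.
#' @param std_resid_cutoff cutoff for variant 6, default 3.
#' @return list with `base` (the base `transfer_model`), `variants` (named
#'   list of `transfer_model`s) and `summary` (data.frame of the atypical,
#'   regular and site AMEs per variant).
#' @export
run_sensitivity_suite <- function(cohort, variants = 1:6,
                                  covariates = NULL,
                                  cluster = "patient_id",
                                  min_deposits = 10, threshold_hours = 6,
                                  std_resid_cutoff = 3) {
  stage <- derive_exposures(cohort, mode = "last",
                            min_deposits = min_deposits,
                            threshold_hours = threshold_hours)
  analysis <- build_analysis_table(stage$included, stage$exposures)
  base <- fit_outcome_model(analysis, "los", covariates = covariates,
                            cluster = cluster)
  results <- list()

  if (1 %in% variants) {
    results[["exclude_deaths"]] <-
      fit_outcome_model(analysis[!analysis$died, , drop = FALSE], "los",
                        covariates = covariates, cluster = cluster)
  }
  if (2 %in% variants) {
    if (!"infection_flag" %in% names(analysis)) {
      stop("variant 2 requires an infection_flag column")
    }
    results[["exclude_infection"]] <-
      fit_outcome_model(analysis[!isTRUE_vec(analysis$infection_flag), ,
                                 drop = FALSE],
                        "los", covariates = covariates, cluster = cluster)
  }
  if (3 %in% variants) {
    a <- analysis
    t0 <- min(as.numeric(a$admission_ts))
    bin <- floor((as.numeric(a$admission_ts) - t0) / (30 * 86400)) %% 12
    a$admission_month_bin <- factor(bin, levels = sort(unique(bin)))
    covs <- if (is.null(covariates)) {
      intersect(default_covariates("los"), names(a))
    } else covariates
    results[["month_dummies"]] <-
      fit_outcome_model(a, "los",
                        covariates = c(covs, "admission_month_bin"),
                        cluster = cluster)
  }
  if (4 %in% variants) {
    alt <- c("alt_minor_proc_count", "alt_intermediate_proc_count",
             "alt_major_proc_count")
    if (!all(alt %in% names(analysis))) {
      stop("variant 4 requires alternative surgical-category columns: ",
           paste(alt, collapse = ", "))
    }
    covs <- if (is.null(covariates)) {
      intersect(default_covariates("los"), names(analysis))
    } else covariates
    covs <- setdiff(covs, c("minor_proc_count", "intermediate_proc_count",
                            "major_proc_count"))
    results[["alt_surgical"]] <-
      fit_outcome_model(analysis, "los", covariates = c(covs, alt),
                        cluster = cluster)
  }
  if (5 %in% variants) {
    stage1 <- derive_exposures(cohort, mode = "first",
                               min_deposits = min_deposits,
                               threshold_hours = threshold_hours)
    analysis1 <- build_analysis_table(stage1$included, stage1$exposures)
    results[["first_tfc"]] <-
      fit_outcome_model(analysis1, "los", covariates = covariates,
                        cluster = cluster)
  }
  if (6 %in% variants) {
    pearson <- residuals(base$fit, type = "pearson")
    phi <- sum(pearson^2) / base$fit$df.residual
    std <- pearson / sqrt(phi)
    keep_ids <- base$data$spell_id[abs(std) <= std_resid_cutoff]
    results[["drop_residual_outliers"]] <-
      fit_outcome_model(analysis[analysis$spell_id %in% keep_ids, ,
                                 drop = FALSE],
                        "los", covariates = covariates, cluster = cluster)
  }

  summ <- do.call(rbind, lapply(c(list(base = base), results), function(m) {
    average_marginal_effect(m)
  }))
  summ$variant <- rep(c("base", names(results)),
                      each = length(intersect(exposure_variables(),
                                              names(base$coefficients))))
  rownames(summ) <- NULL
  list(base = base, variants = results,
       summary = summ[, c("variant", "term", "ame", "se", "lower", "upper")])
}
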