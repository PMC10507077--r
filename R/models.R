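## Outcome models: gamma log-link GLM for LOS, logistic models for
## readmission and mortality, patient-clustered covariances, average
## marginal effects.

#' Transfer exposure variable names
#' @return character vector of the three exposure count columns.
#' @export
exposure_variables <- function() c("n_atypical", "n_regular", "n_site")

#' Default covariate sets per outcome
#'
#' The confounder set: patient demographics, Elixhauser comorbidity count,
#' weekend and out-of-hours admission, discharge destination, ICU
#' admission, number of primary diagnoses, imaging and surgical procedure
#' counts by severity, and major diagnostic category. The mortality model
#' omits discharge destination (death determines it); the readmission model
#' additionally adjusts for length of stay.
#'
#' @param outcome one of `"los"`, `"readmission"`, `"mortality"`.
#' @return character vector of covariate names (exposures first).
#' @export
default_covariates <- function(outcome = c("los", "readmission", "mortality")) {
  outcome <- match.arg(outcome)
  base <- c(exposure_variables(),
            "age_band", "gender", "ethnicity", "elixhauser_count",
            "weekend_admission", "out_of_hours_admission",
            "discharge_destination", "icu_flag",
            "primary_diagnosis_count", "imaging_count",
            "minor_proc_count", "intermediate_proc_count",
            "major_proc_count", "major_diagnostic_category")
  switch(outcome,
         los = base,
         readmission = c(base, "los_days"),
         mortality = setdiff(base, "discharge_destination"))
}

#' Assemble the spell-level analysis table
#'
#' Joins the included spells with their exposure counts and (optionally)
#' the readmission index, sets factor reference levels (youngest age band,
#' female, usual residence, the modal diagnostic category) and removes
#' incomplete rows, logging the count in the `n_dropped_missing` attribute.
#'
#' @param included the included `transfer_cohort` from [apply_inclusion()].
#' @param exposures output of [count_exposures()].
#' @param readmission_index optional output of [build_readmission_index()];
#'   adds `readmitted_30d` (NA for spells that are not index admissions).
#' @return data.frame, one row per included spell, with a `died` column
#'   copied from `death_flag`.
#' @export
build_analysis_table <- function(included, exposures,
                                 readmission_index = NULL) {
  df <- merge(included$spells, exposures, by = "spell_id", sort = FALSE)
  if (!is.null(readmission_index)) {
    df <- merge(df,
                readmission_index[, c("spell_id", "readmitted_30d")],
                by = "spell_id", all.x = TRUE, sort = FALSE)
  }
  df$died <- isTRUE_vec(df$death_flag)

  if ("age_band" %in% names(df)) {
    lv <- intersect(c("18-39", "40-65", "over65"), unique(df$age_band))
    df$age_band <- factor(df$age_band, levels = c(lv,
      setdiff(unique(df$age_band), lv)))
  }
  if ("gender" %in% names(df)) {
    lv <- intersect(c("female", "male"), unique(df$gender))
    df$gender <- factor(df$gender, levels = c(lv,
      setdiff(unique(df$gender), lv)))
  }
  if ("discharge_destination" %in% names(df)) {
    lv <- intersect(c("usual residence", "not usual residence"),
                    unique(df$discharge_destination))
    df$discharge_destination <- factor(df$discharge_destination,
      levels = c(lv, setdiff(unique(df$discharge_destination), lv)))
  }
  if ("ethnicity" %in% names(df)) df$ethnicity <- factor(df$ethnicity)
  if ("major_diagnostic_category" %in% names(df)) {
    tab <- sort(table(df$major_diagnostic_category), decreasing = TRUE)
    df$major_diagnostic_category <-
      factor(df$major_diagnostic_category, levels = names(tab))
  }

  check <- intersect(c(exposure_variables(), "los_days", "died",
                       default_covariates("los")), names(df))
  complete <- complete.cases(df[, check, drop = FALSE])
  out <- df[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_missing") <- sum(!complete)
  out
}

#' Patient-clustered sandwich covariance
#'
#' CR1-style cluster-robust covariance: the HC0 sandwich aggregated within
#' clusters, scaled by the small-sample factor `G/(G-1)`. With one
#' observation per cluster it reduces to the heteroskedasticity-robust
#' estimator (up to that factor). Delegates to [sandwich::vcovCL()].
#'
#' @param fit a fitted `glm`.
#' @param clusters cluster ids, one per estimation-sample observation.
#' @return covariance matrix on the link scale.
#' @export
cluster_robust_vcov <- function(fit, clusters) {
  n_used <- length(fit$residuals)
  if (length(clusters) != n_used) {
    stop("cluster vector length (", length(clusters),
         ") does not match estimation sample size (", n_used, ")")
  }
  if (anyNA(clusters)) stop("missing cluster ids")
  sandwich::vcovCL(fit, cluster = factor(clusters), type = "HC0",
                   cadjust = TRUE)
}

#' Fit an outcome model with patient-clustered standard errors
#'
#' Gamma GLM with log link for length of stay; logistic regression for
#' 30-day readmission and in-hospital mortality. Transfer-count exposures
#' enter as continuous integers. For the logistic models, levels of
#' `major_diagnostic_category` with no outcome events, or with fewer than
#' `min_category_size` observations, are removed (positivity filter), with
#' the dropped row count recorded.
#'
#' @param data analysis table from [build_analysis_table()].
#' @param outcome `"los"`, `"readmission"` or `"mortality"`.
#' @param covariates covariate names; defaults to
#'   [default_covariates()] intersected with available columns.
#' @param cluster name of the cluster id column (default `"patient_id"`).
#' @param ci_level confidence level, default 0.95.
#' @param min_category_size positivity filter threshold for logistic
#'   models, default 10 observations per diagnostic category.
#' @param interaction_age_atypical add an age-band by atypical-count
#'   interaction (off by default).
#' @return object of class `transfer_model`: list with the `glm` fit,
#'   `vcov` (cluster-robust), `coefficients`, `n_obs`, `n_clusters`,
#'   `outcome`, `data` (estimation sample), `clusters`, `ci_level`,
#'   `n_dropped_sparse`.
#' @export
fit_outcome_model <- function(data,
                              outcome = c("los", "readmission", "mortality"),
                              covariates = NULL, cluster = "patient_id",
                              ci_level = 0.95, min_category_size = 10,
                              interaction_age_atypical = FALSE) {
  outcome <- match.arg(outcome)
  response <- switch(outcome, los = "los_days",
                     readmission = "readmitted_30d", mortality = "died")
  if (!response %in% names(data)) {
    stop("analysis table lacks the response column '", response, "'")
  }
  if (is.null(covariates)) {
    covariates <- intersect(default_covariates(outcome), names(data))
  } else {
    missing_cov <- setdiff(covariates, names(data))
    if (length(missing_cov) > 0) {
      stop("covariate(s) absent from data: ",
           paste(missing_cov, collapse = ", "))
    }
  }
  fam <- if (outcome == "los") Gamma(link = "log") else binomial()

  df <- data
  if (outcome == "readmission") {
    # index admissions only: spells ending in death carry NA here
    df <- df[!is.na(df$readmitted_30d), , drop = FALSE]
  }
  used <- c(response, covariates, cluster)
  df <- df[complete.cases(df[, used, drop = FALSE]), , drop = FALSE]

  n_dropped_sparse <- 0L
  if (fam$family == "binomial" &&
      "major_diagnostic_category" %in% covariates) {
    y <- as.numeric(df[[response]])
    ev <- tapply(y, df$major_diagnostic_category, sum)
    nn <- tapply(y, df$major_diagnostic_category, length)
    sparse <- names(ev)[is.na(ev) | ev == 0 | nn < min_category_size]
    if (length(sparse) > 0) {
      drop_rows <- df$major_diagnostic_category %in% sparse
      n_dropped_sparse <- sum(drop_rows)
      df <- df[!drop_rows, , drop = FALSE]
      df$major_diagnostic_category <- droplevels(df$major_diagnostic_category)
    }
  }
  # drop constant factors (can arise in small simulated cohorts)
  for (v in covariates) {
    if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  }
  keep_cov <- vapply(covariates, function(v) {
    length(unique(df[[v]])) > 1
  }, logical(1))
  covariates <- covariates[keep_cov]

  rhs <- if (length(covariates) == 0) "1" else
    paste(covariates, collapse = " + ")
  if (interaction_age_atypical &&
      all(c("age_band", "n_atypical") %in% covariates)) {
    rhs <- paste(rhs, "+ age_band:n_atypical")
  }
  fml <- as.formula(paste(response, "~", rhs))
  if (outcome == "los" && any(df[[response]] <= 0)) {
    stop("non-positive length of stay in analysis table")
  }

  fit <- withCallingHandlers(
    glm(fml, family = fam, data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        # only a diverging coefficient marks true separation; extreme but
        # finite fitted probabilities are tolerated
        cf <- suppressWarnings(coef(glm(fml, family = fam, data = df)))
        suspects <- names(cf)[!is.na(cf) & abs(cf) > 15]
        if (length(suspects) > 0) {
          stop("perfect separation detected (suspect covariate(s): ",
               paste(suspects, collapse = ", "), ")")
        }
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    stop("GLM failed to converge after ", fit$iter, " IRLS iterations")
  }

  clusters <- df[[cluster]]
  vc <- cluster_robust_vcov(fit, clusters)
  structure(list(fit = fit, vcov = vc, coefficients = coef(fit),
                 n_obs = nrow(df),
                 n_clusters = length(unique(clusters)),
                 outcome = outcome, covariates = covariates,
                 response = response, data = df, clusters = clusters,
                 ci_level = ci_level,
                 n_dropped_sparse = n_dropped_sparse),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat("<transfer_model> outcome:", x$outcome,
      sprintf("(%s)\n", if (x$outcome == "los") "gamma, log link"
              else "binomial, logit link"))
  cat("  n =", x$n_obs, " clusters =", x$n_clusters, "\n")
  expo <- intersect(exposure_variables(), names(x$coefficients))
  if (x$outcome == "los") {
    print(average_marginal_effect(x, expo), row.names = FALSE)
  } else {
    or <- odds_ratios(x)
    print(or[or$term %in% expo, ], row.names = FALSE)
  }
  invisible(x)
}

model_mu_and_X <- function(model) {
  fit <- model$fit
  X <- model.matrix(fit)
  mu <- fit$fitted.values
  list(X = X, mu = mu)
}

#' Average marginal effect of a continuous covariate
#'
#' The mean, over the estimation sample, of the derivative of the
#' predicted response with respect to the covariate (`type =
#' "derivative"`, the `margins`-style `dydx` with `type = "response"`), or
#' the mean one-unit finite difference in predictions (`type = "unit"`).
#' Confidence intervals use the delta method with the cluster-robust
#' covariance, so AMEs for length of stay are reported in days with
#' patient-clustered uncertainty.
#'
#' @param model a `transfer_model`.
#' @param variables covariate names (must enter the model linearly as
#'   numeric columns); defaults to the transfer exposures in the model.
#' @param type `"derivative"` (default) or `"unit"`.
#' @return data.frame with `term`, `ame`, `se`, `lower`, `upper`.
#' @export
average_marginal_effect <- function(model, variables = NULL,
                                    type = c("derivative", "unit")) {
  type <- match.arg(type)
  if (is.null(variables)) {
    variables <- intersect(exposure_variables(), names(model$coefficients))
  }
  beta <- model$coefficients
  absent <- setdiff(variables, names(beta))
  if (length(absent) > 0) {
    stop("variable(s) not in the model: ", paste(absent, collapse = ", "))
  }
  mx <- model_mu_and_X(model)
  X <- mx$X
  mu <- mx$mu
  fam <- family(model$fit)$family
  V <- model$vcov
  z <- qnorm(1 - (1 - model$ci_level) / 2)
  n <- length(mu)
  p <- length(beta)

  rows <- lapply(variables, function(v) {
    bv <- beta[[v]]
    if (type == "derivative") {
      if (fam == "Gamma") {
        # log link: dmu/dx = beta_v * mu
        ame <- mean(bv * mu)
        grad <- colMeans(bv * mu * X)
        grad[v] <- grad[v] + mean(mu)
      } else {
        w <- mu * (1 - mu)
        ame <- mean(bv * w)
        grad <- colMeans(bv * w * (1 - 2 * mu) * X)
        grad[v] <- grad[v] + mean(w)
      }
    } else {
      X1 <- X
      X1[, v] <- X1[, v] + 1
      eta1 <- drop(X1 %*% beta)
      mu1 <- family(model$fit)$linkinv(eta1)
      ame <- mean(mu1 - mu)
      if (fam == "Gamma") {
        grad <- colMeans(mu1 * X1 - mu * X)
      } else {
        grad <- colMeans(mu1 * (1 - mu1) * X1 - mu * (1 - mu) * X)
      }
    }
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    data.frame(term = v, ame = ame, se = se,
               lower = ame - z * se, upper = ame + z * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Odds ratios with cluster-robust confidence intervals
#'
#' @param model a logistic `transfer_model`.
#' @return data.frame with `term`, `or`, `lower`, `upper` (intercept
#'   excluded).
#' @export
odds_ratios <- function(model) {
  if (family(model$fit)$family != "binomial") {
    stop("odds ratios are defined for the logistic models only")
  }
  beta <- model$coefficients
  se <- sqrt(diag(model$vcov))
  z <- qnorm(1 - (1 - model$ci_level) / 2)
  keep <- names(beta) != "(Intercept)"
  out <- data.frame(term = names(beta)[keep],
                    or = exp(beta[keep]),
                    lower = exp(beta[keep] - z * se[keep]),
                    upper = exp(beta[keep] + z * se[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Randomised-quantile-residual model diagnostics
#'
#' Computes randomised quantile residuals (uniform under a well-specified
#' model), a Kolmogorov-Smirnov uniformity test, a dispersion ratio (the
#' variance of the probit-transformed residuals, which is 1 under correct
#' specification) and standardised Pearson residual extremes.
#'
#' @param model a `transfer_model`.
#' @param dispersion_bounds flag dispersion outside this interval.
#' @return list of class `wardflow_diagnostics`: `uniformity_p`,
#'   `dispersion_ratio`, `dispersion_flagged`, `max_abs_std_resid`,
#'   `n_std_resid_gt3`, `degenerate`.
#' @export
model_diagnostics <- function(model, dispersion_bounds = c(0.8, 1.25)) {
  fit <- model$fit
  y <- fit$y
  mu <- fit$fitted.values
  fam <- family(fit)$family
  degenerate <- length(unique(y)) < 2
  if (degenerate) {
    warning("constant response: degenerate fit")
    out <- list(uniformity_p = NA_real_, dispersion_ratio = NA_real_,
                dispersion_flagged = NA, max_abs_std_resid = NA_real_,
                n_std_resid_gt3 = NA_integer_, degenerate = TRUE)
    class(out) <- "wardflow_diagnostics"
    return(out)
  }
  pearson <- residuals(fit, type = "pearson")
  phi <- sum(pearson^2) / fit$df.residual
  if (fam == "Gamma") {
    shape <- 1 / phi
    u <- pgamma(y, shape = shape, rate = shape / mu)
  } else if (fam == "binomial") {
    lo <- ifelse(y >= 1, 1 - mu, 0)
    hi <- ifelse(y >= 1, 1, 1 - mu)
    u <- runif(length(y), lo, hi)
  } else {
    stop("unsupported family: ", fam)
  }
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  ks <- suppressWarnings(ks.test(u, "punif"))
  zres <- qnorm(u)
  disp <- var(zres)
  std <- pearson / sqrt(phi)
  out <- list(uniformity_p = unname(ks$p.value),
              dispersion_ratio = disp,
              dispersion_flagged = disp < dispersion_bounds[1] |
                disp > dispersion_bounds[2],
              max_abs_std_resid = max(abs(std)),
              n_std_resid_gt3 = sum(abs(std) > 3),
              degenerate = FALSE)
  class(out) <- "wardflow_diagnostics"
  out
}

#' @export
print.wardflow_diagnostics <- function(x, ...) {
  cat("Randomised quantile residual diagnostics\n")
  cat(sprintf("  uniformity (KS) p = %.3f\n", x$uniformity_p))
  cat(sprintf("  dispersion ratio = %.3f%s\n", x$dispersion_ratio,
              if (isTRUE(x$dispersion_flagged)) " [flagged]" else ""))
  cat(sprintf("  max |standardised residual| = %.2f (%d above 3)\n",
              x$max_abs_std_resid, x$n_std_resid_gt3))
  invisible(x)
}
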