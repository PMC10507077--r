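ts0 <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")
day <- 86400

mk_spell <- function(spell_id, patient_id, adm_day, los_days,
                     class = "emergency", death = FALSE, mdc = "circulatory") {
  data.frame(spell_id = spell_id, patient_id = patient_id,
             admission_ts = ts0 + adm_day * day,
             discharge_ts = ts0 + (adm_day + los_days) * day,
             admission_class = class, death_flag = death,
             major_diagnostic_category = mdc, stringsAsFactors = FALSE)
}

test_that("readmission index reproduces the hand-traced toy patients", {
  # patient pA: S1 discharged day 5 alive, S2 emergency admit day 15
  # patient pB: S3 ends in death (excluded from the index set)
  # patient pC: S5 followed only by a pregnancy admission (not counted)
  spells <- rbind(
    mk_spell("S1", "pA", 0, 5), mk_spell("S2", "pA", 15, 3),
    mk_spell("S3", "pB", 0, 4, death = TRUE),
    mk_spell("S5", "pC", 0, 2),
    mk_spell("S6", "pC", 10, 1, mdc = "pregnancy_childbirth")
  )
  idx <- build_readmission_index(spells)
  expect_setequal(idx$spell_id, c("S1", "S2", "S5", "S6"))
  expect_true(idx$readmitted_30d[idx$spell_id == "S1"])
  expect_equal(idx$days_to_readmission[idx$spell_id == "S1"], 10)
  expect_false(idx$readmitted_30d[idx$spell_id == "S2"])
  expect_false("S3" %in% idx$spell_id)
  expect_false(idx$readmitted_30d[idx$spell_id == "S5"])
})

test_that("the 30-day window is inclusive at exactly 30 days", {
  at30 <- rbind(mk_spell("S1", "p", 0, 5), mk_spell("S2", "p", 35, 1))
  idx <- build_readmission_index(at30)
  expect_true(idx$readmitted_30d[idx$spell_id == "S1"])
  past30 <- rbind(mk_spell("S1", "p", 0, 5), mk_spell("S2", "p", 35.01, 1))
  idx2 <- build_readmission_index(past30)
  expect_false(idx2$readmitted_30d[idx2$spell_id == "S1"])
  # non-emergency subsequent admissions never count
  elec <- rbind(mk_spell("S1", "p", 0, 5),
                mk_spell("S2", "p", 10, 1, class = "elective"))
  expect_false(build_readmission_index(elec)$readmitted_30d[1])
})

test_that("overlapping spells for one patient are a data error", {
  bad <- rbind(mk_spell("S1", "p", 0, 10), mk_spell("S2", "p", 5, 10))
  expect_error(build_readmission_index(bad), "overlapping")
})

test_that("readmission model rows equal included rows minus deaths", {
  sim <- small_sim()
  res <- run_pipeline(sim$cohort)
  n_included <- nrow(res$analysis)
  n_deaths <- sum(res$analysis$died)
  expect_equal(sum(!is.na(res$analysis$readmitted_30d)),
               n_included - n_deaths)
})

test_that("intercept-only gamma fit recovers the log sample mean", {
  set.seed(8)
  y <- rgamma(500, shape = 2, rate = 2 / 10)
  df <- data.frame(los_days = y, patient_id = seq_along(y))
  m <- fit_outcome_model(df, "los", covariates = character(0))
  expect_equal(unname(m$coefficients["(Intercept)"]), log(mean(y)),
               tolerance = 1e-7)
})

test_that("logit fit on a 2x2 table equals the cross-product odds ratio", {
  # exposed: 30 events / 100; unexposed: 15 events / 100
  df <- data.frame(
    readmitted_30d = c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85)),
    x = rep(c(1, 0), each = 100),
    patient_id = 1:200
  )
  m <- fit_outcome_model(df, "readmission", covariates = "x")
  or_hand <- (30 * 85) / (70 * 15)
  expect_equal(unname(exp(m$coefficients["x"])), or_hand,
               tolerance = 1e-9)
  expect_equal(odds_ratios(m)$or[odds_ratios(m)$term == "x"], or_hand,
               tolerance = 1e-9)
})

test_that("cluster covariance reduces to HC0 (scaled) with singleton clusters", {
  set.seed(9)
  n <- 200
  df <- data.frame(x = rnorm(n), patient_id = 1:n)
  df$los_days <- rgamma(n, 2, 2 / exp(1 + 0.3 * df$x))
  fit <- glm(los_days ~ x, Gamma(link = "log"), data = df)
  vc <- cluster_robust_vcov(fit, df$patient_id)
  hc0 <- sandwich::vcovHC(fit, type = "HC0")
  expect_equal(vc, hc0 * n / (n - 1), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("duplicating rows within clusters inflates clustered SEs", {
  set.seed(10)
  n <- 150
  df <- data.frame(x = rnorm(n), patient_id = 1:n)
  df$los_days <- rgamma(n, 2, 2 / exp(1 + 0.3 * df$x))
  dup <- rbind(df, df)  # perfectly correlated within cluster
  fit <- glm(los_days ~ x, Gamma(link = "log"), data = dup)
  se_cl <- sqrt(diag(cluster_robust_vcov(fit, dup$patient_id)))["x"]
  se_iid <- sqrt(diag(vcov(fit)))["x"]
  expect_gt(se_cl, se_iid)
})

test_that("clustered covariance matches a first-principles sandwich", {
  set.seed(12)
  n <- 80
  df <- data.frame(x = rnorm(n), patient_id = rep(1:20, each = 4))
  df$los_days <- rgamma(n, 2, 2 / exp(1 + 0.2 * df$x))
  fit <- glm(los_days ~ x, Gamma(link = "log"), data = df)
  vc <- cluster_robust_vcov(fit, df$patient_id)
  oracle <- sandwich_oracle_glm(fit, df$patient_id)
  expect_equal(unname(vc), unname(oracle), tolerance = 1e-8)
  # length mismatch is an error
  expect_error(cluster_robust_vcov(fit, df$patient_id[-1]),
               "does not match")
})

test_that("AME is zero for a zero-coefficient variable and errors off-model", {
  set.seed(13)
  n <- 400
  df <- data.frame(z = rnorm(n), patient_id = 1:n)
  df$los_days <- rgamma(n, 2, 2 / 10)
  df$n_atypical <- rpois(n, 0.2)
  m <- fit_outcome_model(df, "los", covariates = "z")
  # z has a near-zero estimated coefficient: AME near zero, CI spans it
  ame <- average_marginal_effect(m, "z")
  expect_lt(ame$lower, 0 + 0.5)
  expect_gt(ame$upper, 0 - 0.5)
  expect_error(average_marginal_effect(m, "nope"), "not in the model")
  # closed form: constant mu, added variable with coefficient b -> AME b*mu
  b <- coef(m$fit)
  mu <- mean(m$fit$fitted.values)
  expect_equal(ame$ame, unname(b["z"]) * mean(m$fit$fitted.values),
               tolerance = 1e-10)
})

test_that("delta-method AME equals numerical differentiation of predictions", {
  sim <- small_sim()
  res <- run_pipeline(sim$cohort)
  m <- res$models$los
  h <- 1e-4
  for (v in c("n_atypical", "n_regular", "n_site")) {
    up <- m$data; up[[v]] <- up[[v]] + h
    dn <- m$data; dn[[v]] <- dn[[v]] - h
    num <- (mean(predict(m$fit, newdata = up, type = "response")) -
              mean(predict(m$fit, newdata = dn, type = "response"))) / (2 * h)
    ana <- average_marginal_effect(m, v)$ame
    expect_equal(ana, num, tolerance = 1e-6)
  }
  # the logit AME matches too
  mm <- res$models$mortality
  up <- mm$data; up$n_regular <- up$n_regular + h
  dn <- mm$data; dn$n_regular <- dn$n_regular - h
  num <- (mean(predict(mm$fit, newdata = up, type = "response")) -
            mean(predict(mm$fit, newdata = dn, type = "response"))) / (2 * h)
  expect_equal(average_marginal_effect(mm, "n_regular")$ame, num,
               tolerance = 1e-6)
  # unit-difference convention stays close to the derivative for small effects
  expect_equal(average_marginal_effect(m, "n_regular", type = "unit")$ame,
               average_marginal_effect(m, "n_regular")$ame,
               tolerance = 0.2)
})

test_that("quantile-residual diagnostics separate good and bad gamma fits", {
  set.seed(14)
  ok <- 0
  for (r in 1:20) {
    n <- 400
    df <- data.frame(x = rnorm(n), patient_id = 1:n)
    df$los_days <- rgamma(n, shape = 2, rate = 2 / exp(1.5 + 0.3 * df$x))
    m <- fit_outcome_model(df, "los", covariates = "x")
    d <- model_diagnostics(m)
    if (d$uniformity_p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 18 * 0.9)  # >=90% of replicates pass under the truth

  # heavy-tailed lognormal data fit as gamma: dispersion flagged
  set.seed(15)
  flagged <- 0
  for (r in 1:5) {
    df <- data.frame(los_days = exp(rnorm(600, 1, 1.6)), patient_id = 1:600)
    m <- fit_outcome_model(df, "los", covariates = character(0))
    d <- model_diagnostics(m)
    if (isTRUE(d$dispersion_flagged) || d$uniformity_p < 0.01) {
      flagged <- flagged + 1
    }
  }
  expect_gte(flagged, 4)

  # constant response: degenerate-fit warning
  dfc <- data.frame(readmitted_30d = rep(0, 50), x = rnorm(50),
                    patient_id = 1:50)
  fitc <- suppressWarnings(glm(readmitted_30d ~ x, binomial, dfc))
  mc <- structure(list(fit = fitc), class = "transfer_model")
  expect_warning(dd <- model_diagnostics(mc), "degenerate")
  expect_true(dd$degenerate)
})

test_that("exposure coefficient recovery on a simulated cohort", {
  sim <- generate_cohort(sim_config(seed = 31, n_patients = 4000))
  res <- run_pipeline(sim$cohort)
  m <- res$models$los
  b <- m$coefficients
  se <- sqrt(diag(m$vcov))
  truth <- c(n_atypical = 0.25, n_regular = 0.15, n_site = 0.28)
  for (v in names(truth)) {
    expect_lt(abs(b[[v]] - truth[[v]]), 3.5 * se[[v]])
  }
})

test_that("sensitivity variants behave as designed on invariance cases", {
  sim <- generate_cohort(sim_config(seed = 32, n_patients = 1200))
  co <- sim$cohort
  # force every episode to a single TFC so first and last coincide:
  # variant 5 must reproduce the base exposures exactly
  ep <- co$episodes[order(co$episodes$spell_id, co$episodes$episode_order), ]
  last <- ep[!duplicated(ep$spell_id, fromLast = TRUE), ]
  last$episode_order <- 1L
  co$episodes <- last
  suite <- run_sensitivity_suite(co, variants = c(1, 2, 3, 4, 5),
                                 min_deposits = 5)
  expect_equal(suite$variants$first_tfc$coefficients,
               suite$base$coefficients, tolerance = 1e-10)
  # variant 6 with an infinite cutoff is the base fit
  suite6 <- run_sensitivity_suite(co, variants = 6, min_deposits = 5,
                                  std_resid_cutoff = Inf)
  expect_equal(suite6$variants$drop_residual_outliers$coefficients,
               suite6$base$coefficients)
  # death-exclusion variant drops exactly the death spells
  expect_equal(suite$variants$exclude_deaths$n_obs,
               suite$base$n_obs - sum(suite$base$data$died))
  # month dummies add 11 extra parameters at most
  extra <- length(suite$variants$month_dummies$coefficients) -
    length(suite$base$coefficients)
  expect_lte(extra, 11)
  expect_gte(extra, 1)
  # the alternative surgical categorisation swaps the covariate columns
  expect_true(any(grepl("alt_minor_proc_count",
                        names(suite$variants$alt_surgical$coefficients))))
  expect_false(any(grepl("^minor_proc_count",
                         names(suite$variants$alt_surgical$coefficients))))
  # summary table carries one AME row per exposure per variant
  expect_setequal(unique(suite$summary$term),
                  c("n_atypical", "n_regular", "n_site"))
})
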