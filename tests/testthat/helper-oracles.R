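# Independent oracles and tiny hand-built fixtures shared across tests.

# Brute-force HHI: the probability that two independent draws from the
# ward's deposit distribution fall in the same speciality, computed as an
# explicit double loop over all (i, j) pairs.
hhi_oracle <- function(counts) {
  p <- counts / sum(counts)
  acc <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i == j) acc <- acc + p[i] * p[j]
    }
  }
  acc
}

# Brute-force transfer classification: site comparison first, then set
# intersection emptiness with the procedure-ward exemption.
classify_oracle <- function(from, to, from_site, to_site, sets, exempt) {
  if (from_site != to_site) return("site")
  if (length(intersect(sets[[from]], sets[[to]])) == 0 &&
      !(from %in% exempt) && !(to %in% exempt)) {
    return("atypical")
  }
  "regular"
}

# Two-block cluster sandwich computed from first principles for a gamma
# log-link GLM: B^{-1} (sum_g s_g s_g') B^{-1} * G/(G-1), with the bread
# from the IRLS weighted cross-product.
sandwich_oracle_glm <- function(fit, clusters) {
  X <- model.matrix(fit)
  mu <- fit$fitted.values
  y <- fit$y
  fam <- family(fit)
  eta <- fit$linear.predictors
  mu_eta <- fam$mu.eta(eta)
  vmu <- fam$variance(mu)
  # score contribution per observation (estimating equations, phi ignored
  # as it cancels in the sandwich for the covariance shape used by vcovCL)
  r <- (y - mu) * mu_eta / vmu
  S <- X * r
  G <- length(unique(clusters))
  Sg <- rowsum(S, clusters)
  meat <- crossprod(as.matrix(Sg)) * G / (G - 1)
  W <- mu_eta^2 / vmu
  bread_inv <- solve(crossprod(X * sqrt(W)))
  bread_inv %*% meat %*% bread_inv
}

# Minimal ward catalogue for hand-built fixtures.
toy_wards <- function() {
  data.frame(
    ward_id = c("ED1", "A", "B", "C", "D", "E2"),
    site_id = c("S1", "S1", "S1", "S1", "S1", "S2"),
    is_ed = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_procedure_ward = FALSE,
    stringsAsFactors = FALSE
  )
}

# Build an event log from a compact stay spec:
# list(spell_id, patient_id, wards = c(...), times = c(entry1, exit1, ...))
toy_events <- function(..., t0 = as.POSIXct("2015-01-01 00:00:00",
                                            tz = "UTC")) {
  specs <- list(...)
  rows <- lapply(specs, function(s) {
    k <- length(s$wards)
    hours <- s$hours  # length k+1 boundaries in hours from t0
    data.frame(patient_id = s$patient_id, spell_id = s$spell_id,
               ward_id = s$wards,
               entry_ts = t0 + hours[seq_len(k)] * 3600,
               exit_ts = t0 + hours[seq_len(k) + 1] * 3600,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# A fake ward_profiles object with directly chosen assigned sets, for
# exercising the classifier in isolation.
fake_profiles <- function(assigned) {
  structure(list(assigned = assigned,
                 profiles = data.frame(ward_id = names(assigned),
                                       stringsAsFactors = FALSE),
                 shares = NULL),
            class = "ward_profiles")
}

# Small simulated cohort shared by several test files (kept modest so the
# default test run stays fast).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(sim_config(seed = 99, n_patients = 1500))
    }
    cache
  }
})

spec_set <- function(x) sort(strsplit(x, "|", fixed = TRUE)[[1]])
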