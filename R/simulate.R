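## Synthetic multi-site EHR cohort generator with planted transfer
## structure. Every pipeline stage can be exercised against known ground
## truth: ward speciality sets, per-transfer class labels, and the
## generating outcome coefficients.

SIM_SPECIALITIES <- c("general_medicine", "elderly_care", "gastroenterology",
                      "respiratory", "cardiology", "renal",
                      "trauma_orthopaedics", "neurosurgery")
SIM_SPEC_WEIGHTS <- c(general_medicine = 0.16, elderly_care = 0.13,
                      gastroenterology = 0.13, respiratory = 0.13,
                      cardiology = 0.13, renal = 0.10,
                      trauma_orthopaedics = 0.12, neurosurgery = 0.10)
SIM_SURGICAL_SPECS <- c("trauma_orthopaedics", "neurosurgery")

#' Simulation configuration
#'
#' Defaults describe a three-site hospital network over a three-year
#' window: ~55% of patients over 65, Poisson(1.1) moves per spell (so just
#' over half of moving patients move exactly once), a per-move atypical
#' probability of 0.08 (about 13% of included spells see at least one
#' atypical move), per-move site probability 0.055, gamma length of stay
#' with shape 2 and log-scale transfer effects 0.25/0.15/0.28
#' (atypical/regular/site), and a site-transfer mortality odds ratio of
#' 0.72.
#'
#' @param seed integer seed; fully determines all outputs.
#' @param n_patients number of patients.
#' @param n_sites number of hospital sites (>= 2).
#' @param wards_per_site wards per site (>= 10; the first ten fill the
#'   fixed roles ED, procedure, four specialist, two paired-speciality and
#'   two general wards, extras cycle specialist roles).
#' @param start_date ISO date anchoring the admission window.
#' @param study_years length of the admission window in years.
#' @param p_elective,p_day_case admission-class mix (remainder emergency).
#' @param p_maternity_paed probability of the maternity/paediatric flag.
#' @param p_ed_first probability an emergency spell starts in the ED.
#' @param lambda_moves Poisson mean of ward moves per non-day-case spell.
#' @param p_atypical,p_site,p_procedure per-move probabilities of planting
#'   a cross-speciality move, a cross-site move, or a short procedure-ward
#'   detour (remainder: within-speciality regular moves).
#' @param p_second_spell probability a patient contributes a second
#'   independent spell.
#' @param gamma_shape gamma shape of length of stay.
#' @param frailty_sd sd of the patient-level log-normal frailty shared by a
#'   patient's spells (induces within-patient correlation).
#' @param los_coefficients named log-scale coefficients for the LOS mean:
#'   `intercept`, `atypical`, `regular`, `site`, `icu`, `age_40_65`,
#'   `age_over65`, `elixhauser`, `imaging`.
#' @param mortality_coefficients,readmission_coefficients named logit-scale
#'   coefficients (same exposure names; subsets allowed).
#' @param p_pregnancy_admission probability of a spurious pregnancy-related
#'   subsequent admission (which must not count as a readmission).
#' @param readmission_horizon_days latent readmission times beyond this are
#'   not materialised as spells.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 20000,
                       n_sites = 3,
                       wards_per_site = 10,
                       start_date = "2015-01-01",
                       study_years = 3,
                       p_elective = 0.25,
                       p_day_case = 0.10,
                       p_maternity_paed = 0.05,
                       p_ed_first = 0.9,
                       lambda_moves = 1.1,
                       p_atypical = 0.08,
                       p_site = 0.055,
                       p_procedure = 0.04,
                       p_second_spell = 0.08,
                       gamma_shape = 2,
                       frailty_sd = 0.25,
                       los_coefficients = c(intercept = 1.55,
                                            atypical = 0.25,
                                            regular = 0.15,
                                            site = 0.28,
                                            icu = 0.5,
                                            age_40_65 = 0.10,
                                            age_over65 = 0.25,
                                            elixhauser = 0.05,
                                            imaging = 0.05),
                       mortality_coefficients = c(intercept = -3.4,
                                                  atypical = 0,
                                                  regular = 0,
                                                  site = log(0.72),
                                                  icu = 1.0,
                                                  age_40_65 = 0.3,
                                                  age_over65 = 0.8,
                                                  elixhauser = 0.05),
                       readmission_coefficients = c(intercept = -1.9,
                                                    atypical = 0,
                                                    regular = log(1.02),
                                                    site = 0,
                                                    elixhauser = 0.08),
                       p_pregnancy_admission = 0.01,
                       readmission_horizon_days = 40) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer")
  }
  probs <- c(p_elective = p_elective, p_day_case = p_day_case,
             p_maternity_paed = p_maternity_paed, p_ed_first = p_ed_first,
             p_atypical = p_atypical, p_site = p_site,
             p_procedure = p_procedure, p_second_spell = p_second_spell,
             p_pregnancy_admission = p_pregnancy_admission)
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[probs < 0 | probs > 1]
    stop("probabilities outside [0, 1]: ", paste(bad, collapse = ", "))
  }
  if (p_atypical + p_site + p_procedure > 1) {
    stop("per-move probabilities p_atypical + p_site + p_procedure exceed 1")
  }
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  if (n_sites < 2) stop("at least two sites are required")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Per-site ward role template. Roles: ed, procedure, specialist, paired,
# general. general wards use mixture weights 0.4/0.2/0.2/0.2 over their
# speciality set; all other roles are uniform over theirs.
sim_site_template <- function(wards_per_site) {
  # every speciality is hosted by at least two (non-ED, non-procedure)
  # wards per site, so within-speciality moves never need to leave the
  # patient's speciality and ward profiles stay well separated
  roles <- list(
    list(role = "ed", specs = "emergency_medicine"),
    list(role = "procedure", specs = "gastroenterology"),
    list(role = "specialist", specs = "cardiology"),
    list(role = "specialist", specs = "trauma_orthopaedics"),
    list(role = "specialist", specs = "respiratory"),
    list(role = "specialist", specs = "gastroenterology"),
    list(role = "paired", specs = c("cardiology", "renal")),
    list(role = "paired", specs = c("trauma_orthopaedics", "neurosurgery")),
    list(role = "general", specs = c("general_medicine", "elderly_care",
                                     "respiratory", "renal")),
    list(role = "general", specs = c("general_medicine", "elderly_care",
                                     "gastroenterology", "neurosurgery"))
  )
  if (wards_per_site < length(roles)) {
    stop("wards_per_site must be at least ", length(roles),
         " to cover the required ward roles")
  }
  extra_specs <- c("cardiology", "trauma_orthopaedics", "respiratory",
                   "gastroenterology")
  i <- 0
  while (length(roles) < wards_per_site) {
    i <- i + 1
    roles[[length(roles) + 1]] <-
      list(role = "specialist",
           specs = extra_specs[(i - 1) %% length(extra_specs) + 1])
  }
  roles
}

#' Generate the synthetic ward catalogue
#'
#' Each site receives the same role template: an ED location, a short-stay
#' procedure ward, four single-speciality specialist wards, two
#' paired-speciality wards and two general wards with diffuse four-way
#' mixtures. True speciality sets are recorded as ground truth in the
#' `true_specialities` column. Deterministic given the configuration.
#'
#' @param config a [sim_config()].
#' @return ward catalogue data.frame with `ward_id`, `site_id`, `role`,
#'   `is_ed`, `is_procedure_ward`, `true_specialities` (`|`-delimited).
#' @export
generate_ward_catalogue <- function(config = sim_config()) {
  template <- sim_site_template(config$wards_per_site)
  rows <- list()
  for (s in seq_len(config$n_sites)) {
    for (k in seq_along(template)) {
      rows[[length(rows) + 1]] <- data.frame(
        ward_id = sprintf("S%dW%02d", s, k),
        site_id = sprintf("S%d", s),
        ward_index = k,
        role = template[[k]]$role,
        is_ed = template[[k]]$role == "ed",
        is_procedure_ward = template[[k]]$role == "procedure",
        true_specialities = paste(template[[k]]$specs, collapse = "|"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Movement geometry precomputed from the catalogue: per-ward candidate
# target sets, hosting wards per (site, speciality), per-site procedure/ED
# wards.
build_sim_geometry <- function(catalogue) {
  specs <- strsplit(catalogue$true_specialities, "|", fixed = TRUE)
  names(specs) <- catalogue$ward_id
  sites <- unique(catalogue$site_id)
  movable <- !(catalogue$is_ed | catalogue$is_procedure_ward)

  reg <- aty <- vector("list", nrow(catalogue))
  names(reg) <- names(aty) <- catalogue$ward_id
  for (i in seq_len(nrow(catalogue))) {
    if (!movable[i]) next
    same_site <- catalogue$site_id == catalogue$site_id[i] & movable &
      catalogue$ward_id != catalogue$ward_id[i]
    share <- vapply(specs, function(s) length(intersect(s, specs[[i]])) > 0,
                    logical(1))
    reg[[i]] <- catalogue$ward_id[same_site & share]
    aty[[i]] <- catalogue$ward_id[same_site & !share]
  }
  hosting <- lapply(setNames(sites, sites), function(s) {
    on_site <- catalogue$site_id == s & movable
    lapply(setNames(SIM_SPECIALITIES, SIM_SPECIALITIES), function(sp) {
      catalogue$ward_id[on_site &
        vapply(specs, function(x) sp %in% x, logical(1))]
    })
  })
  proc_ward <- vapply(setNames(sites, sites), function(s) {
    catalogue$ward_id[catalogue$site_id == s & catalogue$is_procedure_ward][1]
  }, character(1))
  ed_ward <- vapply(setNames(sites, sites), function(s) {
    catalogue$ward_id[catalogue$site_id == s & catalogue$is_ed][1]
  }, character(1))
  list(specs = specs, sites = sites, reg = reg, aty = aty,
       hosting = hosting, proc_ward = proc_ward, ed_ward = ed_ward,
       ward_index = setNames(catalogue$ward_index, catalogue$ward_id),
       ward_at = lapply(setNames(sites, sites), function(s) {
         w <- catalogue[catalogue$site_id == s, ]
         setNames(w$ward_id, w$ward_index)
       }),
       site_of = setNames(catalogue$site_id, catalogue$ward_id))
}

pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Generate one spell's ward trajectory
#'
#' A spell's latent speciality drives ward choice: the spell starts on a
#' ward hosting the latent speciality (after an optional ED stay), and each
#' subsequent move is regular (to a ward sharing a speciality with the
#' current ward), atypical (to a same-site ward with a disjoint true
#' speciality set), a site transfer (to the corresponding ward on another
#' site), or a short procedure-ward detour with forced return. Ground-truth
#' labels are recorded per move.
#'
#' @param geom geometry from the ward catalogue (internal).
#' @param site starting site id.
#' @param latent latent speciality code.
#' @param n_moves number of planted moves.
#' @param move_types character vector of length `n_moves` drawn from
#'   `c("regular", "atypical", "site", "procedure")`.
#' @param ed_first logical: prepend an ED stay.
#' @return list with `wards` (stay sequence) and `labels` (one per
#'   ward-to-ward transfer, excluding the ED-origin move).
#' @keywords internal
sim_trajectory <- function(geom, site, latent, n_moves, move_types,
                           ed_first) {
  w0 <- pick1(geom$hosting[[site]][[latent]])
  wards <- if (ed_first) c(geom$ed_ward[[site]], w0) else w0
  labels <- character(0)
  cur <- w0
  cur_site <- site
  for (k in seq_len(n_moves)) {
    type <- move_types[k]
    if (type == "procedure") {
      pw <- geom$proc_ward[[cur_site]]
      wards <- c(wards, pw, cur)
      labels <- c(labels, "regular", "regular")
      next
    }
    if (type == "site") {
      new_site <- pick1(setdiff(geom$sites, cur_site))
      nxt <- geom$ward_at[[new_site]][[as.character(geom$ward_index[[cur]])]]
      cur_site <- new_site
    } else if (type == "atypical") {
      cand <- geom$aty[[cur]]
      if (length(cand) == 0) {  # no disjoint ward available: fall back
        cand <- geom$reg[[cur]]
        type <- "regular"
      }
      nxt <- pick1(cand)
    } else {
      # within-speciality move: another ward hosting the latent speciality
      cand <- setdiff(geom$hosting[[cur_site]][[latent]], cur)
      if (length(cand) == 0) cand <- geom$reg[[cur]]
      nxt <- pick1(cand)
    }
    wards <- c(wards, nxt)
    labels <- c(labels, type)
    cur <- nxt
  }
  list(wards = wards, labels = labels)
}

# Spell-level covariate draws, margins loosely matching a UK emergency
# inpatient population (conveniences, not contracts).
sim_covariates <- function(m) {
  alt_shift <- function(x) {
    pmax(0L, x + sample(c(-1L, 0L, 1L), length(x), TRUE, c(0.1, 0.8, 0.1)))
  }
  minor <- rpois(m, 0.20)
  inter <- rpois(m, 0.15)
  major <- rpois(m, 0.18)
  data.frame(
    age_band = sample(c("18-39", "40-65", "over65"), m, TRUE,
                      c(0.130, 0.318, 0.552)),
    gender = sample(c("female", "male"), m, TRUE, c(0.472, 0.528)),
    ethnicity = sample(c("white", "asian", "black", "mixed_other"), m, TRUE,
                       c(0.45, 0.25, 0.18, 0.12)),
    elixhauser_count = rpois(m, 1.8),
    icu_flag = runif(m) < 0.068,
    discharge_destination = sample(c("usual residence",
                                     "not usual residence"), m, TRUE,
                                   c(0.848, 0.152)),
    primary_diagnosis_count = 1L + rpois(m, 0.25),
    imaging_count = rpois(m, 1.0),
    minor_proc_count = minor,
    intermediate_proc_count = inter,
    major_proc_count = major,
    alt_minor_proc_count = alt_shift(minor),
    alt_intermediate_proc_count = alt_shift(inter),
    alt_major_proc_count = alt_shift(major),
    infection_flag = runif(m) < 0.08,
    major_diagnostic_category = sample(
      c("circulatory", "respiratory", "digestive", "injury", "nervous",
        "musculoskeletal", "infectious"), m, TRUE,
      c(0.22, 0.18, 0.16, 0.14, 0.12, 0.10, 0.08)),
    stringsAsFactors = FALSE
  )
}

# Linear predictor from a named coefficient vector; missing names are 0.
sim_linpred <- function(co, counts, covs) {
  g <- function(nm) if (nm %in% names(co)) co[[nm]] else 0
  g("intercept") +
    g("atypical") * counts$n_atypical +
    g("regular") * counts$n_regular +
    g("site") * counts$n_site +
    g("icu") * as.numeric(covs$icu_flag) +
    g("age_40_65") * as.numeric(covs$age_band == "40-65") +
    g("age_over65") * as.numeric(covs$age_band == "over65") +
    g("elixhauser") * covs$elixhauser_count +
    g("imaging") * covs$imaging_count
}

round_to_grid <- function(x, sec = 900) floor(x / sec) * sec

#' Generate a synthetic cohort with ground truth
#'
#' Draws patients, trajectories, and outcomes under the generating models
#' the analysis assumes: gamma length of stay with log-linear transfer
#' effects (plus a shared patient frailty), logistic in-hospital mortality,
#' and a latent-exponential 30-day readmission process calibrated so the
#' readmission indicator follows its logistic model marginally. Readmitted
#' patients receive a materialised subsequent emergency spell; a small
#' fraction of patients receive a pregnancy-related subsequent admission
#' that must *not* count as a readmission. Stay timestamps are written back
#' so the rebuilt length of stay equals the drawn value.
#'
#' @param config a [sim_config()].
#' @return list of class `wardflow_sim` with elements `cohort` (a
#'   [transfer_cohort()]), `truth_spells` (per-spell true exposure counts,
#'   latent speciality and generating-outcome draws), `truth_transfers`
#'   (per-move true class labels), and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(as.integer(cfg$seed) %% .Machine$integer.max)
  catalogue <- generate_ward_catalogue(cfg)
  geom <- build_sim_geometry(catalogue)
  t0 <- as.POSIXct(paste0(cfg$start_date, " 00:00:00"), tz = "UTC")

  wards_tbl <- catalogue[, c("ward_id", "site_id", "is_ed",
                             "is_procedure_ward", "role",
                             "true_specialities")]

  if (cfg$n_patients == 0) {
    empty_sp <- sim_empty_spells()
    cohort <- transfer_cohort(
      spells = empty_sp,
      stays = data.frame(spell_id = character(0), patient_id = character(0),
                         ward_id = character(0),
                         entry_ts = as.POSIXct(character(0), tz = "UTC"),
                         exit_ts = as.POSIXct(character(0), tz = "UTC"),
                         site_id = character(0), stay_order = integer(0),
                         stringsAsFactors = FALSE),
      episodes = data.frame(spell_id = character(0),
                            episode_order = integer(0),
                            tfc = character(0), stringsAsFactors = FALSE),
      wards = wards_tbl)
    return(structure(list(cohort = cohort,
                          truth_spells = data.frame(),
                          truth_transfers = data.frame(),
                          config = cfg),
                     class = "wardflow_sim"))
  }

  n_pat <- cfg$n_patients
  patient_ids <- sprintf("P%06d", seq_len(n_pat))
  frailty <- rnorm(n_pat, 0, cfg$frailty_sd)
  second <- runif(n_pat) < cfg$p_second_spell

  # ---- primary spells ----
  pat_row <- c(seq_len(n_pat), which(second))
  spell_seq <- c(rep(1L, n_pat), rep(2L, sum(second)))
  m <- length(pat_row)
  ordp <- order(pat_row, spell_seq)
  pat_row <- pat_row[ordp]; spell_seq <- spell_seq[ordp]

  covs <- sim_covariates(m)
  admission_class <- sample(c("emergency", "elective", "day_case"), m, TRUE,
                            c(1 - cfg$p_elective - cfg$p_day_case,
                              cfg$p_elective, cfg$p_day_case))
  maternity <- runif(m) < cfg$p_maternity_paed
  covs$major_diagnostic_category[maternity] <- "pregnancy_childbirth"
  latent <- sample(SIM_SPECIALITIES, m, TRUE, SIM_SPEC_WEIGHTS)
  site0 <- sample(sprintf("S%d", seq_len(cfg$n_sites)), m, TRUE)
  n_moves <- ifelse(admission_class == "day_case", 0L,
                    rpois(m, cfg$lambda_moves))
  ed_first <- admission_class == "emergency" & runif(m) < cfg$p_ed_first

  p_rest <- 1 - cfg$p_atypical - cfg$p_site - cfg$p_procedure
  ward_seq <- vector("list", m)
  label_seq <- vector("list", m)
  n_at <- n_reg <- n_st <- integer(m)
  for (i in seq_len(m)) {
    if (n_moves[i] == 0) {
      ward_seq[[i]] <- pick1(geom$hosting[[site0[i]]][[latent[i]]])
      label_seq[[i]] <- character(0)
      next
    }
    types <- sample(c("site", "atypical", "procedure", "regular"),
                    n_moves[i], TRUE,
                    c(cfg$p_site, cfg$p_atypical, cfg$p_procedure, p_rest))
    # atypical detours are planted at the end of the trajectory, so every
    # within-speciality move starts from a ward hosting the latent
    # speciality and the drawn move types coincide with the true
    # classification rule applied to the true speciality sets
    types <- c(types[types != "atypical"], types[types == "atypical"])
    tr <- sim_trajectory(geom, site0[i], latent[i], n_moves[i], types,
                         ed_first[i])
    ward_seq[[i]] <- tr$wards
    label_seq[[i]] <- tr$labels
    n_at[i] <- sum(tr$labels == "atypical")
    n_reg[i] <- sum(tr$labels == "regular")
    n_st[i] <- sum(tr$labels == "site")
  }
  counts <- data.frame(n_atypical = n_at, n_regular = n_reg, n_site = n_st)

  lp_los <- sim_linpred(cfg$los_coefficients, counts, covs) +
    frailty[pat_row]
  mu_los <- exp(lp_los)
  los <- rgamma(m, shape = cfg$gamma_shape, rate = cfg$gamma_shape / mu_los)
  day_case <- admission_class == "day_case"
  los[day_case] <- runif(sum(day_case), 2, 8) / 24

  p_die <- plogis(sim_linpred(cfg$mortality_coefficients, counts, covs))
  died <- runif(m) < p_die
  p_readmit <- plogis(sim_linpred(cfg$readmission_coefficients, counts,
                                  covs))
  t_readmit <- rexp(m, rate = -log(1 - p_readmit) / 30)
  t_readmit[died] <- Inf

  # admission times: first spells uniform over the window (15-min grid);
  # second spells at least 45 days after the first discharge so they never
  # collide with the 30-day readmission window
  adm <- numeric(m)
  first_rows <- which(spell_seq == 1L)
  adm[first_rows] <- as.numeric(t0) +
    round_to_grid(runif(length(first_rows), 0,
                        cfg$study_years * 365 * 86400))
  second_rows <- which(spell_seq == 2L)
  if (length(second_rows) > 0) {
    prev <- match(pat_row[second_rows], pat_row[first_rows])
    gap <- (45 + rexp(length(second_rows), 1 / 60)) * 86400
    adm[second_rows] <- adm[first_rows][prev] +
      los[first_rows][prev] * 86400 + round_to_grid(gap)
  }
  dis <- adm + los * 86400

  spell_ids <- sprintf("SP%07d", seq_len(m))

  # ---- subsequent admissions (readmissions and pregnancy noise) ----
  alive <- !died
  gets_readmit_spell <- alive & is.finite(t_readmit) &
    t_readmit <= cfg$readmission_horizon_days
  gets_preg <- alive & !gets_readmit_spell &
    runif(m) < cfg$p_pregnancy_admission
  sub_of <- c(which(gets_readmit_spell), which(gets_preg))
  is_preg <- c(rep(FALSE, sum(gets_readmit_spell)),
               rep(TRUE, sum(gets_preg)))
  m2 <- length(sub_of)
  if (m2 > 0) {
    covs2 <- sim_covariates(m2)
    latent2 <- sample(SIM_SPECIALITIES, m2, TRUE, SIM_SPEC_WEIGHTS)
    site2 <- sample(sprintf("S%d", seq_len(cfg$n_sites)), m2, TRUE)
    delay <- ifelse(is_preg, runif(m2, 1, 29), t_readmit[sub_of])
    los2 <- pmin(rgamma(m2, shape = 2, rate = 2 / 2.5), 4)
    adm2 <- dis[sub_of] + delay * 86400
    dis2 <- adm2 + los2 * 86400
    covs2$major_diagnostic_category[is_preg] <- "pregnancy_childbirth"
    died2 <- runif(m2) < 0.02
    ward2 <- vapply(seq_len(m2), function(j) {
      pick1(geom$hosting[[site2[j]]][[latent2[j]]])
    }, character(1))
    spell_ids2 <- sprintf("SR%07d", seq_len(m2))
  }

  # ---- stay timestamps ----
  # ED and procedure stays get fixed short durations; the remaining stays
  # share the rest of the spell proportionally to gamma weights, so the
  # rebuilt LOS equals the drawn value exactly
  stays_list <- vector("list", m)
  proc_wards <- unname(geom$proc_ward)
  ed_wards <- unname(geom$ed_ward)
  for (i in seq_len(m)) {
    w <- ward_seq[[i]]
    k <- length(w)
    is_p <- w %in% proc_wards
    is_e <- w %in% ed_wards
    fixed <- ifelse(is_p, runif(k, 1.5, 4) / 24,
                    ifelse(is_e, runif(k, 1, 4) / 24, 0))
    free <- !(is_p | is_e)
    dur <- fixed
    rest <- los[i] - sum(fixed)
    if (any(free) && rest > sum(fixed) * 0.1) {
      wts <- rgamma(sum(free), shape = 1.5, rate = 1)
      dur[free] <- rest * wts / sum(wts)
    } else {
      # very short spell: split the whole LOS proportionally
      wts <- rgamma(k, shape = 1.5, rate = 1)
      dur <- los[i] * wts / sum(wts)
    }
    ends <- adm[i] + cumsum(dur) * 86400
    ends[k] <- dis[i]  # guard against rounding drift
    starts <- c(adm[i], ends[-k])
    stays_list[[i]] <- list(w = w, s = starts, e = ends)
  }

  stays <- data.frame(
    spell_id = rep(spell_ids, lengths(ward_seq)),
    patient_id = rep(patient_ids[pat_row], lengths(ward_seq)),
    ward_id = unlist(ward_seq),
    entry_ts = .POSIXct(unlist(lapply(stays_list, `[[`, "s")), tz = "UTC"),
    exit_ts = .POSIXct(unlist(lapply(stays_list, `[[`, "e")), tz = "UTC"),
    stringsAsFactors = FALSE
  )
  if (m2 > 0) {
    stays2 <- data.frame(
      spell_id = spell_ids2,
      patient_id = patient_ids[pat_row[sub_of]],
      ward_id = ward2,
      entry_ts = .POSIXct(adm2, tz = "UTC"),
      exit_ts = .POSIXct(dis2, tz = "UTC"),
      stringsAsFactors = FALSE
    )
    stays <- rbind(stays, stays2)
  }

  # ---- episodes (TFC sequences) ----
  # admitting codes are broad (division-level) and evolve into the latent
  # speciality; ~40% of spells only ever record the latent code
  division_code <- ifelse(latent %in% SIM_SURGICAL_SPECS,
                          "general_surgery", "general_medicine")
  singleton <- runif(m) < 0.4 | division_code == latent
  ep1 <- data.frame(spell_id = spell_ids,
                    episode_order = 1L,
                    tfc = ifelse(singleton, latent, division_code),
                    stringsAsFactors = FALSE)
  ep2 <- data.frame(spell_id = spell_ids[!singleton],
                    episode_order = 2L,
                    tfc = latent[!singleton],
                    stringsAsFactors = FALSE)
  episodes <- rbind(ep1, ep2)
  if (m2 > 0) {
    episodes <- rbind(episodes,
                      data.frame(spell_id = spell_ids2, episode_order = 1L,
                                 tfc = latent2, stringsAsFactors = FALSE))
  }
  episodes <- episodes[order(episodes$spell_id, episodes$episode_order), ]
  rownames(episodes) <- NULL

  # ---- spell table ----
  sp <- data.frame(spell_id = spell_ids,
                   patient_id = patient_ids[pat_row],
                   admission_class = admission_class,
                   maternity_paediatric_flag = maternity,
                   death_flag = died,
                   stringsAsFactors = FALSE)
  sp <- cbind(sp, covs)
  if (m2 > 0) {
    sp2 <- data.frame(spell_id = spell_ids2,
                      patient_id = patient_ids[pat_row[sub_of]],
                      admission_class = "emergency",
                      maternity_paediatric_flag = is_preg,
                      death_flag = died2,
                      stringsAsFactors = FALSE)
    sp <- rbind(sp, cbind(sp2, covs2))
  }

  events <- stays[, c("patient_id", "spell_id", "ward_id", "entry_ts",
                      "exit_ts")]
  cohort <- build_spells(events, wards_tbl,
                         covariates = sp[, setdiff(names(sp), "patient_id")],
                         episodes = episodes)

  # ---- ground truth ----
  truth_spells <- data.frame(
    spell_id = spell_ids, patient_id = patient_ids[pat_row],
    latent_speciality = latent,
    n_atypical = counts$n_atypical, n_regular = counts$n_regular,
    n_site = counts$n_site,
    mu_los = mu_los, los_days = los, died = died,
    p_readmit = p_readmit,
    readmitted_30d = !died & is.finite(t_readmit) & t_readmit <= 30,
    days_to_readmission = ifelse(is.finite(t_readmit), t_readmit, NA_real_),
    frailty = frailty[pat_row],
    stringsAsFactors = FALSE
  )
  truth_spells <- cbind(truth_spells,
                        covs[, c("age_band", "icu_flag",
                                 "elixhauser_count", "imaging_count")])
  n_pairs <- pmax(lengths(ward_seq) - 1L, 0L)
  truth_transfers <- data.frame(
    spell_id = rep(spell_ids, n_pairs),
    from_ward = unlist(lapply(ward_seq, function(w) {
      k <- length(w)
      if (k < 2) character(0) else w[-k]
    }), use.names = FALSE),
    to_ward = unlist(lapply(ward_seq, function(w) {
      k <- length(w)
      if (k < 2) character(0) else w[-1]
    }), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  # drop the ED-origin first move so rows align with the move labels
  keep <- !(truth_transfers$from_ward %in% ed_wards)
  truth_transfers <- truth_transfers[keep, , drop = FALSE]
  stopifnot(nrow(truth_transfers) == sum(lengths(label_seq)))
  truth_transfers$true_class <- unlist(label_seq, use.names = FALSE)
  truth_transfers$ordinal <- stats::ave(seq_len(nrow(truth_transfers)),
                                        truth_transfers$spell_id,
                                        FUN = seq_along)
  rownames(truth_transfers) <- NULL
  truth_transfers <- truth_transfers[, c("spell_id", "ordinal", "from_ward",
                                         "to_ward", "true_class")]

  structure(list(cohort = cohort, truth_spells = truth_spells,
                 truth_transfers = truth_transfers, config = cfg),
            class = "wardflow_sim")
}

sim_empty_spells <- function() {
  data.frame(spell_id = character(0), patient_id = character(0),
             admission_ts = as.POSIXct(character(0), tz = "UTC"),
             discharge_ts = as.POSIXct(character(0), tz = "UTC"),
             n_stays = integer(0), los_days = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.wardflow_sim <- function(x, ...) {
  cat("<wardflow_sim> seed", x$config$seed, "\n")
  print(x$cohort)
  invisible(x)
}

#' Write a simulated cohort, its ground truth and config to disk
#'
#' Writes the interchange CSVs via [write_cohort()] plus
#' `ground_truth_spells.csv`, `ground_truth_transfers.csv` and a YAML echo
#' of the configuration (`config.yaml`, requires the `yaml` package; a
#' plain `config.txt` deparse is written otherwise).
#'
#' @param sim a `wardflow_sim` from [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  write_cohort(sim$cohort, dir)
  write.csv(sim$truth_spells, file.path(dir, "ground_truth_spells.csv"),
            row.names = FALSE)
  write.csv(sim$truth_transfers,
            file.path(dir, "ground_truth_transfers.csv"), row.names = FALSE)
  cfg <- sim$config
  plain <- lapply(unclass(cfg), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(plain, file.path(dir, "config.yaml"))
  } else {
    writeLines(deparse(plain), file.path(dir, "config.txt"))
  }
  invisible(dir)
}
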