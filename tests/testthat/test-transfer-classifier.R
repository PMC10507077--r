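mk_transfers <- function(from, to, from_site = "S1", to_site = "S1",
                         spell = "s1") {
  n <- length(from)
  data.frame(spell_id = rep_len(spell, n), ordinal = seq_len(n),
             from_ward = from, to_ward = to,
             from_site = rep_len(from_site, n),
             to_site = rep_len(to_site, n),
             transfer_ts = as.POSIXct("2015-06-01", tz = "UTC"),
             classification = "unclassified", stringsAsFactors = FALSE)
}

test_that("classification follows site > atypical > regular precedence", {
  prof <- fake_profiles(list(
    A = "general_medicine",
    B = c("trauma", "neurosurgery"),
    C = c("cardiology", "renal"),
    D = "cardiology",
    E2 = "general_medicine"
  ))
  # cross-site wins even when speciality sets are disjoint
  tr <- mk_transfers("B", "E2", from_site = "S1", to_site = "S2")
  expect_equal(classify_transfers(tr, prof)$classification, "site")
  # disjoint sets on the same site: atypical
  tr <- mk_transfers("A", "B")
  expect_equal(classify_transfers(tr, prof)$classification, "atypical")
  # overlapping sets: regular
  tr <- mk_transfers("C", "D")
  expect_equal(classify_transfers(tr, prof)$classification, "regular")
  # exemption turns a would-be atypical move into a regular one
  tr <- mk_transfers("A", "B")
  expect_equal(classify_transfers(tr, prof, exempt_wards = "B")$classification,
               "regular")
  # unknown ward errors
  tr <- mk_transfers("A", "Z")
  expect_error(classify_transfers(tr, prof), "without a speciality profile")
})

test_that("classification matches the brute-force oracle on random catalogues", {
  set.seed(21)
  pool <- paste0("spec", 1:6)
  for (rep in 1:60) {
    n_w <- sample(4:8, 1)
    wards <- paste0("W", seq_len(n_w))
    sites <- sample(c("S1", "S2"), n_w, replace = TRUE)
    names(sites) <- wards
    sets <- lapply(wards, function(w) sample(pool, sample(1:3, 1)))
    names(sets) <- wards
    exempt <- sample(wards, sample(0:1, 1))
    prof <- fake_profiles(sets)
    pairs <- expand.grid(from = wards, to = wards,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    tr <- mk_transfers(pairs$from, pairs$to,
                       from_site = sites[pairs$from],
                       to_site = sites[pairs$to])
    got <- classify_transfers(tr, prof, exempt_wards = exempt)
    want <- mapply(classify_oracle, pairs$from, pairs$to,
                   sites[pairs$from], sites[pairs$to],
                   MoreArgs = list(sets = sets, exempt = exempt))
    expect_equal(got$classification, unname(want))
    # partition: exactly one class each
    expect_true(all(got$classification %in%
                      c("atypical", "regular", "site")))
  }
})

test_that("procedure-ward exemption requires both the flag and short stays", {
  wards <- toy_wards()
  wards$is_procedure_ward[wards$ward_id %in% c("B", "C")] <- TRUE
  # A: long stays, flagged FALSE; B: 4h stays, flagged; C: 12h, flagged;
  # D: 4h stays but unflagged
  wards$is_procedure_ward[wards$ward_id == "D"] <- FALSE
  ev <- toy_events(
    list(spell_id = "s1", patient_id = "p1", wards = c("A", "B", "A"),
         hours = c(0, 24, 28, 48)),
    list(spell_id = "s2", patient_id = "p2", wards = c("A", "C", "A"),
         hours = c(0, 24, 36, 60)),
    list(spell_id = "s3", patient_id = "p3", wards = c("A", "D", "A"),
         hours = c(0, 24, 28, 48))
  )
  co <- build_spells(ev, wards)
  expect_equal(prune_procedure_wards(co, threshold_hours = 6), "B")
  # threshold 0 exempts nothing
  expect_equal(length(prune_procedure_wards(co, threshold_hours = 0)), 0)
})

test_that("exposure tallies partition the classified transfers", {
  tr <- mk_transfers(c("A", "B"), c("B", "C"))
  tr$classification <- c("atypical", "regular")
  ex <- count_exposures(tr)
  expect_equal(ex[, c("n_atypical", "n_regular", "n_site")],
               data.frame(n_atypical = 1L, n_regular = 1L, n_site = 0L))

  tr2 <- mk_transfers(c("A", "B", "C"), c("B", "C", "A"))
  tr2$classification <- c("site", "atypical", "atypical")
  ex2 <- count_exposures(tr2)
  expect_equal(ex2$n_atypical, 2L)
  expect_equal(ex2$n_site, 1L)

  expect_error(count_exposures(tr[0, ]), "no transfers")
  tr$classification[1] <- "unclassified"
  expect_error(count_exposures(tr), "unclassified")
})

test_that("atypical pair statistics pool reciprocal trips", {
  tr <- mk_transfers(c("a", "a", "a", "b", "b"), c("b", "b", "b", "a", "a"))
  tr$classification <- "atypical"
  ps <- atypical_pair_stats(tr)
  expect_equal(ps$n_unique_pairs, 1L)
  expect_equal(ps$pairs$count, 5L)
  expect_equal(sum(ps$frequency_distribution), 1)
  # ordered direction keeps the two routes apart
  ps2 <- atypical_pair_stats(tr, direction = "ordered")
  expect_equal(ps2$n_unique_pairs, 2L)
  expect_equal(sort(ps2$pairs$count), c(2L, 3L))

  one <- mk_transfers("a", "b")
  one$classification <- "atypical"
  ps3 <- atypical_pair_stats(one)
  expect_equal(ps3$n_unique_pairs, 1L)
  expect_equal(unname(ps3$frequency_distribution["1"]), 1)

  none <- mk_transfers("a", "b")
  none$classification <- "regular"
  ps4 <- atypical_pair_stats(none)
  expect_equal(ps4$n_unique_pairs, 0L)
})

test_that("chord matrices count per-site atypical traffic with capped labels", {
  sim <- small_sim()
  res <- run_pipeline(sim$cohort)
  tr <- res$transfers
  at <- tr[tr$classification == "atypical" & tr$from_site == "S1", ]
  cm <- chord_matrix(tr, res$profiles, "S1")
  expect_equal(sum(cm), nrow(at))
  # labels carry at most 3 specialities
  n_specs <- vapply(strsplit(sub(".*\\[(.*)\\]", "\\1", rownames(cm)),
                             "|", fixed = TRUE), length, integer(1))
  expect_true(all(n_specs <= 3))
  # a one-off matrix entry matches a direct count
  i <- which(cm > 0, arr.ind = TRUE)[1, ]
  fw <- sub(" \\[.*", "", rownames(cm)[i["row"]])
  tw <- sub(" \\[.*", "", colnames(cm)[i["col"]])
  expect_equal(cm[i["row"], i["col"]],
               sum(at$from_ward == fw & at$to_ward == tw))
  # absent site yields an empty matrix
  expect_equal(nrow(chord_matrix(tr, res$profiles, "S9")), 0)
})

test_that("lowering the pruning threshold never removes atypical transfers", {
  sim <- small_sim()
  co <- sim$cohort
  stage6 <- run_pipeline(co, threshold_hours = 6)
  stage0 <- run_pipeline(co, threshold_hours = 0)
  n6 <- sum(stage6$transfers$classification == "atypical")
  n0 <- sum(stage0$transfers$classification == "atypical")
  expect_gte(n0, n6)
})
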