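test_that("spells are rebuilt from events with same-ward merging", {
  wards <- toy_wards()

  # minimal path: two wards, contiguous
  ev <- toy_events(list(spell_id = "s1", patient_id = "p1",
                        wards = c("A", "B"), hours = c(0, 24, 48)))
  co <- build_spells(ev, wards)
  expect_equal(nrow(co$spells), 1)
  expect_equal(nrow(co$stays), 2)
  expect_equal(nrow(extract_transfers(co)), 1)
  expect_equal(co$spells$los_days, 2)
  expect_equal(co$spells$admission_ts, co$stays$entry_ts[1])

  # back-to-back rows on the same ward merge into one stay
  ev <- toy_events(list(spell_id = "s1", patient_id = "p1",
                        wards = c("A", "A"), hours = c(0, 24, 48)))
  co <- build_spells(ev, wards)
  expect_equal(nrow(co$stays), 1)
  expect_equal(nrow(extract_transfers(co)), 0)

  # a return visit is a separate stay and a second transfer
  ev <- toy_events(list(spell_id = "s1", patient_id = "p1",
                        wards = c("A", "B", "A"), hours = c(0, 24, 48, 72)))
  co <- build_spells(ev, wards)
  expect_equal(nrow(co$stays), 3)
  tr <- extract_transfers(co)
  expect_equal(tr$ordinal, c(1, 2))
  expect_equal(tr$from_ward, c("A", "B"))
  expect_equal(tr$to_ward, c("B", "A"))
})

test_that("malformed event logs are rejected and gaps only warn", {
  wards <- toy_wards()
  ev <- toy_events(list(spell_id = "s1", patient_id = "p1",
                        wards = c("A", "B"), hours = c(0, 24, 48)))
  expect_error(build_spells(ev[, setdiff(names(ev), "ward_id")], wards),
               "missing mandatory field")

  # overlapping stays beyond the tolerance name the spell
  ev2 <- ev
  ev2$entry_ts[2] <- ev2$entry_ts[2] - 3 * 3600
  expect_error(build_spells(ev2, wards), "overlapping stays.*s1")

  # a gap beyond tolerance warns but keeps the spell
  ev3 <- ev
  ev3$entry_ts[2] <- ev3$entry_ts[2] + 2 * 3600
  expect_warning(co <- build_spells(ev3, wards), "gap")
  expect_equal(nrow(co$spells), 1)

  # a 10-minute jitter is within the 15-minute resolution: silent
  ev4 <- ev
  ev4$entry_ts[2] <- ev4$entry_ts[2] + 10 * 60
  expect_silent(build_spells(ev4, wards))
})

test_that("ED-origin moves are dropped but the ED stay is kept", {
  wards <- toy_wards()
  ev <- toy_events(list(spell_id = "s1", patient_id = "p1",
                        wards = c("ED1", "A", "B"), hours = c(0, 3, 24, 48)))
  co <- build_spells(ev, wards)
  expect_equal(nrow(co$stays), 3)
  tr <- extract_transfers(co)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$from_ward, "A")
  expect_equal(tr$to_ward, "B")
  expect_equal(tr$ordinal, 1)
  # admission timestamp still anchored at the ED entry
  expect_equal(co$spells$admission_ts, ev$entry_ts[1])
})

test_that("inclusion keeps emergency movers and logs exclusions in order", {
  wards <- toy_wards()
  ev <- toy_events(
    list(spell_id = "s1", patient_id = "p1", wards = "A",
         hours = c(0, 48)),                                  # single ward
    list(spell_id = "s2", patient_id = "p2", wards = c("A", "B", "C"),
         hours = c(0, 24, 48, 72)),                          # elective
    list(spell_id = "s3", patient_id = "p3", wards = c("A", "B"),
         hours = c(0, 24, 48)),                              # included
    list(spell_id = "s4", patient_id = "p4", wards = c("A", "B"),
         hours = c(0, 24, 48))                               # maternity
  )
  covs <- data.frame(
    spell_id = c("s1", "s2", "s3", "s4"),
    admission_class = c("emergency", "elective", "emergency", "emergency"),
    maternity_paediatric_flag = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  co <- build_spells(ev, wards, covariates = covs)
  inc <- apply_inclusion(co)
  expect_equal(inc$cohort$spells$spell_id, "s3")
  expect_equal(inc$exclusion_log$criterion,
               c("single ward", "non-emergency admission",
                 "maternity or paediatric"))
  expect_equal(inc$exclusion_log$n_excluded, c(1, 1, 1))
  expect_equal(inc$exclusion_log$n_remaining, c(3, 2, 1))
  expect_equal(unique(inc$transfers$spell_id), "s3")

  # empty result warns rather than errors
  co2 <- build_spells(ev[ev$spell_id == "s2", ], wards,
                      covariates = covs[covs$spell_id == "s2", ])
  expect_warning(apply_inclusion(co2), "no spells meet")
})

test_that("included set is invariant to the order criteria are applied", {
  sim <- small_sim()
  co <- sim$cohort
  tr <- extract_transfers(co)
  inc <- apply_inclusion(co, tr)
  # each criterion is a pure predicate; intersect them in a shuffled order
  sp <- co$spells
  preds <- list(sp$spell_id %in% tr$spell_id,
                sp$admission_class == "emergency",
                !sp$maternity_paediatric_flag)
  for (perm in list(c(3, 1, 2), c(2, 3, 1))) {
    keep <- Reduce(`&`, preds[perm])
    expect_setequal(sp$spell_id[keep], inc$cohort$spells$spell_id)
  }
})

test_that("transfer counts equal merged stays minus one minus ED drops", {
  sim <- small_sim()
  co <- sim$cohort
  tr <- extract_transfers(co)
  ed <- co$wards$ward_id[co$wards$is_ed]
  st <- co$stays
  per_spell_stays <- table(st$spell_id)
  ed_origin <- st$spell_id[st$ward_id %in% ed &
                             st$stay_order < per_spell_stays[st$spell_id]]
  n_tr <- table(factor(tr$spell_id, levels = names(per_spell_stays)))
  n_ed <- table(factor(ed_origin, levels = names(per_spell_stays)))
  expect_equal(as.integer(n_tr),
               as.integer(per_spell_stays) - 1L - as.integer(n_ed))
})

test_that("writing and rebuilding a cohort round-trips the spells", {
  sim <- generate_cohort(sim_config(seed = 5, n_patients = 200))
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir)
  back <- read_cohort(dir)
  a <- sim$cohort$spells[order(sim$cohort$spells$spell_id), ]
  b <- back$spells[order(back$spells$spell_id), ]
  expect_equal(a$spell_id, b$spell_id)
  expect_equal(as.numeric(a$admission_ts), as.numeric(b$admission_ts),
               tolerance = 1e-5)
  expect_equal(a$los_days, b$los_days, tolerance = 1e-8)
  expect_equal(a$n_stays, b$n_stays)
  expect_equal(a$admission_class, b$admission_class)
  expect_equal(nrow(back$stays), nrow(sim$cohort$stays))
  # and the derived transfer list is identical
  ta <- extract_transfers(sim$cohort)
  tb <- extract_transfers(back)
  expect_equal(ta[, c("spell_id", "ordinal", "from_ward", "to_ward")],
               tb[, c("spell_id", "ordinal", "from_ward", "to_ward")])
})
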