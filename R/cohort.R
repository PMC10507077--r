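## Cohort construction: spells from ward-entry events, inclusion rules,
## transfer extraction.

TS_FORMAT <- "%Y-%m-%dT%H:%M:%OS"

#' Parse ISO-8601 timestamps to POSIXct (UTC)
#' @param x character vector of ISO-8601 timestamps.
#' @return POSIXct vector in UTC.
#' @keywords internal
parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
  if (anyNA(out) && !anyNA(x)) {
    # fall back to a date-only or space-separated form
    alt <- as.POSIXct(x, tz = "UTC")
    out[is.na(out)] <- alt[is.na(out)]
  }
  out
}

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")

#' Construct a transfer cohort object
#'
#' Bundles the four tables the pipeline operates on: one row per spell
#' (admission-level covariates and outcomes), one row per ward stay, one row
#' per consultant episode (TFC sequence), and the ward catalogue.
#'
#' @param spells data.frame, one row per spell.
#' @param stays data.frame, one row per ward stay.
#' @param episodes data.frame with columns `spell_id`, `episode_order`, `tfc`.
#' @param wards ward catalogue with columns `ward_id`, `site_id`, `is_ed`,
#'   `is_procedure_ward`.
#' @return An object of class `transfer_cohort`.
#' @export
transfer_cohort <- function(spells, stays, episodes, wards) {
  structure(list(spells = spells, stays = stays,
                 episodes = episodes, wards = wards),
            class = "transfer_cohort")
}

#' @export
print.transfer_cohort <- function(x, ...) {
  cat("<transfer_cohort>\n")
  cat("  spells:  ", nrow(x$spells), "\n")
  cat("  stays:   ", nrow(x$stays), "\n")
  cat("  episodes:", nrow(x$episodes), "\n")
  cat("  wards:   ", nrow(x$wards),
      sprintf("(%d sites)\n", length(unique(x$wards$site_id))))
  invisible(x)
}

REQUIRED_EVENT_COLS <- c("patient_id", "spell_id", "ward_id", "entry_ts", "exit_ts")
REQUIRED_WARD_COLS <- c("ward_id", "site_id", "is_ed", "is_procedure_ward")

#' Reconstruct spells from raw ward-entry events
#'
#' Orders each spell's ward-entry rows by entry time, merges back-to-back
#' rows on the same ward into a single stay, and derives the spell-level
#' admission and discharge timestamps. Gaps between consecutive stays larger
#' than `tol_minutes` produce a warning; overlaps beyond the tolerance are a
#' malformed-spell error. The event data are recorded at roughly 15-minute
#' resolution, hence the default tolerance.
#'
#' @param events data.frame with columns `patient_id`, `spell_id`,
#'   `ward_id`, `entry_ts`, `exit_ts` (ISO-8601 strings or POSIXct).
#' @param wards ward catalogue (see [transfer_cohort()]); supplies
#'   `site_id` and the ED / procedure-ward flags.
#' @param covariates optional data.frame of spell-level covariates keyed by
#'   `spell_id`; merged onto the spell table.
#' @param episodes optional data.frame of consultant episodes
#'   (`spell_id`, `episode_order`, `tfc`).
#' @param tol_minutes contiguity tolerance between consecutive stays.
#' @return A `transfer_cohort`. Spell rows carry `patient_id`,
#'   `admission_ts`, `discharge_ts`, `los_days`, `n_stays`, and (derived
#'   from the admission timestamp unless already present in `covariates`)
#'   `weekend_admission` and `out_of_hours_admission`.
#' @export
build_spells <- function(events, wards, covariates = NULL, episodes = NULL,
                         tol_minutes = 15) {
  missing_cols <- setdiff(REQUIRED_EVENT_COLS, names(events))
  if (length(missing_cols) > 0) {
    stop("event log is missing mandatory field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  missing_w <- setdiff(REQUIRED_WARD_COLS, names(wards))
  if (length(missing_w) > 0) {
    stop("ward catalogue is missing mandatory field(s): ",
         paste(missing_w, collapse = ", "))
  }
  events$entry_ts <- parse_ts(events$entry_ts)
  events$exit_ts <- parse_ts(events$exit_ts)
  if (anyNA(events$entry_ts) || anyNA(events$exit_ts)) {
    stop("unparseable entry/exit timestamps in event log")
  }
  if (any(events$exit_ts < events$entry_ts)) {
    bad <- unique(events$spell_id[events$exit_ts < events$entry_ts])
    stop("malformed spell(s) with exit before entry: ",
         paste(head(bad, 5), collapse = ", "))
  }
  unknown <- setdiff(unique(events$ward_id), wards$ward_id)
  if (length(unknown) > 0) {
    stop("event log references ward(s) absent from the catalogue: ",
         paste(head(unknown, 5), collapse = ", "))
  }

  ord <- order(events$spell_id, events$entry_ts)
  ev <- events[ord, , drop = FALSE]
  tol <- tol_minutes * 60

  same_spell <- c(FALSE, ev$spell_id[-1] == ev$spell_id[-nrow(ev)])
  if (nrow(ev) > 1) {
    prev_exit <- c(ev$exit_ts[1], ev$exit_ts[-nrow(ev)])
    overlap <- same_spell &
      (as.numeric(ev$entry_ts) < as.numeric(prev_exit) - tol)
    if (any(overlap)) {
      stop("malformed spell(s) with overlapping stays: ",
           paste(unique(ev$spell_id[overlap]), collapse = ", "))
    }
    gap <- same_spell &
      (as.numeric(ev$entry_ts) > as.numeric(prev_exit) + tol)
    if (any(gap)) {
      warning(sum(gap), " stay gap(s) beyond ", tol_minutes,
              " minutes in spell(s): ",
              paste(head(unique(ev$spell_id[gap]), 5), collapse = ", "))
    }
    # merge back-to-back rows on the same ward into one stay
    same_ward <- same_spell &
      c(FALSE, ev$ward_id[-1] == ev$ward_id[-nrow(ev)]) &
      (as.numeric(ev$entry_ts) <= as.numeric(prev_exit) + tol)
    grp <- cumsum(!same_ward)
  } else {
    grp <- seq_len(nrow(ev))
  }

  first_of <- !duplicated(grp)
  last_of <- !duplicated(grp, fromLast = TRUE)
  stays <- data.frame(
    spell_id = ev$spell_id[first_of],
    patient_id = ev$patient_id[first_of],
    ward_id = ev$ward_id[first_of],
    entry_ts = ev$entry_ts[first_of],
    exit_ts = ev$exit_ts[last_of],
    stringsAsFactors = FALSE
  )
  stays$site_id <- wards$site_id[match(stays$ward_id, wards$ward_id)]
  stays$stay_order <- stats::ave(seq_len(nrow(stays)), stays$spell_id,
                                 FUN = seq_along)

  sfirst <- !duplicated(stays$spell_id)
  slast <- !duplicated(stays$spell_id, fromLast = TRUE)
  spells <- data.frame(
    spell_id = stays$spell_id[sfirst],
    patient_id = stays$patient_id[sfirst],
    admission_ts = stays$entry_ts[sfirst],
    discharge_ts = stays$exit_ts[slast],
    n_stays = as.integer(tabulate(factor(stays$spell_id,
                                         levels = stays$spell_id[sfirst]))),
    stringsAsFactors = FALSE
  )
  spells$los_days <-
    as.numeric(spells$discharge_ts) - as.numeric(spells$admission_ts)
  spells$los_days <- spells$los_days / 86400

  if (!is.null(covariates)) {
    spells <- merge(spells, covariates, by = "spell_id", all.x = TRUE,
                    sort = FALSE)
    spells <- spells[order(spells$spell_id), , drop = FALSE]
    rownames(spells) <- NULL
  }
  if (!"weekend_admission" %in% names(spells)) {
    spells$weekend_admission <- is_weekend(spells$admission_ts)
  }
  if (!"out_of_hours_admission" %in% names(spells)) {
    spells$out_of_hours_admission <- is_out_of_hours(spells$admission_ts)
  }

  if (is.null(episodes)) {
    episodes <- data.frame(spell_id = character(0),
                           episode_order = integer(0), tfc = character(0),
                           stringsAsFactors = FALSE)
  }
  transfer_cohort(spells, stays, episodes, wards)
}

#' @keywords internal
is_weekend <- function(ts) {
  format(ts, "%u", tz = "UTC") %in% c("6", "7")
}

#' Out-of-hours admission flag (7pm to 7am)
#' @keywords internal
is_out_of_hours <- function(ts) {
  hr <- as.integer(format(ts, "%H", tz = "UTC"))
  hr >= 19 | hr < 7
}

#' Extract ward-to-ward transfers from a cohort
#'
#' One record per consecutive pair of stays on different wards. Moves whose
#' origin ward is flagged as an emergency-department location are dropped
#' (the ED stay itself is retained so the admission timestamp is
#' preserved). Ordinals are renumbered contiguously from 1 after the drop.
#'
#' @param cohort a `transfer_cohort`.
#' @return data.frame with columns `spell_id`, `ordinal`, `from_ward`,
#'   `to_ward`, `from_site`, `to_site`, `transfer_ts`, `classification`
#'   (initialised to `"unclassified"`).
#' @export
extract_transfers <- function(cohort) {
  st <- cohort$stays
  n <- nrow(st)
  empty <- data.frame(spell_id = character(0), ordinal = integer(0),
                      from_ward = character(0), to_ward = character(0),
                      from_site = character(0), to_site = character(0),
                      transfer_ts = as.POSIXct(character(0), tz = "UTC"),
                      classification = character(0), stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  idx <- which(st$spell_id[-1] == st$spell_id[-n])
  if (length(idx) == 0) return(empty)
  tr <- data.frame(
    spell_id = st$spell_id[idx],
    from_ward = st$ward_id[idx],
    to_ward = st$ward_id[idx + 1],
    from_site = st$site_id[idx],
    to_site = st$site_id[idx + 1],
    transfer_ts = st$entry_ts[idx + 1],
    stringsAsFactors = FALSE
  )
  # a repeat of the same ward after a tolerated gap is not a transfer
  tr <- tr[tr$from_ward != tr$to_ward, , drop = FALSE]
  ed_wards <- cohort$wards$ward_id[cohort$wards$is_ed]
  tr <- tr[!(tr$from_ward %in% ed_wards), , drop = FALSE]
  if (nrow(tr) == 0) return(empty)
  tr$ordinal <- stats::ave(seq_len(nrow(tr)), tr$spell_id, FUN = seq_along)
  tr$classification <- "unclassified"
  rownames(tr) <- NULL
  tr[, c("spell_id", "ordinal", "from_ward", "to_ward", "from_site",
         "to_site", "transfer_ts", "classification")]
}

#' Apply the study inclusion criteria
#'
#' Retains emergency spells with at least one (non-ED-origin) transfer and
#' no maternity/paediatric flag. Each criterion is a pure predicate, so the
#' included set does not depend on their order; the exclusion log reports
#' sequential removals in the order applied.
#'
#' @param cohort a `transfer_cohort`.
#' @param transfers output of [extract_transfers()]; computed if `NULL`.
#' @return list with elements `cohort` (subset), `transfers` (subset),
#'   `exclusion_log` (data.frame of criterion, n_excluded, n_remaining).
#' @export
apply_inclusion <- function(cohort, transfers = NULL) {
  if (is.null(transfers)) transfers <- extract_transfers(cohort)
  sp <- cohort$spells
  keep <- rep(TRUE, nrow(sp))
  log_rows <- list()

  has_transfer <- sp$spell_id %in% transfers$spell_id
  criteria <- list(
    `single ward` = has_transfer,
    `non-emergency admission` =
      if ("admission_class" %in% names(sp)) sp$admission_class == "emergency"
      else rep(TRUE, nrow(sp)),
    `maternity or paediatric` =
      if ("maternity_paediatric_flag" %in% names(sp))
        !isTRUE_vec(sp$maternity_paediatric_flag)
      else rep(TRUE, nrow(sp))
  )
  for (nm in names(criteria)) {
    pass <- criteria[[nm]]
    n_removed <- sum(keep & !pass)
    keep <- keep & pass
    log_rows[[nm]] <- data.frame(criterion = nm, n_excluded = n_removed,
                                 n_remaining = sum(keep),
                                 stringsAsFactors = FALSE)
  }
  exclusion_log <- do.call(rbind, log_rows)
  rownames(exclusion_log) <- NULL

  if (!any(keep)) warning("no spells meet the inclusion criteria")
  ids <- sp$spell_id[keep]
  out <- transfer_cohort(
    spells = sp[keep, , drop = FALSE],
    stays = cohort$stays[cohort$stays$spell_id %in% ids, , drop = FALSE],
    episodes = cohort$episodes[cohort$episodes$spell_id %in% ids, ,
                               drop = FALSE],
    wards = cohort$wards
  )
  rownames(out$spells) <- NULL
  list(cohort = out,
       transfers = transfers[transfers$spell_id %in% ids, , drop = FALSE],
       exclusion_log = exclusion_log)
}

# treat NA flags as FALSE
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Write a cohort to a directory of CSV files
#'
#' Writes `events.csv` (one row per stay), `spells.csv`, `episodes.csv` and
#' `wards.csv` with ISO-8601 timestamps, the interchange format understood
#' by [read_cohort()].
#'
#' @param cohort a `transfer_cohort`.
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- cohort$stays[, c("patient_id", "spell_id", "ward_id",
                         "entry_ts", "exit_ts")]
  ev$entry_ts <- format_ts(ev$entry_ts)
  ev$exit_ts <- format_ts(ev$exit_ts)
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)

  sp <- cohort$spells
  for (col in c("admission_ts", "discharge_ts")) {
    if (col %in% names(sp)) sp[[col]] <- format_ts(sp[[col]])
  }
  write.csv(sp, file.path(dir, "spells.csv"), row.names = FALSE)
  write.csv(cohort$episodes, file.path(dir, "episodes.csv"),
            row.names = FALSE)
  write.csv(cohort$wards, file.path(dir, "wards.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' Rebuilds the spell table from the raw events via [build_spells()], using
#' `spells.csv` as the covariate table.
#'
#' @param dir directory containing `events.csv`, `spells.csv`,
#'   `episodes.csv`, `wards.csv`.
#' @param tol_minutes passed to [build_spells()].
#' @return A `transfer_cohort`.
#' @export
read_cohort <- function(dir, tol_minutes = 15) {
  events <- read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  wards <- read.csv(file.path(dir, "wards.csv"), stringsAsFactors = FALSE)
  episodes <- read.csv(file.path(dir, "episodes.csv"),
                       stringsAsFactors = FALSE)
  covs <- read.csv(file.path(dir, "spells.csv"), stringsAsFactors = FALSE)
  drop <- intersect(c("patient_id", "admission_ts", "discharge_ts",
                      "los_days", "n_stays"), names(covs))
  covs <- covs[, setdiff(names(covs), drop), drop = FALSE]
  build_spells(events, wards, covariates = covs, episodes = episodes,
               tol_minutes = tol_minutes)
}
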