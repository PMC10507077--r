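## 30-day emergency readmission index construction.

#' Build the 30-day readmission index
#'
#' Index admissions are defined iteratively: every included spell that did
#' not end in death is an index admission, and is flagged readmitted if the
#' same patient has a subsequent *emergency* admission to any site of the
#' network, for any reason except pregnancy, with admission time in
#' `(discharge, discharge + window_days]` (inclusive at the boundary).
#' Subsequent spells need not themselves meet the inclusion criteria.
#'
#' @param spells the full spell table (all spells of each patient, every
#'   admission class), with columns `spell_id`, `patient_id`,
#'   `admission_ts`, `discharge_ts`, `admission_class`, `death_flag` and
#'   `major_diagnostic_category`.
#' @param included_ids spell ids eligible to be index admissions (the
#'   included analysis cohort); defaults to all spells.
#' @param window_days readmission window, default 30.
#' @param pregnancy_categories diagnostic categories that do not count as
#'   readmissions.
#' @return data.frame with `spell_id`, `readmitted_30d`,
#'   `days_to_readmission` (NA when not readmitted). Spells ending in death
#'   are absent from the result.
#' @export
build_readmission_index <- function(spells, included_ids = spells$spell_id,
                                    window_days = 30,
                                    pregnancy_categories = "pregnancy_childbirth") {
  sp <- spells
  sp$admission_ts <- parse_ts(sp$admission_ts)
  sp$discharge_ts <- parse_ts(sp$discharge_ts)
  ord <- order(sp$patient_id, sp$admission_ts)
  sp <- sp[ord, , drop = FALSE]

  n <- nrow(sp)
  if (n > 1) {
    same <- sp$patient_id[-1] == sp$patient_id[-n]
    overlap <- same & (as.numeric(sp$admission_ts[-1]) <
                         as.numeric(sp$discharge_ts[-n]))
    if (any(overlap)) {
      stop("overlapping spells for patient(s): ",
           paste(head(unique(sp$patient_id[-1][overlap]), 5),
                 collapse = ", "))
    }
  }

  death <- isTRUE_vec(sp$death_flag)
  is_index <- (sp$spell_id %in% included_ids) & !death
  counts_as_readmission <- sp$admission_class == "emergency" &
    !(sp$major_diagnostic_category %in% pregnancy_categories)

  win <- window_days * 86400
  readmitted <- rep(FALSE, n)
  days_to <- rep(NA_real_, n)
  # candidate admissions per patient, scanned forward from each index spell
  idx_by_patient <- split(seq_len(n), sp$patient_id)
  for (rows in idx_by_patient) {
    if (length(rows) < 2) next
    adm <- as.numeric(sp$admission_ts[rows])
    dis <- as.numeric(sp$discharge_ts[rows])
    ok <- counts_as_readmission[rows]
    for (j in seq_along(rows)) {
      if (!is_index[rows[j]]) next
      later <- which(ok & adm > dis[j] & adm <= dis[j] + win)
      later <- later[later != j]
      if (length(later) > 0) {
        readmitted[rows[j]] <- TRUE
        days_to[rows[j]] <- (min(adm[later]) - dis[j]) / 86400
      }
    }
  }

  out <- data.frame(spell_id = sp$spell_id[is_index],
                    readmitted_30d = readmitted[is_index],
                    days_to_readmission = days_to[is_index],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
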