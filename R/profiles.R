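## Ward speciality profiles: TFC deposits, Herfindahl-Hirschman index,
## equivalent market size, speciality assignment.

#' Select the representative TFC of each spell
#'
#' A spell's consultant episodes carry an ordered sequence of treatment
#' function codes (TFCs). Admitting codes are broad (e.g. general medicine)
#' and typically evolve into more specific ones, so the last episode's code
#' is taken as the most accurate summary of the spell; `mode = "first"` is
#' the sensitivity alternative.
#'
#' @param episodes data.frame with `spell_id`, `episode_order`, `tfc`.
#' @param mode `"last"` (default) or `"first"`.
#' @return named character vector: TFC per spell_id.
#' @export
select_spell_tfc <- function(episodes, mode = c("last", "first")) {
  mode <- match.arg(mode)
  if (nrow(episodes) == 0) {
    return(setNames(character(0), character(0)))
  }
  if (anyNA(episodes$tfc)) stop("missing TFC code in episode table")
  ord <- order(episodes$spell_id, episodes$episode_order)
  ep <- episodes[ord, , drop = FALSE]
  pick <- if (mode == "last") {
    !duplicated(ep$spell_id, fromLast = TRUE)
  } else {
    !duplicated(ep$spell_id)
  }
  setNames(ep$tfc[pick], ep$spell_id[pick])
}

#' Deposit spell specialities onto wards
#'
#' Each spell's selected TFC is recorded once against every distinct ward
#' the patient entered during that spell (repeat visits to the same ward do
#' not deposit twice). The unit of deposit is the spell. The profiling
#' population should be the full cohort, including elective and day-case
#' spells, since ward function is defined by total usage.
#'
#' @param cohort a `transfer_cohort`.
#' @param mode TFC selection mode, see [select_spell_tfc()].
#' @return data.frame of (`ward_id`, `speciality`, `n`) counts.
#' @export
deposit_specialities <- function(cohort, mode = c("last", "first")) {
  mode <- match.arg(mode)
  tfc <- select_spell_tfc(cohort$episodes, mode)
  st <- cohort$stays
  visits <- unique(st[, c("spell_id", "ward_id")])
  visits$speciality <- unname(tfc[visits$spell_id])
  missing <- is.na(visits$speciality)
  if (any(missing)) {
    stop("spell(s) without any TFC episode: ",
         paste(head(unique(visits$spell_id[missing]), 5), collapse = ", "))
  }
  if (nrow(visits) == 0) {
    return(data.frame(ward_id = character(0), speciality = character(0),
                      n = integer(0), stringsAsFactors = FALSE))
  }
  agg <- aggregate(list(n = rep(1L, nrow(visits))),
                   by = list(ward_id = visits$ward_id,
                             speciality = visits$speciality),
                   FUN = sum)
  agg <- agg[order(agg$ward_id, agg$speciality), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Herfindahl-Hirschman concentration index
#'
#' `HHI = sum_i S_i^2`, where `S_i` is the share of deposits from
#' speciality `i`. Equals 1 for a single-speciality ward and `1/N` for a
#' ward uniformly shared by `N` specialities.
#'
#' @param counts non-negative numeric vector of deposit counts (or shares).
#' @return HHI in `(0, 1]`.
#' @export
compute_hhi <- function(counts) {
  counts <- counts[!is.na(counts)]
  total <- sum(counts)
  if (length(counts) == 0 || total <= 0) {
    stop("undefined speciality profile: no positive deposit counts")
  }
  if (any(counts < 0)) stop("negative deposit counts")
  sum((counts / total)^2)
}

#' Equivalent market size
#'
#' The inverse of the HHI is the effective number of speciality groupings a
#' ward serves; it is rounded to the nearest integer (halves up, for
#' platform-independent determinism) to give the number of specialities
#' assigned to the ward.
#'
#' @param hhi numeric in `(0, 1]`.
#' @return positive integer.
#' @export
compute_ems <- function(hhi) {
  if (any(is.na(hhi)) || any(hhi <= 0) || any(hhi > 1 + 1e-12)) {
    stop("hhi must lie in (0, 1]")
  }
  pmax(1L, as.integer(floor(1 / hhi + 0.5)))
}

#' Assign a ward's representative specialities
#'
#' The `ems` specialities with the largest deposit shares; ties are broken
#' by lexicographic speciality code so assignment is deterministic.
#'
#' @param counts named numeric vector of deposit counts per speciality.
#' @param ems number of specialities to assign.
#' @return character vector of speciality codes (length `min(ems, N)`).
#' @export
assign_specialities <- function(counts, ems) {
  counts <- counts[!is.na(counts) & counts > 0]
  if (length(counts) == 0) stop("no positive deposit counts")
  if (ems > length(counts)) {
    warning("ems (", ems, ") exceeds number of observed specialities (",
            length(counts), "); capping")
    ems <- length(counts)
  }
  ord <- order(-counts, names(counts))
  sort(names(counts)[ord[seq_len(ems)]])
}

#' Profile every ward's speciality mix
#'
#' Chains deposits, HHI, EMS and assignment for each ward. Wards with fewer
#' than `min_deposits` deposits are marked low-evidence and assigned the
#' union of all specialities observed on them, so transfers touching them
#' are never classified atypical on thin evidence.
#'
#' @param cohort a `transfer_cohort` (the full profiling population).
#' @param mode TFC selection mode, see [select_spell_tfc()].
#' @param min_deposits stability threshold for EMS-based assignment.
#' @return An object of class `ward_profiles`: list with `profiles` (one
#'   row per ward: `ward_id`, `total_deposits`, `n_specialities`, `hhi`,
#'   `ems`, `low_evidence`, `specialities` as a `|`-delimited string),
#'   `shares` (long table of per-ward speciality shares) and `assigned`
#'   (named list of speciality character vectors).
#' @export
profile_wards <- function(cohort, mode = c("last", "first"),
                          min_deposits = 10) {
  mode <- match.arg(mode)
  dep <- deposit_specialities(cohort, mode)
  wards <- unique(dep$ward_id)
  assigned <- vector("list", length(wards))
  names(assigned) <- wards
  rows <- vector("list", length(wards))
  for (i in seq_along(wards)) {
    w <- wards[i]
    sub <- dep[dep$ward_id == w, , drop = FALSE]
    counts <- setNames(sub$n, sub$speciality)
    total <- sum(counts)
    hhi <- compute_hhi(counts)
    ems <- compute_ems(hhi)
    low <- total < min_deposits
    specs <- if (low) sort(names(counts)) else assign_specialities(counts, ems)
    assigned[[i]] <- specs
    rows[[i]] <- data.frame(
      ward_id = w, total_deposits = total,
      n_specialities = length(counts), hhi = hhi, ems = ems,
      low_evidence = low,
      specialities = paste(specs, collapse = "|"),
      stringsAsFactors = FALSE
    )
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  tot <- setNames(profiles$total_deposits, profiles$ward_id)
  dep$share <- dep$n / tot[dep$ward_id]
  structure(list(profiles = profiles, shares = dep, assigned = assigned),
            class = "ward_profiles")
}

#' @export
print.ward_profiles <- function(x, ...) {
  cat("<ward_profiles> ", nrow(x$profiles), " wards\n", sep = "")
  cat("  EMS range: ", min(x$profiles$ems), "-", max(x$profiles$ems),
      "; low-evidence wards: ", sum(x$profiles$low_evidence), "\n", sep = "")
  invisible(x)
}
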