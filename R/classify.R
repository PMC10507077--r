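## Transfer classification: atypical / regular / site decision rule,
## procedure-ward exemption, exposure counts, pair statistics.

#' Identify exempt short-stay procedure wards
#'
#' Reciprocal trips to temporary minor procedure wards (e.g. endoscopy)
#' would inflate the atypical count. A ward is exempt if its mean stay
#' duration over the full profiling population is at most `threshold_hours`
#' *and* its catalogue `is_procedure_ward` flag is set (the flag stands in
#' for manual verification of ward function). Transfers touching an exempt
#' ward are never classified atypical.
#'
#' @param cohort a `transfer_cohort` (full profiling population).
#' @param threshold_hours mean-stay threshold, default 6.
#' @return character vector of exempt ward ids.
#' @export
prune_procedure_wards <- function(cohort, threshold_hours = 6) {
  st <- cohort$stays
  dur_h <- (as.numeric(st$exit_ts) - as.numeric(st$entry_ts)) / 3600
  mean_h <- tapply(dur_h, st$ward_id, mean)
  flagged <- cohort$wards$ward_id[cohort$wards$is_procedure_ward]
  short <- names(mean_h)[mean_h <= threshold_hours]
  sort(intersect(flagged, short))
}

#' Classify transfers as atypical, regular or site
#'
#' Applies the decision rule, with the three classes mutually exclusive and
#' evaluated in precedence order:
#' \enumerate{
#'   \item different hospital sites: `site`;
#'   \item assigned speciality sets disjoint and neither ward exempt
#'         (see [prune_procedure_wards()]): `atypical`;
#'   \item otherwise: `regular`.
#' }
#'
#' @param transfers output of [extract_transfers()].
#' @param profiles a `ward_profiles` object.
#' @param exempt_wards character vector of exempt procedure ward ids.
#' @return `transfers` with the `classification` column filled in.
#' @export
classify_transfers <- function(transfers, profiles,
                               exempt_wards = character(0)) {
  if (nrow(transfers) == 0) {
    transfers$classification <- character(0)
    return(transfers)
  }
  assigned <- profiles$assigned
  known <- names(assigned)
  unknown <- setdiff(unique(c(transfers$from_ward, transfers$to_ward)), known)
  if (length(unknown) > 0) {
    stop("ward(s) without a speciality profile: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  # classify each unique (from, to) pair once, then join back
  key <- paste(transfers$from_ward, transfers$to_ward, sep = "\r")
  uk <- !duplicated(key)
  ufrom <- transfers$from_ward[uk]
  uto <- transfers$to_ward[uk]
  ufrom_site <- transfers$from_site[uk]
  uto_site <- transfers$to_site[uk]
  ucls <- character(length(ufrom))
  for (i in seq_along(ufrom)) {
    if (ufrom_site[i] != uto_site[i]) {
      ucls[i] <- "site"
    } else if (length(intersect(assigned[[ufrom[i]]],
                                assigned[[uto[i]]])) == 0 &&
               !(ufrom[i] %in% exempt_wards) &&
               !(uto[i] %in% exempt_wards)) {
      ucls[i] <- "atypical"
    } else {
      ucls[i] <- "regular"
    }
  }
  transfers$classification <- ucls[match(key, key[uk])]
  transfers
}

#' Per-spell exposure counts
#'
#' Tallies each spell's classified transfers into the three exposure
#' variables entered in the outcome models.
#'
#' @param transfers classified transfer table (no `unclassified` rows).
#' @return data.frame with `spell_id`, `n_atypical`, `n_regular`, `n_site`.
#' @export
count_exposures <- function(transfers) {
  if (nrow(transfers) == 0) {
    stop("no transfers to tally; inclusion guarantees at least one per spell")
  }
  if (any(transfers$classification == "unclassified")) {
    stop("unclassified transfers remain; run classify_transfers() first")
  }
  cls <- factor(transfers$classification,
                levels = c("atypical", "regular", "site"))
  tab <- table(transfers$spell_id, cls)
  out <- data.frame(
    spell_id = rownames(tab),
    n_atypical = as.integer(tab[, "atypical"]),
    n_regular = as.integer(tab[, "regular"]),
    n_site = as.integer(tab[, "site"]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Atypical ward-pair usage statistics
#'
#' Summarises how concentrated atypical traffic is over ward pairs. By
#' default the pair (a, b) pools both directions, since reciprocal trips
#' between the same two wards represent one route.
#'
#' @param transfers classified transfer table.
#' @param direction `"unordered"` (default) or `"ordered"`.
#' @param bands upper edges of the lower count bands; the default
#'   `c(1, 10)` yields bands `1`, `2-10` and `>10`.
#' @return list with `pairs` (data.frame `ward_a`, `ward_b`, `count`),
#'   `n_unique_pairs`, and `frequency_distribution` (named proportions per
#'   band, summing to 1).
#' @export
atypical_pair_stats <- function(transfers,
                                direction = c("unordered", "ordered"),
                                bands = c(1, 10)) {
  direction <- match.arg(direction)
  at <- transfers[transfers$classification == "atypical", , drop = FALSE]
  if (nrow(at) == 0) {
    return(list(pairs = data.frame(ward_a = character(0),
                                   ward_b = character(0),
                                   count = integer(0)),
                n_unique_pairs = 0L,
                frequency_distribution = setNames(numeric(0), character(0))))
  }
  if (direction == "unordered") {
    a <- pmin(at$from_ward, at$to_ward)
    b <- pmax(at$from_ward, at$to_ward)
  } else {
    a <- at$from_ward
    b <- at$to_ward
  }
  key <- paste(a, b, sep = "\r")
  tab <- table(key)
  split_keys <- strsplit(names(tab), "\r", fixed = TRUE)
  pairs <- data.frame(
    ward_a = vapply(split_keys, `[`, character(1), 1),
    ward_b = vapply(split_keys, `[`, character(1), 2),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(-pairs$count, pairs$ward_a, pairs$ward_b), ,
                 drop = FALSE]
  rownames(pairs) <- NULL

  bands <- sort(unique(bands))
  edges <- c(0, bands, Inf)
  labels <- character(length(edges) - 1)
  lo <- edges[-length(edges)] + 1
  hi <- edges[-1]
  for (i in seq_along(labels)) {
    labels[i] <- if (is.infinite(hi[i])) paste0(">", edges[i])
      else if (lo[i] == hi[i]) as.character(hi[i])
      else paste0(lo[i], "-", hi[i])
  }
  band_of <- cut(pairs$count, breaks = edges, labels = labels)
  freq <- prop.table(table(band_of))
  list(pairs = pairs, n_unique_pairs = nrow(pairs),
       frequency_distribution = setNames(as.numeric(freq), names(freq)))
}

#' Atypical transfer chord-diagram matrix for one site
#'
#' Square ward-by-ward matrix of atypical transfer counts within one
#' hospital site, with dimnames labelled by ward id and its top
#' specialities (at most `max_label_specs`, by deposit share), the data
#' behind a chord diagram.
#'
#' @param transfers classified transfer table.
#' @param profiles a `ward_profiles` object (for the labels).
#' @param site site id to filter on.
#' @param max_label_specs maximum specialities in a label, default 3.
#' @return integer matrix (possibly 0 x 0).
#' @export
chord_matrix <- function(transfers, profiles, site, max_label_specs = 3) {
  at <- transfers[transfers$classification == "atypical" &
                    transfers$from_site == site &
                    transfers$to_site == site, , drop = FALSE]
  if (nrow(at) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  wards <- sort(unique(c(at$from_ward, at$to_ward)))
  m <- matrix(0L, length(wards), length(wards),
              dimnames = list(wards, wards))
  tab <- table(factor(at$from_ward, wards), factor(at$to_ward, wards))
  m[] <- as.integer(tab)
  labels <- vapply(wards, function(w) {
    sh <- profiles$shares[profiles$shares$ward_id == w, , drop = FALSE]
    sh <- sh[order(-sh$share, sh$speciality), , drop = FALSE]
    top <- head(sh$speciality, max_label_specs)
    paste0(w, " [", paste(top, collapse = "|"), "]")
  }, character(1))
  dimnames(m) <- list(labels, labels)
  m
}
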