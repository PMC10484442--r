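# Treatment-episode construction.
#
# Within an admission, a drug's active timeline (the union of its prescription
# validity intervals, abutting intervals chained) is partitioned into maximal
# sub-intervals over which the set of OTHER active drugs is constant. A
# sub-interval with an empty set is a monotherapy episode of the index drug;
# one with co-medications yields one concomitant episode per (index, co-med)
# pair. Each episode carries the index drug's prescriptions whose validity
# intersects it, time-ordered, and the counts N (prescriptions) and y
# (adjacent unequal ADD pairs) that feed the binomial dosage-change model.

#' Merge re-admissions within a 24-hour gap
#'
#' Admissions of the same patient that start within `gap_hours` of the previous
#' discharge are combined into one record (the earlier admission's identity and
#' covariates are kept; the discharge time, length of stay and death/readmission
#' fields are taken from the last record of the chain).
#'
#' @param admissions admissions table with `patient_id`, `admit_time`,
#'   `discharge_time` (minutes).
#' @param gap_hours maximal gap, default 24.
#' @return combined admissions tibble.
#' @export
merge_readmissions <- function(admissions, gap_hours = 24) {
  a <- dplyr::arrange(tibble::as_tibble(admissions), .data$patient_id,
                      .data$admit_time)
  gap <- gap_hours * MIN_PER_HOUR
  a <- dplyr::group_by(a, .data$patient_id)
  a <- dplyr::mutate(
    a,
    new_chain = c(TRUE, .data$admit_time[-1] -
                    .data$discharge_time[-dplyr::n()] > gap),
    chain = cumsum(.data$new_chain)
  )
  a <- dplyr::group_by(a, .data$patient_id, .data$chain)
  id_map <- dplyr::mutate(a, new_admission_id = dplyr::first(.data$admission_id))
  out <- dplyr::summarise(
    a,
    dplyr::across(-c("admit_time", "discharge_time", "new_chain"),
                  dplyr::first),
    admit_time = dplyr::first(.data$admit_time),
    discharge_time = dplyr::last(.data$discharge_time),
    .groups = "drop"
  )
  if ("los_days" %in% names(out)) {
    out$los_days <- (out$discharge_time - out$admit_time) / MIN_PER_DAY
  }
  out <- dplyr::select(out, -"chain")
  attr(out, "id_map") <- tibble::tibble(
    admission_id = id_map$admission_id,
    merged_admission_id = id_map$new_admission_id)
  out
}

#' Re-key a table onto merged admission identities
#'
#' After [merge_readmissions()], tables keyed by the original `admission_id`
#' (prescriptions, diagnoses, blood tests) are re-pointed at the surviving
#' admission record of each chain.
#'
#' @param x table with an `admission_id` column.
#' @param merged_admissions result of [merge_readmissions()].
#' @return `x` with `admission_id` remapped.
#' @export
remap_admissions <- function(x, merged_admissions) {
  map <- attr(merged_admissions, "id_map")
  if (is.null(map)) return(x)
  i <- match(x$admission_id, map$admission_id)
  x$admission_id[!is.na(i)] <- map$merged_admission_id[i[!is.na(i)]]
  x
}

# active timeline per (admission, drug): merged [start, end) intervals;
# warns when same-drug prescriptions overlap (they are merged)
drug_activity <- function(prescriptions) {
  p <- dplyr::arrange(tibble::as_tibble(prescriptions),
                      .data$admission_id, .data$drug_atc, .data$start,
                      .data$end)
  p <- dplyr::group_by(p, .data$admission_id, .data$drug_atc)
  p <- dplyr::mutate(
    p,
    prev_reach = dplyr::lag(cummax(.data$end), default = -Inf),
    chain = cumsum(.data$start > .data$prev_reach),
    overlap = .data$start < .data$prev_reach)
  n_overlap <- sum(dplyr::summarise(p, ov = any(.data$overlap),
                                    .groups = "drop")$ov)
  if (n_overlap > 0L) {
    warn(sprintf(
      "%d admission-drug series had overlapping duplicate prescriptions; merged",
      n_overlap))
  }
  act <- dplyr::summarise(
    dplyr::group_by(p, .data$admission_id, .data$drug_atc, .data$chain),
    start = min(.data$start), end = max(.data$end), .groups = "drop")
  dplyr::select(act, -"chain")
}

#' Count lagged dosage changes in an ADD sequence
#'
#' The number of modifications y of an episode is the number of adjacent
#' prescription pairs whose ADDs differ, compared after rounding to 6
#' significant digits (see [add_round()]).
#'
#' @param add_values ordered numeric ADD sequence.
#' @return integer count, between 0 and `length(add_values) - 1`.
#' @export
count_changes <- function(add_values) {
  v <- add_round(as.numeric(add_values))
  if (length(v) < 2L) return(0L)
  sum(v[-1] != v[-length(v)])
}

#' Build monotherapy and concomitant treatment episodes
#'
#' @param prescriptions prescriptions table (`rx_id`, `admission_id`,
#'   `patient_id`, `drug_atc`, `start`, `end` in minutes, plus regimen columns).
#' @param add ADD table from [compute_add_table()]; computed from
#'   `prescriptions` when omitted.
#' @return tibble with one row per episode: `episode_id`, `patient_id`,
#'   `admission_id`, `index_drug`, `co_med` (`"MONOTHERAPY"` for reference
#'   episodes), `start`, `end`, `N`, `y`, `complete`, `discontinued`,
#'   `add_values` (list column).
#' @export
build_episodes <- function(prescriptions, add = NULL) {
  p <- tibble::as_tibble(prescriptions)
  if (is.null(add)) add <- compute_add_table(p)
  p <- dplyr::left_join(p, add[, c("rx_id", "kind", "add_value")], by = "rx_id")
  p <- dplyr::arrange(p, .data$admission_id, .data$drug_atc, .data$start)

  act <- drug_activity(p)
  p_split <- split(p, p$admission_id)
  a_split <- split(act, act$admission_id)
  parts <- lapply(names(a_split), function(adm) {
    .episodes_one_admission(p_split[[adm]], a_split[[adm]])
  })
  parts <- parts[vapply(parts, function(x) length(x$start) > 0, logical(1))]
  if (length(parts) == 0L) {
    return(tibble::tibble(
      episode_id = character(0), patient_id = character(0),
      admission_id = character(0), index_drug = character(0),
      co_med = character(0), start = numeric(0), end = numeric(0),
      N = integer(0), y = integer(0), complete = logical(0),
      discontinued = logical(0), add_values = list()
    ))
  }
  gather <- function(f) unlist(lapply(parts, `[[`, f), use.names = FALSE)
  ep <- tibble::tibble(
    patient_id = gather("patient_id"), admission_id = gather("admission_id"),
    index_drug = gather("index_drug"), co_med = gather("co_med"),
    start = gather("start"), end = gather("end"),
    N = gather("N"), y = gather("y"), complete = gather("complete"),
    discontinued = FALSE,
    add_values = do.call(c, lapply(parts, `[[`, "add_values")))
  ep$episode_id <- sprintf("E%06d", seq_len(nrow(ep)))
  ep <- flag_discontinuation(ep, act)
  dplyr::relocate(ep, "episode_id")
}

# episodes for all index drugs of one admission; returns plain column vectors
.episodes_one_admission <- function(pa, aa) {
  drugs <- unique(aa$drug_atc)
  pat <- pa$patient_id[1]
  adm <- pa$admission_id[1]
  o_idx <- o_cm <- character(0)
  o_s <- o_e <- numeric(0)
  o_n <- o_y <- integer(0)
  o_c <- logical(0)
  o_add <- list()
  all_bounds <- sort(unique(c(aa$start, aa$end)))
  for (d in drugs) {
    own_i <- aa$drug_atc == d
    os <- aa$start[own_i]; oe <- aa$end[own_i]
    xs <- aa$start[!own_i]; xe <- aa$end[!own_i]
    xd <- aa$drug_atc[!own_i]
    rx_i <- which(pa$drug_atc == d)
    rx_s <- pa$start[rx_i]; rx_e <- pa$end[rx_i]
    for (j in seq_along(os)) {
      cc <- c(os[j], all_bounds[all_bounds > os[j] & all_bounds < oe[j]], oe[j])
      ss <- cc[-length(cc)]; se <- cc[-1]
      key <- vapply(seq_along(ss), function(i) {
        paste(sort(unique(xd[xs < se[i] & ss[i] < xe])), collapse = "|")
      }, character(1))
      # merge consecutive segments with the same active set
      run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
      for (r in unique(run)) {
        w <- which(run == r)
        s0 <- ss[w[1]]; e0 <- se[w[length(w)]]
        in_ep <- rx_i[intervals_overlap(rx_s, rx_e, s0, e0)]
        in_ep <- in_ep[order(pa$start[in_ep])]
        seq_ <- .add_seq(pa$kind[in_ep], pa$add_value[in_ep], pa$unit[in_ep])
        y <- if (seq_$complete) count_changes(seq_$values) else NA_integer_
        comeds <- if (key[w[1]] == "") MONOTHERAPY else
          strsplit(key[w[1]], "|", fixed = TRUE)[[1]]
        for (cm in comeds) {
          o_idx <- c(o_idx, d); o_cm <- c(o_cm, cm)
          o_s <- c(o_s, s0); o_e <- c(o_e, e0)
          o_n <- c(o_n, length(in_ep)); o_y <- c(o_y, y)
          o_c <- c(o_c, seq_$complete)
          o_add[[length(o_add) + 1L]] <- seq_$values
        }
      }
    }
  }
  list(patient_id = rep(pat, length(o_idx)),
       admission_id = rep(adm, length(o_idx)),
       index_drug = o_idx, co_med = o_cm, start = o_s, end = o_e,
       N = o_n, y = o_y, complete = o_c, add_values = o_add)
}

#' Flag index-drug discontinuations during concomitant treatment
#'
#' A concomitant episode is flagged when the index drug's last validity end in
#' the admission lies strictly inside an active interval of the co-medication
#' (the co-medication continues after the index drug stops) and no later
#' index-drug prescription exists. A simultaneous end of index drug and
#' co-medication is not a discontinuation: cessation must happen during, not
#' at the edge of, concomitant exposure.
#'
#' @param episodes episode tibble from [build_episodes()].
#' @param activity internal activity table; recomputed if a prescriptions table
#'   is given.
#' @return `episodes` with the `discontinued` column filled.
#' @export
flag_discontinuation <- function(episodes, activity) {
  if (!all(c("admission_id", "drug_atc", "start", "end") %in% names(activity))) {
    activity <- drug_activity(activity)
  }
  ep <- tibble::as_tibble(episodes)
  last_end <- dplyr::summarise(
    dplyr::group_by(activity, .data$admission_id, .data$drug_atc),
    last_end = max(.data$end), .groups = "drop")
  conc <- ep[ep$co_med != MONOTHERAPY,
             c("episode_id", "admission_id", "index_drug", "co_med")]
  conc <- dplyr::left_join(
    conc, last_end,
    by = c(admission_id = "admission_id", index_drug = "drug_atc"))
  hits <- dplyr::inner_join(
    conc, activity, by = c(admission_id = "admission_id",
                           co_med = "drug_atc"),
    relationship = "many-to-many")
  hits <- hits[hits$start < hits$last_end & hits$last_end < hits$end, ]
  ep$discontinued <- ep$episode_id %in% hits$episode_id
  ep
}

#' Apply cohort-level drug and pair selection filters
#'
#' Retains index drugs with a monotherapy episode in at least
#' `min_mono_patients` patients and pairs present in at least
#' `min_pair_patients` patients; drops, as co-medications only, drugs that are
#' one-time prescriptions in more than `one_time_max_frac` of their
#' prescriptions; episodes with an incomplete ADD sequence are excluded first.
#'
#' @param episodes episode tibble from [build_episodes()].
#' @param prescriptions prescriptions table (for one-time fractions).
#' @param min_mono_patients,min_pair_patients,one_time_max_frac thresholds
#'   (defaults 50, 50, 0.70).
#' @return list with `episodes` (retained) and `report` (a one-row tibble of
#'   counts plus an `exclusions` list column mapping reason to count).
#' @export
apply_selection_filters <- function(episodes, prescriptions,
                                    min_mono_patients = 50,
                                    min_pair_patients = 50,
                                    one_time_max_frac = 0.70) {
  ep <- tibble::as_tibble(episodes)
  excl <- c(incomplete_add_sequence = 0L, one_time_co_medication = 0L,
            index_insufficient_monotherapy = 0L,
            pair_insufficient_patients = 0L)

  drugs_considered <- length(unique(ep$index_drug))
  pairs0 <- unique(ep[ep$co_med != MONOTHERAPY, c("index_drug", "co_med")])
  pairs_considered <- nrow(pairs0)

  drop <- !ep$complete
  excl["incomplete_add_sequence"] <- sum(drop)
  ep <- ep[!drop, ]

  p <- tibble::as_tibble(prescriptions)
  ot <- dplyr::summarise(dplyr::group_by(p, .data$drug_atc),
                         frac = mean(.data$rx_type == "one-time"),
                         .groups = "drop")
  ot_drugs <- ot$drug_atc[ot$frac > one_time_max_frac]
  drop <- ep$co_med %in% ot_drugs
  excl["one_time_co_medication"] <- sum(drop)
  ep <- ep[!drop, ]

  mono_pat <- dplyr::summarise(
    dplyr::group_by(ep[ep$co_med == MONOTHERAPY, ], .data$index_drug),
    n_pat = dplyr::n_distinct(.data$patient_id), .groups = "drop")
  keep_idx <- mono_pat$index_drug[mono_pat$n_pat >= min_mono_patients]
  drop <- !ep$index_drug %in% keep_idx
  excl["index_insufficient_monotherapy"] <- sum(drop)
  ep <- ep[!drop, ]

  pair_pat <- dplyr::summarise(
    dplyr::group_by(ep[ep$co_med != MONOTHERAPY, ],
                    .data$index_drug, .data$co_med),
    n_pat = dplyr::n_distinct(.data$patient_id), .groups = "drop")
  small <- pair_pat[pair_pat$n_pat < min_pair_patients, ]
  drop <- ep$co_med != MONOTHERAPY &
    paste(ep$index_drug, ep$co_med) %in% paste(small$index_drug, small$co_med)
  excl["pair_insufficient_patients"] <- sum(drop)
  ep <- ep[!drop, ]

  report <- tibble::tibble(
    drugs_considered = drugs_considered,
    drugs_retained = length(unique(ep$index_drug)),
    pairs_considered = pairs_considered,
    pairs_retained = nrow(unique(
      ep[ep$co_med != MONOTHERAPY, c("index_drug", "co_med")])),
    exclusions = list(excl)
  )
  list(episodes = ep, report = report)
}
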