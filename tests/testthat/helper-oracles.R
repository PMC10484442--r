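# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval algebra and HDI code paths.

# mean daily dose by expanding a regimen into a minute-resolution dispensing
# calendar over one interval: administrations placed at random minutes, total
# dispensed divided by interval length in days
oracle_add_calendar <- function(dose, freq, interval_hours) {
  minutes <- round(interval_hours * 60)
  total <- 0
  for (i in seq_along(dose)) {
    at <- sample.int(minutes, freq[i], replace = TRUE)
    total <- total + sum(rep(dose[i], length(at)))
  }
  total / (interval_hours / 24)
}

# count of adjacent unequal values at 6 significant digits
oracle_count_changes <- function(v) {
  v <- signif(v, 6)
  if (length(v) < 2) return(0L)
  sum(v[-1] != v[-length(v)])
}

# per-minute active-set scan: enumerate episodes of every index drug in one
# admission's prescriptions table
oracle_episode_scan <- function(pa, add_values, step = 1) {
  drugs <- sort(unique(pa$drug_atc))
  lo <- min(pa$start)
  hi <- max(pa$end)
  ts <- seq(lo, hi - step, by = step)
  act <- matrix(FALSE, length(ts), length(drugs),
                dimnames = list(NULL, drugs))
  for (r in seq_len(nrow(pa))) {
    d <- pa$drug_atc[r]
    act[ts >= pa$start[r] & ts < pa$end[r], d] <- TRUE
  }
  out <- list()
  for (d in drugs) {
    on <- act[, d]
    oth <- act[, setdiff(drugs, d), drop = FALSE]
    code <- as.vector(oth %*% 2^(seq_len(ncol(oth)) - 1))
    code[!on] <- -1
    run_id <- cumsum(c(TRUE, code[-1] != code[-length(code)]))
    for (rid in unique(run_id[on])) {
      w <- which(run_id == rid)
      s0 <- ts[w[1]]
      e0 <- ts[w[length(w)]] + step
      comeds <- setdiff(drugs, d)[oth[w[1], ] > 0]
      rx <- which(pa$drug_atc == d & pa$start < e0 & s0 < pa$end)
      rx <- rx[order(pa$start[rx])]
      y <- oracle_count_changes(add_values[rx])
      cms <- if (length(comeds) == 0) "MONOTHERAPY" else comeds
      for (cm in cms) {
        out[[length(out) + 1L]] <- data.frame(
          index_drug = d, co_med = cm, start = s0, end = e0,
          N = length(rx), y = y)
      }
    }
  }
  do.call(rbind, out)
}

# random small admission fixture for the oracle equivalence tests; all times
# in whole minutes, ADDs from a small menu
random_admission_fixture <- function(n_drugs = NULL, max_days = 30) {
  if (is.null(n_drugs)) n_drugs <- sample(2:5, 1)
  L <- sample(3:max_days, 1) * 1440
  drugs <- sprintf("D%02d", seq_len(n_drugs))
  rows <- list()
  for (d in drugs) {
    n_win <- sample(1:2, 1)
    cuts <- sort(sample(seq(0, L, by = 60), 2 * n_win))
    for (w in seq_len(n_win)) {
      s <- cuts[2 * w - 1]
      e <- cuts[2 * w]
      if (e - s < 120) next
      n_rx <- sample(1:4, 1)
      pop <- seq(s + 60, e - 60, by = 60)
      k <- min(n_rx - 1, length(pop))
      bb <- sort(c(s, e, pop[sample.int(length(pop), k)]))
      bb <- unique(bb)
      for (i in seq_len(length(bb) - 1)) {
        rows[[length(rows) + 1L]] <- data.frame(
          drug_atc = d, start = bb[i], end = bb[i + 1],
          dose = sample(c(100, 200, 300), 1))
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  pa <- do.call(rbind, rows)
  pa$rx_id <- sprintf("R%03d", seq_len(nrow(pa)))
  pa$admission_id <- "A1"
  pa$patient_id <- "P1"
  pa$unit <- "mg"
  pa$freq <- 1
  pa$interval_hours <- 24
  pa$rx_type <- "scheduled"
  pa$strength <- NA_real_
  pa$volume <- NA_real_
  pa
}

# exhaustive shortest-window HDI
oracle_hdi <- function(x, mass = 0.89) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1]) {
      best <- c(x[i], x[i + m - 1])
    }
  }
  best
}

# crude 2x2 odds ratio of change, concomitant vs monotherapy transitions
oracle_crude_or <- function(episodes) {
  conc <- episodes[episodes$co_med != "MONOTHERAPY" & episodes$complete, ]
  mono <- episodes[episodes$co_med == "MONOTHERAPY" & episodes$complete, ]
  tr <- function(e) c(ch = sum(e$y), tot = sum(pmax(e$N - 1, 0)))
  a <- tr(conc)
  b <- tr(mono)
  (a["ch"] / (a["tot"] - a["ch"])) / (b["ch"] / (b["tot"] - b["ch"]))
}

# small planted-effect recovery fixture shared by model tests
recovery_cohort <- function(n_patients, effect, seed) {
  drugs <- synthetic_drugs(2)
  cohort_config(
    n_patients = n_patients, n_drugs = 2, max_admissions_per_patient = 1,
    planted_effects = if (is.null(effect)) NULL else
      data.frame(index_drug = drugs[1], co_med = drugs[2],
                 log_odds_effect = effect),
    n_hospitals = 1, years = 2010, n_diag_chapters = 1,
    pn_vao_fraction = 0, one_time_fraction = 0, seed = seed)
}

fit_first_drug <- function(cohort, spec, seed = 1) {
  eps <- build_episodes(cohort$prescriptions)
  sel <- apply_selection_filters(eps, cohort$prescriptions)
  d1 <- synthetic_drugs(1)
  fit_index_drug(sel$episodes[sel$episodes$index_drug == d1, ],
                 cohort$admissions, spec, seed = seed)
}

# reduced-settings model spec used in simulation-based tests
fast_spec <- function(chains = 2, iter = 1000, warmup = 500) {
  model_spec(chains = chains, iter = iter, warmup = warmup,
             trials = "transitions")
}
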