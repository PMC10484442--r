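# Synthetic inpatient cohort with planted dosage-change effects.
#
# The generator runs the dosage-change model forward: within each admission a
# drug's scheduled prescriptions are renewed at a fixed cadence, and at each
# renewal the regimen is resampled (a guaranteed different menu entry) with
# probability inverse-logit(eta), where eta is the baseline change logit plus
# the planted log-odds effect of any co-medication active at the renewal time,
# covariate terms and a patient random intercept. Change indicators are
# therefore exactly Bernoulli given eta, so episode change counts are binomial
# and the downstream model's estimand equals the planted coefficient.

#' ATC-shaped drug codes of the synthetic universe
#'
#' The first `n` codes used by [generate_cohort()], in order; use these when
#' specifying `planted_effects`.
#'
#' @param n number of drugs.
#' @return character vector of ATC-format codes.
#' @export
synthetic_drugs <- function(n) .synth_atc(n)

.synth_atc <- function(n) {
  anat <- c("A", "B", "C", "J", "L", "M", "N", "R")
  sprintf("%s%02d%s%s%02d", anat[(seq_len(n) - 1) %% length(anat) + 1],
          (seq_len(n) - 1) %/% length(anat) + 1, "A", "A",
          (seq_len(n) - 1) %% 9 + 1)
}

.default_menu <- function() {
  list(
    list(dose = 200, freq = 1), list(dose = 200, freq = 2),
    list(dose = 200, freq = 3), list(dose = 400, freq = 2),
    list(dose = 100, freq = 1), list(dose = 400, freq = 3)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults describe a small general-medicine inpatient cohort: lognormal
#' length of stay around 5 days, daily prescription renewal, a ~15% baseline
#' per-renewal probability of a dosage change (logit -1.7), a patient random
#' intercept with standard deviation 0.5, and 60% of admissions carrying a
#' drug pair with partial temporal overlap (the remainder are single-drug
#' stays, the source of monotherapy reference episodes).
#'
#' @param n_patients number of patients.
#' @param n_drugs size of the drug universe.
#' @param max_admissions_per_patient admissions are drawn uniformly from
#'   1..this.
#' @param admission_los list(meanlog, sdlog) of the lognormal stay length, days.
#' @param baseline_change_logit intercept of the change model (log-odds).
#' @param planted_effects data frame (`index_drug`, `co_med`,
#'   `log_odds_effect`) of planted concomitant-drug effects; `NULL` for none.
#' @param covariate_effects list of log-odds effects `age` (per SD of age) and
#'   `sex` (male vs female) on the change probability.
#' @param patient_sd standard deviation of the patient random intercept.
#' @param regimen_menu list of `list(dose, freq)` regimens to sample from
#'   (all at daily interval); at least 2 entries so a "change" is always
#'   possible.
#' @param pn_vao_fraction probability that a drug-admission series is written
#'   as "as needed"/variable-dose (categorical ADD, excluded downstream).
#' @param one_time_fraction named per-drug probability that an admission gains
#'   an extra one-time prescription of that drug; a scalar recycles.
#' @param pair_fraction fraction of admissions carrying a drug pair.
#' @param rx_duration_hours renewal cadence of scheduled prescriptions.
#' @param n_hospitals,years,n_diag_chapters covariate universes.
#' @param outcome_effects list of log-effects applied to admissions exposed to
#'   a drug pair: `mortality_loghr`, `readmission_loghr`, `los_lograte`,
#'   `discontinuation_logodds`, `bloodtest_logodds`, `diagnosis_logodds`.
#' @param seed integer seed fixing all randomness.
#' @return validated object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 500,
                          n_drugs = 8,
                          max_admissions_per_patient = 2,
                          admission_los = list(meanlog = log(5), sdlog = 0.5),
                          baseline_change_logit = -1.7,
                          planted_effects = NULL,
                          covariate_effects = list(age = 0, sex = 0),
                          patient_sd = 0.5,
                          regimen_menu = .default_menu(),
                          pn_vao_fraction = 0.02,
                          one_time_fraction = 0.02,
                          pair_fraction = 0.6,
                          rx_duration_hours = 24,
                          n_hospitals = 4,
                          years = 2008:2015,
                          n_diag_chapters = 6,
                          outcome_effects = list(),
                          seed = 1L) {
  if (n_patients < 1) stop_config("n_patients must be >= 1")
  if (n_drugs < 1) stop_config("n_drugs must be >= 1")
  if (patient_sd < 0) stop_config("patient_sd must be >= 0")
  for (p in c(pn_vao_fraction, pair_fraction, unlist(one_time_fraction))) {
    if (is.na(p) || p < 0 || p > 1) {
      stop_config("fractions must be probabilities in [0, 1]")
    }
  }
  if (!is.list(admission_los) ||
      !all(c("meanlog", "sdlog") %in% names(admission_los)) ||
      admission_los$sdlog < 0) {
    stop_config("admission_los must be list(meanlog, sdlog) with sdlog >= 0")
  }
  if (length(regimen_menu) < 2) {
    stop_config("regimen_menu needs at least 2 regimens")
  }
  drugs <- .synth_atc(n_drugs)
  if (!is.null(planted_effects)) {
    planted_effects <- tibble::as_tibble(planted_effects)
    stopifnot(all(c("index_drug", "co_med", "log_odds_effect") %in%
                    names(planted_effects)))
    bad <- !(planted_effects$index_drug %in% drugs &
               planted_effects$co_med %in% drugs)
    if (any(bad)) {
      stop_config("planted_effects reference drugs outside the drug universe")
    }
  } else {
    planted_effects <- tibble::tibble(index_drug = character(0),
                                      co_med = character(0),
                                      log_odds_effect = numeric(0))
  }
  oe_default <- list(mortality_loghr = 0, readmission_loghr = 0,
                     los_lograte = 0, discontinuation_logodds = 0,
                     bloodtest_logodds = 0, diagnosis_logodds = 0)
  oe <- utils::modifyList(oe_default, outcome_effects)
  structure(list(
    n_patients = as.integer(n_patients), n_drugs = as.integer(n_drugs),
    drugs = drugs,
    max_admissions_per_patient = as.integer(max_admissions_per_patient),
    admission_los = admission_los,
    baseline_change_logit = baseline_change_logit,
    planted_effects = planted_effects,
    covariate_effects = utils::modifyList(list(age = 0, sex = 0),
                                          covariate_effects),
    patient_sd = patient_sd, regimen_menu = regimen_menu,
    pn_vao_fraction = pn_vao_fraction,
    one_time_fraction = one_time_fraction,
    pair_fraction = pair_fraction,
    rx_duration_hours = rx_duration_hours,
    n_hospitals = as.integer(n_hospitals), years = as.integer(years),
    n_diag_chapters = as.integer(n_diag_chapters),
    outcome_effects = oe, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return list of class `"synthetic_cohort"` with tibbles `admissions`,
#'   `prescriptions`, `diagnoses`, `blood_tests`, `ddi_reference`,
#'   `pk_annotations`, `comention_counts`, `truth`, and the `config`.
#'   All times are minutes since the cohort epoch; intervals are half-open
#'   `[start, end)`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  set.seed(cf$seed)

  drugs <- cf$drugs
  planted <- setNames(cf$planted_effects$log_odds_effect,
                      paste(cf$planted_effects$index_drug,
                            cf$planted_effects$co_med))
  oe <- cf$outcome_effects

  patients <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(cf$n_patients)),
    age = round(pmin(pmax(rnorm(cf$n_patients, 65, 15), 18), 100)),
    sex = sample(c("F", "M"), cf$n_patients, replace = TRUE),
    gamma = rnorm(cf$n_patients, 0, cf$patient_sd)
  )

  adm_rows <- list(); rx_rows <- list(); dx_rows <- list(); bt_rows <- list()
  adm_i <- 0L; rx_i <- 0L
  ot_frac <- cf$one_time_fraction
  if (!is.list(ot_frac) && length(ot_frac) == 1L) {
    ot_frac <- setNames(rep(ot_frac, cf$n_drugs), drugs)
  } else {
    ot_frac <- unlist(ot_frac)
  }

  for (pi in seq_len(cf$n_patients)) {
    n_adm <- sample.int(cf$max_admissions_per_patient, 1L)
    t_cursor <- round(runif(1, 0, 365) * MIN_PER_DAY)
    for (ai in seq_len(n_adm)) {
      adm_i <- adm_i + 1L
      adm_id <- sprintf("A%06d", adm_i)
      los0 <- rlnorm(1, cf$admission_los$meanlog, cf$admission_los$sdlog)
      los0 <- max(los0, 2)

      # drug layout: pair admissions carry two drugs with partial overlap
      is_pair <- cf$n_drugs >= 2 && runif(1) < cf$pair_fraction
      if (is_pair) {
        dd <- drugs[sample.int(length(drugs), 2L)]
        exposed_pair <- paste(dd[1], dd[2], sep = "|")
      } else {
        dd <- drugs[sample.int(length(drugs), 1L)]
        exposed_pair <- NA_character_
      }
      los <- los0 * if (is_pair) exp(oe$los_lograte) else 1
      L <- round(los * MIN_PER_DAY)
      admit <- t_cursor
      discharge <- admit + L

      windows <- tibble::tibble(drug = dd[1], start = admit, end = discharge)
      if (is_pair) {
        a_f <- runif(1, 0.2, 0.4); b_f <- runif(1, 0.6, 0.8)
        windows <- dplyr::bind_rows(windows, tibble::tibble(
          drug = dd[2],
          start = admit + round(a_f * L), end = admit + round(b_f * L)))
      }

      # discontinuation: truncate the index drug inside the co-med window
      if (is_pair) {
        p_disc <- plogis(qlogis(0.10) + oe$discontinuation_logodds)
        if (runif(1) < p_disc) {
          mid <- round((windows$start[2] + windows$end[2]) / 2)
          windows$end[1] <- max(windows$start[1] + MIN_PER_DAY, mid)
        }
      }

      pat <- patients[pi, ]
      age_z <- (pat$age - 65) / 15
      sex_m <- as.integer(pat$sex == "M")

      for (w in seq_len(nrow(windows))) {
        d <- windows$drug[w]
        is_pn <- runif(1) < cf$pn_vao_fraction
        rx_type <- if (is_pn) sample(c("PN", "VAO"), 1L) else "scheduled"
        bounds <- seq(windows$start[w], windows$end[w],
                      by = cf$rx_duration_hours * MIN_PER_HOUR)
        if (bounds[length(bounds)] < windows$end[w]) {
          bounds <- c(bounds, windows$end[w])
        }
        n_rx <- length(bounds) - 1L
        if (n_rx < 1L) next
        reg_idx <- integer(n_rx)
        reg_idx[1] <- sample.int(length(cf$regimen_menu), 1L)
        for (r in seq_len(n_rx)[-1]) {
          tau <- bounds[r]
          others <- windows$drug[windows$drug != d &
                                   windows$start <= tau & tau < windows$end]
          eta <- cf$baseline_change_logit +
            cf$covariate_effects$age * age_z +
            cf$covariate_effects$sex * sex_m +
            pat$gamma
          for (cm in others) {
            pe <- planted[paste(d, cm)]
            if (!is.na(pe)) eta <- eta + pe
          }
          if (runif(1) < plogis(eta)) {
            cand <- setdiff(seq_along(cf$regimen_menu), reg_idx[r - 1L])
            reg_idx[r] <- cand[sample.int(length(cand), 1L)]
          } else {
            reg_idx[r] <- reg_idx[r - 1L]
          }
        }
        rx_i <- rx_i + 1L
        rx_rows[[rx_i]] <- list(
          admission_id = rep(adm_id, n_rx),
          patient_id = rep(pat$patient_id, n_rx), drug_atc = rep(d, n_rx),
          start = bounds[-length(bounds)], end = bounds[-1],
          dose = vapply(reg_idx, function(k) cf$regimen_menu[[k]]$dose,
                        numeric(1)),
          unit = rep("mg", n_rx),
          freq = vapply(reg_idx, function(k) cf$regimen_menu[[k]]$freq,
                        numeric(1)),
          interval_hours = rep(24, n_rx), rx_type = rep(rx_type, n_rx),
          strength = rep(NA_real_, n_rx), volume = rep(NA_real_, n_rx))
      }

      # occasional extra one-time prescriptions of inactive drugs
      inactive <- setdiff(drugs, dd)
      if (length(inactive)) {
        hit <- runif(length(inactive)) <
          unname(unlist(ot_frac[inactive], use.names = FALSE) %||% 0)
        hit[is.na(hit)] <- FALSE
        if (any(hit)) {
          nh <- sum(hit)
          t0 <- admit + round(runif(nh, 0.1, 0.9) * L)
          rx_i <- rx_i + 1L
          rx_rows[[rx_i]] <- list(
            admission_id = rep(adm_id, nh),
            patient_id = rep(pat$patient_id, nh), drug_atc = inactive[hit],
            start = t0, end = pmin(t0 + MIN_PER_HOUR, discharge),
            dose = rep(100, nh), unit = rep("mg", nh), freq = rep(1, nh),
            interval_hours = rep(NA_real_, nh), rx_type = rep("one-time", nh),
            strength = rep(NA_real_, nh), volume = rep(NA_real_, nh))
        }
      }

      # outcomes: 30-day mortality (from admission), 30-day readmission
      # (from discharge), exponential event times
      lam_m <- -log(1 - 0.05) / 30 * if (is_pair) exp(oe$mortality_loghr) else 1
      t_death <- stats::rexp(1, lam_m)
      death_time <- if (t_death <= 30) round(t_death * MIN_PER_DAY) else NA_real_
      lam_r <- -log(1 - 0.15) / 30 *
        if (is_pair) exp(oe$readmission_loghr) else 1
      t_re <- stats::rexp(1, lam_r)
      readmit_gap <- if (is.na(death_time) && t_re <= 30) t_re else NA_real_

      adm_rows[[adm_i]] <- list(
        admission_id = adm_id, patient_id = pat$patient_id,
        admit_time = admit, discharge_time = discharge,
        age = pat$age, sex = pat$sex,
        hospital = sprintf("H%02d", sample.int(cf$n_hospitals, 1L)),
        year = cf$years[sample.int(length(cf$years), 1L)],
        diag_chapter = sprintf("CH%02d", sample.int(cf$n_diag_chapters, 1L)),
        charlson = rpois(1, 1.2),
        med_burden = length(dd),
        los_days = L / MIN_PER_DAY,
        death_time = death_time, readmit_gap_days = readmit_gap,
        exposed_pair = exposed_pair)

      # diagnoses (secondary) and blood tests, with optional exposure link
      p_dx <- plogis(qlogis(0.10) + if (is_pair) oe$diagnosis_logodds else 0)
      dx_hit <- runif(8) < p_dx
      if (any(dx_hit)) {
        dx_rows[[length(dx_rows) + 1L]] <- list(
          admission_id = rep(adm_id, sum(dx_hit)),
          icd_code = sprintf("DX%02d", which(dx_hit)))
      }
      taken <- runif(5) < 0.7 # untaken tests are absent rows
      if (any(taken)) {
        p_ab <- plogis(qlogis(0.15) + if (is_pair) oe$bloodtest_logodds else 0)
        bt_rows[[length(bt_rows) + 1L]] <- list(
          admission_id = rep(adm_id, sum(taken)),
          test_code = sprintf("BT%02d", which(taken)),
          abnormal = as.integer(runif(sum(taken)) < p_ab))
      }
      t_cursor <- discharge +
        round((if (!is.na(readmit_gap)) readmit_gap
               else runif(1, 40, 200)) * MIN_PER_DAY)
    }
  }

  gather <- function(rows) {
    if (length(rows) == 0L) return(tibble::tibble())
    tibble::as_tibble(lapply(setNames(nm = names(rows[[1]])), function(f) {
      unlist(lapply(rows, `[[`, f), use.names = FALSE)
    }))
  }
  admissions <- gather(adm_rows)
  prescriptions <- gather(rx_rows)
  prescriptions <- dplyr::mutate(
    prescriptions, rx_id = sprintf("R%07d", dplyr::row_number()),
    .before = 1)

  cohort <- structure(list(
    admissions = admissions,
    prescriptions = prescriptions,
    diagnoses = gather(dx_rows),
    blood_tests = gather(bt_rows),
    ddi_reference = generate_ddi_reference(drugs, known_fraction = 0.3,
                                           seed = derive_seed(cf$seed, 11L)),
    pk_annotations = .generate_pk(drugs, derive_seed(cf$seed, 12L)),
    comention_counts = .generate_comentions(drugs, derive_seed(cf$seed, 13L)),
    truth = cf$planted_effects,
    config = cf
  ), class = "synthetic_cohort")
  cohort
}

#' Generate a symmetric binary DDI reference table
#'
#' Emulates a merged drug-drug-interaction knowledge base in the binary
#' present/absent form used downstream: each unordered pair is flagged as a
#' known interaction with probability `known_fraction`, and the flag is
#' symmetric by construction.
#'
#' @param cohort_drugs character vector of drug codes.
#' @param known_fraction probability a pair is flagged.
#' @param seed integer seed.
#' @return tibble (`drug_a`, `drug_b`, `has_ddi`, `source`) containing both
#'   orientations of every pair.
#' @export
generate_ddi_reference <- function(cohort_drugs, known_fraction, seed = 1L) {
  if (is.na(known_fraction) || known_fraction < 0 || known_fraction > 1) {
    stop_config("known_fraction must be in [0, 1]")
  }
  set.seed(seed)
  if (length(cohort_drugs) < 2) {
    return(tibble::tibble(drug_a = character(0), drug_b = character(0),
                          has_ddi = logical(0), source = character(0)))
  }
  cmb <- utils::combn(sort(cohort_drugs), 2)
  flag <- runif(ncol(cmb)) < known_fraction
  half <- tibble::tibble(drug_a = cmb[1, ], drug_b = cmb[2, ],
                         has_ddi = flag, source = "synthetic")
  sym <- tibble::tibble(drug_a = half$drug_b, drug_b = half$drug_a,
                        has_ddi = half$has_ddi, source = half$source)
  dplyr::bind_rows(half, sym)
}

# core regulatory-listed CYPs and transporters
.pk_proteins <- c("CYP1A2", "CYP2B6", "CYP2C8", "CYP2C9", "CYP2C19", "CYP2D6",
                  "CYP2E1", "CYP3A4", "CYP3A5", "CYP3A7", "ABCB1", "BCRP",
                  "MATE1", "Mate-2k", "OAT1", "OAT3", "OCT1", "OCT2",
                  "OATP1B1", "OATP1B3", "P-SP")

.generate_pk <- function(drugs, seed) {
  set.seed(seed)
  rows <- lapply(drugs, function(d) {
    k <- sample.int(4, 1L)
    tibble::tibble(drug_atc = d,
                   protein = sample(.pk_proteins, k),
                   role = sample(c("inducer", "inhibitor", "substrate"), k,
                                 replace = TRUE))
  })
  dplyr::bind_rows(rows)
}

.generate_comentions <- function(drugs, seed) {
  set.seed(seed)
  if (length(drugs) < 2) {
    return(tibble::tibble(drug_a = character(0), drug_b = character(0),
                          n_articles = integer(0)))
  }
  cmb <- utils::combn(sort(drugs), 2)
  keep <- runif(ncol(cmb)) < 0.7 # missing pairs read as zero co-mentions
  tibble::tibble(drug_a = cmb[1, keep], drug_b = cmb[2, keep],
                 n_articles = rpois(sum(keep), 20))
}
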