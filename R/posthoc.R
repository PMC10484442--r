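# Propensity-matched post-hoc association analyses for significant pairs:
# index-drug discontinuation, 30-day post-admission mortality, 30-day
# post-discharge readmission, length of stay, and diagnosis / blood-test
# enrichment. Exposed admissions (first exposure per patient) are matched 1:1
# to controls on the same index drug with a different concomitant drug, by
# greedy nearest-neighbour matching on the propensity-score difference.

# adjustment covariates with more than one observed level (single-level
# factors carry no information and would break the model matrix)
.adjust_rhs <- function(data) {
  covs <- c("age", "sex", "diag_chapter", "charlson", "med_burden")
  keep <- covs[vapply(covs, function(v) length(unique(data[[v]])) > 1L,
                      logical(1))]
  if (length(keep) == 0L) "1" else paste(keep, collapse = " + ")
}

#' Build a propensity-matched cohort for one pair
#'
#' Propensity scores come from a logistic model of exposure on age, sex,
#' primary-diagnosis chapter, weighted Charlson score and medication burden.
#' Exposed admissions are processed in a seeded random order; each takes the
#' still-unused control with the smallest score difference, ties broken by
#' lowest admission id. Only a patient's first exposure to the pair (and, for
#' controls, first eligible admission) is used.
#'
#' @param pair character `c(index_drug, co_med)`.
#' @param episodes episode tibble (used to find exposure).
#' @param admissions admissions table with the matching covariates.
#' @param seed integer seed for the processing order.
#' @return tibble of matched admissions: `match_id`, `exposed`,
#'   `admission_id`, `patient_id`, `pscore`, covariates; `NULL` (with a
#'   warning) when either arm is empty.
#' @export
match_cohort <- function(pair, episodes, admissions, seed = 1L) {
  ep <- tibble::as_tibble(episodes)
  adm <- tibble::as_tibble(admissions)
  conc <- ep[ep$co_med != MONOTHERAPY & ep$index_drug == pair[1], ]
  expo_adm <- unique(conc$admission_id[conc$co_med == pair[2]])
  ctrl_adm <- setdiff(unique(conc$admission_id), expo_adm)
  expo_pat <- unique(conc$patient_id[conc$co_med == pair[2]])
  # controls: same index drug, different co-med, patient never exposed
  ctrl_adm <- ctrl_adm[!ctrl_adm %in%
                         adm$admission_id[adm$patient_id %in% expo_pat]]

  first_per_patient <- function(ids) {
    a <- adm[adm$admission_id %in% ids, ]
    a <- dplyr::arrange(a, .data$patient_id, .data$admit_time)
    a <- dplyr::distinct(a, .data$patient_id, .keep_all = TRUE)
    a
  }
  ex <- first_per_patient(expo_adm)
  ct <- first_per_patient(ctrl_adm)
  if (nrow(ex) == 0L || nrow(ct) == 0L) {
    warn(sprintf("pair %s|%s skipped: no %s admissions", pair[1], pair[2],
                 if (nrow(ex) == 0L) "exposed" else "eligible control"))
    return(NULL)
  }

  pool <- dplyr::bind_rows(dplyr::mutate(ex, exposed = 1L),
                           dplyr::mutate(ct, exposed = 0L))
  ps <- glm(stats::as.formula(paste("exposed ~", .adjust_rhs(pool))),
            family = binomial(), data = pool)
  pool$pscore <- stats::fitted(ps)

  exp_rows <- pool[pool$exposed == 1L, ]
  ctl_rows <- pool[pool$exposed == 0L, ]
  set.seed(seed)
  ord <- sample.int(nrow(exp_rows))
  used <- rep(FALSE, nrow(ctl_rows))
  m_exp <- integer(0); m_ctl <- integer(0)
  for (i in ord) {
    free <- which(!used)
    if (length(free) == 0L) break
    d <- abs(ctl_rows$pscore[free] - exp_rows$pscore[i])
    best <- free[d == min(d)]
    j <- best[order(ctl_rows$admission_id[best])][1]
    used[j] <- TRUE
    m_exp <- c(m_exp, i); m_ctl <- c(m_ctl, j)
  }
  o <- order(m_exp)
  m_exp <- m_exp[o]; m_ctl <- m_ctl[o]
  matched <- dplyr::bind_rows(
    dplyr::mutate(exp_rows[m_exp, ], match_id = seq_along(m_exp)),
    dplyr::mutate(ctl_rows[m_ctl, ], match_id = seq_along(m_ctl)))
  matched$pair_index <- pair[1]
  matched$pair_co_med <- pair[2]
  dplyr::relocate(matched, "match_id", "exposed", "admission_id", "patient_id",
                  "pscore")
}

# Wald test for one coefficient of a fitted model; NULL when inestimable
.wald <- function(fit, term) {
  est <- tryCatch(coef(fit)[[term]], error = function(e) NA_real_)
  # a near-singular vcov can yield a negative diagonal; the finiteness check
  # below turns that into "inestimable"
  se <- tryCatch(suppressWarnings(sqrt(diag(vcov(fit)))[[term]]),
                 error = function(e) NA_real_)
  if (!is.finite(est) || !is.finite(se) || se > 1e3) return(NULL)
  z <- est / se
  list(effect = est, se = se, p = 2 * pnorm(-abs(z)))
}

#' Outcome associations on a matched cohort
#'
#' Mortality (30 days post admission) and readmission (30 days post discharge)
#' use Cox partial likelihood stratified by matched pair (Breslow ties), with
#' exposure as the explanatory variable and the standard adjustment set.
#' Length of stay uses Poisson regression stratified by matched pair, fitted
#' by the exact conditional likelihood given each pair's total (a binomial
#' logistic model on the exposed share), which is the stratified Poisson
#' estimate without thousands of per-pair nuisance parameters.
#'
#' @param matched matched cohort from [match_cohort()].
#' @param admissions admissions table with `death_time` (minutes from
#'   admission start, `NA` if alive), `readmit_gap_days` (`NA` if none),
#'   `los_days`.
#' @return tibble of `AssociationResult` rows (`endpoint`, `effect`, `se`,
#'   `p_raw`; Bonferroni is applied family-wise by [bonferroni_family()]).
#' @export
test_outcomes <- function(matched, admissions) {
  m <- dplyr::select(
    tibble::as_tibble(matched),
    -dplyr::any_of(c("death_time", "readmit_gap_days", "los_days")))
  m <- dplyr::left_join(
    m,
    tibble::as_tibble(admissions)[, c("admission_id", "death_time",
                                      "readmit_gap_days", "los_days")],
    by = "admission_id")
  if (nrow(m) == 0L) stop_contract("matched cohort is empty")
  pair_id <- paste(m$pair_index[1], m$pair_co_med[1], sep = "|")
  out <- list()

  death_days <- m$death_time / MIN_PER_DAY
  m$t_mort <- pmin(ifelse(is.na(death_days), 30, death_days), 30)
  m$e_mort <- as.integer(!is.na(death_days) & death_days <= 30)
  m$t_re <- pmin(ifelse(is.na(m$readmit_gap_days), 30, m$readmit_gap_days), 30)
  m$e_re <- as.integer(!is.na(m$readmit_gap_days) & m$readmit_gap_days <= 30)

  for (ept in c("mortality_30d", "readmission_30d")) {
    tv <- if (ept == "mortality_30d") "t_mort" else "t_re"
    ev <- if (ept == "mortality_30d") "e_mort" else "e_re"
    w <- NULL
    if (sum(m[[ev]]) > 0L) {
      f <- stats::as.formula(paste0(
        "survival::Surv(", tv, ", ", ev, ") ~ exposed + age + sex + charlson",
        " + med_burden + diag_chapter + survival::strata(match_id)"))
      fit <- tryCatch(
        suppressWarnings(survival::coxph(f, data = m, ties = "breslow")),
        error = function(e) NULL)
      if (!is.null(fit)) w <- .wald(fit, "exposed")
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      pair_id = pair_id, endpoint = ept,
      effect = w$effect %||% NA_real_, se = w$se %||% NA_real_,
      p_raw = w$p %||% NA_real_, estimable = !is.null(w))
  }

  # conditional (pair-total) likelihood of the stratified Poisson LOS model
  wide <- dplyr::arrange(m, .data$match_id, dplyr::desc(.data$exposed))
  wide$los <- round(wide$los_days)
  g <- dplyr::summarise(
    dplyr::group_by(wide, .data$match_id),
    y1 = .data$los[1], tot = sum(.data$los),
    d_age = .data$age[1] - .data$age[2],
    d_sex = as.integer(.data$sex[1] == "M") - as.integer(.data$sex[2] == "M"),
    d_charlson = .data$charlson[1] - .data$charlson[2],
    d_burden = .data$med_burden[1] - .data$med_burden[2],
    .groups = "drop")
  g <- g[g$tot > 0, ]
  w <- NULL
  if (nrow(g) > 1L) {
    fit <- tryCatch(
      suppressWarnings(glm(cbind(y1, tot - y1) ~ 1 + d_age + d_sex +
                             d_charlson + d_burden, family = binomial(),
                           data = g)),
      error = function(e) NULL)
    if (!is.null(fit)) w <- .wald(fit, "(Intercept)")
  }
  out[[length(out) + 1L]] <- tibble::tibble(
    pair_id = pair_id, endpoint = "LOS",
    effect = w$effect %||% NA_real_, se = w$se %||% NA_real_,
    p_raw = w$p %||% NA_real_, estimable = !is.null(w))

  dplyr::bind_rows(out)
}

#' Diagnosis and blood-test enrichment on a matched cohort
#'
#' Per diagnosis code (assigned / not assigned) and per blood test (abnormal /
#' within range) present in at least `min_patients` patients of the matched
#' cohort: logistic regression of the outcome on exposure with the standard
#' adjustment set. Blood tests never taken are read as within range.
#'
#' @param matched matched cohort from [match_cohort()].
#' @param diagnoses tibble (`admission_id`, `icd_code`).
#' @param blood_tests tibble (`admission_id`, `test_code`, `abnormal`);
#'   absent rows impute 0.
#' @param min_patients presence threshold (default 50).
#' @return tibble of `AssociationResult` rows; constant outcomes are skipped.
#' @export
test_enrichment <- function(matched, diagnoses, blood_tests,
                            min_patients = 50) {
  m <- tibble::as_tibble(matched)
  if (nrow(m) == 0L) stop_contract("matched cohort is empty")
  pair_id <- paste(m$pair_index[1], m$pair_co_med[1], sep = "|")
  dx <- tibble::as_tibble(diagnoses)
  bt <- tibble::as_tibble(blood_tests)
  out <- list()

  run_code <- function(endpoint, outcome) {
    if (length(unique(outcome)) < 2L) return()
    m$outcome <- outcome
    fit <- tryCatch(
      suppressWarnings(glm(
        stats::as.formula(paste("outcome ~ exposed +", .adjust_rhs(m))),
        family = binomial(), data = m)),
      error = function(e) NULL)
    w <- if (!is.null(fit)) .wald(fit, "exposed") else NULL
    out[[length(out) + 1L]] <<- tibble::tibble(
      pair_id = pair_id, endpoint = endpoint,
      effect = w$effect %||% NA_real_, se = w$se %||% NA_real_,
      p_raw = w$p %||% NA_real_, estimable = !is.null(w))
  }

  dx_in <- dx[dx$admission_id %in% m$admission_id, ]
  for (code in sort(unique(dx_in$icd_code))) {
    hit <- m$admission_id %in% dx_in$admission_id[dx_in$icd_code == code]
    if (sum(hit) < min_patients) next
    run_code(paste0("diagnosis:", code), as.integer(hit))
  }
  bt_in <- bt[bt$admission_id %in% m$admission_id, ]
  for (code in sort(unique(bt_in$test_code))) {
    sub <- bt_in[bt_in$test_code == code, ]
    if (dplyr::n_distinct(sub$admission_id) < min_patients) next
    abn <- m$admission_id %in% sub$admission_id[sub$abnormal == 1L]
    run_code(paste0("bloodtest:", code), as.integer(abn))
  }
  dplyr::bind_rows(out)
}

#' Discontinuation association on a matched cohort
#'
#' Logistic regression of index-drug discontinuation during concomitant
#' treatment on exposure to the co-medication, with the standard adjustment
#' set, over the matched admissions.
#'
#' @param matched matched cohort from [match_cohort()].
#' @param episodes episode tibble with the `discontinued` flag.
#' @return one `AssociationResult` row.
#' @export
test_discontinuation <- function(matched, episodes) {
  m <- tibble::as_tibble(matched)
  if (nrow(m) == 0L) stop_contract("matched cohort is empty")
  pair_id <- paste(m$pair_index[1], m$pair_co_med[1], sep = "|")
  ep <- tibble::as_tibble(episodes)
  conc <- ep[ep$co_med != MONOTHERAPY & ep$index_drug == m$pair_index[1], ]
  disc_adm <- unique(conc$admission_id[conc$discontinued])
  m$outcome <- as.integer(m$admission_id %in% disc_adm)
  w <- NULL
  if (length(unique(m$outcome)) > 1L) {
    fit <- tryCatch(
      suppressWarnings(glm(
        stats::as.formula(paste("outcome ~ exposed +", .adjust_rhs(m))),
        family = binomial(), data = m)),
      error = function(e) NULL)
    if (!is.null(fit)) w <- .wald(fit, "exposed")
  }
  tibble::tibble(pair_id = pair_id, endpoint = "discontinuation",
                 effect = w$effect %||% NA_real_, se = w$se %||% NA_real_,
                 p_raw = w$p %||% NA_real_, estimable = !is.null(w))
}

#' Bonferroni adjustment within endpoint families
#'
#' One family per endpoint type across all pairs: `p_bonferroni = min(1,
#' p_raw * m)` where `m` is the family size (diagnosis and blood-test
#' endpoints each form one family).
#'
#' @param results row-bound association results.
#' @return `results` with `family`, `family_size`, `p_bonferroni` columns.
#' @export
bonferroni_family <- function(results) {
  r <- tibble::as_tibble(results)
  r$family <- sub(":.*$", "", r$endpoint)
  r <- dplyr::group_by(r, .data$family)
  r <- dplyr::mutate(r, family_size = sum(!is.na(.data$p_raw)),
                     p_bonferroni = pmin(1, .data$p_raw * .data$family_size))
  dplyr::ungroup(r)
}

#' Standardised mean differences of matching covariates
#'
#' Balance diagnostic: |mean difference| / pooled SD per covariate, exposed vs
#' control, computed on any cohort with an `exposed` column.
#'
#' @param cohort data frame with `exposed` and the matching covariates.
#' @return named numeric vector of absolute standardised mean differences.
#' @export
matching_smd <- function(cohort) {
  covs <- c("age", "charlson", "med_burden")
  vapply(covs, function(v) {
    x1 <- cohort[[v]][cohort$exposed == 1L]
    x0 <- cohort[[v]][cohort$exposed == 0L]
    sp <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
    if (!is.finite(sp) || sp == 0) return(0)
    abs(mean(x1) - mean(x0)) / sp
  }, numeric(1))
}
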