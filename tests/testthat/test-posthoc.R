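# constructed admissions pool with episodes marking exposure
posthoc_fixture <- function(n_exposed, n_control, seed = 1,
                            covar_shift = 0) {
  set.seed(seed)
  n <- n_exposed + n_control
  adm <- tibble::tibble(
    admission_id = sprintf("a%04d", 1:n),
    patient_id = sprintf("p%04d", 1:n),
    admit_time = 1440 * (1:n),
    age = round(runif(n, 40, 90)) + covar_shift * rep(c(1, 0),
                                                      c(n_exposed, n_control)),
    sex = sample(c("F", "M"), n, TRUE),
    diag_chapter = sample(c("C1", "C2"), n, TRUE),
    charlson = rpois(n, 1), med_burden = sample(2:6, n, TRUE),
    los_days = round(runif(n, 3, 12)),
    death_time = NA_real_, readmit_gap_days = NA_real_)
  eps <- tibble::tibble(
    episode_id = sprintf("e%04d", 1:n),
    patient_id = adm$patient_id, admission_id = adm$admission_id,
    index_drug = "X",
    co_med = rep(c("Y", "Z"), c(n_exposed, n_control)),
    N = 2L, y = 0L, complete = TRUE, discontinued = FALSE)
  list(adm = adm, eps = eps)
}

test_that("identical covariate pools match every exposed unit at distance 0", {
  fx <- posthoc_fixture(6, 6, seed = 2)
  fx$adm$age <- 70
  fx$adm$sex <- "F"
  fx$adm$diag_chapter <- "C1"
  fx$adm$charlson <- 1L
  fx$adm$med_burden <- 3L
  m <- match_cohort(c("X", "Y"), fx$eps, fx$adm, seed = 1)
  expect_equal(sum(m$exposed == 1), 6)
  expect_equal(sum(m$exposed == 0), 6)
  d <- tapply(m$pscore, m$match_id, function(s) abs(diff(s)))
  expect_true(all(d < 1e-12))
})

test_that("1:1 matching is capped by the smaller arm and reuses no control", {
  fx <- posthoc_fixture(10, 5, seed = 3)
  # tiny saturated pool: propensity separation warnings are expected here
  m <- suppressWarnings(match_cohort(c("X", "Y"), fx$eps, fx$adm, seed = 1))
  expect_equal(sum(m$exposed == 1), 5)
  expect_equal(sum(m$exposed == 0), 5)
  expect_false(any(duplicated(m$admission_id)))
  # empty arm: skipped with a warning
  expect_warning(
    out <- match_cohort(c("X", "Q"), fx$eps, fx$adm, seed = 1),
    "skipped")
  expect_null(out)
})

test_that("greedy matching equals sequential minimal-distance assignment", {
  fx <- posthoc_fixture(4, 4, seed = 4)
  m <- suppressWarnings(match_cohort(c("X", "Y"), fx$eps, fx$adm, seed = 9))
  # oracle: replay the documented rule by hand on the fitted scores
  pool <- rbind(
    data.frame(id = m$admission_id[m$exposed == 1],
               ps = m$pscore[m$exposed == 1]),
    data.frame(id = fx$adm$admission_id[5:8], ps = NA))
  ps_fit <- suppressWarnings(
    glm(exposed ~ age + sex + diag_chapter + charlson + med_burden,
        family = binomial(),
        data = transform(fx$adm, exposed = rep(c(1, 0), c(4, 4)))))
  scores <- fitted(ps_fit)
  names(scores) <- fx$adm$admission_id
  set.seed(9)
  ord <- sample.int(4)
  used <- character(0)
  expected <- list()
  for (i in ord) {
    ex_id <- fx$adm$admission_id[i]
    free <- setdiff(fx$adm$admission_id[5:8], used)
    d <- abs(scores[free] - scores[ex_id])
    pick <- sort(free[d == min(d)])[1]
    used <- c(used, pick)
    expected[[ex_id]] <- pick
  }
  for (mid in unique(m$match_id)) {
    ex_id <- m$admission_id[m$match_id == mid & m$exposed == 1]
    ct_id <- m$admission_id[m$match_id == mid & m$exposed == 0]
    expect_identical(unname(expected[[ex_id]]), ct_id)
  }
})

test_that("matching improves or preserves covariate balance", {
  fx <- posthoc_fixture(40, 120, seed = 5, covar_shift = 8)
  pre <- rbind(transform(fx$adm[1:40, ], exposed = 1L),
               transform(fx$adm[41:160, ], exposed = 0L))
  m <- match_cohort(c("X", "Y"), fx$eps, fx$adm, seed = 2)
  smd_pre <- matching_smd(pre)
  smd_post <- matching_smd(m)
  expect_true(all(smd_post <= smd_pre + 1e-8))
})

test_that("planted outcome effects are recovered within 2 SE", {
  set.seed(6)
  n <- 400
  fx <- posthoc_fixture(n, n, seed = 6)
  m <- match_cohort(c("X", "Y"), fx$eps, fx$adm, seed = 3)
  # plant: mortality hazard ratio 2, LOS rate ratio 2
  lam0 <- -log(1 - 0.15) / 30
  lam <- lam0 * ifelse(m$exposed == 1, 2, 1)
  td <- rexp(nrow(m), lam)
  m2 <- m
  adm2 <- fx$adm
  adm2$death_time <- ifelse(td <= 30, td * 1440, NA)[
    match(adm2$admission_id, m2$admission_id)]
  adm2$los_days <- rpois(nrow(adm2), 6 * ifelse(
    adm2$admission_id %in% m2$admission_id[m2$exposed == 1], 2, 1))
  res <- test_outcomes(m2, adm2)
  mort <- res[res$endpoint == "mortality_30d", ]
  expect_true(mort$estimable)
  expect_lt(abs(mort$effect - log(2)), 2 * mort$se)
  los <- res[res$endpoint == "LOS", ]
  expect_true(los$estimable)
  expect_lt(abs(los$effect - log(2)), 2 * los$se)
})

test_that("conditional pair-total fit equals per-pair fixed-effects Poisson", {
  set.seed(7)
  fx <- posthoc_fixture(60, 60, seed = 7)
  m <- match_cohort(c("X", "Y"), fx$eps, fx$adm, seed = 4)
  adm2 <- fx$adm
  adm2$los_days <- rpois(nrow(adm2), 7)
  res <- test_outcomes(m, adm2)
  los <- res[res$endpoint == "LOS", ]
  # independent route: Poisson GLM with one dummy per matched pair
  mm <- dplyr::left_join(dplyr::select(m, -dplyr::any_of("los_days")),
                         adm2[, c("admission_id", "los_days")],
                         by = "admission_id")
  g <- glm(round(los_days) ~ exposed + age + sex + charlson + med_burden +
             factor(match_id), family = poisson(), data = mm)
  expect_lt(abs(los$effect - coef(g)[["exposed"]]), 0.08)
})

test_that("discontinuation association recovers a planted odds shift", {
  set.seed(8)
  fx <- posthoc_fixture(300, 300, seed = 8)
  m <- match_cohort(c("X", "Y"), fx$eps, fx$adm, seed = 5)
  p_disc <- plogis(qlogis(0.15) + log(2) * m$exposed)
  disc_eps <- fx$eps
  hit <- rbinom(nrow(m), 1, p_disc) == 1
  disc_eps$discontinued <- disc_eps$admission_id %in% m$admission_id[hit]
  res <- test_discontinuation(m, disc_eps)
  expect_true(res$estimable)
  expect_lt(abs(res$effect - log(2)), 2.5 * res$se)
})

test_that("enrichment respects the presence threshold and imputes missing", {
  set.seed(10)
  fx <- posthoc_fixture(100, 100, seed = 10)
  m <- match_cohort(c("X", "Y"), fx$eps, fx$adm, seed = 6)
  dx <- tibble::tibble(
    admission_id = c(sample(m$admission_id, 120), # common code
                     sample(m$admission_id, 49)), # sub-threshold code
    icd_code = rep(c("DXA", "DXB"), c(120, 49)))
  bt <- tibble::tibble(admission_id = sample(m$admission_id, 150),
                       test_code = "BT1", abnormal = rbinom(150, 1, 0.3))
  res <- test_enrichment(m, dx, bt, min_patients = 50)
  expect_true("diagnosis:DXA" %in% res$endpoint)
  expect_false("diagnosis:DXB" %in% res$endpoint)
  expect_true("bloodtest:BT1" %in% res$endpoint)
  # all-normal test: constant outcome, skipped
  bt0 <- tibble::tibble(admission_id = sample(m$admission_id, 60),
                        test_code = "BT9", abnormal = 0L)
  res0 <- test_enrichment(m, dx[0, ], bt0, min_patients = 50)
  expect_equal(nrow(res0), 0)
})

test_that("Bonferroni adjustment is family-wise and monotone", {
  res <- tibble::tibble(
    pair_id = "X|Y",
    endpoint = c("mortality_30d", "mortality_30d", "diagnosis:D1",
                 "diagnosis:D2", "diagnosis:D3"),
    effect = 1, se = 1, p_raw = c(0.01, 0.04, 0.02, 0.5, NA),
    estimable = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  adj <- bonferroni_family(res)
  expect_equal(adj$p_bonferroni[1], 0.02)
  expect_equal(adj$family_size[adj$endpoint == "diagnosis:D1"][1], 2)
  expect_equal(adj$p_bonferroni[adj$endpoint == "diagnosis:D2"], 1)
  expect_true(all(adj$p_bonferroni >= adj$p_raw, na.rm = TRUE))
})
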