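test_that("the HDI is the shortest window at the requested mass", {
  # constant sample: zero width
  expect_equal(unname(hdi(rep(3.2, 100))), c(3.2, 3.2))
  # uniform grid 0..999 at mass 0.89: any window of 890 points, width 889
  g <- hdi(0:999, mass = 0.89)
  expect_equal(unname(g["high"] - g["low"]), 889)
  # brute-force agreement on assorted samples
  set.seed(9)
  for (i in 1:12) {
    n <- sample(50:2000, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rexp(n), c(rnorm(n / 2), rnorm(n / 2, 5)))
    expect_equal(unname(hdi(x)), oracle_hdi(x), tolerance = 1e-12)
  }
  # symmetric unimodal: close to the central interval
  x <- rnorm(50000)
  h <- hdi(x)
  q <- quantile(x, c(0.055, 0.945))
  expect_lt(max(abs(unname(h) - unname(q))), 0.08)
  expect_error(hdi(1), class = "dosepair_contract_error")
})

test_that("ROPE decisions follow the containment rule", {
  expect_identical(rope_decision(c(0.10, 0.30)), "reject_null")
  expect_identical(rope_decision(c(-0.02, 0.03)), "accept_null")
  expect_identical(rope_decision(c(-0.01, 0.20)), "undecided")
  expect_identical(rope_decision(c(-0.30, -0.10)), "reject_null")
  # boundary contact is not rejection
  expect_identical(rope_decision(c(0.05, 0.30)), "undecided")
  expect_identical(rope_decision(c(-0.05, 0.05)), "accept_null")
})

test_that("Rice's rule bin counts are exact", {
  expect_identical(rice_bins(1000), 21L)
  expect_identical(rice_bins(1), 3L)
  expect_identical(rice_bins(8), 5L)
  expect_equal(rice_bins(100), ceiling(2 * 100^(1 / 3)) + 1)
})

test_that("down-sampling preserves stratum proportions", {
  set.seed(15)
  n <- 20000
  adm <- data.frame(admission_id = sprintf("a%05d", 1:n),
                    age = sample(c(40, 80), n, TRUE, prob = c(0.9, 0.1)),
                    sex = "F", hospital = "H1", diag_chapter = "C1",
                    year = 2010)
  eps <- data.frame(episode_id = sprintf("e%05d", 1:n),
                    admission_id = adm$admission_id,
                    patient_id = sprintf("p%05d", 1:n),
                    index_drug = "X", co_med = "Y", N = 2L, y = 0L,
                    complete = TRUE)
  small <- stratified_downsample(eps, adm, threshold = 2000,
                                 min_pair_patients = 1, seed = 3)
  expect_equal(nrow(small), 2000)
  got <- mean(adm$age[match(small$admission_id, adm$admission_id)] == 80)
  expect_lt(abs(got - 0.1), 0.03)
  # below threshold: unchanged
  expect_identical(stratified_downsample(eps, adm, threshold = 1e6),
                   tibble::as_tibble(eps))
})

test_that("down-sampling keeps only the most frequent co-medications", {
  set.seed(16)
  n <- 6000
  adm <- data.frame(admission_id = sprintf("a%05d", 1:n), age = 50, sex = "F",
                    hospital = "H1", diag_chapter = "C1", year = 2010)
  eps <- data.frame(episode_id = sprintf("e%05d", 1:n),
                    admission_id = adm$admission_id,
                    patient_id = sprintf("p%05d", 1:n),
                    index_drug = "X",
                    co_med = sample(c("C1", "C2", "C3"), n, TRUE,
                                    prob = c(0.7, 0.25, 0.05)),
                    N = 2L, y = 0L, complete = TRUE)
  out <- stratified_downsample(eps, adm, threshold = 3000,
                               top_comedications = 2, min_pair_patients = 1,
                               seed = 4)
  expect_setequal(unique(out$co_med), c("C1", "C2"))
  expect_lte(nrow(out), 3000)
})

test_that("the posterior intercept matches the closed-form rate on balanced data", {
  # all-monotherapy, no covariate variation, no patient replication:
  # posterior of the population intercept should sit near logit(sum y / sum N)
  n <- 400
  set.seed(2)
  eps <- tibble::tibble(
    episode_id = sprintf("e%04d", 1:n), patient_id = sprintf("p%04d", 1:n),
    admission_id = sprintf("a%04d", 1:n), index_drug = "X",
    co_med = "MONOTHERAPY", N = 6L, y = rbinom(n, 5, 0.3), complete = TRUE)
  adm <- tibble::tibble(admission_id = eps$admission_id, age = 50, sex = "F",
                        hospital = "H1", diag_chapter = "C1", year = 2010)
  fit <- fit_index_drug(eps, adm, fast_spec(iter = 800, warmup = 400),
                        seed = 8)
  expect_equal(nrow(fit), 0) # no pairs, intercept only
  dr <- attr(fit, "intercept_draws")
  mle <- qlogis(sum(eps$y) / sum(pmax(eps$N - 1, 0)))
  expect_lt(abs(median(dr) - mle), 3 * sd(dr))
})

test_that("pair coefficients agree with a likelihood fit on the same data", {
  drugs <- synthetic_drugs(2)
  co <- generate_cohort(recovery_cohort(800, log(2.5), seed = 55))
  eps <- build_episodes(co$prescriptions)
  sel <- apply_selection_filters(eps, co$prescriptions)
  e1 <- sel$episodes[sel$episodes$index_drug == drugs[1], ]
  fit <- fit_index_drug(e1, co$admissions, fast_spec(), seed = 9)
  # independent route: binomial GLM on transitions, no patient effect
  g <- glm(cbind(y, pmax(N - 1, 0) - y) ~ (co_med != "MONOTHERAPY"),
           family = binomial(), data = e1[e1$N > 1, ])
  b_glm <- coef(g)[2]
  se_glm <- sqrt(diag(vcov(g)))[2]
  expect_lt(abs(fit$coef_median - b_glm), 3 * se_glm + 0.05)
})

test_that("seeded fits replay identically", {
  co <- generate_cohort(recovery_cohort(400, log(2), seed = 60))
  eps <- build_episodes(co$prescriptions)
  sel <- apply_selection_filters(eps, co$prescriptions)
  e1 <- sel$episodes[sel$episodes$index_drug == synthetic_drugs(1), ]
  spec <- fast_spec(iter = 600, warmup = 300)
  f1 <- fit_index_drug(e1, co$admissions, spec, seed = 13)
  f2 <- fit_index_drug(e1, co$admissions, spec, seed = 13)
  expect_equal(f1$or_median, f2$or_median, tolerance = 1e-12)
  expect_equal(f1$hdi_low, f2$hdi_low, tolerance = 1e-12)
})

test_that("missing monotherapy reference is refused as unidentifiable", {
  eps <- tibble::tibble(
    episode_id = "e1", patient_id = "p1", admission_id = "a1",
    index_drug = "X", co_med = "Y", N = 3L, y = 1L, complete = TRUE)
  adm <- tibble::tibble(admission_id = "a1", age = 50, sex = "F",
                        hospital = "H1", diag_chapter = "C1", year = 2010)
  expect_error(fit_index_drug(eps, adm, fast_spec(), seed = 1),
               "unidentifiable", class = "dosepair_data_error")
})

test_that("model specs validate their settings", {
  expect_error(model_spec(iter = 500, warmup = 500),
               class = "dosepair_config_error")
  expect_error(model_spec(rope = c(0.1, -0.1)),
               class = "dosepair_config_error")
})
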