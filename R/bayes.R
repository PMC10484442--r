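# Hierarchical Bayesian binomial logistic regression per index drug.
#
# For every episode e of an index drug, the change count y_e is binomial with
# N_e trials and probability p_e, where logit(p_e) is the sum of an intercept,
# a coefficient for the concomitant drug (monotherapy is the reference level),
# fixed effects for age, sex, hospital, primary-diagnosis chapter and calendar
# year, and a patient random intercept. Coefficients get zero-mean normal
# priors whose scales are themselves half-normal(0, 1) (sex: half-normal(0,
# 0.5)). The exponentiated concomitant-drug coefficient is the pair's adjusted
# odds ratio of dosage modification versus monotherapy.

#' Highest density interval of a posterior sample
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the `n`
#' sorted draws. 89% mass is the default: narrower than 95% and more stable at
#' moderate effective sample sizes.
#'
#' @param draws numeric sample (at least 2 finite values).
#' @param mass probability mass to cover, in (0, 1].
#' @return named numeric `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.89) {
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n < 2L) stop_contract("hdi() needs at least 2 finite draws")
  if (mass <= 0 || mass > 1) stop_contract("mass must be in (0, 1]")
  m <- ceiling(mass * n)
  if (m >= n) return(c(low = x[1], high = x[n]))
  w <- x[(m):n] - x[1:(n - m + 1)]
  i <- which.min(w)
  c(low = x[i], high = x[i + m - 1])
}

#' ROPE decision for a coefficient HDI
#'
#' The region of practical equivalence (ROPE) is an interval around zero on
#' the log-odds scale, default (-0.05, 0.05). The null is rejected when the
#' HDI lies completely outside the ROPE, accepted when the HDI is completely
#' inside, and otherwise the decision is withheld.
#'
#' @param interval numeric `c(low, high)` HDI on the coefficient scale.
#' @param rope numeric `c(low, high)` null region.
#' @return one of `"reject_null"`, `"accept_null"`, `"undecided"`.
#' @export
rope_decision <- function(interval, rope = c(-0.05, 0.05)) {
  lo <- interval[[1]]; hi <- interval[[2]]
  if (lo > hi) stop_contract("invalid HDI: low > high")
  if (rope[[1]] >= rope[[2]]) stop_contract("invalid ROPE bounds")
  if (hi < rope[[1]] || lo > rope[[2]]) return("reject_null")
  if (lo >= rope[[1]] && hi <= rope[[2]]) return("accept_null")
  "undecided"
}

#' Rice's rule bin count
#'
#' k = ceiling(2 n^(1/3)) + 1, used to discretise age for stratified
#' down-sampling. A 1e-9 guard absorbs binary floating-point error in the cube
#' root (e.g. n = 1000, where 2 n^(1/3) is mathematically exactly 20).
#'
#' @param n number of observations.
#' @return integer bin count.
#' @export
rice_bins <- function(n) {
  if (n < 1) stop_contract("n must be >= 1")
  as.integer(ceiling(2 * n^(1 / 3) - 1e-9) + 1)
}

#' MCMC and prior settings of the dosage-change model
#'
#' @param chains number of chains (default 4).
#' @param iter iterations per chain including warmup (default 2000).
#' @param warmup warmup iterations per chain (default 1000; adaptation uses
#'   the first half of warmup).
#' @param hdi_mass posterior mass of reported intervals (default 0.89).
#' @param rope null region on the log-odds scale (default (-0.05, 0.05)).
#' @param prior_mode `"hierarchical"` (coefficient scales are half-normal
#'   hyperpriors) or `"fixed"` (scales fixed at `sigma_fixed`; sensitivity
#'   mode).
#' @param sigma_sex scale parameter of the sex coefficient's half-normal
#'   hyperprior (default 0.5; all other scales use 1).
#' @param sigma_fixed coefficient scale used in `"fixed"` mode.
#' @param trials `"prescriptions"` (N = prescription count, as the model is
#'   defined) or `"transitions"` (N - 1; sensitivity mode with a tight y <= N
#'   bound).
#' @param rhat_max convergence threshold on the largest split R-hat.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(chains = 4, iter = 2000, warmup = 1000,
                       hdi_mass = 0.89, rope = c(-0.05, 0.05),
                       prior_mode = c("hierarchical", "fixed"),
                       sigma_sex = 0.5, sigma_fixed = 1,
                       trials = c("prescriptions", "transitions"),
                       rhat_max = 1.1) {
  if (warmup >= iter) stop_config("warmup must be smaller than iter")
  if (rope[1] >= rope[2]) stop_config("rope must satisfy low < high")
  structure(list(chains = chains, iter = iter, warmup = warmup,
                 hdi_mass = hdi_mass, rope = rope,
                 prior_mode = match.arg(prior_mode), sigma_sex = sigma_sex,
                 sigma_fixed = sigma_fixed, trials = match.arg(trials),
                 rhat_max = rhat_max),
            class = "model_spec")
}

# JAGS model source, assembled from the terms identified in the data
.jags_model_source <- function(has, hier, sigma_sex, sigma_fixed) {
  pr <- function(sig, half = 1) {
    if (hier) sprintf("dnorm(0, 1 / (%s * %s))", sig, sig)
    else sprintf("dnorm(0, %g)", 1 / sigma_fixed^2)
  }
  lp <- c("b0",
          if (has["com"]) "bc[com[e]]",
          if (has["age"]) "b_age * age[e]",
          if (has["sex"]) "b_sex * sex[e]",
          if (has["hospital"]) "b_hosp[hosp[e]]",
          if (has["diagnosis"]) "b_diag[diag[e]]",
          if (has["year"]) "b_year[yr[e]]",
          if (has["patient"]) "u[pat[e]]")
  body <- c(
    "model {",
    "  for (e in 1:E) {",
    "    y[e] ~ dbin(p[e], Ntr[e])",
    paste0("    logit(p[e]) <- ", paste(lp, collapse = " + ")),
    "  }",
    paste0("  b0 ~ ", pr("sig_0")),
    if (has["com"]) c(
      "  bc[1] <- 0",
      paste0("  for (k in 2:K) { bc[k] ~ ", pr("sig_c"), " }")),
    if (has["age"]) paste0("  b_age ~ ", pr("sig_a")),
    if (has["sex"]) paste0("  b_sex ~ ", pr("sig_s")),
    if (has["hospital"]) c(
      "  b_hosp[1] <- 0",
      paste0("  for (k in 2:H) { b_hosp[k] ~ ", pr("sig_h"), " }")),
    if (has["diagnosis"]) c(
      "  b_diag[1] <- 0",
      paste0("  for (k in 2:D) { b_diag[k] ~ ", pr("sig_d"), " }")),
    if (has["year"]) c(
      "  b_year[1] <- 0",
      paste0("  for (k in 2:Y) { b_year[k] ~ ", pr("sig_y"), " }")),
    if (has["patient"]) c(
      "  for (j in 1:P) { u[j] ~ dnorm(0, 1 / (sig_p * sig_p)) }",
      # the identified population intercept; b0 and mean(u) trade off freely
      "  b0c <- b0 + mean(u[1:P])"),
    if (hier) c(
      "  sig_0 ~ dnorm(0, 1) T(0,)",
      if (has["com"]) "  sig_c ~ dnorm(0, 1) T(0,)",
      if (has["age"]) "  sig_a ~ dnorm(0, 1) T(0,)",
      if (has["sex"]) sprintf("  sig_s ~ dnorm(0, %g) T(0,)", 1 / sigma_sex^2),
      if (has["hospital"]) "  sig_h ~ dnorm(0, 1) T(0,)",
      if (has["diagnosis"]) "  sig_d ~ dnorm(0, 1) T(0,)",
      if (has["year"]) "  sig_y ~ dnorm(0, 1) T(0,)"),
    if (has["patient"]) "  sig_p ~ dnorm(0, 1) T(0,)",
    "}")
  paste(body, collapse = "\n")
}

#' Fit the dosage-change model for one index drug
#'
#' One joint model over all the index drug's complete episodes, with
#' monotherapy as the reference level of the concomitant-drug factor. Factor
#' covariates observed at a single level carry no term; a co-medication with
#' no monotherapy episodes anywhere in the input makes the intercept and the
#' pair coefficients collinear, so the fit is refused. Convergence is declared
#' when the largest split R-hat across monitored parameters is at most
#' `spec$rhat_max`. The Gibbs-family sampler used here has no divergence or
#' tree-depth diagnostic, so `divergences` is always 0; R-hat and effective
#' sample size are the operative gates.
#'
#' @param episodes episode tibble (one index drug, `complete == TRUE`,
#'   `y <= N`).
#' @param covariates admissions table supplying `age`, `sex`, `hospital`,
#'   `diag_chapter`, `year` per `admission_id`.
#' @param spec a [model_spec()].
#' @param seed integer seed; chain RNGs are derived from it.
#' @return tibble with one row per co-medication: `index_drug`, `co_med`,
#'   `or_median`, `hdi_low`, `hdi_high` (odds-ratio scale), `coef_median`,
#'   `coef_hdi_low`, `coef_hdi_high`, `rope_decision`, `significant`,
#'   `converged`, `rhat_max`, `divergences`, `ess_bulk_min`, `n_patients`,
#'   `n_episodes`.
#' @export
fit_index_drug <- function(episodes, covariates, spec = model_spec(),
                           seed = 1L) {
  ep <- tibble::as_tibble(episodes)
  if (length(unique(ep$index_drug)) != 1L) {
    stop_contract("fit_index_drug() expects episodes of exactly one index drug")
  }
  ep <- ep[ep$complete, ]
  if (nrow(ep) == 0L) stop_contract("no complete episodes to fit")
  if (any(ep$y > ep$N, na.rm = TRUE)) {
    stop_contract("episode with y > N; change counts exceed trials")
  }
  if (!any(ep$co_med == MONOTHERAPY) && any(ep$co_med != MONOTHERAPY)) {
    stop_data(paste("no monotherapy reference episodes for index drug",
                    ep$index_drug[1], "- pair coefficients unidentifiable"))
  }
  cov <- tibble::as_tibble(covariates)
  ep <- dplyr::left_join(
    ep, cov[, intersect(c("admission_id", "age", "sex", "hospital",
                          "diag_chapter", "year"), names(cov))],
    by = "admission_id")

  ntr <- if (spec$trials == "prescriptions") ep$N else pmax(ep$N - 1L, 0L)
  keep <- ntr > 0L
  ep <- ep[keep, ]
  ntr <- ntr[keep]

  com_lv <- c(MONOTHERAPY, sort(setdiff(unique(ep$co_med), MONOTHERAPY)))
  pat_lv <- unique(ep$patient_id)
  fac <- function(x) as.integer(factor(x))
  nlv <- function(x) length(unique(x))

  has <- c(com = length(com_lv) > 1L,
           age = "age" %in% names(ep) && nlv(ep$age) > 1L,
           sex = "sex" %in% names(ep) && nlv(ep$sex) > 1L,
           hospital = "hospital" %in% names(ep) && nlv(ep$hospital) > 1L,
           diagnosis = "diag_chapter" %in% names(ep) && nlv(ep$diag_chapter) > 1L,
           year = "year" %in% names(ep) && nlv(ep$year) > 1L,
           patient = TRUE)

  dat <- list(E = nrow(ep), y = as.integer(ep$y), Ntr = as.integer(ntr))
  if (has["com"]) {
    dat$com <- match(ep$co_med, com_lv)
    dat$K <- length(com_lv)
  }
  if (has["age"]) dat$age <- as.numeric(scale(ep$age))
  if (has["sex"]) dat$sex <- as.integer(ep$sex == sort(unique(ep$sex))[2])
  if (has["hospital"]) { dat$hosp <- fac(ep$hospital); dat$H <- nlv(ep$hospital) }
  if (has["diagnosis"]) { dat$diag <- fac(ep$diag_chapter); dat$D <- nlv(ep$diag_chapter) }
  if (has["year"]) { dat$yr <- fac(ep$year); dat$Y <- nlv(ep$year) }
  dat$pat <- match(ep$patient_id, pat_lv)
  dat$P <- length(pat_lv)

  src <- .jags_model_source(has, spec$prior_mode == "hierarchical",
                            spec$sigma_sex, spec$sigma_fixed)
  b0_name <- if (has["patient"]) "b0c" else "b0"
  monitors <- c(b0_name, if (has["com"]) "bc")
  inits <- lapply(seq_len(spec$chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, 100L + i))
  })
  n_adapt <- max(100L, floor(spec$warmup / 2))
  n_burn <- max(0L, spec$warmup - n_adapt)
  jm <- rjags::jags.model(textConnection(src), data = dat,
                          n.chains = spec$chains, n.adapt = n_adapt,
                          inits = inits, quiet = TRUE)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitors, n.iter = spec$iter - spec$warmup,
                            progress.bar = "none")

  vn <- coda::varnames(sm)
  drop_const <- vapply(vn, function(v) {
    all(vapply(sm, function(ch) stats::var(as.numeric(ch[, v])) == 0,
               logical(1)))
  }, logical(1)) # bc[1] is the fixed reference level
  keep_vn <- vn[!drop_const]
  rhat <- if (spec$chains > 1L) {
    tryCatch(
      max(coda::gelman.diag(sm[, keep_vn, drop = FALSE], autoburnin = FALSE,
                            multivariate = FALSE)$psrf[, 1]),
      error = function(e) NA_real_)
  } else NA_real_
  ess <- min(coda::effectiveSize(sm[, keep_vn, drop = FALSE]))
  converged <- !is.na(rhat) && rhat <= spec$rhat_max

  draws <- do.call(rbind, lapply(sm, as.matrix))
  out <- list()
  for (k in seq_along(com_lv)[-1]) {
    d <- draws[, sprintf("bc[%d]", k)]
    ch <- hdi(d, spec$hdi_mass)
    dec <- rope_decision(ch, spec$rope)
    orm <- exp(median(d))
    n_pat <- dplyr::n_distinct(ep$patient_id[ep$co_med == com_lv[k]])
    out[[length(out) + 1L]] <- tibble::tibble(
      index_drug = ep$index_drug[1], co_med = com_lv[k],
      or_median = orm, hdi_low = exp(ch[["low"]]), hdi_high = exp(ch[["high"]]),
      coef_median = median(d), coef_hdi_low = ch[["low"]],
      coef_hdi_high = ch[["high"]],
      rope_decision = dec,
      significant = converged && dec == "reject_null" && orm > 1,
      converged = converged, rhat_max = rhat, divergences = 0L,
      ess_bulk_min = ess,
      n_patients = n_pat,
      n_episodes = sum(ep$co_med == com_lv[k]))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "intercept_draws") <- draws[, b0_name]
  attr(res, "jags_model") <- src
  res
}

#' Fit the dosage-change model for every retained index drug
#'
#' @param episodes filtered episode tibble (any number of index drugs).
#' @param covariates admissions table.
#' @param spec a [model_spec()].
#' @param seed integer; each index drug gets a derived seed, so results do not
#'   depend on fit order.
#' @return row-bound [fit_index_drug()] results.
#' @export
fit_all_pairs <- function(episodes, covariates, spec = model_spec(),
                          seed = 1L) {
  idx <- sort(unique(episodes$index_drug))
  res <- lapply(seq_along(idx), function(i) {
    e <- episodes[episodes$index_drug == idx[i], ]
    if (!any(e$co_med != MONOTHERAPY)) return(NULL)
    fit_index_drug(e, covariates, spec,
                   seed = derive_seed(seed, 1000L + i))
  })
  dplyr::bind_rows(res)
}

#' Stratified down-sampling of oversized episode sets
#'
#' Applied per index drug when its episode count exceeds `threshold`: the most
#' frequent `top_comedications` co-medications are kept, then episodes are
#' sampled down to `threshold` preserving the joint frequency profile of age
#' bin (Rice's rule on the episode count), sex, calendar year, hospital,
#' diagnosis chapter and concomitant drug; co-medications left with fewer than
#' `min_pair_patients` patients are dropped.
#'
#' @param episodes episode tibble joined or joinable to covariates.
#' @param covariates admissions table.
#' @param threshold maximal episode count (default 500000).
#' @param top_comedications co-medications kept (default 300).
#' @param min_pair_patients post-sampling patient floor (default 50).
#' @param seed integer seed.
#' @return episode tibble, unchanged when below the threshold.
#' @export
stratified_downsample <- function(episodes, covariates, threshold = 500000,
                                  top_comedications = 300,
                                  min_pair_patients = 50, seed = 1L) {
  ep <- tibble::as_tibble(episodes)
  if (nrow(ep) <= threshold) return(ep)
  set.seed(seed)
  cov <- tibble::as_tibble(covariates)
  epc <- dplyr::left_join(
    ep, cov[, intersect(c("admission_id", "age", "sex", "hospital",
                          "diag_chapter", "year"), names(cov))],
    by = "admission_id")

  cm_rank <- sort(table(epc$co_med[epc$co_med != MONOTHERAPY]),
                  decreasing = TRUE)
  keep_cm <- c(MONOTHERAPY, names(head(cm_rank, top_comedications)))
  epc <- epc[epc$co_med %in% keep_cm, ]
  if (nrow(epc) <= threshold) return(ep[ep$episode_id %in% epc$episode_id, ])

  k <- rice_bins(nrow(epc))
  age_bin <- cut(epc$age, breaks = k, include.lowest = TRUE, labels = FALSE)
  stratum <- paste(age_bin, epc$sex, epc$year, epc$hospital, epc$diag_chapter,
                   epc$co_med, sep = "\r")
  tab <- table(stratum)
  # proportional allocation, exact total via largest remainders
  raw <- as.numeric(tab) / nrow(epc) * threshold
  n_take <- floor(raw)
  rem <- threshold - sum(n_take)
  if (rem > 0) {
    o <- order(raw - n_take, decreasing = TRUE)
    n_take[o[seq_len(rem)]] <- n_take[o[seq_len(rem)]] + 1L
  }
  n_take <- pmin(n_take, as.numeric(tab))
  picked <- unlist(lapply(seq_along(tab), function(i) {
    ids <- which(stratum == names(tab)[i])
    ids[sample.int(length(ids), n_take[i])]
  }))
  out <- ep[ep$episode_id %in% epc$episode_id[picked], ]

  pair_pat <- dplyr::summarise(
    dplyr::group_by(out[out$co_med != MONOTHERAPY, ],
                    .data$index_drug, .data$co_med),
    n_pat = dplyr::n_distinct(.data$patient_id), .groups = "drop")
  small <- pair_pat[pair_pat$n_pat < min_pair_patients, ]
  out[!(out$co_med != MONOTHERAPY &
          paste(out$index_drug, out$co_med) %in%
            paste(small$index_drug, small$co_med)), ]
}
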