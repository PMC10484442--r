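# shared toy: drug A active [0, 14400), drug B active [5760, 8640)
two_drug_fixture <- function(doses_a = c(200, 200, 300, 300, 300),
                             dose_b = 100) {
  bounds_a <- seq(0, 14400, length.out = length(doses_a) + 1)
  rbind(
    data.frame(drug_atc = "A", start = head(bounds_a, -1),
               end = tail(bounds_a, -1), dose = doses_a),
    data.frame(drug_atc = "B", start = 5760, end = 8640, dose = dose_b)
  ) |>
    transform(rx_id = sprintf("R%02d", seq_len(length(doses_a) + 1)),
              admission_id = "A1", patient_id = "P1", unit = "mg", freq = 1,
              interval_hours = 24, rx_type = "scheduled",
              strength = NA_real_, volume = NA_real_)
}

test_that("partial overlap yields two monotherapy and one concomitant episode", {
  eps <- build_episodes(two_drug_fixture())
  a <- eps[eps$index_drug == "A", ]
  mono <- a[a$co_med == "MONOTHERAPY", ]
  conc <- a[a$co_med == "B", ]
  expect_equal(nrow(mono), 2)
  expect_equal(nrow(conc), 1)
  expect_equal(sort(mono$start), c(0, 8640))
  expect_equal(sort(mono$end), c(5760, 14400))
  expect_equal(c(conc$start, conc$end), c(5760, 8640))
  # B is concomitant with A for its whole activity
  b <- eps[eps$index_drug == "B", ]
  expect_equal(b$co_med, "A")
})

test_that("a single drug produces exactly one monotherapy episode", {
  p <- two_drug_fixture()
  p <- p[p$drug_atc == "A", ]
  eps <- build_episodes(p)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$co_med, "MONOTHERAPY")
  expect_equal(eps$N, 5)
})

test_that("change counts follow the lagged-difference definition", {
  expect_equal(count_changes(c(600, 600, 300, 300)), 1L)
  expect_equal(count_changes(rep(42, 10)), 0L)
  expect_equal(count_changes(c(1, 2, 1, 2)), 3L)
  expect_equal(count_changes(numeric(0)), 0L)
  expect_equal(count_changes(5), 0L)
  # rounding rule: differences beyond 6 significant digits are not changes
  expect_equal(count_changes(c(100, 100 + 1e-6)), 0L)
  for (i in 1:20) {
    v <- sample(c(100, 200, 300), sample(2:8, 1), replace = TRUE)
    expect_equal(count_changes(v), oracle_count_changes(v))
  }
})

test_that("episode sets match a per-minute active-set enumeration", {
  set.seed(1203)
  for (i in 1:15) {
    pa <- random_admission_fixture()
    if (is.null(pa)) next
    add <- compute_add_table(pa)
    eps <- build_episodes(pa, add)
    got <- eps[order(eps$index_drug, eps$co_med, eps$start),
               c("index_drug", "co_med", "start", "end", "N", "y")]
    want <- oracle_episode_scan(pa, add$add_value)
    want <- want[order(want$index_drug, want$co_med, want$start), ]
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("episodes partition each drug's active timeline", {
  set.seed(77)
  for (i in 1:10) {
    pa <- random_admission_fixture()
    if (is.null(pa)) next
    eps <- build_episodes(pa)
    for (d in unique(pa$drug_atc)) {
      sub <- eps[eps$index_drug == d, ]
      segs <- unique(sub[, c("start", "end")])
      segs <- segs[order(segs$start), ]
      # pairwise disjoint
      if (nrow(segs) > 1) {
        expect_true(all(segs$start[-1] >= segs$end[-nrow(segs)]))
      }
      # union equals activity: total length matches merged prescriptions
      pd <- pa[pa$drug_atc == d, ]
      merged <- dosepair:::merge_intervals(pd$start, pd$end)
      expect_equal(sum(segs$end - segs$start), sum(merged$end - merged$start))
    }
  }
})

test_that("change counts are invariant to time translation", {
  pa <- two_drug_fixture(doses_a = c(200, 300, 300, 100, 100))
  eps <- build_episodes(pa)
  pa2 <- pa
  pa2$start <- pa2$start + 99990
  pa2$end <- pa2$end + 99990
  eps2 <- build_episodes(pa2)
  o <- order(eps$index_drug, eps$co_med, eps$start)
  o2 <- order(eps2$index_drug, eps2$co_med, eps2$start)
  expect_equal(eps$y[o], eps2$y[o2])
  expect_equal(eps$N[o], eps2$N[o2])
  expect_equal(eps2$start[o2] - eps$start[o], rep(99990, nrow(eps)))
})

test_that("overlapping duplicate prescriptions merge with a warning", {
  p <- two_drug_fixture()
  dup <- p[1, ]
  dup$rx_id <- "R99"
  dup$end <- dup$end + 1440
  expect_warning(build_episodes(rbind(p, dup)), "overlap")
})

test_that("discontinuation requires cessation strictly inside co-medication", {
  base <- function(a_end, b_end) {
    rbind(
      data.frame(drug_atc = "A", start = 0, end = a_end, dose = 200),
      data.frame(drug_atc = "B", start = 1440, end = b_end, dose = 100)
    ) |>
      transform(rx_id = c("R1", "R2"), admission_id = "A1", patient_id = "P1",
                unit = "mg", freq = 1, interval_hours = 24,
                rx_type = "scheduled", strength = NA_real_, volume = NA_real_)
  }
  # index ends day 3, co-med runs to day 5 -> discontinuation
  eps <- build_episodes(base(3 * 1440, 5 * 1440))
  expect_true(all(eps$discontinued[eps$index_drug == "A" & eps$co_med == "B"]))
  # index outlives co-med -> not discontinued (B, ending inside A, is)
  eps2 <- build_episodes(base(6 * 1440, 5 * 1440))
  expect_false(any(eps2$discontinued[eps2$index_drug == "A"]))
  expect_true(all(eps2$discontinued[eps2$index_drug == "B" &
                                      eps2$co_med == "A"]))
  # simultaneous end -> none on either side (strict interior)
  eps3 <- build_episodes(base(5 * 1440, 5 * 1440))
  expect_false(any(eps3$discontinued))
})

test_that("selection filters exclude exactly the hand-enumerated sets", {
  # drugs: X (index everywhere), Y (adequate pair), Z (rare pair),
  # W (one-time-dominated co-med)
  mk_adm <- function(pid, adm, drugs_on, w_one_time = FALSE) {
    # first drug spans the stay; later drugs are strictly inside it, so they
    # never have monotherapy time
    rows <- lapply(seq_along(drugs_on), function(i) {
      data.frame(drug_atc = drugs_on[i], start = (i - 1) * 100,
                 end = 1440 * 3 - (i - 1) * 100, dose = 100)
    })
    p <- do.call(rbind, rows)
    if (w_one_time) {
      p <- rbind(p, data.frame(drug_atc = "W", start = 500, end = 560,
                               dose = 50))
    }
    transform(p, rx_id = sprintf("%s-%d", adm, seq_len(nrow(p))),
              admission_id = adm, patient_id = pid, unit = "mg", freq = 1,
              interval_hours = 24,
              rx_type = ifelse(drug_atc == "W" & w_one_time, "one-time",
                               "scheduled"),
              strength = NA_real_, volume = NA_real_)
  }
  parts <- list()
  # 6 patients with X monotherapy, 5 with X+Y, 2 with X+Z, 2 with X+W one-time
  for (i in 1:6) parts[[length(parts) + 1]] <-
    mk_adm(sprintf("pm%d", i), sprintf("am%d", i), "X")
  for (i in 1:5) parts[[length(parts) + 1]] <-
    mk_adm(sprintf("py%d", i), sprintf("ay%d", i), c("X", "Y"))
  for (i in 1:2) parts[[length(parts) + 1]] <-
    mk_adm(sprintf("pz%d", i), sprintf("az%d", i), c("X", "Z"))
  for (i in 1:2) parts[[length(parts) + 1]] <-
    mk_adm(sprintf("pw%d", i), sprintf("aw%d", i), "X", w_one_time = TRUE)
  p <- do.call(rbind, parts)
  eps <- build_episodes(p)
  sel <- apply_selection_filters(eps, p, min_mono_patients = 5,
                                 min_pair_patients = 5,
                                 one_time_max_frac = 0.70)
  kept_pairs <- unique(sel$episodes[sel$episodes$co_med != "MONOTHERAPY",
                                    c("index_drug", "co_med")])
  # X|Y survives; X|Z (2 patients < 5) and X|W (one-time co-med) do not;
  # Y and Z lack monotherapy patients and cannot be index drugs
  expect_equal(nrow(kept_pairs), 1)
  expect_equal(kept_pairs$index_drug, "X")
  expect_equal(kept_pairs$co_med, "Y")
  expect_equal(sel$report$drugs_considered, 4) # X, Y, Z and one-time W
  expect_equal(sel$report$drugs_retained, 1)
  excl <- sel$report$exclusions[[1]]
  expect_gt(excl[["pair_insufficient_patients"]], 0)
  expect_gt(excl[["one_time_co_medication"]], 0)
})

test_that("re-admissions within 24 hours are combined", {
  adm <- data.frame(
    admission_id = c("a1", "a2", "a3"),
    patient_id = "P1",
    admit_time = c(0, 10 * 1440 + 600, 30 * 1440),
    discharge_time = c(10 * 1440, 12 * 1440, 31 * 1440),
    age = 60, sex = "F", los_days = c(10, 1.6, 1))
  out <- merge_readmissions(adm)
  expect_equal(nrow(out), 2)
  first <- out[out$admit_time == 0, ]
  expect_equal(first$discharge_time, 12 * 1440)
  expect_equal(first$admission_id, "a1")
  expect_equal(first$los_days, 12)
})
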