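# DDI evidence, shared pharmacokinetic activity and literature annotation of
# significant pairs, and rank-based comparison of known-DDI vs unknown-DDI
# groups.

.atc_pattern <- "^[A-Z][0-9]{2}([A-Z]{2}([0-9]{2})?)?$"

# unordered pair key
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Annotate co-medication pairs
#'
#' Flags, per pair: presence in the (unordered) DDI reference table; shared
#' cytochrome activity and shared transporter activity — both drugs acting on
#' a common listed protein in any role (an inducer and a substrate of the same
#' CYP qualify); a gene-variant link, when an annotated variant of one drug
#' maps to a protein that metabolises or transports the other; patient volume;
#' and literature co-mention count (0 when the pair is absent from the
#' co-mention table). Rows with malformed ATC codes are rejected with a
#' warning.
#'
#' @param pairs tibble with `index_drug`, `co_med` and optionally
#'   `n_patients`.
#' @param ddi_table tibble (`drug_a`, `drug_b`, `has_ddi`).
#' @param pk_table tibble (`drug_atc`, `protein`, `role`).
#' @param comention_table tibble (`drug_a`, `drug_b`, `n_articles`), optional.
#' @param variants tibble (`drug_atc`, `gene`, `protein`), optional.
#' @return tibble of `AnnotationRecord` rows.
#' @export
annotate_pairs <- function(pairs, ddi_table, pk_table,
                           comention_table = NULL, variants = NULL) {
  pr <- tibble::as_tibble(pairs)
  bad <- !(grepl(.atc_pattern, pr$index_drug) & grepl(.atc_pattern, pr$co_med))
  if (any(bad)) {
    warn(sprintf("%d pair row(s) rejected: malformed ATC code", sum(bad)))
    pr <- pr[!bad, ]
  }
  ddi <- tibble::as_tibble(ddi_table)
  ddi_keys <- unique(.pair_key(ddi$drug_a, ddi$drug_b)[ddi$has_ddi])
  pk <- tibble::as_tibble(pk_table)
  cyps <- grepl("^CYP", pk$protein)

  prot_of <- function(drug, transporter = FALSE) {
    sel <- pk$drug_atc == drug & (if (transporter) !cyps else cyps)
    unique(pk$protein[sel])
  }
  com <- if (!is.null(comention_table)) {
    cm <- tibble::as_tibble(comention_table)
    setNames(cm$n_articles, .pair_key(cm$drug_a, cm$drug_b))
  } else setNames(integer(0), character(0))
  var_tab <- if (!is.null(variants)) tibble::as_tibble(variants) else NULL

  out <- lapply(seq_len(nrow(pr)), function(i) {
    a <- pr$index_drug[i]; b <- pr$co_med[i]
    shared_cyp <- length(intersect(prot_of(a), prot_of(b))) > 0
    shared_tr <- length(intersect(prot_of(a, TRUE), prot_of(b, TRUE))) > 0
    vl <- FALSE
    if (!is.null(var_tab)) {
      # variant-annotated protein of one drug is a metabolising/transporting
      # protein of the other
      va <- var_tab$protein[var_tab$drug_atc == a]
      vb <- var_tab$protein[var_tab$drug_atc == b]
      vl <- length(intersect(va, pk$protein[pk$drug_atc == b])) > 0 ||
        length(intersect(vb, pk$protein[pk$drug_atc == a])) > 0
    }
    nc <- com[.pair_key(a, b)]
    tibble::tibble(
      index_drug = a, co_med = b,
      has_ddi = .pair_key(a, b) %in% ddi_keys,
      shared_cyp = shared_cyp, shared_transporter = shared_tr,
      variant_link = vl,
      n_patients = if ("n_patients" %in% names(pr)) pr$n_patients[i]
                   else NA_integer_,
      n_comentions = if (is.na(nc)) 0L else as.integer(nc))
  })
  dplyr::bind_rows(out)
}

#' Two-sided Mann-Whitney U comparison
#'
#' U statistic with exact p-value when `n1 * n2 <= 400` and the data are
#' tie-free, otherwise the normal approximation with continuity and tie
#' correction. The effect size is r = |z| / sqrt(n1 + n2), with z derived from
#' the tie-corrected normal approximation.
#'
#' @param x,y numeric samples.
#' @return list with `u`, `p`, `z`, `r`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop_contract("both samples must be nonempty")
  r_all <- rank(c(x, y))
  u <- sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact_ok <- n1 * n2 <= 400 && !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact_ok, correct = TRUE)$p.value)
  mu <- n1 * n2 / 2
  ties <- table(r_all)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (u - mu - sign(u - mu) * 0.5) / sqrt(sig2) else 0
  list(u = u, p = p, z = z, r = abs(z) / sqrt(n), n1 = n1, n2 = n2)
}

#' Compare annotated pair groups with and without DDI evidence
#'
#' For each of patient volume, literature co-mentions and the posterior median
#' OR: a two-sided Mann-Whitney U test of pairs with known DDI evidence
#' against pairs without, with effect size r (conventional labels: small
#' >= 0.1, moderate >= 0.3, large >= 0.5). When `group_var` is supplied
#' (e.g. a therapeutic group), comparisons are additionally run per group
#' value with at least `min_group` observations in each class.
#'
#' @param annotations [annotate_pairs()] output.
#' @param posteriors pair posterior tibble with `or_median` (joined on
#'   `index_drug`, `co_med`); optional.
#' @param group_var optional column name in `annotations` to stratify by.
#' @param min_group minimal per-class size within a stratum (default 5).
#' @return tibble of `GroupComparison` rows.
#' @export
compare_groups <- function(annotations, posteriors = NULL, group_var = NULL,
                           min_group = 5) {
  a <- tibble::as_tibble(annotations)
  if (!is.null(posteriors)) {
    a <- dplyr::left_join(
      a, tibble::as_tibble(posteriors)[, c("index_drug", "co_med",
                                           "or_median")],
      by = c("index_drug", "co_med"))
  }
  vars <- intersect(c("n_patients", "n_comentions", "or_median"), names(a))

  one <- function(dat, label) {
    res <- list()
    for (v in vars) {
      x <- dat[[v]][dat$has_ddi]
      y <- dat[[v]][!dat$has_ddi]
      if (sum(is.finite(x)) == 0L || sum(is.finite(y)) == 0L) next
      mw <- mann_whitney(x, y)
      lab <- if (mw$r >= 0.5) "large" else if (mw$r >= 0.3) "moderate"
             else if (mw$r >= 0.1) "small" else "negligible"
      res[[length(res) + 1L]] <- tibble::tibble(
        group = label, variable = v, u_statistic = mw$u,
        p_two_sided = mw$p, effect_size_r = mw$r, magnitude = lab,
        n_ddi = mw$n1, n_no_ddi = mw$n2)
    }
    dplyr::bind_rows(res)
  }

  out <- one(a, "all")
  if (!is.null(group_var)) {
    for (gv in sort(unique(a[[group_var]]))) {
      sub <- a[a[[group_var]] == gv, ]
      if (sum(sub$has_ddi) >= min_group && sum(!sub$has_ddi) >= min_group) {
        out <- dplyr::bind_rows(out, one(sub, as.character(gv)))
      }
    }
  }
  out
}
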