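# Paired cross-sectional statistics: discordant-pair prevalences with exact
# McNemar tests, paired t-tests on adjusted rates, Kruskal-Wallis haplogroup
# tests, Monte Carlo Fisher tests, BH-FDR, covariate battery, and the
# matched-pair power calculation by trinomial enumeration.

comparison_result <- function(family, unit, test_name, statistic, effect,
                              n, p_raw, note = "") {
  data.frame(family = family, unit = unit, test_name = test_name,
             statistic = statistic, effect = effect, n = n,
             p_raw = p_raw, p_fdr = NA_real_, note = note,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment within one test family; order-preserving.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values, elementwise at least `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Apply BH-FDR within each family of a comparison table
#'
#' @param results Data frame with `family` and `p_raw` columns.
#' @return The table with `p_fdr` filled (rows with NA `p_raw` are skipped).
#' @export
apply_fdr <- function(results) {
  for (fam in unique(results$family)) {
    i <- which(results$family == fam & !is.na(results$p_raw))
    if (length(i)) results$p_fdr[i] <- bh_fdr(results$p_raw[i])
  }
  results
}

#' Discordant-pair counts and discordant prevalence
#'
#' For matched pairs and a binary qualifier (e.g. "carries at least one
#' deleterious variant in Complex I"), counts the pairs where only member A
#' qualifies (`b`) and where only member B qualifies (`c`). The discordant
#' prevalence of group A is `b/N` and of group B `c/N`.
#'
#' @param qual_a,qual_b Logical vectors over pairs: does the A (B) member
#'   qualify?
#' @return List with `b`, `c`, `n`, `concordant`, `prev_a`, `prev_b`.
#' @export
discordant_prevalence <- function(qual_a, qual_b) {
  if (length(qual_a) == 0L) stop("empty pair set")
  stopifnot(length(qual_a) == length(qual_b),
            !any(is.na(qual_a)), !any(is.na(qual_b)))
  b <- sum(qual_a & !qual_b)
  cc <- sum(!qual_a & qual_b)
  n <- length(qual_a)
  list(b = b, c = cc, n = n, concordant = n - b - cc,
       prev_a = b / n, prev_b = cc / n)
}

#' Exact McNemar test on discordant counts
#'
#' Two-sided exact binomial test of `b ~ Binomial(b + c, 1/2)` when
#' `b + c < exact_max`; continuity-corrected chi-square otherwise;
#' `b + c = 0` gives p = 1.
#'
#' @param b,c Non-negative integer discordant-pair counts.
#' @param exact_max Discordant total at and above which the asymptotic test
#'   is used.
#' @return Two-sided p-value.
#' @export
mcnemar_exact <- function(b, c, exact_max = 25) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("b and c must be non-negative integers")
  m <- b + c
  if (m == 0) return(1)
  if (m < exact_max) {
    stats::binom.test(b, m, p = 0.5)$p.value
  } else {
    stat <- (abs(b - c) - 1)^2 / m
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Paired t-test on a per-pair metric
#'
#' Tests the mean of within-pair differences (A minus B) against zero.
#' Zero-variance differences are flagged degenerate: all-zero differences
#' report effect 0 and p = 1 (no evidence); a nonzero constant difference
#' reports the shift with p = 0.
#'
#' @param x_a,x_b Metric values for the A and B members, pair-aligned.
#' @param family,unit Labels for the comparison table.
#' @return A one-row comparison data frame (`effect` = mean difference).
#' @export
paired_rate_test <- function(x_a, x_b, family = "paired", unit = "metric") {
  stopifnot(length(x_a) == length(x_b))
  ok <- !is.na(x_a) & !is.na(x_b)
  d <- x_a[ok] - x_b[ok]
  n <- length(d)
  if (n < 2)
    return(comparison_result(family, unit, "paired t-test", NA_real_,
                             if (n) mean(d) else NA_real_, n, NA_real_,
                             "not-testable"))
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
    return(comparison_result(family, unit, "paired t-test", NA_real_,
                             mean(d), n, if (abs(mean(d)) < 1e-12) 1 else 0,
                             "degenerate"))
  }
  tt <- stats::t.test(d)
  comparison_result(family, unit, "paired t-test",
                    unname(tt$statistic), mean(d), n, tt$p.value)
}

#' Kruskal-Wallis test of a metric across haplogroups
#'
#' Haplogroups with fewer than `min_per_group` samples are dropped; the test
#' uses midrank tie correction (via [stats::kruskal.test()]).
#'
#' @param values Numeric metric per sample (variant count, deleterious
#'   count, burden, cumulative MitoTIP score, ...).
#' @param haplogroup Haplogroup label per sample.
#' @param min_per_group Minimum group size retained.
#' @param family,unit Labels for the comparison table.
#' @return A one-row comparison data frame.
#' @export
haplogroup_variant_test <- function(values, haplogroup, min_per_group = 3,
                                    family = "haplogroup", unit = "metric") {
  ok <- !is.na(values) & !is.na(haplogroup)
  values <- values[ok]; haplogroup <- haplogroup[ok]
  keep_groups <- names(which(table(haplogroup) >= min_per_group))
  use <- haplogroup %in% keep_groups
  if (length(unique(haplogroup[use])) < 2)
    return(comparison_result(family, unit, "Kruskal-Wallis", NA_real_,
                             NA_real_, sum(use), NA_real_, "not-testable"))
  kw <- stats::kruskal.test(values[use], factor(haplogroup[use]))
  comparison_result(family, unit, "Kruskal-Wallis",
                    unname(kw$statistic), NA_real_, sum(use), kw$p.value)
}

#' Fisher's exact test with Monte Carlo simulation
#'
#' Estimates the p-value by sampling contingency tables with fixed margins;
#' seeded and reproducible. The caller's RNG state is restored on exit.
#'
#' @param tab Non-negative integer contingency table (matrix).
#' @param n_sim Number of simulated tables (at least 1000).
#' @param seed Mandatory RNG seed.
#' @return Estimated p-value.
#' @export
fisher_montecarlo <- function(tab, n_sim = 1e5, seed) {
  if (missing(seed)) stop("a seed is required")
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero-margin contingency table")
  if (n_sim < 1000) stop("n_sim must be at least 1000")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::fisher.test(tab, simulate.p.value = TRUE, B = as.integer(n_sim))$p.value
}

#' Covariate battery for paired metrics
#'
#' Runs the standard covariate checks on a per-sample metric: linear
#' regression on age (slope and p), Kendall rank correlation with age for
#' count-like metrics, two-sample t-test of per-pair differences by sex, and
#' carrier-status-by-sex chi-square and two-proportion z tests.
#'
#' @param metric Per-sample metric values.
#' @param age Per-sample ages (years).
#' @param sex Per-sample sex labels (two levels).
#' @param carrier Optional per-sample logical carrier status.
#' @param paired_diff Optional per-pair differences (A minus B) with
#'   `pair_sex` giving each pair's (matched) sex.
#' @param pair_sex Sex label per pair, for the paired-difference t-test.
#' @param kendall If `TRUE`, add the Kendall rank correlation with age.
#' @param family Family label for FDR grouping.
#' @return Comparison data frame, one row per executed test.
#' @export
covariate_checks <- function(metric, age, sex, carrier = NULL,
                             paired_diff = NULL, pair_sex = NULL,
                             kendall = FALSE, family = "covariates") {
  out <- list()
  if (stats::sd(age) > 0) {
    fit <- summary(stats::lm(metric ~ age))
    out$age_lm <- comparison_result(
      family, "age", "linear regression", fit$coefficients["age", "t value"],
      fit$coefficients["age", "Estimate"], length(metric),
      fit$coefficients["age", "Pr(>|t|)"])
  } else {
    out$age_lm <- comparison_result(family, "age", "linear regression",
                                    NA_real_, NA_real_, length(metric),
                                    NA_real_, "not-testable")
  }
  if (kendall) {
    kt <- suppressWarnings(stats::cor.test(metric, age, method = "kendall"))
    out$age_kendall <- comparison_result(
      family, "age", "Kendall rank correlation",
      unname(kt$estimate), unname(kt$estimate), length(metric), kt$p.value)
  }
  if (!is.null(paired_diff) && !is.null(pair_sex) &&
      length(unique(pair_sex)) == 2 && all(table(pair_sex) >= 2) &&
      stats::sd(paired_diff) > 0) {
    tt <- stats::t.test(paired_diff ~ factor(pair_sex))
    out$sex_t <- comparison_result(
      family, "sex", "two-sample t-test (paired differences)",
      unname(tt$statistic), diff(rev(tt$estimate)), length(paired_diff),
      tt$p.value)
  }
  if (!is.null(carrier) && length(unique(sex)) == 2) {
    tab <- table(factor(sex), factor(carrier, levels = c(FALSE, TRUE)))
    if (all(rowSums(tab) > 0)) {
      cs <- suppressWarnings(stats::chisq.test(tab))
      out$carrier_chisq <- comparison_result(
        family, "carrier x sex", "chi-square independence",
        unname(cs$statistic), NA_real_, length(carrier), cs$p.value)
      pz <- suppressWarnings(stats::prop.test(tab[, "TRUE"], rowSums(tab)))
      out$carrier_propz <- comparison_result(
        family, "carrier x sex", "two-proportion z-test",
        unname(pz$statistic), diff(rev(unname(pz$estimate))),
        length(carrier), pz$p.value)
    }
  }
  do.call(rbind, out)
}

#' Power of the matched-pair (McNemar) design by trinomial enumeration
#'
#' Each matched pair is case-only discordant with probability `p1`,
#' control-only discordant with probability `p2`, concordant otherwise. The
#' rejection rule is the one applied by [mcnemar_exact()] at level `alpha`.
#' Power is computed exactly by enumerating the distribution of the
#' discordant-pair counts: the total `m = b + c` is Binomial(n, p1 + p2) and,
#' given `m`, `b` is Binomial(m, p1 / (p1 + p2)).
#'
#' @param n_pairs Number of matched pairs.
#' @param p1 Probability a pair is discordant with only the case affected.
#' @param p2 Probability a pair is discordant with only the control affected.
#' @param alpha Two-sided significance level.
#' @param exact_max Passed to [mcnemar_exact()].
#' @return Rejection probability under the specified alternative.
#' @export
dupont_paired_power <- function(n_pairs, p1, p2, alpha = 0.05,
                                exact_max = 25) {
  if (p1 < 0 || p2 < 0 || p1 > 1 || p2 > 1 || p1 + p2 > 1)
    stop("p1, p2 must lie in [0,1] with p1 + p2 <= 1")
  stopifnot(n_pairs >= 1, n_pairs == round(n_pairs))
  pd <- p1 + p2
  if (pd == 0) return(0)
  power <- 0
  for (m in seq_len(n_pairs)) {
    pm <- stats::dbinom(m, n_pairs, pd)
    if (pm < 1e-15) next
    b <- 0:m
    rej <- vapply(b, function(bb)
      mcnemar_exact(bb, m - bb, exact_max = exact_max) < alpha, TRUE)
    power <- power + pm * sum(stats::dbinom(b[rej], m, p1 / pd))
  }
  power
}

#' Draw independent carrier statuses for matched pairs
#'
#' Shared sampling model of the effect-injection machinery and its power
#' checks: the case member carries with probability `p_case`, the control
#' member independently with probability `p_control`.
#'
#' @param n Number of pairs.
#' @param p_case,p_control Carrier probabilities.
#' @return List of logical vectors `case` and `control`.
#' @export
draw_carriers <- function(n, p_case, p_control) {
  list(case = stats::runif(n) < p_case,
       control = stats::runif(n) < p_control)
}
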