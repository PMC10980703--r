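test_that("exact McNemar equals the closed-form binomial sum", {
  expect_equal(mcnemar_exact(5, 5), 1.0)
  expect_equal(mcnemar_exact(0, 0), 1.0)
  # two-sided tail sum for b=9, c=2: 2 * sum_{k>=9} C(11,k) / 2^11
  p_oracle <- 2 * sum(choose(11, 9:11)) / 2^11
  expect_equal(mcnemar_exact(9, 2), p_oracle, tolerance = 1e-12)
  expect_equal(round(p_oracle, 4), 0.0654)
  # asymptotic branch: continuity-corrected chi-square
  b <- 20; c <- 10
  expect_equal(mcnemar_exact(b, c),
               pchisq((abs(b - c) - 1)^2 / (b + c), 1, lower.tail = FALSE))
  expect_error(mcnemar_exact(-1, 2), "non-negative")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(0.5), 0.5)
  set.seed(41)
  p <- runif(30)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("discordant prevalence counts asymmetric pairs", {
  qa <- c(rep(TRUE, 9), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 7))
  qb <- c(rep(FALSE, 9), rep(TRUE, 2), rep(TRUE, 2), rep(FALSE, 7))
  dp <- discordant_prevalence(qa, qb)
  expect_equal(dp$b, 9); expect_equal(dp$c, 2)
  expect_equal(dp$prev_a, 0.45); expect_equal(dp$prev_b, 0.10)
  expect_equal(dp$b + dp$c + dp$concordant, dp$n)
  # swapping roles swaps b and c
  sw <- discordant_prevalence(qb, qa)
  expect_equal(sw$b, dp$c); expect_equal(sw$c, dp$b)
  conc <- discordant_prevalence(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(c(conc$b, conc$c), c(0, 0))
  expect_error(discordant_prevalence(logical(0), logical(0)), "empty")
})

test_that("paired t-test matches the closed-form oracle and handles shifts", {
  ident <- paired_rate_test(1:5, 1:5)
  expect_equal(ident$p_raw, 1); expect_equal(ident$effect, 0)
  expect_equal(ident$note, "degenerate")

  set.seed(42)
  base <- rnorm(10)
  shifted <- paired_rate_test(base + 0.7, base)
  expect_equal(shifted$effect, 0.7, tolerance = 1e-12)

  for (i in 1:100) {
    n <- sample(3:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- paired_rate_test(a, b)
    d <- a - b
    t_stat <- mean(d) / (sd(d) / sqrt(n))
    p <- 2 * pt(abs(t_stat), n - 1, lower.tail = FALSE)
    expect_equal(got$statistic, t_stat, tolerance = 1e-10)
    expect_equal(got$p_raw, p, tolerance = 1e-10)
  }
})

test_that("one-sample VL-change test matches the closed form", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    d <- rnorm(n, 0, 0.05)
    got <- vl_change_test(d)
    t_stat <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(got$statistic, t_stat, tolerance = 1e-10)
    expect_equal(got$p_raw, 2 * pt(abs(t_stat), n - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("haplogroup Kruskal-Wallis matches the midrank-formula oracle", {
  kw_oracle <- function(x, g) {
    r <- rank(x)
    n <- length(x)
    groups <- split(r, g)
    h <- 12 / (n * (n + 1)) *
      sum(vapply(groups, function(ri) length(ri) *
                   (mean(ri) - (n + 1) / 2)^2, 0))
    ties <- table(x)
    h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
    pchisq(h, length(groups) - 1, lower.tail = FALSE)
  }
  set.seed(44)
  for (i in 1:100) {
    x <- sample.int(12, 40, replace = TRUE)  # heavy ties
    g <- sample(letters[1:3], 40, replace = TRUE)
    got <- haplogroup_variant_test(x, g, min_per_group = 1)
    expect_equal(got$p_raw, kw_oracle(x, g), tolerance = 1e-10)
  }
  # small groups are dropped before testing
  x <- c(1, 2, 3, 10, 11, 12, 99)
  g <- c("H", "H", "H", "J", "J", "J", "rare")
  got <- haplogroup_variant_test(x, g, min_per_group = 3)
  expect_equal(got$n, 6)
  # identical distributions give no evidence
  same <- haplogroup_variant_test(rep(1:5, 4), rep(c("H", "J"), each = 10))
  expect_gt(same$p_raw, 0.9)
})

test_that("Monte Carlo Fisher test is seeded and calibrated", {
  tab <- matrix(c(10, 10, 10, 10), 2)
  p1 <- fisher_montecarlo(tab, n_sim = 2000, seed = 9)
  p2 <- fisher_montecarlo(tab, n_sim = 2000, seed = 9)
  expect_identical(p1, p2)
  expect_gt(p1, 0.5)
  diag_tab <- matrix(c(12, 0, 0, 12), 2)
  p_mc <- fisher_montecarlo(diag_tab, n_sim = 1e5, seed = 10)
  p_exact <- fisher.test(diag_tab)$p.value
  expect_lt(abs(p_mc - p_exact), 0.005)
  expect_error(fisher_montecarlo(matrix(c(0, 0, 1, 1), 2), seed = 1),
               "zero-margin")
  expect_error(fisher_montecarlo(tab, n_sim = 10, seed = 1), "1000")
})

test_that("covariate battery behaves on constructed inputs", {
  set.seed(45)
  n <- 60
  age <- sample(20:55, n, replace = TRUE)
  sex <- rep(c("F", "M"), n / 2)
  # any monotone transform of age has Kendall tau 1 with age
  res <- covariate_checks(metric = age^2, age = age, sex = sex,
                          kendall = TRUE)
  kt <- res[res$test_name == "Kendall rank correlation", ]
  expect_equal(kt$statistic, 1)
  # identical distributions across sexes: two-proportion z near 1
  carrier <- rep(c(TRUE, TRUE, FALSE, FALSE), n / 4)
  res2 <- covariate_checks(metric = rnorm(n), age = age, sex = sex,
                           carrier = carrier)
  pz <- res2[res2$test_name == "two-proportion z-test", ]
  expect_gt(pz$p_raw, 0.9)
})

test_that("age-independent metrics give calibrated regression slopes", {
  # an age slope CI covering zero is equivalent to the regression p > 0.05
  covered <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    set.seed(5000 + r)
    n <- 200
    age <- runif(n, 19, 56)
    res <- covariate_checks(metric = rnorm(n), age = age,
                            sex = rep(c("F", "M"), n / 2))
    if (res$p_raw[res$unit == "age"] > 0.05) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.9)
})

test_that("paired-design power enumeration is valid and monotone", {
  # under the null the size cannot exceed the level (discrete test)
  expect_lte(dupont_paired_power(20, 0.3, 0.3), 0.05 + 1e-12)
  expect_gt(dupont_paired_power(20, 0.3, 0.3), 0)
  expect_equal(dupont_paired_power(20, 0, 0), 0)
  # nondecreasing in the number of pairs
  pw <- vapply(c(10, 20, 40, 80), function(n)
    dupont_paired_power(n, 0.45, 0.10), 0)
  expect_true(all(diff(pw) >= -1e-12))
})

test_that("power enumeration matches a large Monte Carlo simulation", {
  n <- 20; p1 <- 0.45; p2 <- 0.10
  enum <- dupont_paired_power(n, p1, p2)
  set.seed(46)
  reps <- 1e5
  m <- rbinom(reps, n, p1 + p2)
  b <- rbinom(reps, m, p1 / (p1 + p2))
  # precompute the rejection rule for every reachable (b, m)
  p_tab <- matrix(NA_real_, n + 1, n + 1)
  for (mm in 0:n) for (bb in 0:mm)
    p_tab[bb + 1, mm + 1] <- mcnemar_exact(bb, mm - bb)
  rej <- p_tab[cbind(b + 1, m + 1)] < 0.05
  expect_lt(abs(mean(rej) - enum), 0.01)
})
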