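make_visit <- function(pos, vl, alt = NULL) {
  n <- length(pos)
  ref <- c("A", "C", "G", "T")[(pos %% 4) + 1]
  if (is.null(alt)) alt <- ifelse(ref == "G", "A", "G")
  data.frame(pos = as.integer(pos), ref = ref, alt = alt, vl = vl,
             cov_ratio = runif(n, 0.8, 1.2), stringsAsFactors = FALSE)
}

test_that("visit matching partitions variants into trajectories", {
  v1 <- make_visit(c(100L, 200L, 300L), c(0.30, 0.10, 1.0))
  v2 <- make_visit(c(100L, 300L, 400L), c(0.35, 1.0, 0.05))
  tr <- match_visits(v1, v2, "P1")
  expect_equal(nrow(tr), 4)
  expect_equal(tr$status[tr$pos == 100], "persistent")
  expect_equal(tr$dvl[tr$pos == 100], 0.05, tolerance = 1e-12)
  expect_equal(tr$status[tr$pos == 200], "transient_v1")
  expect_equal(tr$status[tr$pos == 400], "transient_v2")
  # partition conservation per visit
  expect_equal(sum(tr$status %in% c("persistent", "transient_v1")), nrow(v1))
  expect_equal(sum(tr$status %in% c("persistent", "transient_v2")), nrow(v2))

  same <- match_visits(v1, v1)
  expect_true(all(same$status == "persistent"))
  expect_true(all(same$dvl == 0))

  dup <- rbind(v1, v1[1, ])
  expect_error(match_visits(dup, v2), "duplicate")
})

test_that("swapping visit labels negates dvl and flips transient labels", {
  set.seed(61)
  v1 <- make_visit(sample.int(16569, 8), runif(8))
  v2 <- make_visit(c(v1$pos[1:5], 9999L), c(runif(5), 0.2),
                   alt = c(v1$alt[1:5], "A"))
  fwd <- match_visits(v1, v2)
  rev <- match_visits(v2, v1)
  key <- function(d) paste(d$pos, d$alt)
  m <- match(key(fwd), key(rev))
  expect_equal(rev$dvl[m][fwd$status == "persistent"],
               -fwd$dvl[fwd$status == "persistent"])
  expect_equal(rev$status[m][fwd$status == "transient_v1"],
               rep("transient_v2", sum(fwd$status == "transient_v1")))
})

test_that("transient summary uses per-visit denominators and censors", {
  v1 <- make_visit(seq(100L, 1000L, by = 100L), rep(0.2, 10))
  v2 <- make_visit(seq(100L, 900L, by = 100L), rep(0.2, 9))
  tr <- match_visits(v1, v2)
  ts <- transient_summary(tr)
  expect_equal(ts$prop_transient_v1, 1 / 10)
  expect_equal(ts$prop_transient_v2, 0)
  expect_true(is.na(ts$mean_transient_vl_v2))

  none <- transient_summary(match_visits(v1, v1))
  expect_equal(none$prop_transient_v1, 0)
  expect_true(is.na(none$mean_transient_vl_v1))

  empty <- match_visits(v1[0, ], v1[0, ])
  expect_true(is.na(transient_summary(empty)$prop_transient_v1))
})

test_that("transient-vs-persistent contrasts detect the built-in asymmetry", {
  set.seed(62)
  v1 <- make_visit(1:40, c(rep(0.30, 20), rep(0.03, 20)))
  v2 <- make_visit(1:20, rep(0.30, 20))
  tr <- match_visits(v1, v2)
  res <- transient_vs_persistent(tr, variables = c("vl", "cov_ratio"))
  vl_row <- res[res$unit == "vl", ]
  expect_lt(vl_row$p_fdr, 0.05)
  expect_lt(vl_row$effect, 0)      # transient lower than persistent
  expect_true(all(res$p_fdr >= res$p_raw))

  # identical distributions: no family-wide signal
  tr2 <- match_visits(make_visit(1:30, rep(0.2, 30)),
                      make_visit(1:15, rep(0.2, 15)))
  res2 <- transient_vs_persistent(tr2, variables = "vl")
  expect_equal(res2$p_raw, 1)
})

test_that("subject-level metrics average visits and censor missing ones", {
  v1 <- make_visit(c(100L, 200L), c(0.2, 0.4))
  v2 <- make_visit(c(100L, 200L), c(0.3, 0.4))
  traj <- list(P1 = match_visits(v1, v2, "P1"))
  burden <- data.frame(sample_id = c("S1_V1", "S1_V2"),
                       n_variants = c(2, 4), n_deleterious = c(0, 0),
                       cumulative_deleterious_burden = c(0.1, 0.3),
                       cumulative_mitotip = c(0, 0))
  sheet <- data.frame(sample_id = c("S1_V1", "S1_V2"),
                      subject_id = "P1", role = c("V1", "V2"))
  sm <- subject_level_wgs_metrics(traj, burden, sheet)
  expect_equal(sm$n_variants, 3)
  expect_equal(sm$cumulative_deleterious_burden, 0.2)
  expect_equal(sm$mean_dvl, 0.05)
  expect_equal(sm$mean_abs_dvl, 0.05)

  # missing V2 burden row: burden metrics censored
  sm2 <- subject_level_wgs_metrics(traj, burden[1, ], sheet)
  expect_true(is.na(sm2$n_variants))
})

test_that("evolution batch tests emit one row per variable and mode", {
  set.seed(63)
  df <- data.frame(evolution = rep(c("CIS-CIS", "CIS-RRMS", "RRMS-RRMS"),
                                   each = 10),
                   a = rnorm(30), b = rnorm(30))
  res <- rbind(evolution_group_tests(df, c("a", "b"), mode = "mean"),
               evolution_group_tests(df, c("a", "b"), mode = "delta"))
  expect_equal(nrow(res), 4)
  expect_equal(sort(unique(res$unit)),
               sort(c("a (mean)", "a (delta)", "b (mean)", "b (delta)")))
  # identical values across groups give p near 1
  df$c <- rep(1:10, 3)
  same <- evolution_group_tests(df, "c")
  expect_gt(same$p_raw, 0.9)
  # an injected group shift is detected
  df$d <- rnorm(30) + ifelse(df$evolution == "RRMS-RRMS", 3, 0)
  shift <- evolution_group_tests(df, "d")
  expect_lt(shift$p_fdr, 0.01)
})

test_that("NEDA-3 requires all four components and censors missing data", {
  expect_true(neda3_classify(0, 0, FALSE, 1.5, 1.5))
  expect_false(neda3_classify(1, 0, FALSE, 1.5, 1.5))
  # EDSS worsening threshold from baseline 0 is 1.5
  expect_true(neda3_classify(0, 0, FALSE, 0.0, 1.0))
  expect_false(neda3_classify(0, 0, FALSE, 0.0, 1.5))
  expect_true(is.na(neda3_classify(0, NA, FALSE, 1.5, 1.5)))
  # monotone: worsening a single component can only flip true -> false
  base <- neda3_classify(0, 0, FALSE, 2.0, 2.0)
  expect_true(base)
  expect_false(neda3_classify(0, 1, FALSE, 2.0, 2.0))
  expect_false(neda3_classify(0, 0, TRUE, 2.0, 2.0))
  expect_false(neda3_classify(0, 0, FALSE, 2.0, 3.5))
})

test_that("EDSS worsening uses baseline-dependent thresholds", {
  expect_false(edss_worsened(0, 1.0))
  expect_true(edss_worsened(0, 1.5))
  expect_true(edss_worsened(2.0, 3.0))
  expect_false(edss_worsened(2.0, 2.5))
  expect_true(edss_worsened(6.0, 6.5))
})

test_that("annualized relapse rate uses 365.25-day years", {
  expect_equal(annualized_relapse_rate(1, 365.25), 1.0)
  expect_equal(annualized_relapse_rate(0, 900), 0.0)
  expect_equal(annualized_relapse_rate(2, 730.5), 1.0)
  expect_error(annualized_relapse_rate(1, 0), "positive")
})
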