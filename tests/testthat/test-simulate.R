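test_that("cohort simulation is deterministic and sized correctly", {
  cfg <- sim_config(n_triplets = 6, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$pcp, b$pcp)
  expect_identical(a$sample_sheet, b$sample_sheet)
  expect_identical(a$scores, b$scores)
  expect_identical(a$clinical, b$clinical)
  expect_equal(nrow(a$sample_sheet), 18)
  expect_equal(sort(unique(a$sample_sheet$role)), c("HC", "V1", "V2"))
})

test_that("extending a cohort never perturbs existing triplets", {
  small <- simulate_cohort(sim_config(n_triplets = 4, seed = 12))
  large <- simulate_cohort(sim_config(n_triplets = 7, seed = 12))
  keep <- large$pcp$sample_id %in% small$pcp$sample_id
  expect_identical(small$pcp, {
    x <- large$pcp[keep, , drop = FALSE]; rownames(x) <- NULL; x
  })
})

test_that("matching constraints and VL ranges hold", {
  co <- simulate_cohort(sim_config(n_triplets = 20, seed = 13))
  ss <- co$sample_sheet
  for (t in unique(ss$triplet)) {
    tri <- ss[ss$triplet == t, ]
    expect_equal(length(unique(tri$sex)), 1)
    expect_lte(abs(tri$age[tri$role == "HC"] - tri$age[tri$role == "V1"]), 5)
    expect_equal(tri$haplogroup[tri$role == "V1"],
                 tri$haplogroup[tri$role == "V2"])
  }
  expect_true(all(co$pcp$vl > 0 & co$pcp$vl <= 1))
  expect_true(all(co$pcp$alt != co$pcp$ref))
})

test_that("a zero transient rate makes every patient heteroplasmy persistent", {
  co <- simulate_cohort(sim_config(n_triplets = 8, seed = 14,
                                   transient_rate = 0))
  expect_false(any(co$truth$status %in% c("transient_v1", "transient_v2")))
  rep <- run_pipeline(co, pipeline_config(fisher_nsim = 1000,
                                          families = "macro_prevalence"))
  ps <- rep$longitudinal$per_subject_summary
  expect_true(all(ps$prop_transient_v1 == 0 | is.na(ps$prop_transient_v1)))
  expect_true(all(ps$prop_transient_v2 == 0 | is.na(ps$prop_transient_v2)))
})

test_that("visit tables differ only in transients and persistent drift", {
  co <- simulate_cohort(sim_config(n_triplets = 10, seed = 15))
  tr <- co$truth
  for (s in unique(tr$subject_id[grepl("^P", tr$subject_id)])) {
    rows <- tr[tr$subject_id == s, ]
    key <- paste(rows$pos, rows$alt)
    v1 <- rows$sample_id == unique(rows$sample_id)[1]
    both <- intersect(key[v1], key[!v1])
    only1 <- setdiff(key[v1], key[!v1])
    only2 <- setdiff(key[!v1], key[v1])
    expect_true(all(rows$status[key %in% only1 & v1] == "transient_v1"))
    expect_true(all(rows$status[key %in% only2 & !v1] == "transient_v2"))
    expect_true(all(rows$status[key %in% both] %in%
                      c("backbone", "persistent")))
  }
})

test_that("haplogroup backbone structure is bimodal: H/HV below J/T", {
  co <- simulate_cohort(sim_config(n_triplets = 67, seed = 16))
  acc <- consensus_filter(co$pcp, co$tss, allowlist = co$allowlist)
  counts <- table(acc$sample_id)
  hg <- co$sample_sheet$haplogroup[match(names(counts),
                                         co$sample_sheet$sample_id)]
  low <- as.numeric(counts[hg %in% c("H", "HV")])
  jt <- as.numeric(counts[hg %in% c("J", "T")])
  expect_gt(length(low), 10)
  expect_gt(length(jt), 5)
  expect_lt(wilcox.test(low, jt, alternative = "less")$p.value, 0.01)
})

test_that("effect injection hits the target prevalences and is logged", {
  co <- simulate_cohort(sim_config(n_triplets = 500, seed = 17))
  inj <- inject_effect(co, group = "V1", macro_region = "ComplexI",
                       prevalence_delta = 0.35, baseline = 0.20)
  info <- attr(inj, "injection")
  expect_lt(abs(mean(info$case_carrier) - 0.55), 0.04)
  expect_lt(abs(mean(info$control_carrier) - 0.20), 0.04)
  expect_equal(macro_of(info$pos), "ComplexI")
  # ledger rows record exactly the injected carriers' samples
  inj_rows <- inj$truth[inj$truth$status == "injected", ]
  carriers_v1 <- inj$sample_sheet$sample_id[
    inj$sample_sheet$role == "V1" &
      inj$sample_sheet$triplet %in% which(info$case_carrier)]
  expect_setequal(inj_rows$sample_id[grepl("_V1$", inj_rows$sample_id)],
                  carriers_v1)
  expect_error(inject_effect(co, prevalence_delta = 0.9, baseline = 0.2),
               "\\[0,1\\]")
})

test_that("pipeline recovers injected carriers through the qualifier", {
  cfg <- sim_config(n_triplets = 40, seed = 18,
                    effect = list(group = "V1", macro_region = "ComplexI",
                                  baseline = 0.20, prevalence_delta = 0.35))
  co <- simulate_cohort(cfg)
  info <- attr(co, "injection")
  acc <- consensus_filter(co$pcp, co$tss, allowlist = co$allowlist)
  acc <- annotate_scores(annotate_regions(acc), co$scores)
  del_ci <- acc[acc$is_deleterious & acc$macro == "ComplexI", ]
  ss <- co$sample_sheet
  v1_carriers <- unique(del_ci$sample_id[grepl("_V1$", del_ci$sample_id)])
  expect_setequal(v1_carriers,
                  ss$sample_id[ss$role == "V1" &
                                 ss$triplet %in% which(info$case_carrier)])
  hc_carriers <- unique(del_ci$sample_id[grepl("_HC$", del_ci$sample_id)])
  expect_setequal(hc_carriers,
                  ss$sample_id[ss$role == "HC" &
                                 ss$triplet %in% which(info$control_carrier)])
})

test_that("truth check reports perfect recovery in the zero-noise setting", {
  cfg <- sim_config(n_triplets = 8, seed = 19, tss_dropout_low = 0,
                    drift_sd = 0)
  co <- simulate_cohort(cfg)
  rep <- run_pipeline(co, pipeline_config(fisher_nsim = 1000,
                                          families = "macro_prevalence"))
  tc <- truth_check(rep, co)
  expect_equal(tc$trajectory_accuracy, 1)
  expect_lt(tc$max_burden_error, 1e-12)
})

test_that("cohort writing round-trips through the file parsers", {
  co <- simulate_cohort(sim_config(n_triplets = 3, seed = 20))
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(sort(unique(back$pcp$sample_id)),
               sort(unique(co$pcp$sample_id)))
  key <- function(d) sort(paste(d$sample_id, d$pos, d$alt))
  expect_equal(key(back$pcp), key(co$pcp))
  expect_equal(key(back$tss), key(co$tss))
  m <- match(paste(back$pcp$sample_id, back$pcp$pos, back$pcp$alt),
             paste(co$pcp$sample_id, co$pcp$pos, co$pcp$alt))
  expect_equal(back$pcp$vl, co$pcp$vl[m], tolerance = 1e-9)
})
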