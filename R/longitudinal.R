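# Intra-subject visit-1 to visit-2 dynamics: transient/persistent variant
# trajectories, VL drift, transient-vs-persistent contrasts, subject-level
# summaries and clinical grouping analyses.

#' Match one subject's variants across two visits
#'
#' Partitions the union of both visits' accepted variants, keyed on
#' (pos, alt), into trajectories: `persistent` (seen at both visits, with
#' `dvl = vl_v2 - vl_v1`), `transient_v1` and `transient_v2` (seen at
#' exactly one visit). Non-key columns (quality indicators, scores) are
#' carried from the visit-1 record when present, else visit-2.
#'
#' @param v1,v2 Accepted-variant data frames of the same subject, with
#'   `pos`, `ref`, `alt`, `vl`.
#' @param subject_id Optional subject identifier stamped on the output.
#' @return Data frame of trajectories with `status`, `vl_v1`, `vl_v2`, `dvl`.
#' @export
match_visits <- function(v1, v2, subject_id = NA_character_) {
  key1 <- paste(v1$pos, v1$alt)
  key2 <- paste(v2$pos, v2$alt)
  if (anyDuplicated(key1) || anyDuplicated(key2))
    stop("duplicate (pos, alt) keys within a visit")
  keys <- union(key1, key2)
  i1 <- match(keys, key1)
  i2 <- match(keys, key2)

  carry_cols <- setdiff(intersect(names(v1), names(v2)),
                        c("sample_id", "vl", "support", "in_curated_db"))
  src <- ifelse(is.na(i1), "v2", "v1")
  out <- data.frame(subject_id = subject_id, row.names = NULL,
                    stringsAsFactors = FALSE)[rep(1, length(keys)), ,
                                              drop = FALSE]
  for (col in carry_cols)
    out[[col]] <- ifelse(src == "v1", v1[[col]][i1], v2[[col]][i2])
  # restore column types clobbered by ifelse on mixed sources
  for (col in carry_cols) {
    proto <- if (col %in% names(v1)) v1[[col]] else v2[[col]]
    if (is.integer(proto)) out[[col]] <- as.integer(out[[col]])
    if (is.logical(proto)) out[[col]] <- as.logical(out[[col]])
  }
  out$vl_v1 <- v1$vl[i1]
  out$vl_v2 <- v2$vl[i2]
  out$status <- ifelse(!is.na(i1) & !is.na(i2), "persistent",
                       ifelse(!is.na(i1), "transient_v1", "transient_v2"))
  out$dvl <- ifelse(out$status == "persistent", out$vl_v2 - out$vl_v1,
                    NA_real_)
  rownames(out) <- NULL
  out
}

#' Per-visit transient-variant summary
#'
#' The transient proportion of visit v is the number of variants seen only
#' at that visit divided by the number of variants observed at that visit
#' (transient of v plus persistent); undefined (NA) when the visit has no
#' variants. The mean transient VL is taken over the visit's transient
#' variants (NA when there are none).
#'
#' @param traj Trajectory data frame from [match_visits()].
#' @return One-row data frame: counts, proportions and mean transient VLs
#'   per visit.
#' @export
transient_summary <- function(traj) {
  n_pers <- sum(traj$status == "persistent")
  n_t1 <- sum(traj$status == "transient_v1")
  n_t2 <- sum(traj$status == "transient_v2")
  n_v1 <- n_pers + n_t1
  n_v2 <- n_pers + n_t2
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  data.frame(
    n_v1 = n_v1, n_v2 = n_v2, n_persistent = n_pers,
    n_transient_v1 = n_t1, n_transient_v2 = n_t2,
    prop_transient_v1 = if (n_v1) n_t1 / n_v1 else NA_real_,
    prop_transient_v2 = if (n_v2) n_t2 / n_v2 else NA_real_,
    mean_transient_vl_v1 = mean_or_na(traj$vl_v1[traj$status == "transient_v1"]),
    mean_transient_vl_v2 = mean_or_na(traj$vl_v2[traj$status == "transient_v2"]),
    mean_dvl = mean_or_na(traj$dvl[traj$status == "persistent"])
  )
}

#' One-sample t-test of persistent-variant VL change against zero
#'
#' @param dvl Numeric vector of VL changes (visit 2 minus visit 1).
#' @param family,unit Labels for the comparison table.
#' @return One-row comparison data frame (`effect` = mean change).
#' @export
vl_change_test <- function(dvl, family = "longitudinal", unit = "dVL") {
  dvl <- dvl[!is.na(dvl)]
  n <- length(dvl)
  if (n < 2)
    return(comparison_result(family, unit, "one-sample t-test", NA_real_,
                             if (n) mean(dvl) else NA_real_, n, NA_real_,
                             "not-testable"))
  if (stats::sd(dvl) <= 1e-10 * (abs(mean(dvl)) + 1))
    return(comparison_result(family, unit, "one-sample t-test", NA_real_,
                             mean(dvl), n,
                             if (abs(mean(dvl)) < 1e-12) 1 else 0,
                             "degenerate"))
  tt <- stats::t.test(dvl, mu = 0)
  comparison_result(family, unit, "one-sample t-test", unname(tt$statistic),
                    mean(dvl), n, tt$p.value)
}

#' Transient versus persistent variant contrasts
#'
#' Two-sample t-tests of variant-level variables (VL, the four quality
#' indicators, deleterious score, MitoTIP score) between transient and
#' persistent variants, FDR-adjusted within the family. The VL of a
#' transient variant is its VL at the visit where it was seen.
#'
#' @param traj Pooled trajectory data frame (all subjects).
#' @param variables Variable columns to contrast; variables absent or
#'   all-missing in one group are censored from the family.
#' @return Comparison data frame with `p_fdr` filled.
#' @export
transient_vs_persistent <- function(traj,
                                    variables = c("vl", "cov_ratio",
                                                  "norm_cov", "numt_mean",
                                                  "edge_dist",
                                                  "deleterious_score",
                                                  "mitotip")) {
  traj$vl <- ifelse(traj$status == "persistent",
                    (traj$vl_v1 + traj$vl_v2) / 2,
                    ifelse(traj$status == "transient_v1",
                           traj$vl_v1, traj$vl_v2))
  is_trans <- traj$status != "persistent"
  out <- list()
  for (v in variables) {
    if (!v %in% names(traj)) next
    x <- traj[[v]][is_trans]
    y <- traj[[v]][!is_trans]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) next
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    if (se <= 1e-10 * (abs(mean(x) - mean(y)) + 1)) {
      d <- mean(x) - mean(y)
      out[[v]] <- comparison_result("transient_vs_persistent", v,
                                    "two-sample t-test", NA_real_, d,
                                    length(x) + length(y),
                                    if (abs(d) < 1e-12) 1 else 0,
                                    "degenerate")
      next
    }
    tt <- stats::t.test(x, y)
    out[[v]] <- comparison_result("transient_vs_persistent", v,
                                  "two-sample t-test", unname(tt$statistic),
                                  mean(x) - mean(y), length(x) + length(y),
                                  tt$p.value)
  }
  apply_fdr(do.call(rbind, out))
}

#' Subject-level summaries across both visits
#'
#' Collapses each subject to a single data point: transient proportions and
#' transient mean VLs averaged over the two visits, mean VL change and mean
#' absolute VL change of persistent variants, and burden metrics averaged
#' over the two visits. Subjects missing a visit are censored.
#'
#' @param traj_by_subject Named list of trajectory data frames, one per
#'   subject.
#' @param burden Per-sample burden table (from [burden_table()]).
#' @param sample_sheet Data frame mapping `sample_id` to `subject_id` and
#'   `role` (`"V1"`/`"V2"`).
#' @return Data frame, one row per subject with both visits available.
#' @export
subject_level_wgs_metrics <- function(traj_by_subject, burden = NULL,
                                      sample_sheet = NULL) {
  rows <- lapply(names(traj_by_subject), function(s) {
    ts <- transient_summary(traj_by_subject[[s]])
    pers <- traj_by_subject[[s]]$dvl
    pers <- pers[!is.na(pers)]
    props <- c(ts$prop_transient_v1, ts$prop_transient_v2)
    tvls <- c(ts$mean_transient_vl_v1, ts$mean_transient_vl_v2)
    out <- data.frame(
      subject_id = s,
      prop_transient = if (all(is.na(props))) NA_real_ else
        mean(props, na.rm = TRUE),
      mean_transient_vl = if (all(is.na(tvls))) NA_real_ else
        mean(tvls, na.rm = TRUE),
      mean_dvl = if (length(pers)) mean(pers) else NA_real_,
      mean_abs_dvl = if (length(pers)) mean(abs(pers)) else NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(burden) && !is.null(sample_sheet)) {
      ids <- sample_sheet$sample_id[sample_sheet$subject_id == s &
                                      sample_sheet$role %in% c("V1", "V2")]
      bi <- burden[burden$sample_id %in% ids, , drop = FALSE]
      if (nrow(bi) == 2) {
        out$n_variants <- mean(bi$n_variants)
        out$n_deleterious <- mean(bi$n_deleterious)
        out$cumulative_deleterious_burden <-
          mean(bi$cumulative_deleterious_burden)
        out$cumulative_mitotip <- mean(bi$cumulative_mitotip)
      } else {
        out$n_variants <- out$n_deleterious <- NA_real_
        out$cumulative_deleterious_burden <- out$cumulative_mitotip <- NA_real_
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Batch Kruskal-Wallis tests by diagnostic-evolution group
#'
#' For each variable, collapses the two visits per subject by `mode`
#' (`"mean"`: mean of the visits; `"delta"`: visit 2 minus visit 1; WGS
#' subject metrics are already single values and used as-is), then tests
#' across evolution groups with Kruskal-Wallis; FDR within the batch.
#' Variables leaving any group with fewer than 2 subjects are marked
#' not-testable.
#'
#' @param values Data frame, one row per subject, variable columns plus
#'   `evolution`.
#' @param variables Columns of `values` to test.
#' @param mode Label recorded on the output rows (`"mean"` or `"delta"`);
#'   collapsing is the caller's responsibility.
#' @param family Family label for FDR.
#' @return Comparison data frame with exactly one row per variable.
#' @export
evolution_group_tests <- function(values, variables, mode = "mean",
                                  family = "evolution") {
  out <- lapply(variables, function(v) {
    x <- values[[v]]
    g <- values$evolution
    ok <- !is.na(x) & !is.na(g)
    unit <- paste0(v, " (", mode, ")")
    if (length(unique(g[ok])) < 2 || any(table(g[ok]) < 2))
      return(comparison_result(family, unit, "Kruskal-Wallis", NA_real_,
                               NA_real_, sum(ok), NA_real_, "not-testable"))
    kw <- stats::kruskal.test(x[ok], factor(g[ok]))
    comparison_result(family, unit, "Kruskal-Wallis", unname(kw$statistic),
                      NA_real_, sum(ok), kw$p.value)
  })
  apply_fdr(do.call(rbind, out))
}

#' EDSS worsening relative to baseline
#'
#' Field-standard confirmed-progression thresholds: an increase of at least
#' 1.5 from baseline 0, at least 1.0 from baseline 0.5-5.5, at least 0.5
#' from baseline 6.0 or higher.
#'
#' @param edss_baseline,edss_followup EDSS scores.
#' @return Logical (NA propagates).
#' @export
edss_worsened <- function(edss_baseline, edss_followup) {
  thr <- ifelse(edss_baseline == 0, 1.5,
                ifelse(edss_baseline < 6.0, 1.0, 0.5))
  (edss_followup - edss_baseline) >= thr
}

#' NEDA-3 classification
#'
#' No evidence of disease activity: zero relapses, zero gadolinium-enhancing
#' lesions, no new or enlarging T2 hyperintense lesions, and no EDSS
#' worsening ([edss_worsened()]). Any missing component gives NA (censored),
#' never FALSE.
#'
#' @param relapses_between_visits Relapse count between the visits.
#' @param gd_lesions Gadolinium-enhancing lesion count at follow-up.
#' @param new_or_enlarging_t2 Logical: new/enlarging T2 lesions present?
#' @param edss_v1,edss_v2 EDSS at baseline and follow-up.
#' @return Logical (vectorized); NA where any component is missing.
#' @export
neda3_classify <- function(relapses_between_visits, gd_lesions,
                           new_or_enlarging_t2, edss_v1, edss_v2) {
  relapses_between_visits == 0 & gd_lesions == 0 &
    !new_or_enlarging_t2 & !edss_worsened(edss_v1, edss_v2)
}

#' Annualized relapse rate
#'
#' @param n_relapses Relapse count over the observation period.
#' @param observation_days Observation period in days (> 0).
#' @return Relapses per year (365.25-day years).
#' @export
annualized_relapse_rate <- function(n_relapses, observation_days) {
  if (any(observation_days <= 0)) stop("observation_days must be positive")
  n_relapses * 365.25 / observation_days
}
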