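# Stage orchestration: ingest -> consensus filter -> annotation -> burden ->
# cross-sectional paired statistics -> longitudinal dynamics -> report.

#' Pipeline configuration
#'
#' Assembles (or loads from YAML) the run configuration: rescue-filter
#' thresholds, statistics settings, burden scope, and analysis switches.
#'
#' @param path Optional YAML file; keys override the defaults.
#' @param filter Rescue thresholds ([rescue_rules()]).
#' @param fisher_nsim Monte Carlo Fisher simulation count.
#' @param seed Seed for the stochastic tests (Monte Carlo Fisher).
#' @param burden_scope `"all_scored"` or `"deleterious_only"`.
#' @param discordant_only Compute region-rate paired tests from
#'   pair-discordant variants only (the default reading).
#' @param per_variant Run the per-variant McNemar family.
#' @param families Cross-sectional families to run.
#' @return A named list.
#' @export
pipeline_config <- function(path = NULL,
                            filter = rescue_rules(),
                            fisher_nsim = 1e5, seed = 1,
                            burden_scope = "all_scored",
                            discordant_only = TRUE,
                            per_variant = FALSE,
                            families = c("macro_prevalence",
                                         "deleterious_prevalence",
                                         "macro_rates",
                                         "deleterious_rates",
                                         "haplogroup", "covariates")) {
  cfg <- list(filter = filter, fisher_nsim = fisher_nsim, seed = seed,
              burden_scope = burden_scope,
              discordant_only = discordant_only,
              per_variant = per_variant, families = families)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user$filter))
      cfg$filter <- utils::modifyList(cfg$filter, user$filter)
    cfg <- utils::modifyList(cfg, user[setdiff(names(user), "filter")])
  }
  cfg
}

#' Read a simulated or real cohort from disk
#'
#' Reads the directory layout written by [write_cohort()]: sample sheet,
#' clinical table, score table, allow-list, per-sample PCP TSVs and TSS
#' VCFs.
#'
#' @param dir Cohort directory.
#' @return A `mito_cohort`-shaped list (without config/truth unless
#'   present).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), comment.char = "#",
                                      stringsAsFactors = FALSE)
  must <- c("sample_sheet.tsv", "scores.tsv", "allowlist.tsv")
  for (f in must)
    if (!file.exists(file.path(dir, f))) stop("missing input file: ",
                                              file.path(dir, f))
  sheet <- rd("sample_sheet.tsv")
  pcp <- do.call(rbind, lapply(sheet$sample_id, function(s) {
    f <- file.path(dir, "pcp", paste0(s, ".tsv"))
    if (!file.exists(f)) stop("missing PCP table: ", f)
    parse_pcp_table(f)
  }))
  tss <- do.call(rbind, lapply(sheet$sample_id, function(s) {
    f <- file.path(dir, "tss", paste0(s, ".vcf"))
    if (!file.exists(f)) stop("missing TSS VCF: ", f)
    parse_tss_vcf(f, sample_id = s)
  }))
  out <- list(sample_sheet = sheet, pcp = pcp, tss = tss,
              scores = rd("scores.tsv"), allowlist = rd("allowlist.tsv"))
  if (file.exists(file.path(dir, "clinical.tsv")))
    out$clinical <- rd("clinical.tsv")
  if (file.exists(file.path(dir, "ground_truth.tsv")))
    out$truth <- rd("ground_truth.tsv")
  class(out) <- "mito_cohort"
  out
}

pair_table <- function(sample_sheet) {
  v1 <- sample_sheet[sample_sheet$role == "V1", ]
  hc <- sample_sheet[sample_sheet$role == "HC", ]
  m <- match(v1$pair_id, hc$pair_id)
  data.frame(pair_id = v1$pair_id, member_a = v1$sample_id,
             member_b = hc$sample_id[m], sex = v1$sex,
             age_a = v1$age, age_b = hc$age[m], stringsAsFactors = FALSE)
}

# per-(sample, macro) qualifier matrix from an annotated variant table
qualifier_matrix <- function(variants, sample_ids, deleterious = FALSE) {
  v <- if (deleterious) variants[variants$is_deleterious, ] else variants
  out <- matrix(FALSE, nrow = length(sample_ids), ncol = length(MACRO_LEVELS),
                dimnames = list(sample_ids, MACRO_LEVELS))
  if (nrow(v)) {
    tab <- unique(v[, c("sample_id", "macro")])
    tab <- tab[tab$sample_id %in% sample_ids, ]
    out[cbind(tab$sample_id, tab$macro)] <- TRUE
  }
  out
}

discordant_variants <- function(va, vb) {
  ka <- paste(va$pos, va$alt)
  kb <- paste(vb$pos, vb$alt)
  list(a = va[!(ka %in% kb), , drop = FALSE],
       b = vb[!(kb %in% ka), , drop = FALSE])
}

#' Cross-sectional paired analysis
#'
#' Runs the paired comparison battery between the case group (patients at
#' visit 1) and matched healthy controls on accepted, score-annotated
#' variants: per-macro-region discordant prevalence with exact McNemar
#' tests, per-macro-region adjusted mutational / deleterious rates with
#' paired t-tests (computed from pair-discordant variants when
#' `discordant_only`), haplogroup Kruskal-Wallis tests, a Monte Carlo
#' Fisher test of haplogroup against subject type, the covariate battery,
#' and optionally per-variant McNemar tests. FDR is applied within each
#' family.
#'
#' @param variants Accepted, annotated cohort variant table.
#' @param sample_sheet Sample sheet with `pair_id` and `role`.
#' @param burden Per-sample burden table (with `"rates"` attribute).
#' @param map An `mt_region_map`.
#' @param config A [pipeline_config()].
#' @return Named list of comparison data frames.
#' @export
cross_sectional_analysis <- function(variants, sample_sheet, burden,
                                     map = default_region_map(),
                                     config = pipeline_config()) {
  pairs <- pair_table(sample_sheet)
  ids <- c(pairs$member_a, pairs$member_b)
  by_sample <- split(variants, factor(variants$sample_id, levels = ids))
  res <- list()

  if (any(c("macro_prevalence", "deleterious_prevalence") %in%
          config$families)) {
    for (del in c(FALSE, TRUE)) {
      fam <- if (del) "deleterious_prevalence" else "macro_prevalence"
      if (!fam %in% config$families) next
      qm <- qualifier_matrix(variants, ids, deleterious = del)
      rows <- lapply(MACRO_LEVELS, function(m) {
        dp <- discordant_prevalence(qm[pairs$member_a, m],
                                    qm[pairs$member_b, m])
        comparison_result(fam, m, "exact McNemar",
                          NA_real_, dp$prev_a - dp$prev_b, dp$n,
                          mcnemar_exact(dp$b, dp$c),
                          sprintf("b=%d;c=%d", dp$b, dp$c))
      })
      res[[fam]] <- apply_fdr(do.call(rbind, rows))
    }
  }

  rate_funs <- list(macro_rates = adjusted_mutational_rate,
                    deleterious_rates = adjusted_deleterious_rate)
  for (fam in intersect(names(rate_funs), config$families)) {
    f <- rate_funs[[fam]]
    rows <- lapply(MACRO_LEVELS, function(m) {
      vals <- vapply(seq_len(nrow(pairs)), function(i) {
        va <- by_sample[[pairs$member_a[i]]]
        vb <- by_sample[[pairs$member_b[i]]]
        if (config$discordant_only) {
          dv <- discordant_variants(va, vb)
          va <- dv$a; vb <- dv$b
        }
        c(f(va, m, map), f(vb, m, map))
      }, c(0, 0))
      paired_rate_test(vals[1, ], vals[2, ], family = fam, unit = m)
    })
    res[[fam]] <- apply_fdr(do.call(rbind, rows))
  }

  if ("haplogroup" %in% config$families) {
    ss <- sample_sheet[sample_sheet$sample_id %in% ids, ]
    b <- burden[match(ss$sample_id, burden$sample_id), ]
    metrics <- list(n_variants = b$n_variants,
                    n_deleterious = b$n_deleterious,
                    cumulative_deleterious_burden =
                      b$cumulative_deleterious_burden,
                    cumulative_mitotip = b$cumulative_mitotip)
    rows <- lapply(names(metrics), function(nm)
      haplogroup_variant_test(metrics[[nm]], ss$haplogroup,
                              family = "haplogroup", unit = nm))
    res$haplogroup <- apply_fdr(do.call(rbind, rows))
    tab <- table(ss$haplogroup, ss$role)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    res$haplogroup_independence <- comparison_result(
      "haplogroup_independence", "haplogroup x subject type",
      "Fisher exact (Monte Carlo)", NA_real_, NA_real_, nrow(ss),
      fisher_montecarlo(tab, n_sim = config$fisher_nsim,
                        seed = config$seed))
  }

  if ("covariates" %in% config$families) {
    ss <- sample_sheet[sample_sheet$sample_id %in% ids, ]
    b <- burden[match(ss$sample_id, burden$sample_id), ]
    diffs <- burden$n_variants[match(pairs$member_a, burden$sample_id)] -
      burden$n_variants[match(pairs$member_b, burden$sample_id)]
    res$covariates <- apply_fdr(covariate_checks(
      metric = b$n_variants, age = ss$age, sex = ss$sex,
      carrier = b$n_deleterious > 0,
      paired_diff = diffs, pair_sex = pairs$sex,
      kendall = TRUE, family = "covariates"))
  }

  if (isTRUE(config$per_variant)) {
    keys <- unique(paste(variants$pos, variants$alt)[
      variants$sample_id %in% ids])
    have <- split(paste(variants$pos, variants$alt), variants$sample_id)
    rows <- lapply(keys, function(k) {
      qa <- vapply(pairs$member_a, function(s) k %in% have[[s]], TRUE)
      qb <- vapply(pairs$member_b, function(s) k %in% have[[s]], TRUE)
      dp <- discordant_prevalence(qa, qb)
      comparison_result("per_variant", k, "exact McNemar", NA_real_,
                        dp$prev_a - dp$prev_b, dp$n,
                        mcnemar_exact(dp$b, dp$c),
                        sprintf("b=%d;c=%d", dp$b, dp$c))
    })
    res$per_variant <- apply_fdr(do.call(rbind, rows))
  }
  res
}

#' Longitudinal visit-1 to visit-2 analysis
#'
#' Builds per-subject trajectories, summarises transient variants and VL
#' drift, contrasts transient against persistent variants, collapses
#' subjects to single data points, and runs the diagnostic-evolution,
#' medication-change and NEDA-3 grouping batteries.
#'
#' @param variants Accepted, annotated cohort variant table.
#' @param sample_sheet Sample sheet.
#' @param clinical Clinical table, one row per (subject, visit); optional.
#' @param burden Per-sample burden table.
#' @param config A [pipeline_config()].
#' @return Named list: trajectories, per-subject summaries and metrics,
#'   comparison tables.
#' @export
longitudinal_analysis <- function(variants, sample_sheet, clinical = NULL,
                                  burden = NULL,
                                  config = pipeline_config()) {
  v1s <- sample_sheet[sample_sheet$role == "V1", ]
  v2s <- sample_sheet[sample_sheet$role == "V2", ]
  subjects <- intersect(v1s$subject_id, v2s$subject_id)
  by_sample <- split(variants, variants$sample_id)
  empty <- variants[0, , drop = FALSE]

  traj <- lapply(subjects, function(s) {
    s1 <- v1s$sample_id[v1s$subject_id == s]
    s2 <- v2s$sample_id[v2s$subject_id == s]
    g <- function(id) if (id %in% names(by_sample)) by_sample[[id]] else empty
    match_visits(g(s1), g(s2), subject_id = s)
  })
  names(traj) <- subjects

  per_subject <- do.call(rbind, lapply(traj, transient_summary))
  per_subject <- cbind(subject_id = subjects, per_subject)
  rownames(per_subject) <- NULL
  pooled <- do.call(rbind, traj)

  out <- list(trajectories = traj, per_subject_summary = per_subject)
  out$transient_means <- c(
    prop_v1 = mean(per_subject$prop_transient_v1, na.rm = TRUE),
    prop_v2 = mean(per_subject$prop_transient_v2, na.rm = TRUE),
    vl_v1 = mean(per_subject$mean_transient_vl_v1, na.rm = TRUE),
    vl_v2 = mean(per_subject$mean_transient_vl_v2, na.rm = TRUE))
  out$vl_change <- rbind(
    vl_change_test(pooled$dvl, unit = "dVL (all variants)"),
    vl_change_test(per_subject$mean_dvl, unit = "dVL (per subject)"))
  out$transient_vs_persistent <- transient_vs_persistent(pooled)
  out$subject_metrics <- subject_level_wgs_metrics(traj, burden,
                                                   sample_sheet)

  if (!is.null(clinical)) {
    cl <- clinical[clinical$subject_id %in% subjects, ]
    wide <- merge(cl[cl$visit == "V1", ], cl[cl$visit == "V2", ],
                  by = "subject_id", suffixes = c("_v1", "_v2"))
    wide$evolution <- wide$evolution_v1
    clin_vars <- c("edss", "n_relapses", "annualized_relapse_rate", "msfc",
                   "t2_lesion_count", "t2_lesion_vol_ml", "gd_lesion_count",
                   "gd_lesion_vol_ml", "gcipl_mm3", "rnfl_um")
    clin_vars <- clin_vars[paste0(clin_vars, "_v1") %in% names(wide)]
    mean_df <- wide[, "evolution", drop = FALSE]
    delta_df <- wide[, "evolution", drop = FALSE]
    for (v in clin_vars) {
      mean_df[[v]] <- (wide[[paste0(v, "_v1")]] +
                         wide[[paste0(v, "_v2")]]) / 2
      delta_df[[v]] <- wide[[paste0(v, "_v2")]] - wide[[paste0(v, "_v1")]]
    }
    out$evolution_clinical <- rbind(
      evolution_group_tests(mean_df, clin_vars, mode = "mean",
                            family = "evolution_clinical"),
      evolution_group_tests(delta_df, clin_vars, mode = "delta",
                            family = "evolution_clinical"))

    sm <- out$subject_metrics
    sm$evolution <- wide$evolution[match(sm$subject_id, wide$subject_id)]
    wgs_vars <- intersect(c("prop_transient", "mean_transient_vl",
                            "mean_dvl", "mean_abs_dvl", "n_variants",
                            "n_deleterious", "cumulative_deleterious_burden",
                            "cumulative_mitotip"), names(sm))
    out$evolution_wgs <- evolution_group_tests(sm, wgs_vars,
                                               mode = "subject",
                                               family = "evolution_wgs")

    med_change <- wide$on_treatment_v1 != wide$on_treatment_v2
    tab <- table(factor(med_change, levels = c(FALSE, TRUE)), wide$evolution)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    out$medication_evolution <- if (all(dim(tab) >= 2)) comparison_result(
      "medication_evolution", "medication change x evolution",
      "Fisher exact (Monte Carlo)", NA_real_, NA_real_, nrow(wide),
      fisher_montecarlo(tab, n_sim = config$fisher_nsim,
                        seed = config$seed + 1)) else NULL

    hg <- sample_sheet$haplogroup[match(wide$subject_id,
                                        sample_sheet$subject_id)]
    tab <- table(hg, wide$evolution)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    out$haplogroup_evolution <- if (all(dim(tab) >= 2)) comparison_result(
      "haplogroup_evolution", "haplogroup x evolution",
      "Fisher exact (Monte Carlo)", NA_real_, NA_real_, nrow(wide),
      fisher_montecarlo(tab, n_sim = config$fisher_nsim,
                        seed = config$seed + 2)) else NULL

    if (all(c("relapses_between_visits", "gd_lesion_count",
              "new_or_enlarging_t2", "edss") %in% names(cl))) {
      v2r <- cl[cl$visit == "V2", ]
      v1r <- cl[cl$visit == "V1", ]
      m <- match(v2r$subject_id, v1r$subject_id)
      neda <- neda3_classify(v2r$relapses_between_visits,
                             v2r$gd_lesion_count,
                             v2r$new_or_enlarging_t2,
                             v1r$edss[m], v2r$edss)
      out$neda3 <- data.frame(subject_id = v2r$subject_id, neda3 = neda,
                              stringsAsFactors = FALSE)
      sm$neda3 <- out$neda3$neda3[match(sm$subject_id,
                                        out$neda3$subject_id)]
      grp <- sm[!is.na(sm$neda3), ]
      if (length(unique(grp$neda3)) == 2 && all(table(grp$neda3) >= 2)) {
        grp$evolution <- ifelse(grp$neda3, "NEDA3", "EDA")
        out$neda3_wgs <- evolution_group_tests(grp, wgs_vars,
                                               mode = "subject",
                                               family = "neda3_wgs")
      }
    }
  }
  out
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes ingest (consensus filtering per sample), score and region
#' annotation, burden computation, the cross-sectional paired battery and
#' the longitudinal battery, and returns a report object.
#'
#' @param cohort A `mito_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param map An `mt_region_map`.
#' @return A `mito_report` list.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         map = default_region_map()) {
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))

  accepted <- stage("ingest", consensus_filter(
    cohort$pcp, cohort$tss, rules = config$filter,
    allowlist = cohort$allowlist))
  dropped <- attr(accepted, "dropped")
  accepted <- stage("score", annotate_scores(
    annotate_regions(accepted, map), cohort$scores, map))
  burden <- stage("score", burden_table(accepted, map,
                                        scope = config$burden_scope))
  cross <- stage("cross-sectional", cross_sectional_analysis(
    accepted, cohort$sample_sheet, burden, map, config))
  longi <- stage("longitudinal", longitudinal_analysis(
    accepted, cohort$sample_sheet, cohort$clinical, burden, config))

  report <- list(
    accepted = accepted, dropped = dropped, burden = burden,
    rates = attr(burden, "rates"),
    cross_sectional = cross,
    longitudinal = longi[setdiff(names(longi), "trajectories")],
    trajectories = longi$trajectories,
    config = config
  )
  class(report) <- "mito_report"
  report
}

#' Write a report bundle to disk
#'
#' Versioned TSV tables plus a `summary.json`; identical inputs and
#' configuration produce byte-identical bundles.
#'
#' @param report A `mito_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$accepted, "accepted_variants.tsv")
  wt(report$burden, "burden.tsv")
  wt(report$rates, "rates.tsv")
  comp <- do.call(rbind, c(report$cross_sectional,
                           comparison_frames(report$longitudinal)))
  rownames(comp) <- NULL
  wt(comp, "comparisons.tsv")
  traj <- do.call(rbind, report$trajectories)
  rownames(traj) <- NULL
  wt(traj, "trajectories.tsv")
  wt(report$longitudinal$subject_metrics, "subject_metrics.tsv")
  summary <- list(
    schema = "mitoburden-report/1",
    n_accepted = nrow(report$accepted),
    n_dropped = nrow(report$dropped),
    n_samples = length(unique(report$accepted$sample_id)),
    transient_means = as.list(report$longitudinal$transient_means),
    config = report$config[c("fisher_nsim", "seed", "burden_scope",
                             "discordant_only")]
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.mito_report <- function(x, ...) {
  cat("mtDNA cohort analysis report\n")
  cat("  accepted variants:", nrow(x$accepted), "in",
      length(unique(x$accepted$sample_id)), "samples (",
      nrow(x$dropped), "dropped by the consensus filter)\n")
  tm <- x$longitudinal$transient_means
  if (!is.null(tm))
    cat(sprintf("  transient proportions: %.2f%% (V1) / %.2f%% (V2)\n",
                100 * tm[["prop_v1"]], 100 * tm[["prop_v2"]]))
  vc <- x$longitudinal$vl_change
  if (!is.null(vc))
    cat(sprintf("  mean VL change (persistent): %+.4f (p = %.3g)\n",
                vc$effect[1], vc$p_raw[1]))
  cat("  cross-sectional families:",
      paste(names(x$cross_sectional), collapse = ", "), "\n")
  invisible(x)
}

comparison_frames <- function(x) {
  Filter(function(d) is.data.frame(d) && "p_raw" %in% names(d), x)
}

#' @export
summary.mito_report <- function(object, ...) {
  comp <- do.call(rbind, c(object$cross_sectional,
                           comparison_frames(object$longitudinal)))
  rownames(comp) <- NULL
  comp
}
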