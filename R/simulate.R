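# Seeded synthetic triplet-cohort generator with a ground-truth ledger.
#
# Emulates the structure of a matched mtDNA cohort: European haplogroups
# with shared homoplasmic backbone variants (bimodal variant counts, H/HV
# low), private low-VL heteroplasmies, transient variants seen at one visit
# only with stochastically lower VLs, near-zero VL drift in persistent
# variants, haplogroup-linked pathogenicity-score structure (J/T deleterious-
# enriched, K/U MitoTIP-enriched), dual-caller echoes with configurable TSS
# dropout, matched clinical covariates, and optional injected group effects.

BASES <- c("A", "C", "G", "T")

ref_base <- function(pos) BASES[(pos %% 4L) + 1L]

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Per-triplet RNG substream seed, derived arithmetically from the master
# seed so that extending a cohort never perturbs existing triplets.
triplet_seed <- function(seed, t) ((seed %% 65011) * 33029 + t * 7919) %% 2147483629L + 1L

#' Simulation configuration for a synthetic triplet cohort
#'
#' Defaults mirror the study design this generator emulates: 61 triplets
#' (healthy control, patient visit 1, patient visit 2), European haplogroup
#' mix with few backbone variants in H/HV, private heteroplasmy VLs from
#' Beta(1, 12) (mostly below 10%, exercising the rescue path), a transient
#' probability of 0.3 per private heteroplasmy — which, against the backbone
#' of shared homoplasmies, gives a mean per-visit transient proportion of
#' about 4% of a sample's variants — transient VLs scaled down by 0.5,
#' persistent-variant drift sd of 0.02, 5% TSS dropout below 10% VL, and the
#' published diagnostic-evolution mix (23% / 13% / 64%).
#'
#' @param n_triplets Number of matched triplets.
#' @param seed Mandatory master seed (integer below 2^31).
#' @param haplogroup_freqs Named probability vector over haplogroups.
#' @param backbone_counts Named list: haplogroup to `c(mean, sd)` homoplasmic
#'   backbone variant count.
#' @param private_het_rate Expected private heteroplasmies per individual.
#' @param vl_beta `c(alpha, beta)` of the heteroplasmic VL distribution.
#' @param transient_rate Probability a patient heteroplasmy is transient.
#' @param transient_vl_scale Multiplier (< 1) on transient VLs.
#' @param drift_sd SD of persistent-variant VL change between visits.
#' @param min_vl Detection floor for simulated VLs.
#' @param tss_dropout_low TSS echo dropout probability for VL < 10%.
#' @param del_beta_enriched,del_beta_neutral `c(alpha, beta)` of the
#'   MutPred/APOGEE distributions for deleterious-enriched (J/T backbone)
#'   and neutral protein variants.
#' @param mitotip_enriched,mitotip_neutral,mitotip_depleted `c(mean, sd)` of
#'   MitoTIP score distributions (K/U backbone, neutral, H/HV backbone).
#' @param evolution_probs Probabilities of CIS-CIS, CIS-RRMS, RRMS-RRMS.
#' @param age_range Inclusive age range at entry, years.
#' @param p_female Probability a triplet is female.
#' @param effect Optional injected effect: list with `group`,
#'   `macro_region`, `baseline`, `prevalence_delta` (see [inject_effect()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_triplets = 61, seed,
                       haplogroup_freqs = c(H = 0.40, HV = 0.05, U = 0.13,
                                            K = 0.08, J = 0.09, T = 0.09,
                                            V = 0.05, W = 0.04, X = 0.03,
                                            I = 0.04),
                       backbone_counts = list(H = c(4, 1.5), HV = c(9, 2),
                                              V = c(14, 2), U = c(26, 3),
                                              K = c(30, 3), J = c(31, 3),
                                              T = c(30, 3), W = c(28, 3),
                                              X = c(27, 3), I = c(29, 3)),
                       private_het_rate = 3, vl_beta = c(1, 12),
                       transient_rate = 0.3, transient_vl_scale = 0.5,
                       drift_sd = 0.02, min_vl = 0.02,
                       tss_dropout_low = 0.05,
                       del_beta_enriched = c(6, 2),
                       del_beta_neutral = c(2, 6),
                       mitotip_enriched = c(11, 3),
                       mitotip_neutral = c(7, 3),
                       mitotip_depleted = c(4, 2),
                       evolution_probs = c("CIS-CIS" = 0.23,
                                           "CIS-RRMS" = 0.13,
                                           "RRMS-RRMS" = 0.64),
                       age_range = c(19, 56), p_female = 0.66,
                       effect = NULL) {
  if (missing(seed)) stop("a master seed is required")
  if (abs(sum(haplogroup_freqs) - 1) > 1e-9)
    stop("haplogroup frequencies must sum to 1")
  if (abs(sum(evolution_probs) - 1) > 1e-9)
    stop("evolution probabilities must sum to 1")
  stopifnot(n_triplets >= 1, private_het_rate >= 0, transient_rate >= 0,
            transient_rate <= 1, drift_sd >= 0, tss_dropout_low >= 0,
            all(names(haplogroup_freqs) %in% names(backbone_counts)))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Per-haplogroup backbone variant pools, drawn once from the master seed.
# Samples of one haplogroup share a pool prefix (phylogenetic nesting);
# protein-locus pool variants of J/T draw deleterious-enriched scores,
# tRNA-locus pool variants of K/U MitoTIP-enriched, H/HV depleted.
build_backbone_pools <- function(cfg, map) {
  set.seed(cfg$seed %% 2147483629L)
  pools <- list()
  for (hg in names(cfg$haplogroup_freqs)) {
    ms <- cfg$backbone_counts[[hg]]
    size <- ceiling(ms[1] + 4 * ms[2])
    pos <- sample.int(MT_GENOME_LENGTH, size)
    ref <- ref_base(pos)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
    macro <- macro_of(pos, map)
    protein <- touches_macro(data.frame(pos = pos), map, PROTEIN_MACROS)
    trna <- touches_macro(data.frame(pos = pos), map, "tRNA")
    del <- if (hg %in% c("J", "T")) cfg$del_beta_enriched else
      cfg$del_beta_neutral
    mtp <- if (hg %in% c("K", "U")) cfg$mitotip_enriched else
      if (hg %in% c("H", "HV")) cfg$mitotip_depleted else cfg$mitotip_neutral
    pools[[hg]] <- data.frame(
      pos = pos, ref = ref, alt = alt, macro = macro,
      mutpred = ifelse(protein, stats::rbeta(size, del[1], del[2]), NA_real_),
      apogee = ifelse(protein, stats::rbeta(size, del[1], del[2]), NA_real_),
      mitotip = ifelse(trna, clip(stats::rnorm(size, mtp[1], mtp[2]), 0, 21),
                       NA_real_),
      stringsAsFactors = FALSE
    )
  }
  pools
}

draw_private_scores <- function(n, pos, map, cfg) {
  protein <- touches_macro(data.frame(pos = pos), map, PROTEIN_MACROS)
  trna <- touches_macro(data.frame(pos = pos), map, "tRNA")
  nb <- cfg$del_beta_neutral
  mt <- cfg$mitotip_neutral
  data.frame(
    mutpred = ifelse(protein, stats::rbeta(n, nb[1], nb[2]), NA_real_),
    apogee = ifelse(protein, stats::rbeta(n, nb[1], nb[2]), NA_real_),
    mitotip = ifelse(trna, clip(stats::rnorm(n, mt[1], mt[2]), 0, 21),
                     NA_real_)
  )
}

# quality indicators within the rescue-passing range; transient variants get
# a lower coverage ratio (the asymmetry the generator emulates)
draw_quality <- function(n, transient = rep(FALSE, n)) {
  data.frame(
    norm_cov = stats::runif(n, 0.8, 1.5),
    cov_ratio = ifelse(transient, stats::runif(n, 0.60, 1.05),
                       stats::runif(n, 0.85, 1.30)),
    numt_mean = stats::runif(n, 0, 0.5),
    edge_dist = round(stats::runif(n, 10, 60))
  )
}

#' Simulate a matched triplet cohort
#'
#' Generates, from one master seed, the full input set of the pipeline:
#' sample sheet with haplogroups and matching covariates, per-sample PCP
#' caller records, TSS echoes with dropout, pathogenicity score tables, an
#' allow-list covering the simulated variants, a clinical table, and a
#' sample-level ground-truth ledger recording every variant's true status
#' (backbone / persistent / transient_v1 / transient_v2 / hc_het).
#'
#' @param cfg A [sim_config()].
#' @param map An `mt_region_map`.
#' @return A `mito_cohort` list.
#' @export
simulate_cohort <- function(cfg, map = default_region_map()) {
  stopifnot(inherits(cfg, "sim_config"))
  pools <- build_backbone_pools(cfg, map)
  hgs <- names(cfg$haplogroup_freqs)

  sheets <- pcps <- tsss <- truths <- clinicals <- vector("list",
                                                          cfg$n_triplets)
  for (t in seq_len(cfg$n_triplets)) {
    set.seed(triplet_seed(cfg$seed, t))
    pat_id <- sprintf("P%03d", t)
    hc_id <- sprintf("C%03d", t)
    sid <- c(HC = sprintf("T%03d_HC", t), V1 = sprintf("T%03d_V1", t),
             V2 = sprintf("T%03d_V2", t))

    hg_pat <- sample(hgs, 1, prob = cfg$haplogroup_freqs)
    hg_hc <- sample(hgs, 1, prob = cfg$haplogroup_freqs)
    sex <- if (stats::runif(1) < cfg$p_female) "F" else "M"
    age_v1 <- sample(seq(cfg$age_range[1], cfg$age_range[2]), 1)
    age_hc <- clip(age_v1 + sample(-5:5, 1), cfg$age_range[1] - 5,
                   cfg$age_range[2] + 5)

    take_backbone <- function(hg) {
      ms <- cfg$backbone_counts[[hg]]
      k <- clip(round(stats::rnorm(1, ms[1], ms[2])), 1, nrow(pools[[hg]]))
      pools[[hg]][seq_len(k), , drop = FALSE]
    }
    bb_pat <- take_backbone(hg_pat)
    bb_hc <- take_backbone(hg_hc)

    draw_private <- function(n, exclude_pos) {
      free <- setdiff(seq_len(MT_GENOME_LENGTH), exclude_pos)
      pos <- sample(free, n)
      ref <- ref_base(pos)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
      data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
    }
    rbeta_vl <- function(n) clip(stats::rbeta(n, cfg$vl_beta[1],
                                              cfg$vl_beta[2]),
                                 cfg$min_vl, 1)

    # healthy control: backbone homoplasmies + private heteroplasmies
    n_hc <- stats::rpois(1, cfg$private_het_rate)
    hc_priv <- draw_private(n_hc, bb_hc$pos)
    hc_vl <- rbeta_vl(n_hc)

    # patient: shared backbone; private heteroplasmies persistent or
    # transient (one visit only, scaled-down VL)
    n_pat <- stats::rpois(1, cfg$private_het_rate)
    pat_priv <- draw_private(n_pat, bb_pat$pos)
    is_trans <- stats::runif(n_pat) < cfg$transient_rate
    trans_visit <- ifelse(stats::runif(n_pat) < 0.5, 1L, 2L)
    vl1 <- rbeta_vl(n_pat)
    vl1[is_trans] <- clip(vl1[is_trans] * cfg$transient_vl_scale,
                          cfg$min_vl, 1)
    vl2 <- clip(vl1 + stats::rnorm(n_pat, 0, cfg$drift_sd), cfg$min_vl, 1)
    vl2[is_trans] <- vl1[is_trans]

    status <- ifelse(!is_trans, "persistent",
                     ifelse(trans_visit == 1L, "transient_v1",
                            "transient_v2"))

    build_sample <- function(sample_id, bb, priv, vls, transient_flags) {
      n <- nrow(bb) + nrow(priv)
      q <- draw_quality(n, c(rep(FALSE, nrow(bb)), transient_flags))
      data.frame(
        sample_id = sample_id,
        pos = c(bb$pos, priv$pos), ref = c(bb$ref, priv$ref),
        alt = c(bb$alt, priv$alt),
        vl = c(rep(1, nrow(bb)), vls), caller = "PCP", q,
        stringsAsFactors = FALSE
      )
    }
    at_v1 <- status != "transient_v2"
    at_v2 <- status != "transient_v1"
    pcp_hc <- build_sample(sid[["HC"]], bb_hc, hc_priv, hc_vl,
                           rep(FALSE, n_hc))
    pcp_v1 <- build_sample(sid[["V1"]], bb_pat, pat_priv[at_v1, ],
                           vl1[at_v1], is_trans[at_v1])
    pcp_v2 <- build_sample(sid[["V2"]], bb_pat, pat_priv[at_v2, ],
                           vl2[at_v2], is_trans[at_v2])
    pcp <- rbind(pcp_hc, pcp_v1, pcp_v2)

    # TSS echo with dropout for sub-10% VLs
    drop <- pcp$vl < 0.10 & stats::runif(nrow(pcp)) < cfg$tss_dropout_low
    tss <- pcp[!drop, , drop = FALSE]
    tss$caller <- "TSS"
    tss[CALLER_QC_FIELDS] <- NA_real_

    # private-variant scores (backbone scores live in the pools)
    priv_all <- rbind(hc_priv, pat_priv)
    priv_scores <- if (nrow(priv_all))
      cbind(priv_all, draw_private_scores(nrow(priv_all), priv_all$pos,
                                          map, cfg))
    else NULL

    truth <- rbind(
      data.frame(sample_id = sid[["HC"]], subject_id = hc_id,
                 pos = c(bb_hc$pos, hc_priv$pos),
                 ref = c(bb_hc$ref, hc_priv$ref),
                 alt = c(bb_hc$alt, hc_priv$alt),
                 vl = c(rep(1, nrow(bb_hc)), hc_vl),
                 status = c(rep("backbone", nrow(bb_hc)),
                            rep("hc_het", n_hc)),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sid[["V1"]], subject_id = pat_id,
                 pos = c(bb_pat$pos, pat_priv$pos[at_v1]),
                 ref = c(bb_pat$ref, pat_priv$ref[at_v1]),
                 alt = c(bb_pat$alt, pat_priv$alt[at_v1]),
                 vl = c(rep(1, nrow(bb_pat)), vl1[at_v1]),
                 status = c(rep("backbone", nrow(bb_pat)), status[at_v1]),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sid[["V2"]], subject_id = pat_id,
                 pos = c(bb_pat$pos, pat_priv$pos[at_v2]),
                 ref = c(bb_pat$ref, pat_priv$ref[at_v2]),
                 alt = c(bb_pat$alt, pat_priv$alt[at_v2]),
                 vl = c(rep(1, nrow(bb_pat)), vl2[at_v2]),
                 status = c(rep("backbone", nrow(bb_pat)), status[at_v2]),
                 stringsAsFactors = FALSE)
    )

    sheets[[t]] <- data.frame(
      sample_id = unname(sid), subject_id = c(hc_id, pat_id, pat_id),
      triplet = t, role = c("HC", "V1", "V2"), sex = sex,
      age = c(age_hc, age_v1, age_v1 + 2.5),
      haplogroup = c(hg_hc, hg_pat, hg_pat),
      pair_id = t, stringsAsFactors = FALSE
    )
    pcps[[t]] <- pcp
    tsss[[t]] <- tss
    truths[[t]] <- truth
    attr(pcps[[t]], "priv_scores") <- priv_scores

    clinicals[[t]] <- simulate_clinical(cfg, pat_id, age_v1)
  }

  pcp <- do.call(rbind, pcps)
  score_rows <- c(lapply(pools, function(p)
    p[, c("pos", "ref", "alt", "mutpred", "apogee", "mitotip")]),
    lapply(pcps, function(p) {
      ps <- attr(p, "priv_scores")
      if (is.null(ps)) NULL
      else ps[, c("pos", "ref", "alt", "mutpred", "apogee", "mitotip")]
    }))
  scores <- do.call(rbind, score_rows)
  scores <- scores[!duplicated(paste(scores$pos, scores$ref, scores$alt)), ]
  rownames(scores) <- NULL

  allow <- unique(pcp[, c("pos", "ref", "alt")])
  rownames(allow) <- NULL

  cohort <- list(
    config = cfg,
    sample_sheet = do.call(rbind, sheets),
    pcp = pcp,
    tss = do.call(rbind, tsss),
    scores = scores,
    allowlist = allow,
    clinical = do.call(rbind, clinicals),
    truth = do.call(rbind, truths)
  )
  class(cohort) <- "mito_cohort"
  if (!is.null(cfg$effect))
    cohort <- inject_effect(cohort, cfg$effect$group, cfg$effect$macro_region,
                            cfg$effect$prevalence_delta,
                            baseline = cfg$effect$baseline, map = map)
  cohort
}

# clinical covariates for one patient, drawn in the triplet's substream;
# ranges are chosen for realism only
simulate_clinical <- function(cfg, subject_id, age_v1) {
  evol <- sample(names(cfg$evolution_probs), 1, prob = cfg$evolution_probs)
  dx <- strsplit(evol, "-")[[1]]
  edss_v1 <- sample(seq(0, 3.5, by = 0.5), 1)
  edss_v2 <- clip(edss_v1 + sample(c(-0.5, 0, 0, 0, 0.5), 1), 0, 4)
  relapses_between <- stats::rpois(1, 0.45)
  obs_days <- round(stats::rnorm(1, 915, 40))
  treat_v1 <- stats::runif(1) < 0.26
  treat_v2 <- if (treat_v1) TRUE else stats::runif(1) < 0.30
  t2_v1 <- stats::rpois(1, 7)
  gd_v2 <- stats::rpois(1, 0.25)
  data.frame(
    subject_id = subject_id, visit = c("V1", "V2"),
    diagnosis = dx, evolution = evol, age = c(age_v1, age_v1 + 2.5),
    edss = c(edss_v1, edss_v2),
    n_relapses = c(stats::rpois(1, 0.25), relapses_between),
    days_to_last_relapse = round(stats::runif(2, 30, c(240, 1100))),
    annualized_relapse_rate =
      c(stats::rpois(1, 0.25) * 365.25 / 400,
        relapses_between * 365.25 / obs_days),
    msfc = round(stats::rnorm(2, c(0, 0.15), 0.4), 2),
    t2_lesion_count = c(t2_v1, t2_v1 + stats::rpois(1, 1.5)),
    t2_lesion_vol_ml = round(stats::rexp(2, 1 / 2.3), 2),
    gd_lesion_count = c(stats::rpois(1, 0.3), gd_v2),
    gd_lesion_vol_ml = round(stats::rexp(2, 40), 3),
    gcipl_mm3 = round(stats::rnorm(2, 1.97, 0.15), 2),
    rnfl_um = round(stats::rnorm(2, 97, 10), 1),
    on_treatment = c(treat_v1, treat_v2),
    new_or_enlarging_t2 = c(NA, stats::runif(1) < 0.4),
    relapses_between_visits = c(NA_integer_, relapses_between),
    stringsAsFactors = FALSE
  )
}

#' Inject a group difference in deleterious-variant prevalence
#'
#' Sets the carrier prevalence of "at least one deleterious variant in
#' `macro_region`" to `baseline + prevalence_delta` in the case group and
#' `baseline` in the control group. Existing protein scores of variants in
#' the macro region are capped at 0.5 (so pre-existing variants no longer
#' qualify), carrier statuses are drawn independently per pair member via
#' [draw_carriers()], and carriers receive one shared deleterious variant
#' (score 0.9) at a fixed position inside the region; patient carriers carry
#' it at both visits. The injection is recorded in the cohort's
#' `injection` attribute and appended to the truth ledger with status
#' `"injected"`.
#'
#' @param cohort A `mito_cohort`.
#' @param group Case group receiving the raised prevalence (`"V1"` means
#'   the patient, at both visits).
#' @param macro_region Macro region receiving the effect.
#' @param prevalence_delta Case-minus-control carrier prevalence difference.
#' @param baseline Control-group carrier prevalence.
#' @param map An `mt_region_map`.
#' @return The modified cohort.
#' @export
inject_effect <- function(cohort, group = "V1", macro_region = "ComplexI",
                          prevalence_delta, baseline = 0.20,
                          map = default_region_map()) {
  p_case <- baseline + prevalence_delta
  if (baseline < 0 || baseline > 1 || p_case < 0 || p_case > 1)
    stop("prevalences must stay inside [0,1]")

  set.seed((triplet_seed(cohort$config$seed, 0L) + 104729L) %% 2147483629L)

  # neutralise pre-existing deleterious content in the target region
  sc_macro <- macro_of(cohort$scores$pos, map)
  hit <- sc_macro == macro_region
  cohort$scores$mutpred[hit] <- pmin(cohort$scores$mutpred[hit], 0.5)
  cohort$scores$apogee[hit] <- pmin(cohort$scores$apogee[hit], 0.5)

  region_pos <- which(map$macro_at == macro_region)
  free <- setdiff(region_pos, unique(cohort$pcp$pos))
  pos <- if (length(free)) sample(free, 1) else sample(region_pos, 1)
  ref <- ref_base(pos)
  alt <- sample(setdiff(BASES, ref), 1)

  n <- max(cohort$sample_sheet$triplet)
  carriers <- draw_carriers(n, p_case, baseline)
  case_ids <- if (group == "HC") "HC" else c("V1", "V2")
  ctrl_ids <- if (group == "HC") c("V1", "V2") else "HC"

  add_rows <- function(triplets, roles) {
    sel <- cohort$sample_sheet$triplet %in% triplets &
      cohort$sample_sheet$role %in% roles
    ss <- cohort$sample_sheet[sel, , drop = FALSE]
    if (!nrow(ss)) return(NULL)
    vl <- stats::runif(nrow(ss), 0.15, 0.6)
    cbind(data.frame(sample_id = ss$sample_id, pos = pos, ref = ref,
                     alt = alt, vl = vl, caller = "PCP",
                     stringsAsFactors = FALSE),
          draw_quality(nrow(ss)))
  }
  new_pcp <- rbind(add_rows(which(carriers$case), case_ids),
                   add_rows(which(carriers$control), ctrl_ids))
  if (!is.null(new_pcp)) {
    cohort$pcp <- rbind(cohort$pcp, new_pcp)
    new_tss <- new_pcp
    new_tss$caller <- "TSS"
    new_tss[CALLER_QC_FIELDS] <- NA_real_
    cohort$tss <- rbind(cohort$tss, new_tss)
    subj <- cohort$sample_sheet$subject_id[
      match(new_pcp$sample_id, cohort$sample_sheet$sample_id)]
    cohort$truth <- rbind(cohort$truth, data.frame(
      sample_id = new_pcp$sample_id, subject_id = subj, pos = pos,
      ref = ref, alt = alt, vl = new_pcp$vl, status = "injected",
      stringsAsFactors = FALSE))
  }
  cohort$scores <- rbind(cohort$scores,
                         data.frame(pos = pos, ref = ref, alt = alt,
                                    mutpred = 0.9, apogee = 0.9,
                                    mitotip = NA_real_))
  cohort$allowlist <- unique(rbind(cohort$allowlist,
                                   data.frame(pos = pos, ref = ref,
                                              alt = alt)))
  attr(cohort, "injection") <- list(
    group = group, macro_region = macro_region, baseline = baseline,
    prevalence_delta = prevalence_delta, pos = pos, ref = ref, alt = alt,
    case_carrier = carriers$case, control_carrier = carriers$control)
  cohort
}

#' Check pipeline outputs against the ground-truth ledger
#'
#' Reports trajectory-status classification accuracy (backbone variants
#' count as persistent), the largest absolute cumulative-deleterious-burden
#' reconstruction error, and, when an effect was injected, the McNemar
#' detection outcome for the injected qualifier.
#'
#' @param report A `mito_report` from [run_pipeline()].
#' @param cohort The `mito_cohort` the report was computed from.
#' @return List with `trajectory_accuracy`, `max_burden_error` and
#'   optionally `injection_p`.
#' @export
truth_check <- function(report, cohort) {
  truth <- cohort$truth
  ss <- cohort$sample_sheet
  if (!all(unique(truth$sample_id) %in% ss$sample_id))
    stop("truth ledger and sample sheet disagree on sample ids")

  # expected trajectory status per patient (pos, alt): backbone and
  # injected persist across visits
  pat <- truth[truth$sample_id %in% ss$sample_id[ss$role %in% c("V1", "V2")], ]
  exp_status <- unique(data.frame(
    subject_id = pat$subject_id, pos = pat$pos, alt = pat$alt,
    status = ifelse(pat$status %in% c("backbone", "injected"),
                    "persistent", pat$status),
    stringsAsFactors = FALSE))
  obs <- do.call(rbind, lapply(names(report$trajectories), function(s) {
    tr <- report$trajectories[[s]]
    if (!nrow(tr)) return(NULL)
    data.frame(subject_id = s, pos = tr$pos, alt = tr$alt,
               status = tr$status, stringsAsFactors = FALSE)
  }))
  key <- function(d) paste(d$subject_id, d$pos, d$alt)
  m <- match(key(exp_status), key(obs))
  correct <- !is.na(m) & obs$status[m] == exp_status$status
  accuracy <- mean(correct)

  # burden reconstruction from the ledger
  sc <- cohort$scores
  sc$dscore <- ifelse(!is.na(sc$mutpred) & !is.na(sc$apogee),
                      (sc$mutpred + sc$apogee) / 2, NA_real_)
  truth$dscore <- sc$dscore[match(paste(truth$pos, truth$ref, truth$alt),
                                  paste(sc$pos, sc$ref, sc$alt))]
  tb <- tapply(ifelse(is.na(truth$dscore), 0, truth$vl * truth$dscore),
               truth$sample_id, sum)
  got <- report$burden$cumulative_deleterious_burden[
    match(names(tb), report$burden$sample_id)]
  max_err <- max(abs(got - as.numeric(tb)), na.rm = TRUE)

  out <- list(trajectory_accuracy = accuracy, max_burden_error = max_err)
  inj <- attr(cohort, "injection")
  if (!is.null(inj)) {
    dp <- discordant_prevalence(inj$case_carrier, inj$control_carrier)
    out$injection_p <- mcnemar_exact(dp$b, dp$c)
    out$injection_prevalence <- c(case = mean(inj$case_carrier),
                                  control = mean(inj$control_carrier))
  }
  out
}

#' Write a simulated cohort to disk in the pipeline's input dialects
#'
#' Writes `sample_sheet.tsv`, `clinical.tsv`, `scores.tsv`,
#' `allowlist.tsv`, `ground_truth.tsv`, one mutserve-style PCP TSV per
#' sample under `pcp/`, and one TSS VCF per sample under `tss/`.
#'
#' @param cohort A `mito_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "pcp"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tss"), recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$sample_sheet, "sample_sheet.tsv")
  wt(cohort$clinical, "clinical.tsv")
  wt(cohort$scores, "scores.tsv")
  wt(cohort$allowlist, "allowlist.tsv")
  wt(cohort$truth, "ground_truth.tsv")
  for (s in unique(cohort$sample_sheet$sample_id)) {
    p <- cohort$pcp[cohort$pcp$sample_id == s, , drop = FALSE]
    utils::write.table(p, file.path(dir, "pcp", paste0(s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_tss_vcf(cohort$tss[cohort$tss$sample_id == s, , drop = FALSE],
                  file.path(dir, "tss", paste0(s, ".vcf")), s)
  }
  invisible(dir)
}

write_tss_vcf <- function(tss, path, sample_id) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrM,length=16569>",
           paste0("##INFO=<ID=AF,Number=A,Type=Float,",
                  "Description=\"Allele frequency\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  tss <- tss[order(tss$pos, tss$alt), , drop = FALSE]
  body <- if (nrow(tss)) paste("chrM", tss$pos, ".", tss$ref, tss$alt, ".",
                               "PASS", sprintf("AF=%.6f", tss$vl), "GT",
                               "0/1", sep = "\t") else character()
  writeLines(c(hdr, body), path)
}

#' @export
print.mito_cohort <- function(x, ...) {
  cat("synthetic mtDNA triplet cohort:",
      max(x$sample_sheet$triplet), "triplets,",
      nrow(x$sample_sheet), "samples,",
      nrow(x$pcp), "PCP records,", nrow(x$scores), "scored variants\n")
  if (!is.null(attr(x, "injection"))) {
    inj <- attr(x, "injection")
    cat("injected effect:", inj$macro_region, "delta",
        inj$prevalence_delta, "on group", inj$group, "\n")
  }
  invisible(x)
}
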