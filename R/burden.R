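# Pathogenicity annotation and the per-sample / per-region summary scores:
# cumulative deleterious burden, cumulative MitoTIP score, and the
# region-size-adjusted mutational / deleterious / MitoTIP rates.

PROTEIN_MACROS <- c("ComplexI", "ComplexIII", "ComplexIV", "ComplexV")

# does any locus at the variant's position belong to a protein gene / tRNA?
touches_macro <- function(variants, map, macros) {
  if (!nrow(variants)) return(logical(0))
  vapply(variants$pos, function(p) {
    loci <- map$loci_at[[as.integer(p)]]
    any(map$regions$macro[match(loci, map$regions$locus)] %in% macros)
  }, TRUE)
}

#' Attach pathogenicity scores to a variant table
#'
#' Joins MutPred/APOGEE scores (protein-locus variants) and MitoTIP scores
#' (tRNA-locus variants) by (pos, ref, alt). The deleterious score is the
#' mean of MutPred and APOGEE when both are present; a variant is flagged
#' deleterious when that mean is strictly greater than 0.5. Variants missing
#' either protein score get no deleterious score (never imputed); variants
#' outside protein/tRNA loci get no scores.
#'
#' @param variants Variant data frame with `pos`, `ref`, `alt` (region
#'   annotation is added if absent).
#' @param scores Data frame keyed by `pos`, `ref`, `alt` with any of
#'   `mutpred`, `apogee`, `mitotip`.
#' @param map An `mt_region_map`.
#' @return The variants with `mutpred`, `apogee`, `mitotip`,
#'   `deleterious_score` and `is_deleterious` columns.
#' @export
annotate_scores <- function(variants, scores, map = default_region_map()) {
  if (!"macro" %in% names(variants))
    variants <- annotate_regions(variants, map)
  for (col in c("mutpred", "apogee", "mitotip"))
    if (!col %in% names(scores)) scores[[col]] <- NA_real_
  rng <- c(scores$mutpred, scores$apogee)
  if (any(!is.na(rng) & (rng < 0 | rng > 1)))
    stop("MutPred/APOGEE scores must lie in [0,1]")

  idx <- match(paste(variants$pos, variants$ref, variants$alt),
               paste(scores$pos, scores$ref, scores$alt))
  is_protein <- touches_macro(variants, map, PROTEIN_MACROS)
  is_trna <- touches_macro(variants, map, "tRNA")

  variants$mutpred <- ifelse(is_protein, scores$mutpred[idx], NA_real_)
  variants$apogee <- ifelse(is_protein, scores$apogee[idx], NA_real_)
  variants$mitotip <- ifelse(is_trna, scores$mitotip[idx], NA_real_)
  variants$deleterious_score <-
    ifelse(!is.na(variants$mutpred) & !is.na(variants$apogee),
           (variants$mutpred + variants$apogee) / 2, NA_real_)
  variants$is_deleterious <- !is.na(variants$deleterious_score) &
    variants$deleterious_score > 0.5
  variants
}

#' Cumulative deleterious burden of one sample
#'
#' The sum over scored protein variants of VL times deleterious score
#' (dimensionless, VL-weighted). `scope = "deleterious_only"` restricts the
#' sum to variants flagged deleterious (score > 0.5).
#'
#' @param variants Score-annotated variant table of one sample.
#' @param scope `"all_scored"` (default) or `"deleterious_only"`.
#' @return Non-negative number; 0 for an empty or unscored set.
#' @export
cumulative_deleterious_burden <- function(variants,
                                          scope = c("all_scored",
                                                    "deleterious_only")) {
  scope <- match.arg(scope)
  if (!nrow(variants)) return(0)
  use <- !is.na(variants$deleterious_score)
  if (scope == "deleterious_only") use <- use & variants$is_deleterious
  sum(variants$vl[use] * variants$deleterious_score[use])
}

#' Cumulative MitoTIP score of one sample
#'
#' Sum over tRNA-locus variants of VL times raw MitoTIP score.
#'
#' @param variants Score-annotated variant table of one sample.
#' @return Non-negative number; 0 when no tRNA variant is scored.
#' @export
cumulative_mitotip <- function(variants) {
  if (!nrow(variants)) return(0)
  use <- !is.na(variants$mitotip)
  sum(variants$vl[use] * variants$mitotip[use])
}

#' Flag pathogenic tRNA variants by MitoTIP score
#'
#' Raw MitoTIP scores above the "likely pathogenic" quartile boundary
#' (12.66) are flagged.
#'
#' @param mitotip Numeric vector of raw MitoTIP scores (NA allowed).
#' @param threshold Pathogenicity threshold on the raw score.
#' @return Logical vector (NA scores give FALSE).
#' @export
flag_pathogenic_trna <- function(mitotip, threshold = 12.66) {
  !is.na(mitotip) & mitotip > threshold
}

region_mask <- function(variants, region, map) {
  if (region %in% MACRO_LEVELS) {
    variants$macro == region
  } else if (region %in% map$regions$locus) {
    # overlap positions carry macro "Other" and never count toward a locus
    variants$macro != "Other" &
      vapply(variants$pos, function(p)
        region %in% map$loci_at[[as.integer(p)]], TRUE)
  } else stop("unknown region: ", region)
}

adjusted_rate <- function(variants, region, map, weight) {
  if (!"macro" %in% names(variants))
    variants <- annotate_regions(variants, map)
  size <- region_size(region, map)
  if (!nrow(variants)) return(0)
  m <- region_mask(variants, region, map)
  sum(weight[m], na.rm = TRUE) / size
}

#' Region-size-adjusted mutational rate
#'
#' Sum of VLs of the variants located in a region divided by the region size
#' in bp. Variants at multi-locus overlap positions count toward the macro
#' region `"Other"` only.
#'
#' @param variants Variant table of one sample (annotated or not).
#' @param region Locus or macro-region name.
#' @param map An `mt_region_map`.
#' @return Per-bp rate (non-negative).
#' @export
adjusted_mutational_rate <- function(variants, region,
                                     map = default_region_map()) {
  adjusted_rate(variants, region, map, variants$vl)
}

#' Region-size-adjusted cumulative deleterious rate
#'
#' As [adjusted_mutational_rate()] with VL times deleterious score in the
#' numerator (unscored variants contribute 0).
#'
#' @inheritParams adjusted_mutational_rate
#' @return Per-bp rate (non-negative).
#' @export
adjusted_deleterious_rate <- function(variants, region,
                                      map = default_region_map()) {
  adjusted_rate(variants, region, map,
                variants$vl * variants$deleterious_score)
}

#' Region-size-adjusted cumulative MitoTIP rate
#'
#' As [adjusted_mutational_rate()] with VL times MitoTIP score in the
#' numerator.
#'
#' @inheritParams adjusted_mutational_rate
#' @return Per-bp rate (non-negative).
#' @export
adjusted_mitotip_rate <- function(variants, region,
                                  map = default_region_map()) {
  adjusted_rate(variants, region, map, variants$vl * variants$mitotip)
}

#' Per-sample burden summary table
#'
#' One row per sample: variant count, deleterious count, cumulative
#' deleterious burden and cumulative MitoTIP score; optionally the adjusted
#' rates per macro region in long format as attribute `"rates"`.
#'
#' @param variants Score-annotated cohort variant table with `sample_id`.
#' @param map An `mt_region_map`.
#' @param scope Burden scope, see [cumulative_deleterious_burden()].
#' @param macro_rates If `TRUE`, compute per-(sample, macro) adjusted rates.
#' @return Data frame, one row per sample.
#' @export
burden_table <- function(variants, map = default_region_map(),
                         scope = "all_scored", macro_rates = TRUE) {
  stopifnot("sample_id" %in% names(variants))
  by_sample <- split(variants, variants$sample_id)
  out <- do.call(rbind, lapply(names(by_sample), function(s) {
    v <- by_sample[[s]]
    data.frame(
      sample_id = s,
      n_variants = nrow(v),
      n_deleterious = sum(v$is_deleterious),
      cumulative_deleterious_burden =
        cumulative_deleterious_burden(v, scope = scope),
      cumulative_mitotip = cumulative_mitotip(v),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  if (macro_rates) {
    grid <- expand.grid(sample_id = names(by_sample), region = MACRO_LEVELS,
                        stringsAsFactors = FALSE)
    grid$mutational_rate <- mapply(function(s, r)
      adjusted_mutational_rate(by_sample[[s]], r, map),
      grid$sample_id, grid$region)
    grid$deleterious_rate <- mapply(function(s, r)
      adjusted_deleterious_rate(by_sample[[s]], r, map),
      grid$sample_id, grid$region)
    grid$mitotip_rate <- mapply(function(s, r)
      adjusted_mitotip_rate(by_sample[[s]], r, map),
      grid$sample_id, grid$region)
    attr(out, "rates") <- grid
  }
  out
}
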