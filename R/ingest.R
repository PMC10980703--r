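# Parsing of the two callers' per-sample outputs and the consensus filter.
#
# Caller records carry the four variant-reliability indicators used by the
# low-VL rescue path: normalized coverage, strand/amplicon coverage ratio,
# mean reported NUMT count, and distance to the amplicon edge.

CALLER_QC_FIELDS <- c("norm_cov", "cov_ratio", "numt_mean", "edge_dist")

MT_CONTIGS <- c("chrM", "MT", "chrMT", "M", "NC_012920.1", "rCRS")

#' Parse a mutserve-style tab-separated variant table
#'
#' Expects a header with at least `sample_id`, `pos`, `ref`, `alt` and a
#' variant-level column: `vl` (fraction in \[0,1\]) or `vl_pct` (percent,
#' possibly with a trailing `%`). Percent values are normalized to fractions.
#' Optional quality-indicator columns (`norm_cov`, `cov_ratio`, `numt_mean`,
#' `edge_dist`) are carried through; absent ones become `NA`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of caller records with `caller = "PCP"`.
#' @export
parse_pcp_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "pos", "ref", "alt")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("PCP table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  has_frac <- "vl" %in% names(tab)
  has_pct <- "vl_pct" %in% names(tab)
  if (!has_frac && !has_pct)
    stop("PCP table ", path, " has neither a 'vl' nor a 'vl_pct' column")

  if (nrow(tab) == 0L) return(empty_caller_records("PCP"))

  raw <- if (has_frac) tab$vl else sub("%$", "", tab$vl_pct)
  vl <- suppressWarnings(as.numeric(raw))
  if (has_pct) vl <- vl / 100
  pos <- suppressWarnings(as.integer(tab$pos))

  bad <- which(is.na(vl) | vl < 0 | vl > 1 |
                 is.na(pos) | pos < 1L | pos > MT_GENOME_LENGTH)
  if (length(bad))
    stop("PCP table ", path, ": malformed VL or position in data row(s) ",
         paste(bad, collapse = ", "))
  if (any(tab$alt == tab$ref))
    stop("PCP table ", path, ": alt equals ref in data row(s) ",
         paste(which(tab$alt == tab$ref), collapse = ", "))

  num_or_na <- function(col)
    if (col %in% names(tab)) suppressWarnings(as.numeric(tab[[col]]))
    else rep(NA_real_, nrow(tab))

  data.frame(
    sample_id = tab$sample_id, pos = pos, ref = tab$ref, alt = tab$alt,
    vl = vl, caller = "PCP",
    norm_cov = num_or_na("norm_cov"), cov_ratio = num_or_na("cov_ratio"),
    numt_mean = num_or_na("numt_mean"), edge_dist = num_or_na("edge_dist"),
    stringsAsFactors = FALSE
  )
}

empty_caller_records <- function(caller) {
  data.frame(sample_id = character(), pos = integer(), ref = character(),
             alt = character(), vl = numeric(), caller = character(),
             norm_cov = numeric(), cov_ratio = numeric(),
             numt_mean = numeric(), edge_dist = numeric(),
             stringsAsFactors = FALSE)
}

#' Parse a TSS VCF into caller records
#'
#' Reads a VCF 4.x file, splits multiallelic records, and maps the INFO `AF`
#' field to the variant level. The contig must be mitochondrial.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param sample_id Sample identifier to stamp on the records; defaults to
#'   the VCF's single genotype column name, or the file stem.
#' @return Data frame of caller records with `caller = "TSS"`.
#' @export
parse_tss_vcf <- function(path, sample_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcf@fix
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                     dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_caller_records("TSS"))
  if (!all(fix$CHROM %in% MT_CONTIGS))
    stop("VCF ", path, " has non-mitochondrial contig(s): ",
         paste(setdiff(unique(fix$CHROM), MT_CONTIGS), collapse = ", "))
  if (is.null(sample_id)) {
    gt_samples <- colnames(vcf@gt)
    sample_id <- if (!is.null(gt_samples) && length(gt_samples) > 1L)
      gt_samples[2L] else sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  af <- vcfR::extract.info(vcf, element = "AF")

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  afs <- strsplit(ifelse(is.na(af), "", af), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- data.frame(
    sample_id = sample_id,
    pos = rep(as.integer(fix$POS), n_alt),
    ref = rep(fix$REF, n_alt),
    alt = unlist(alts),
    vl = suppressWarnings(as.numeric(unlist(lapply(seq_along(alts), function(i) {
      a <- afs[[i]]
      if (length(a) == n_alt[i]) a else rep(NA_character_, n_alt[i])
    })))),
    caller = "TSS",
    norm_cov = NA_real_, cov_ratio = NA_real_,
    numt_mean = NA_real_, edge_dist = NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(!is.na(rec$vl) & (rec$vl < 0 | rec$vl > 1)))
    stop("VCF ", path, ": AF outside [0,1]")
  rec
}

#' Rescue thresholds for low-VL PCP-only variants
#'
#' Thresholds on the four variant-reliability indicators that a PCP-only
#' variant below the 10% TSS limit of detection must pass (in addition to
#' allow-list membership) to be accepted. Defaults are package choices;
#' the indicators themselves come from the upstream read-level pipeline.
#'
#' @param norm_cov_min Minimum normalized coverage.
#' @param cov_ratio_min,cov_ratio_max Accepted coverage-ratio band.
#' @param numt_mean_max Maximum mean reported NUMT count.
#' @param edge_dist_min Minimum distance to the amplicon edge, bp.
#' @param vl_consensus_min VL at and above which dual-caller support is
#'   mandatory (the TSS limit of detection).
#' @return A named list of thresholds.
#' @export
rescue_rules <- function(norm_cov_min = 0.5, cov_ratio_min = 0.5,
                         cov_ratio_max = 2.0, numt_mean_max = 1.0,
                         edge_dist_min = 5, vl_consensus_min = 0.10) {
  list(norm_cov_min = norm_cov_min, cov_ratio_min = cov_ratio_min,
       cov_ratio_max = cov_ratio_max, numt_mean_max = numt_mean_max,
       edge_dist_min = edge_dist_min, vl_consensus_min = vl_consensus_min)
}

#' Read a curated variant allow-list
#' @param path TSV with `pos` and `alt` columns (`ref`/`note` optional).
#'   Defaults to the bundled example list.
#' @return Data frame with at least `pos` and `alt`.
#' @export
read_allowlist <- function(path = system.file("extdata",
                                              "curated_allowlist.tsv",
                                              package = "mitoburden")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("pos", "alt") %in% names(tab)))
  tab
}

variant_key <- function(df) paste(df$sample_id, df$pos, df$alt, sep = ":")

#' Dual-caller consensus filter
#'
#' Applies the acceptance rules to one or more samples' caller records,
#' keyed per sample on (pos, alt):
#' * a PCP variant with VL at or above the consensus threshold (10%) is kept
#'   iff a TSS record matches;
#' * a PCP variant below the threshold with a TSS match is kept;
#' * a PCP variant below the threshold without a TSS match is kept iff it
#'   passes all four quality-indicator thresholds AND is on the curated
#'   allow-list (`support = "pcp_only_rescued"`);
#' * TSS-only variants are never emitted. The output is a subset of the PCP
#'   input; VL and quality fields come from the PCP record.
#'
#' @param pcp,tss Caller record data frames (see [parse_pcp_table()],
#'   [parse_tss_vcf()]).
#' @param rules Thresholds from [rescue_rules()].
#' @param allowlist Data frame with `pos`, `alt` (see [read_allowlist()]).
#' @return The kept PCP records with `support` and `in_curated_db` columns;
#'   attribute `dropped` holds the rejected PCP records with a `reason`.
#' @export
consensus_filter <- function(pcp, tss, rules = rescue_rules(),
                             allowlist = read_allowlist()) {
  if (nrow(pcp) == 0L) {
    out <- cbind(pcp, support = character(0), in_curated_db = logical(0))
    attr(out, "dropped") <- cbind(pcp, reason = character(0))
    return(out)
  }
  has_tss <- variant_key(pcp) %in% variant_key(tss)
  in_db <- paste(pcp$pos, pcp$alt) %in% paste(allowlist$pos, allowlist$alt)
  qc_ok <- !is.na(pcp$norm_cov) & pcp$norm_cov >= rules$norm_cov_min &
    !is.na(pcp$cov_ratio) & pcp$cov_ratio >= rules$cov_ratio_min &
    pcp$cov_ratio <= rules$cov_ratio_max &
    !is.na(pcp$numt_mean) & pcp$numt_mean <= rules$numt_mean_max &
    !is.na(pcp$edge_dist) & pcp$edge_dist >= rules$edge_dist_min
  low <- pcp$vl < rules$vl_consensus_min
  keep <- has_tss | (low & qc_ok & in_db)

  out <- pcp[keep, , drop = FALSE]
  out$support <- ifelse(has_tss[keep], "both", "pcp_only_rescued")
  out$in_curated_db <- in_db[keep]
  rownames(out) <- NULL

  dropped <- pcp[!keep, , drop = FALSE]
  dropped$reason <- ifelse(!low[!keep], "no_tss_support",
                           ifelse(!qc_ok[!keep], "failed_quality_indicators",
                                  "not_in_curated_db"))
  rownames(dropped) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Sample-level sequencing QC
#'
#' A sample passes iff coverage uniformity is at least 85% and mean coverage
#' at least 1500 reads/bp; failing samples are flagged for resequencing.
#'
#' @param mean_coverage Mean coverage, reads/bp (vectorized).
#' @param coverage_uniformity Fraction of well-covered positions in \[0,1\].
#' @param sample_id Optional sample identifiers.
#' @return Data frame with `qc_pass` and an `action` column
#'   (`"ok"`/`"resequence"`).
#' @export
sample_qc <- function(mean_coverage, coverage_uniformity, sample_id = NULL) {
  stopifnot(all(mean_coverage >= 0), all(coverage_uniformity >= 0))
  pass <- coverage_uniformity >= 0.85 & mean_coverage >= 1500
  data.frame(
    sample_id = if (is.null(sample_id)) seq_along(mean_coverage) else sample_id,
    mean_coverage = mean_coverage,
    coverage_uniformity = coverage_uniformity,
    qc_pass = pass,
    action = ifelse(pass, "ok", "resequence"),
    stringsAsFactors = FALSE
  )
}
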