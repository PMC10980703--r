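# Shared fixture builders; all fixtures are generated in code.

make_caller_records <- function(sample_id = "S1", pos, alt = NULL,
                                vl, caller = "PCP",
                                norm_cov = 1, cov_ratio = 1,
                                numt_mean = 0, edge_dist = 20) {
  n <- length(pos)
  ref <- c("A", "C", "G", "T")[(pos %% 4) + 1]
  if (is.null(alt)) alt <- ifelse(ref == "G", "A", "G")
  data.frame(sample_id = sample_id, pos = as.integer(pos), ref = ref,
             alt = alt, vl = vl, caller = caller,
             norm_cov = rep_len(norm_cov, n),
             cov_ratio = rep_len(cov_ratio, n),
             numt_mean = rep_len(numt_mean, n),
             edge_dist = rep_len(edge_dist, n),
             stringsAsFactors = FALSE)
}

# variant table already carrying scores, for burden arithmetic tests
make_scored_variants <- function(pos, vl, deleterious_score = NA,
                                 mitotip = NA, sample_id = "S1") {
  n <- length(pos)
  ds <- rep_len(deleterious_score, n)
  data.frame(sample_id = sample_id, pos = as.integer(pos),
             ref = "A", alt = "G", vl = vl,
             deleterious_score = ds,
             is_deleterious = !is.na(ds) & ds > 0.5,
             mitotip = rep_len(mitotip, n),
             stringsAsFactors = FALSE)
}

write_pcp_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrM,length=16569>",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

# independent rule-by-rule consensus oracle: one explicit decision per
# variant, no set operations shared with the implementation
consensus_oracle <- function(pcp, tss, rules, allow_keys) {
  keep <- logical(nrow(pcp))
  for (i in seq_len(nrow(pcp))) {
    matched <- FALSE
    for (j in seq_len(nrow(tss))) {
      if (tss$sample_id[j] == pcp$sample_id[i] &&
          tss$pos[j] == pcp$pos[i] && tss$alt[j] == pcp$alt[i])
        matched <- TRUE
    }
    if (matched) { keep[i] <- TRUE; next }
    if (pcp$vl[i] >= rules$vl_consensus_min) { keep[i] <- FALSE; next }
    qc <- !is.na(pcp$norm_cov[i]) && pcp$norm_cov[i] >= rules$norm_cov_min &&
      !is.na(pcp$cov_ratio[i]) && pcp$cov_ratio[i] >= rules$cov_ratio_min &&
      pcp$cov_ratio[i] <= rules$cov_ratio_max &&
      !is.na(pcp$numt_mean[i]) && pcp$numt_mean[i] <= rules$numt_mean_max &&
      !is.na(pcp$edge_dist[i]) && pcp$edge_dist[i] >= rules$edge_dist_min
    keep[i] <- qc && paste(pcp$pos[i], pcp$alt[i]) %in% allow_keys
  }
  keep
}

# random toy sample for filter-oracle comparisons
random_filter_case <- function(n_max = 10) {
  n <- sample.int(n_max, 1)
  pos <- sample.int(16569, n)
  pcp <- make_caller_records(
    pos = pos, vl = round(stats::runif(n, 0.01, 0.9), 3),
    norm_cov = round(stats::runif(n, 0, 1.5), 2),
    cov_ratio = round(stats::runif(n, 0.2, 2.5), 2),
    numt_mean = round(stats::runif(n, 0, 2), 2),
    edge_dist = sample(0:30, n, replace = TRUE))
  echo <- stats::runif(n) < 0.6
  tss <- pcp[echo, , drop = FALSE]
  tss$caller <- rep("TSS", nrow(tss))
  extra <- make_caller_records(pos = sample.int(16569, 2),
                               vl = c(0.3, 0.2), caller = "TSS")
  tss <- rbind(tss, extra)
  allow <- pcp[stats::runif(n) < 0.5, c("pos", "ref", "alt"), drop = FALSE]
  list(pcp = pcp, tss = tss, allow = allow)
}
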