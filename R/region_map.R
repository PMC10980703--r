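#' @keywords internal
"_PACKAGE"

# rCRS genome length (NC_012920.1); the molecule is circular.
MT_GENOME_LENGTH <- 16569L

MACRO_LEVELS <- c("ComplexI", "ComplexIII", "ComplexIV", "ComplexV",
                  "tRNA", "rRNA", "D-loop", "Other")

# Expand a (possibly origin-wrapping) 1-based inclusive interval to positions.
expand_interval <- function(start, end, genome_length = MT_GENOME_LENGTH) {
  if (start <= end) seq.int(start, end)
  else c(seq.int(start, genome_length), seq.int(1L, end))
}

#' Size of a 1-based inclusive mtDNA interval, wrap-aware
#'
#' A region with `start > end` wraps the circular origin; its size is
#' `(L - start + 1) + end` for genome length `L`.
#'
#' @param start,end 1-based inclusive rCRS coordinates.
#' @param genome_length Genome length in bp (rCRS: 16569).
#' @return Integer number of positions covered.
#' @export
interval_size <- function(start, end, genome_length = MT_GENOME_LENGTH) {
  ifelse(start <= end, end - start + 1L, (genome_length - start + 1L) + end)
}

#' Load an rCRS locus annotation into a region map
#'
#' Reads a tab-separated locus table (columns `locus`, `start`, `end`,
#' `macro`, `strand`; 1-based inclusive coordinates, `start > end` wraps the
#' circular origin) and builds the total, disjoint macro-region partition of
#' the 16,569-bp mitochondrial genome. Positions claimed by two loci (e.g.
#' the MT-ATP8/MT-ATP6 overlap) or by none resolve to the complement macro
#' region `"Other"`; all other positions take their locus macro.
#'
#' Uncovered or doubly-claimed runs longer than `max_gap` / `max_overlap`
#' indicate a defective table (e.g. a whole gene missing) and raise an error
#' listing the offending positions; the genuine rCRS gaps and gene overlaps
#' are well below these limits.
#'
#' @param path Path to the annotation table. Defaults to the bundled rCRS
#'   annotation.
#' @param max_gap,max_overlap Longest tolerated unannotated / doubly-claimed
#'   run, in bp.
#' @return An object of class `mt_region_map`: the locus table with
#'   `size_bp`, the per-position macro assignment, per-position locus lists,
#'   and macro-region sizes.
#' @examples
#' map <- load_region_map()
#' locate(11778, map)   # MT-ND4, ComplexI
#' @export
load_region_map <- function(path = system.file("extdata", "rcrs_regions.tsv",
                                               package = "mitoburden"),
                            max_gap = 50L, max_overlap = 50L) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("locus", "start", "end", "macro", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$locus))
    stop("duplicated locus names: ",
         paste(unique(tab$locus[duplicated(tab$locus)]), collapse = ", "))
  bad <- tab$start < 1L | tab$start > MT_GENOME_LENGTH |
    tab$end < 1L | tab$end > MT_GENOME_LENGTH
  if (any(bad))
    stop("coordinates outside 1..", MT_GENOME_LENGTH, " for loci: ",
         paste(tab$locus[bad], collapse = ", "))
  if (!all(tab$macro %in% MACRO_LEVELS))
    stop("unknown macro labels: ",
         paste(setdiff(tab$macro, MACRO_LEVELS), collapse = ", "))

  tab$size_bp <- interval_size(tab$start, tab$end)

  pos_list <- lapply(seq_len(nrow(tab)),
                     function(i) expand_interval(tab$start[i], tab$end[i]))
  expanded <- data.frame(
    pos = unlist(pos_list),
    locus = rep(tab$locus, lengths(pos_list)),
    macro = rep(tab$macro, lengths(pos_list)),
    stringsAsFactors = FALSE
  )
  claims <- tabulate(expanded$pos, nbins = MT_GENOME_LENGTH)

  report_runs <- function(pos, what, limit) {
    runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
    long <- runs[lengths(runs) > limit]
    if (length(long)) {
      desc <- vapply(long, function(r) paste0(min(r), "-", max(r)), "")
      stop(what, " run(s) longer than ", limit, " bp: ",
           paste(desc, collapse = ", "),
           "; the table looks incomplete or malformed")
    }
  }
  report_runs(which(claims == 0L), "uncovered (no locus, not Other-annotated)",
              max_gap)
  report_runs(which(claims > 1L), "multi-locus overlap", max_overlap)

  macro_at <- rep("Other", MT_GENOME_LENGTH)
  single <- expanded$pos[claims[expanded$pos] == 1L]
  macro_at[single] <- expanded$macro[claims[expanded$pos] == 1L]

  loci_at <- split(expanded$locus,
                   factor(expanded$pos, levels = seq_len(MT_GENOME_LENGTH)))

  map <- list(
    regions = tab[, c("locus", "start", "end", "macro", "strand", "size_bp")],
    genome_length = MT_GENOME_LENGTH,
    macro_at = macro_at,
    loci_at = loci_at,
    macro_sizes = table(factor(macro_at, levels = MACRO_LEVELS))
  )
  class(map) <- "mt_region_map"
  map
}

.map_cache <- new.env(parent = emptyenv())

#' Bundled default rCRS region map (cached)
#' @return An `mt_region_map` built from the bundled annotation.
#' @export
default_region_map <- function() {
  if (is.null(.map_cache$map)) .map_cache$map <- load_region_map()
  .map_cache$map
}

#' Locate an rCRS position
#'
#' Maps a position to its locus (or loci, for positions inside gene
#' overlaps) and macro region. Multi-locus and unannotated positions carry
#' macro `"Other"`.
#'
#' @param pos 1-based rCRS position (scalar).
#' @param map An `mt_region_map`.
#' @return A list with `loci` (character vector, possibly empty) and `macro`.
#' @export
locate <- function(pos, map = default_region_map()) {
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > map$genome_length)
    stop("pos must be a single position in 1..", map$genome_length)
  list(loci = map$loci_at[[as.integer(pos)]],
       macro = map$macro_at[[as.integer(pos)]])
}

#' Macro region for a vector of positions
#' @param pos Integer vector of rCRS positions.
#' @param map An `mt_region_map`.
#' @return Character vector of macro labels.
#' @export
macro_of <- function(pos, map = default_region_map()) {
  if (any(is.na(pos)) || any(pos < 1L | pos > map$genome_length))
    stop("positions must be in 1..", map$genome_length)
  map$macro_at[as.integer(pos)]
}

#' Region size in bp
#'
#' For a locus name, the number of positions its annotated interval covers;
#' for a macro-region name (including `"Other"`), the number of positions
#' assigned to that macro in the total partition.
#'
#' @param region Locus or macro-region name.
#' @param map An `mt_region_map`.
#' @return Integer size in bp.
#' @export
region_size <- function(region, map = default_region_map()) {
  if (region %in% map$regions$locus)
    return(map$regions$size_bp[match(region, map$regions$locus)])
  if (region %in% names(map$macro_sizes))
    return(as.integer(map$macro_sizes[[region]]))
  stop("unknown region: ", region)
}

#' Annotate a variant table with locus and macro region
#'
#' Adds `locus` (comma-joined when a position falls in a gene overlap) and
#' `macro` columns keyed on `pos`.
#'
#' @param variants Data frame with a `pos` column.
#' @param map An `mt_region_map`.
#' @return The input with `locus` and `macro` columns.
#' @export
annotate_regions <- function(variants, map = default_region_map()) {
  stopifnot(is.data.frame(variants), "pos" %in% names(variants))
  variants$macro <- if (nrow(variants)) macro_of(variants$pos, map) else character()
  variants$locus <- vapply(variants$pos, function(p)
    paste(map$loci_at[[as.integer(p)]], collapse = ","), "")
  variants
}

#' @export
print.mt_region_map <- function(x, ...) {
  cat("rCRS region map:", nrow(x$regions), "loci over",
      x$genome_length, "bp\n")
  cat("macro partition (bp):\n")
  print(x$macro_sizes)
  invisible(x)
}
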