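# Criteria-based partitioning of an assembly into matched / unmatched
# contig sets, plus the report writers (main CSV, top-hits TSV,
# coverage-weighted taxon word-frequency TSV).

#' Build a set of extraction criteria
#'
#' All supplied criteria are combined with AND; numeric range bounds are
#' inclusive. The taxon criterion uses majority-vote classification
#' ([classify_contig()]), with phage matching semantics when
#' `phage = TRUE`.
#'
#' @param taxon,rank Taxon name and its rank (`domain`, `genus`,
#'   `species`, ...).
#' @param perc Majority threshold percent for the taxon criterion
#'   (default 50; strict `>`).
#' @param phage Phage matching semantics for the taxon criterion.
#' @param gc_min,gc_max GC-content bounds (percent).
#' @param density_min,density_max Coding-density bounds (genes/kbp).
#' @param aai_min,aai_max Mean-AAI bounds (percent).
#' @param length_min Minimum contig length (bp).
#' @param coverage_min,coverage_max Read-coverage bounds.
#' @param clusters Set of acceptable cluster labels.
#' @return An `extraction_criteria` object.
#' @export
extraction_criteria <- function(taxon = NULL, rank = "genus", perc = 50,
                                phage = FALSE,
                                gc_min = NULL, gc_max = NULL,
                                density_min = NULL, density_max = NULL,
                                aai_min = NULL, aai_max = NULL,
                                length_min = NULL,
                                coverage_min = NULL, coverage_max = NULL,
                                clusters = NULL) {
  cr <- list(taxon = taxon, rank = rank, perc = perc, phage = phage,
             gc_min = gc_min, gc_max = gc_max,
             density_min = density_min, density_max = density_max,
             aai_min = aai_min, aai_max = aai_max,
             length_min = length_min,
             coverage_min = coverage_min, coverage_max = coverage_max,
             clusters = clusters)
  active <- !vapply(cr[setdiff(names(cr), c("rank", "perc", "phage"))],
                    is.null, logical(1))
  if (!any(active)) stop_param("at least one extraction criterion must be set")
  for (pair in list(c("gc_min", "gc_max"), c("density_min", "density_max"),
                    c("aai_min", "aai_max"),
                    c("coverage_min", "coverage_max"))) {
    lo <- cr[[pair[1]]]; hi <- cr[[pair[2]]]
    if (!is.null(lo) && !is.null(hi) && lo > hi) {
      stop_param(sprintf("%s exceeds %s", pair[1], pair[2]))
    }
  }
  if (!is.null(taxon) && !rank %in% TAX_RANKS) {
    stop_param(sprintf("unknown rank '%s'", rank))
  }
  structure(cr, class = "extraction_criteria")
}

#' Partition contigs by extraction criteria
#'
#' A contig matches when ALL active criteria hold. Matched and unmatched
#' ids partition the input exactly.
#'
#' @param x A `contig_profiles` object.
#' @param criteria An [extraction_criteria()] object.
#' @return List with character vectors `matched` and `unmatched`.
#' @export
select_contigs <- function(x, criteria) {
  if (!inherits(criteria, "extraction_criteria")) {
    stop_param("criteria must be an extraction_criteria object")
  }
  pf <- x$profiles
  needs_cov <- !is.null(criteria$coverage_min) || !is.null(criteria$coverage_max)
  if (needs_cov && all(is.na(pf$coverage))) {
    stop_param("coverage criterion requires a depth table")
  }
  ok <- rep(TRUE, nrow(pf))
  rng <- function(ok, v, lo, hi) {
    if (!is.null(lo)) ok <- ok & !is.na(v) & v >= lo
    if (!is.null(hi)) ok <- ok & !is.na(v) & v <= hi
    ok
  }
  ok <- rng(ok, pf$gc, criteria$gc_min, criteria$gc_max)
  ok <- rng(ok, pf$coding_density, criteria$density_min, criteria$density_max)
  ok <- rng(ok, pf$mean_aai, criteria$aai_min, criteria$aai_max)
  ok <- rng(ok, pf$coverage, criteria$coverage_min, criteria$coverage_max)
  if (!is.null(criteria$length_min)) ok <- ok & pf$length >= criteria$length_min
  if (!is.null(criteria$clusters)) {
    ok <- ok & !is.na(pf$cluster) & pf$cluster %in% criteria$clusters
  }
  if (!is.null(criteria$taxon)) {
    tax_ok <- vapply(x$summaries[pf$contig_id], classify_contig, logical(1),
                     taxon = criteria$taxon, rank = criteria$rank,
                     perc = criteria$perc, phage = criteria$phage)
    ok <- ok & tax_ok
  }
  list(matched = pf$contig_id[ok], unmatched = pf$contig_id[!ok])
}

#' Write the main per-contig report
#'
#' One row per input contig (zero-ORF contigs included), fixed column
#' order: `contig, length, gc, coding_density, mean_aai, coverage,
#' cluster, n_orfs, n_orfs_with_hits, top_hit_taxa`. Missing values are
#' written as `NA`. `top_hit_taxa` joins, per ORF in contig order, the
#' top-hit taxon at the report rank with `;`.
#'
#' @param x A `contig_profiles` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_main_report <- function(x, path) {
  pf <- x$profiles
  out <- data.frame(
    contig = pf$contig_id,
    length = pf$length,
    gc = round(pf$gc, 4),
    coding_density = round(pf$coding_density, 4),
    mean_aai = round(pf$mean_aai, 4),
    coverage = pf$coverage,
    cluster = pf$cluster,
    n_orfs = pf$n_orfs,
    n_orfs_with_hits = pf$n_orfs_with_hits,
    top_hit_taxa = pf$top_hit_taxa,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "NA", quote = TRUE)
  invisible(path)
}

#' Write the per-ORF top-hits file
#'
#' Re-serializes the ranked hits (up to `n` per ORF) in the same
#' 8-column tabular dialect that [parse_hit_table()] consumes, so the
#' file round-trips.
#'
#' @param hits Ranked hit data frame.
#' @param path Output TSV path.
#' @param n Hits per ORF (default 100).
#' @return Invisibly, `path`.
#' @export
write_tophits_file <- function(hits, path, n = 100L) {
  h <- top_hits(hits, n)
  lineage <- do.call(paste, c(h[TAX_RANKS], sep = ";"))
  lines <- paste(h$orf_id, h$sseqid, h$pident, h$length,
                 h$evalue, h$bitscore, h$stitle, lineage, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Coverage-weighted taxon word-frequency table
#'
#' For every hit-bearing ORF, its top-hit taxon at `rank` receives the
#' weight of the contig's read coverage (or 1 when no depth table is
#' available); weights are normalized to sum 1. This is the data behind
#' the word cloud in the original workflow, kept as a deterministic
#' table.
#'
#' @param x A `contig_profiles` object.
#' @param rank Rank whose taxa are tallied (default `"genus"`).
#' @param use_coverage Weight by coverage when available (default
#'   `TRUE`).
#' @return Named numeric vector of weights, decreasing, summing to 1
#'   (empty when there are no hits).
#' @export
word_frequency_table <- function(x, rank = "genus", use_coverage = TRUE) {
  if (!rank %in% TAX_RANKS) stop_param(sprintf("unknown rank '%s'", rank))
  acc <- list()
  for (s in x$summaries) {
    top <- s$top_hits
    if (is.null(top) || nrow(top) == 0L) next
    cov <- x$profiles$coverage[match(s$contig_id, x$profiles$contig_id)]
    w <- if (use_coverage && !is.na(cov)) cov else 1
    acc[[length(acc) + 1L]] <- data.frame(term = top[[rank]], w = w,
                                          stringsAsFactors = FALSE)
  }
  if (length(acc) == 0L) return(stats::setNames(numeric(0), character(0)))
  d <- do.call(rbind, acc)
  tot <- tapply(d$w, d$term, sum)
  out <- as.numeric(tot) / sum(tot)
  names(out) <- names(tot)
  sort(out, decreasing = TRUE)
}
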