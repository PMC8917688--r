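# Screening eukaryotic contigs for candidate horizontal gene transfers:
# an ORF whose top homologs are predominantly prokaryotic, sitting on a
# contig whose ORFs are otherwise predominantly eukaryotic. Requires a
# reference spanning all domains of life; candidates warrant caution and
# downstream validation.

#' Is a contig eukaryotic by majority vote?
#'
#' `TRUE` when strictly more than `perc` percent of the contig's
#' hit-bearing ORFs have a top hit in domain Eukaryota. A contig without
#' hits is conservatively non-eukaryotic.
#'
#' @param summary A `contig_taxon_summary`.
#' @param perc Threshold percent (default 50).
#' @return Logical.
#' @export
is_eukaryotic_contig <- function(summary, perc = 50) {
  frac <- summary$fractions$domain["Eukaryota"]
  if (is.na(frac)) frac <- 0
  unname(frac * 100 > perc)
}

#' Flag candidate HGT ORFs on eukaryotic contigs
#'
#' For every ORF on every eukaryotic contig, the top `n` ranked hits are
#' examined; the ORF is flagged when strictly more than `perc` percent of
#' them are to bacterial or archaeal proteins (the two prokaryotic
#' domains pooled). Viral hits count in the denominator but not the
#' numerator.
#'
#' @param summaries List of `contig_taxon_summary` objects (the whole
#'   assembly; non-eukaryotic contigs are skipped internally).
#' @param hits Ranked hit data frame.
#' @param orfs ORF data frame (for coordinates in the report).
#' @param n Hits considered per ORF (default 100).
#' @param perc Flagging threshold percent (default 50; strict `>`).
#' @param euk_perc Threshold for calling a contig eukaryotic
#'   (default 50).
#' @param max_density Optional coding-density ceiling (genes/kbp): when
#'   given, a contig must also have density at or below it to be scanned
#'   (prokaryote-style gene calling leaves eukaryotic contigs sparse, so
#'   0.5 is a common choice).
#' @param densities Named numeric vector contig -> coding density; only
#'   needed when `max_density` is set.
#' @return Data frame with one row per call: `orf_id`, `contig_id`,
#'   `start`, `end`, `strand`, `fraction_prokaryotic`, `n_hits`,
#'   `top_hit_title`, `top_hit_lineage`.
#' @export
flag_hgt_orfs <- function(summaries, hits, orfs, n = 100L, perc = 50,
                          euk_perc = 50, max_density = NULL,
                          densities = NULL) {
  if (!is.null(max_density) && is.null(densities)) {
    stop_param("max_density requires per-contig densities")
  }
  euk <- vapply(summaries, is_eukaryotic_contig, logical(1), perc = euk_perc)
  ids <- vapply(summaries, function(s) s$contig_id, character(1))
  scan <- ids[euk]
  if (!is.null(max_density)) {
    scan <- scan[!is.na(densities[scan]) & densities[scan] <= max_density]
  }
  out <- list()
  sub <- hits[hits$contig_id %in% scan & hits$rank <= n, , drop = FALSE]
  for (oid in unique(sub$orf_id)) {
    h <- sub[sub$orf_id == oid, , drop = FALSE]
    frac <- mean(h$domain %in% c("Bacteria", "Archaea"))
    if (frac * 100 > perc) {
      top <- h[h$rank == 1L, , drop = FALSE]
      o <- orfs[orfs$orf_id == oid, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        orf_id = oid,
        contig_id = h$contig_id[1L],
        start = if (nrow(o)) o$start[1L] else NA_integer_,
        end = if (nrow(o)) o$end[1L] else NA_integer_,
        strand = if (nrow(o)) o$strand[1L] else NA_character_,
        fraction_prokaryotic = frac,
        n_hits = nrow(h),
        top_hit_title = top$stitle[1L],
        top_hit_lineage = paste(unlist(top[1L, TAX_RANKS]), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(orf_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0),
                      fraction_prokaryotic = numeric(0), n_hits = integer(0),
                      top_hit_title = character(0),
                      top_hit_lineage = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig_id, res$orf_id), , drop = FALSE]
}
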