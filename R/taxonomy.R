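# Homology-hit handling: the extended tabular dialect (outfmt-6 columns
# plus subject title and a pre-resolved semicolon-joined lineage), per-ORF
# ranking, and per-contig taxonomic summaries.

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore",
              "stitle", "staxlineage")

#' Parse an extended tabular homology-hit file
#'
#' Expects tab-separated rows without header: `qseqid, sseqid, pident,
#' length, evalue, bitscore, stitle, staxlineage`, where `staxlineage` is
#' a semicolon-joined lineage, domain first (fewer than 7 fields are
#' padded with `"unclassified"`), and `qseqid` has the form
#' `<contig_id>_<serial>`. Hits are ranked within each ORF by bitscore
#' (descending), then e-value (ascending), then input order.
#'
#' @param path Path to the `.blast`-style hit table.
#' @return A data frame of hits with columns `orf_id`, `contig_id`,
#'   `sseqid`, `pident`, `length`, `evalue`, `bitscore`, `stitle`, the
#'   seven lineage ranks (`domain` ... `species`) and `rank` (1 = top hit
#'   for its ORF).
#' @export
parse_hit_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("hit table not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hit_frame())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 8L)) {
    bad <- which(nf != 8L)[1L]
    stop_format(sprintf(
      "hit table line %d has %d fields (8 expected: %s)",
      bad, nf[bad], paste(HIT_COLS, collapse = ", ")))
  }
  m <- matrix(unlist(parts), ncol = 8L, byrow = TRUE)
  pident <- suppressWarnings(as.numeric(m[, 3L]))
  bits <- suppressWarnings(as.numeric(m[, 6L]))
  ev <- suppressWarnings(as.numeric(m[, 5L]))
  if (anyNA(pident)) {
    stop_format(sprintf("unparsable pident at line %d", which(is.na(pident))[1L]))
  }
  if (anyNA(bits)) {
    stop_format(sprintf("unparsable bitscore at line %d", which(is.na(bits))[1L]))
  }
  if (anyNA(ev)) {
    stop_format(sprintf("unparsable evalue at line %d", which(is.na(ev))[1L]))
  }
  lineage <- parse_lineages(m[, 8L])
  hits <- data.frame(
    orf_id = m[, 1L],
    contig_id = sub("_[0-9]+$", "", m[, 1L]),
    sseqid = m[, 2L], pident = pident,
    length = suppressWarnings(as.integer(m[, 4L])),
    evalue = ev, bitscore = bits, stitle = m[, 7L],
    lineage, stringsAsFactors = FALSE)
  rank_hits(hits)
}

parse_lineages <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    length(p) <- 7L
    p[is.na(p)] <- "unclassified"
    p[1:7]
  }, character(7)))
  colnames(m) <- TAX_RANKS
  as.data.frame(m, stringsAsFactors = FALSE)
}

# (Re)assign the within-ORF rank: bitscore desc, evalue asc, input order.
rank_hits <- function(hits) {
  ord <- order(hits$orf_id, -hits$bitscore, hits$evalue, seq_len(nrow(hits)))
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$orf_id,
                          FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

empty_hit_frame <- function() {
  lin <- as.data.frame(matrix(character(0), ncol = 7,
                              dimnames = list(NULL, TAX_RANKS)),
                       stringsAsFactors = FALSE)
  cbind(data.frame(orf_id = character(0), contig_id = character(0),
                   sseqid = character(0), pident = numeric(0),
                   length = integer(0), evalue = numeric(0),
                   bitscore = numeric(0), stitle = character(0),
                   stringsAsFactors = FALSE),
        lin, data.frame(rank = integer(0)))
}

#' Keep the top-ranked hits of each ORF
#'
#' @param hits Ranked hit data frame ([parse_hit_table()] layout).
#' @param n Hits to keep per ORF (default 100).
#' @return The truncated hit data frame.
#' @export
top_hits <- function(hits, n = 100L) {
  if (n < 1) stop_param("n must be >= 1")
  if (!"rank" %in% names(hits)) hits <- rank_hits(hits)
  out <- hits[hits$rank <= n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the taxonomy of one contig
#'
#' Fractions at every rank are computed over the ORFs that have at least
#' one hit, using each ORF's top hit only; ORFs without hits are counted
#' separately and do not dilute the fractions. Mean AAI is the arithmetic
#' mean of top-hit percent identities (missing when no ORF has a hit).
#'
#' @param orfs ORF data frame for one contig (may be empty).
#' @param hits Ranked hit data frame (whole assembly or already subset).
#' @param contig_id Contig id; only required when `orfs` is empty.
#' @return An object of class `contig_taxon_summary`: a list with
#'   `contig_id`, `n_orfs`, `n_orfs_with_hits`, `n_orfs_without_hits`,
#'   `mean_aai`, `fractions` (named list over ranks of named numeric
#'   vectors) and `top_hits` (one row per hit-bearing ORF).
#' @export
summarize_contig <- function(orfs, hits, contig_id = NULL) {
  cid <- unique(orfs$contig_id)
  if (length(cid) == 0L) cid <- contig_id
  if (length(cid) != 1L || is.null(cid)) {
    stop_param("summarize_contig: ORFs from one contig only")
  }
  top <- hits[hits$contig_id == cid & hits$rank == 1L & hits$orf_id
              %in% orfs$orf_id, , drop = FALSE]
  top <- top[match(intersect(orfs$orf_id, top$orf_id), top$orf_id), ,
             drop = FALSE]
  n_with <- nrow(top)
  fractions <- lapply(stats::setNames(TAX_RANKS, TAX_RANKS), function(r) {
    if (n_with == 0L) return(stats::setNames(numeric(0), character(0)))
    tab <- table(top[[r]])
    stats::setNames(as.numeric(tab) / n_with, names(tab))
  })
  structure(list(
    contig_id = cid,
    n_orfs = nrow(orfs),
    n_orfs_with_hits = n_with,
    n_orfs_without_hits = nrow(orfs) - n_with,
    mean_aai = if (n_with > 0L) mean(top$pident) else NA_real_,
    fractions = fractions,
    top_hits = top), class = "contig_taxon_summary")
}

#' @export
print.contig_taxon_summary <- function(x, ...) {
  cat(sprintf("Contig %s: %d ORFs (%d with hits), mean AAI %s\n",
              x$contig_id, x$n_orfs, x$n_orfs_with_hits,
              ifelse(is.na(x$mean_aai), "NA",
                     sprintf("%.1f%%", x$mean_aai))))
  g <- x$fractions$genus
  if (length(g)) {
    g <- sort(g, decreasing = TRUE)
    cat("  top genera:",
        paste(sprintf("%s (%.0f%%)", names(g)[seq_len(min(3, length(g)))],
                      100 * g[seq_len(min(3, length(g)))]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Majority-vote taxonomic classification of a contig
#'
#' A contig is classified as `taxon` when strictly more than `perc`
#' percent of its hit-bearing ORFs carry that taxon (at the given rank)
#' in their top hit. With `phage = TRUE` a top hit counts toward the
#' taxon when its domain is `Viruses` and the taxon token appears in the
#' subject title or anywhere in the lineage (host-genus naming of phage
#' reference proteins).
#'
#' @param summary A `contig_taxon_summary`.
#' @param taxon Taxon name (matched case-insensitively).
#' @param rank One of `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @param perc Threshold percentage in `(0, 100]` (default 50; strict
#'   `>`).
#' @param phage Use phage matching semantics (default `FALSE`).
#' @return `TRUE`/`FALSE`; a contig with no hit-bearing ORF is never
#'   classified.
#' @export
classify_contig <- function(summary, taxon, rank = "genus", perc = 50,
                            phage = FALSE) {
  if (!rank %in% TAX_RANKS) {
    stop_param(sprintf("unknown rank '%s'", rank))
  }
  if (!is.numeric(perc) || perc <= 0 || perc > 100) {
    stop_param("perc must be in (0, 100]")
  }
  frac <- taxon_fraction(summary, taxon, rank, phage)
  frac * 100 > perc
}

taxon_fraction <- function(summary, taxon, rank, phage = FALSE) {
  top <- summary$top_hits
  if (is.null(top) || nrow(top) == 0L) return(0)
  if (phage) {
    pat <- taxon
    in_title <- grepl(pat, top$stitle, ignore.case = TRUE, fixed = FALSE)
    lin <- do.call(paste, c(top[TAX_RANKS], sep = ";"))
    in_lineage <- grepl(pat, lin, ignore.case = TRUE)
    hit <- top$domain == "Viruses" & (in_title | in_lineage)
  } else {
    hit <- tolower(top[[rank]]) == tolower(taxon)
  }
  mean(hit)
}
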