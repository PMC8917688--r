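# Composition-based putative binning. The number of clusters is not a free
# parameter: it is estimated from single-copy marker-gene hit counts (each
# marker is expected once per genome, so the mean hit count across the
# marker set approximates the number of genomes in the assembly).

#' The 16-gene universal single-copy marker set
#'
#' Ribosomal proteins L2, L3, L4, L5, L6, L14, L15, L16, L18, L22, L24,
#' S3, S8, S10, S17 and S19 — the widely used universal set for counting
#' genomes in an assembly.
#'
#' @return Character vector of 16 marker names.
#' @export
universal_markers <- function() {
  c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14", "rpL15", "rpL16",
    "rpL18", "rpL22", "rpL24", "rpS3", "rpS8", "rpS10", "rpS17", "rpS19")
}

#' Estimate the number of genome bins from marker hit counts
#'
#' `k = max(1, round_half_up(mean(counts)))`, the mean taken over every
#' marker in the set including zero-hit markers.
#'
#' @param markers Named integer vector, marker id -> hit count.
#' @return Integer `k >= 1`.
#' @export
estimate_k <- function(markers) {
  if (length(markers) == 0L) stop_param("empty marker set")
  if (any(markers < 0)) stop_param("marker counts must be >= 0")
  max(1L, as.integer(round_half_up(mean(markers))))
}

#' Parse single-copy-marker hit counts
#'
#' Two dialects: `"tsv"` (two columns, `marker_id<TAB>count`, no header
#' required; a `marker<TAB>count`-style header row is tolerated) and
#' `"hmmsearch_tblout"` (hits counted as non-comment target lines per
#' query marker, the query name being field 3). Markers in `marker_set`
#' absent from the file get count 0.
#'
#' @param path Input path.
#' @param dialect `"tsv"` or `"hmmsearch_tblout"`.
#' @param marker_set Marker names defining the table (default
#'   [universal_markers()]); pass `NULL` to use exactly the markers seen
#'   in the file.
#' @return Named integer vector of counts.
#' @export
parse_marker_counts <- function(path, dialect = c("tsv", "hmmsearch_tblout"),
                                marker_set = universal_markers()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input(sprintf("marker file not found: %s", path))
  if (dialect == "tsv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (length(parts) && any(lengths(parts) != 2L)) {
      stop_format("marker TSV must have exactly two tab-separated columns")
    }
    ids <- vapply(parts, `[`, character(1), 1L)
    val <- vapply(parts, `[`, character(1), 2L)
    num <- suppressWarnings(as.numeric(val))
    if (length(num) && is.na(num[1L]) && length(num) > 1L) {
      # header row
      ids <- ids[-1L]; num <- num[-1L]
    }
    if (anyNA(num)) stop_format("non-numeric marker count")
    counts <- stats::setNames(as.integer(num), ids)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines)) {
      fields <- strsplit(trimws(lines), "[[:space:]]+")
      qname <- vapply(fields, function(f) {
        if (length(f) < 3L) stop_format("malformed hmmsearch tblout line")
        f[3L]
      }, character(1))
      tab <- table(qname)
      counts <- stats::setNames(as.integer(tab), names(tab))
    } else {
      counts <- stats::setNames(integer(0), character(0))
    }
  }
  if (is.null(marker_set)) return(counts)
  out <- stats::setNames(integer(length(marker_set)), marker_set)
  shared <- intersect(names(counts), marker_set)
  out[shared] <- counts[shared]
  out
}

#' Build the clustering feature matrix
#'
#' Rows are contigs at least `min_length` bp long that carry at least one
#' complete ORF; columns are the 136 canonical TNF features followed by
#' the 59 RSCU features, each standardized to mean 0 / sd 1 (constant
#' columns dropped).
#'
#' @param profiles A `contig_profiles` object ([profile_contigs()]) or a
#'   list with elements `profiles` (data frame with `contig_id`,
#'   `length`, `n_orfs_complete`), `tnf` and `rscu` (matrices with
#'   contig-id rownames).
#' @param min_length Minimum contig length for clustering eligibility
#'   (default 2000 bp).
#' @return List with `matrix` (standardized features) and `contig_ids`
#'   (kept rows), or `NULL` (with a warning) when fewer than two contigs
#'   are eligible.
#' @export
build_feature_matrix <- function(profiles, min_length = 2000L) {
  pf <- profiles$profiles
  keep <- pf$length >= min_length & pf$n_orfs_complete >= 1L
  ids <- pf$contig_id[keep]
  if (length(ids) < 2L) {
    warning("fewer than 2 contigs eligible for clustering; binning skipped",
            call. = FALSE)
    return(NULL)
  }
  feat <- cbind(profiles$tnf[ids, , drop = FALSE],
                profiles$rscu[ids, , drop = FALSE])
  sds <- apply(feat, 2L, stats::sd)
  feat <- feat[, sds > 0, drop = FALSE]
  feat <- scale(feat)
  list(matrix = feat, contig_ids = ids)
}

#' Hierarchical clustering of contigs into putative bins
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance by
#' default) of the standardized composition features, with the tree cut
#' to exactly `k` flat clusters. Deterministic for a fixed input.
#'
#' @param features Feature matrix (rows named by contig id), e.g.
#'   `build_feature_matrix(...)$matrix`.
#' @param k Number of clusters (1 <= k <= rows).
#' @param linkage `"ward"` (default; `hclust` method `ward.D2`),
#'   `"complete"` or `"average"`.
#' @return Named integer vector, contig id -> cluster label in `1..k`.
#' @export
hierarchical_cluster <- function(features, k,
                                 linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  if (k < 1) stop_param("k must be >= 1")
  if (k > nrow(features)) {
    stop_param(sprintf("k = %d exceeds the number of contigs (%d)",
                       k, nrow(features)))
  }
  method <- switch(linkage, ward = "ward.D2", complete = "complete",
                   average = "average")
  hc <- stats::hclust(stats::dist(features, method = "euclidean"),
                      method = method)
  labels <- stats::cutree(hc, k = k)
  stats::setNames(as.integer(labels), rownames(features))
}
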