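# The central profiling step and the end-to-end runner behind the CLI.

#' Profile the contigs of an assembly
#'
#' The package's main computation: per-contig length, GC, coding
#' density, mean AAI, coverage, composition vectors and taxonomy
#' summaries; optionally composition-based putative bins (cluster count
#' estimated from single-copy-marker hit counts) and HGT candidate calls
#' on eukaryotic contigs.
#'
#' @param contigs Contig data frame ([read_fasta()] layout).
#' @param hits Ranked hit data frame ([parse_hit_table()]), or `NULL`
#'   when no homology search is available (taxonomy fields stay
#'   missing).
#' @param depth Optional named depth vector ([read_depth_table()]).
#' @param marker_counts Optional named marker-count vector
#'   ([parse_marker_counts()]); when given, contigs are clustered into
#'   `estimate_k(marker_counts)` putative bins.
#' @param orfs Optional precomputed ORF data frame (e.g.
#'   [import_gene_calls()]); default is the built-in caller
#'   [find_orfs_assembly()].
#' @param rank Rank reported in the `top_hit_taxa` column and the word
#'   table (default `"genus"`).
#' @param hits_n Hits retained per ORF for the top-hits report and the
#'   HGT scan (default 100).
#' @param min_cluster_length Minimum contig length for clustering
#'   eligibility (default 2000 bp).
#' @param linkage Clustering linkage (see [hierarchical_cluster()]).
#' @param hgt Scan eukaryotic contigs for HGT candidates (default
#'   `FALSE`).
#' @param hgt_perc,hgt_max_density HGT flagging threshold percent and
#'   optional coding-density ceiling for the eukaryotic-contig test.
#' @return An object of class `contig_profiles`: list with `profiles`
#'   (the per-contig data frame), `summaries`, `orfs`, `hits`, `tnf`,
#'   `rscu`, `k`, `clusters`, `hgt`, `rank`, `hits_n`.
#' @export
profile_contigs <- function(contigs, hits = NULL, depth = NULL,
                            marker_counts = NULL, orfs = NULL,
                            rank = "genus", hits_n = 100L,
                            min_cluster_length = 2000L,
                            linkage = "ward", hgt = FALSE,
                            hgt_perc = 50, hgt_max_density = NULL) {
  if (!rank %in% TAX_RANKS) stop_param(sprintf("unknown rank '%s'", rank))
  if (is.null(orfs)) orfs <- find_orfs_assembly(contigs)
  if (is.null(hits)) hits <- empty_hit_frame()

  ids <- contigs$contig_id
  lens <- nchar(contigs$sequence)
  orf_by <- split(seq_len(nrow(orfs)), orfs$contig_id)

  tnf <- matrix(0, nrow = length(ids), ncol = 136,
                dimnames = list(ids, names(tnf_vector("ACGT"))))
  rscu <- matrix(0, nrow = length(ids), ncol = 59,
                 dimnames = list(ids, rscu_families()$codons))
  summaries <- vector("list", length(ids))
  names(summaries) <- ids
  gc <- mean_aai <- numeric(length(ids))
  n_orfs <- n_complete <- n_with <- integer(length(ids))
  taxa_col <- character(length(ids))

  for (i in seq_along(ids)) {
    cid <- ids[i]
    o <- orfs[orf_by[[cid]] %||% integer(0), , drop = FALSE]
    gc[i] <- gc_content(contigs$sequence[i])
    tnf[i, ] <- tnf_vector(contigs$sequence[i])
    rscu[i, ] <- rscu_vector(o)
    s <- summarize_contig(o, hits, contig_id = cid)
    summaries[[i]] <- s
    mean_aai[i] <- s$mean_aai
    n_orfs[i] <- nrow(o)
    n_complete[i] <- sum(!o$partial)
    n_with[i] <- s$n_orfs_with_hits
    taxa_col[i] <- if (nrow(s$top_hits)) {
      paste(s$top_hits[[rank]], collapse = ";")
    } else ""
  }

  profiles <- data.frame(
    contig_id = ids,
    length = lens,
    gc = gc,
    coding_density = vapply(seq_along(ids), function(i)
      coding_density(n_orfs[i], lens[i]), numeric(1)),
    mean_aai = mean_aai,
    coverage = if (is.null(depth)) NA_real_ else unname(depth[ids]),
    cluster = NA_integer_,
    n_orfs = n_orfs,
    n_orfs_complete = n_complete,
    n_orfs_with_hits = n_with,
    top_hit_taxa = taxa_col,
    stringsAsFactors = FALSE)

  x <- list(profiles = profiles, summaries = summaries, orfs = orfs,
            hits = hits, tnf = tnf, rscu = rscu, k = NA_integer_,
            clusters = NULL, hgt = NULL, rank = rank,
            hits_n = as.integer(hits_n))
  class(x) <- "contig_profiles"

  if (!is.null(marker_counts)) {
    k <- estimate_k(marker_counts)
    fm <- build_feature_matrix(x, min_length = min_cluster_length)
    if (!is.null(fm)) {
      if (k > nrow(fm$matrix)) {
        warning(sprintf(
          "estimated k (%d) exceeds clusterable contigs (%d); capping",
          k, nrow(fm$matrix)), call. = FALSE)
        k <- nrow(fm$matrix)
      }
      cl <- hierarchical_cluster(fm$matrix, k, linkage = linkage)
      x$clusters <- cl
      x$k <- k
      x$profiles$cluster[match(names(cl), ids)] <- unname(cl)
    }
  }

  if (isTRUE(hgt)) {
    dens <- stats::setNames(x$profiles$coding_density, ids)
    x$hgt <- flag_hgt_orfs(summaries, hits, orfs, n = hits_n,
                           perc = hgt_perc,
                           max_density = hgt_max_density,
                           densities = dens)
  }
  x
}

#' @export
print.contig_profiles <- function(x, ...) {
  pf <- x$profiles
  cat(sprintf("contig_profiles: %d contigs, %s bp total\n",
              nrow(pf), format(sum(pf$length), big.mark = ",")))
  cat(sprintf("  ORFs called: %d (%d with hits)\n",
              sum(pf$n_orfs), sum(pf$n_orfs_with_hits)))
  if (!is.na(x$k)) {
    cat(sprintf("  putative bins: k = %d (%d contigs clustered)\n",
                x$k, sum(!is.na(pf$cluster))))
  }
  if (!is.null(x$hgt)) {
    cat(sprintf("  HGT candidates: %d\n", nrow(x$hgt)))
  }
  invisible(x)
}

#' @method summary contig_profiles
#' @export
summary.contig_profiles <- function(object, ...) {
  pf <- object$profiles
  dom <- table(unlist(lapply(object$summaries, function(s) {
    f <- s$fractions$domain
    if (length(f)) names(f)[which.max(f)] else NA_character_
  })), useNA = "ifany")
  out <- list(
    n_contigs = nrow(pf),
    total_bp = sum(pf$length),
    gc_range = range(pf$gc, na.rm = TRUE),
    density_range = range(pf$coding_density),
    mean_aai = mean(pf$mean_aai, na.rm = TRUE),
    majority_domains = dom,
    k = object$k)
  class(out) <- "summary.contig_profiles"
  out
}

#' @export
print.summary.contig_profiles <- function(x, ...) {
  cat(sprintf("%d contigs, %s bp\n", x$n_contigs,
              format(x$total_bp, big.mark = ",")))
  cat(sprintf("GC %.1f-%.1f%%, coding density %.2f-%.2f genes/kbp\n",
              x$gc_range[1], x$gc_range[2],
              x$density_range[1], x$density_range[2]))
  if (!is.nan(x$mean_aai)) cat(sprintf("mean AAI %.1f%%\n", x$mean_aai))
  cat("majority domain of contigs:\n")
  print(x$majority_domains)
  if (!is.na(x$k)) cat(sprintf("estimated genome count k = %d\n", x$k))
  invisible(x)
}

#' @method as.data.frame contig_profiles
#' @export
as.data.frame.contig_profiles <- function(x, ...) x$profiles

#' Plot GC against coding density
#'
#' The diagnostic scatter used to eyeball an assembly: prokaryotic
#' contigs cluster near 1 gene/kbp while eukaryotic contigs sit low and
#' left of the 0.5 genes/kbp line; point area scales with contig length
#' and color with cluster when bins were computed.
#'
#' @param x A `contig_profiles` object.
#' @param ... Passed to [graphics::plot()].
#' @method plot contig_profiles
#' @export
plot.contig_profiles <- function(x, ...) {
  pf <- x$profiles
  cex <- 0.6 + 1.6 * sqrt(pf$length / max(pf$length))
  col <- if (any(!is.na(pf$cluster))) {
    grDevices::hcl.colors(max(pf$cluster, na.rm = TRUE), "Dark 3")[
      ifelse(is.na(pf$cluster), NA, pf$cluster)]
  } else "steelblue"
  col[is.na(col)] <- "grey60"
  graphics::plot(pf$gc, pf$coding_density, cex = cex, pch = 19, col = col,
                 xlab = "GC content (%)",
                 ylab = "coding density (genes/kbp)", ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  invisible(x)
}
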