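# Built-in six-frame ORF finder. It is a deliberately simple, deterministic
# stand-in for a dedicated prokaryotic gene caller: downstream metrics
# (coding density, RSCU, AAI) only need gene spans and protein translations.

genetic_code_11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

#' Translate coding-strand DNA
#'
#' Uses the bacterial/archaeal genetic code (translation table 11).
#' Codons containing `N` translate to `X`; internal stops render `*`;
#' a terminal stop codon is stripped from the protein.
#'
#' @param dna Coding-strand DNA string, length divisible by 3.
#' @param table Genetic code id (passed to
#'   [Biostrings::getGeneticCode()]; default `"11"`).
#' @return Amino-acid string.
#' @export
translate_dna <- function(dna, table = "11") {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) %% 3L != 0L) {
    stop_param("DNA length must be divisible by 3 for translation")
  }
  if (nchar(dna) == 0L) return("")
  code <- if (identical(table, "11")) genetic_code_11() else
    Biostrings::getGeneticCode(table)
  cods <- codons_of(dna)
  aa <- unname(code[cods])
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# Scan one frame of one strand: codon-index positions of ORFs under the
# "first permitted start after the previous stop, through the next stop"
# rule. Returns a matrix with columns st, en (codon indices, stop included)
# and partial flag (no stop codon before the sequence end).
scan_frame <- function(cods, start_codons) {
  is_stop <- cods %in% STOP_CODONS
  is_start <- cods %in% start_codons
  stops <- which(is_stop)
  starts <- which(is_start)
  res <- matrix(integer(0), ncol = 3L)
  prev <- 0L
  for (s in stops) {
    cand <- starts[starts > prev & starts < s]
    if (length(cand)) res <- rbind(res, c(cand[1L], s, 0L))
    prev <- s
  }
  n <- length(cods)
  cand <- starts[starts > prev & starts <= n]
  if (length(cand) && cand[1L] < n) res <- rbind(res, c(cand[1L], n, 1L))
  res
}

#' Find open reading frames on a contig
#'
#' Scans all six reading frames. Within a frame an ORF runs from the first
#' permitted start codon after the previous stop codon to the next stop
#' codon (inclusive). ORFs reaching the contig end without a stop are
#' emitted with `partial = TRUE`. Candidates shorter than `min_length`
#' nucleotides (stop included) are discarded. Overlap resolution then
#' drops any candidate that overlaps a strictly longer retained ORF by
#' more than `max_overlap` nucleotides, on either strand; equal-length
#' overlapping ORFs are both kept, so the output is symmetric under
#' reverse complementation. Short overlaps (the common case for adjacent
#' prokaryotic genes) survive untouched.
#'
#' @param contig One-row contig data frame or a list with `contig_id` and
#'   `sequence`.
#' @param min_length Minimum ORF length in nucleotides, stop codon
#'   included (default 90, i.e. 30 codons).
#' @param start_codons Permitted start codons (default ATG, GTG, TTG).
#' @param table Genetic code id for translation (default `"11"`).
#' @param max_overlap Maximum tolerated overlap (nt) with a longer ORF
#'   before a candidate is discarded (default 60).
#' @return Data frame with columns `orf_id` (`<contig_id>_<serial>`),
#'   `contig_id`, `start`, `end` (1-based inclusive, forward strand),
#'   `strand` (`+`/`-`), `partial`, `dna` (coding strand) and `protein`.
#'   Sorted by `start`, then strand.
#' @export
find_orfs <- function(contig, min_length = 90L,
                      start_codons = c("ATG", "GTG", "TTG"),
                      table = "11", max_overlap = 60L) {
  seq_fwd <- contig$sequence
  id <- contig$contig_id
  stopifnot(length(seq_fwd) == 1L, length(id) == 1L)
  L <- nchar(seq_fwd)
  strands <- list(`+` = seq_fwd, `-` = revcomp(seq_fwd))
  cand <- list()
  for (str in names(strands)) {
    s <- strands[[str]]
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod < 2L) next
      at <- seq.int(f + 1L, by = 3L, length.out = ncod)
      cods <- substring(s, at, at + 2L)
      m <- scan_frame(cods, start_codons)
      if (nrow(m) == 0L) next
      beg <- f + (m[, 1L] - 1L) * 3L + 1L   # on strand s
      end <- f + m[, 2L] * 3L
      keep <- (end - beg + 1L) >= min_length
      if (!any(keep)) next
      beg <- beg[keep]; end <- end[keep]; part <- m[keep, 3L]
      if (str == "+") {
        fs <- beg; fe <- end
      } else {
        fs <- L - end + 1L; fe <- L - beg + 1L
      }
      cand[[length(cand) + 1L]] <- data.frame(
        start = fs, end = fe, strand = str, partial = as.logical(part),
        s_beg = beg, s_end = end, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(empty_orf_frame())
  cand <- do.call(rbind, cand)
  cand$len <- cand$end - cand$start + 1L

  # greedy overlap resolution, longest first; drop only against strictly
  # longer kept ORFs so ties (and thus revcomp symmetry) are preserved
  ord <- order(-cand$len, cand$start, cand$end, cand$strand)
  cand <- cand[ord, , drop = FALSE]
  n <- nrow(cand)
  kept <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    if (i > 1L) {
      j <- which(kept[seq_len(i - 1L)])
      if (length(j)) {
        ov <- pmin(cand$end[j], cand$end[i]) - pmax(cand$start[j], cand$start[i]) + 1L
        if (any(ov > max_overlap & cand$len[j] > cand$len[i])) ok <- FALSE
      }
    }
    kept[i] <- ok
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$start, cand$strand, cand$end), , drop = FALSE]

  dna <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    dna[i] <- substr(strands[[cand$strand[i]]], cand$s_beg[i], cand$s_end[i])
  }
  prot <- vapply(dna, translate_dna, character(1), table = table,
                 USE.NAMES = FALSE)
  data.frame(
    orf_id = paste0(id, "_", seq_len(nrow(cand))),
    contig_id = id,
    start = cand$start, end = cand$end, strand = cand$strand,
    partial = cand$partial, dna = dna, protein = prot,
    stringsAsFactors = FALSE)
}

empty_orf_frame <- function() {
  data.frame(orf_id = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             partial = logical(0), dna = character(0), protein = character(0),
             stringsAsFactors = FALSE)
}

#' Call ORFs on every contig of an assembly
#'
#' @param contigs Contig data frame.
#' @param ... Passed to [find_orfs()].
#' @return Combined ORF data frame.
#' @export
find_orfs_assembly <- function(contigs, ...) {
  res <- lapply(seq_len(nrow(contigs)), function(i)
    find_orfs(contigs[i, ], ...))
  out <- do.call(rbind, c(res, list(empty_orf_frame())))
  rownames(out) <- NULL
  out
}

#' Import externally produced gene calls
#'
#' Builds ORF records from a GFF3 file of CDS features plus the matching
#' protein FASTA (ids matching the CDS `ID` attribute), e.g. Prodigal
#' output, instead of the built-in caller.
#'
#' @param gff_path GFF3 path (CDS features used; others ignored).
#' @param protein_fasta_path Protein FASTA whose ids match CDS IDs.
#' @param contigs Contig data frame the calls refer to.
#' @return ORF data frame in the [find_orfs()] layout; `partial` is taken
#'   from a `partial` attribute when present (Prodigal's `00` meaning
#'   complete), otherwise `FALSE`.
#' @export
import_gene_calls <- function(gff_path, protein_fasta_path, contigs) {
  if (!file.exists(gff_path)) stop_input(sprintf("GFF not found: %s", gff_path))
  if (!file.exists(protein_fasta_path)) {
    stop_input(sprintf("protein FASTA not found: %s", protein_fasta_path))
  }
  gff <- rtracklayer::readGFF(gff_path)
  gff <- gff[gff$type == "CDS", , drop = FALSE]
  prot <- Biostrings::readAAStringSet(protein_fasta_path)
  names(prot) <- sub("\\s.*$", "", names(prot))
  seqs <- stats::setNames(contigs$sequence, contigs$contig_id)
  n <- nrow(gff)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cid <- as.character(gff$seqid[i])
    if (!cid %in% names(seqs)) {
      stop_format(sprintf("CDS references unknown contig '%s'", cid))
    }
    oid <- if (!is.null(gff$ID)) as.character(gff$ID[i]) else NA_character_
    if (is.na(oid) || !nzchar(oid)) {
      stop_format(sprintf("CDS %d on contig '%s' has no ID attribute", i, cid))
    }
    if (!oid %in% names(prot)) {
      stop_format(sprintf("no protein supplied for CDS '%s'", oid))
    }
    st <- as.integer(gff$start[i]); en <- as.integer(gff$end[i])
    strand <- as.character(gff$strand[i])
    if (!strand %in% c("+", "-")) strand <- "+"
    dna <- substr(seqs[[cid]], st, en)
    if (strand == "-") dna <- revcomp(dna)
    partial <- FALSE
    if (!is.null(gff$partial)) {
      p <- as.character(gff$partial[i])
      partial <- !is.na(p) && nzchar(p) && p != "00"
    }
    out[[i]] <- data.frame(
      orf_id = oid, contig_id = cid, start = st, end = en, strand = strand,
      partial = partial, dna = dna,
      protein = as.character(prot[[oid]]), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(empty_orf_frame())))
  rownames(res) <- NULL
  res[order(res$contig_id, res$start), , drop = FALSE]
}
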