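# Compositional signatures used by the report and by composition-based
# binning: GC, coding density, canonical (strand-folded) tetranucleotide
# frequencies, and relative synonymous codon usage.

#' GC content of a sequence
#'
#' `N` bases are excluded from both numerator and denominator. A sequence
#' consisting only of `N` has undefined GC and returns `NA`.
#'
#' @param sequence Non-empty DNA string over `{A,C,G,T,N}`.
#' @return Percent GC in `[0, 100]`, or `NA` for an all-`N` sequence.
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop_param("gc_content: empty sequence")
  cnt <- table(strsplit(sequence, "", fixed = TRUE)[[1L]])
  gc <- sum(cnt[names(cnt) %in% c("G", "C")])
  at <- sum(cnt[names(cnt) %in% c("A", "T")])
  if (gc + at == 0L) return(NA_real_)
  100 * gc / (gc + at)
}

#' Coding density in genes per kilobase
#'
#' The field's rule of thumb: bacterial and archaeal contigs run near
#' 1 gene/kbp while eukaryotic contigs (called with a prokaryotic gene
#' finder) fall well below 0.5 gene/kbp, which makes density a cheap
#' domain discriminator.
#'
#' @param n_orfs Number of gene calls on the contig.
#' @param contig_length Contig length in bp (>= 1).
#' @return Genes per kbp.
#' @export
coding_density <- function(n_orfs, contig_length) {
  if (contig_length < 1) stop_param("contig_length must be >= 1")
  1000 * n_orfs / contig_length
}

# Canonical 4-mer classes: each of the 256 4-mers mapped to the
# lexicographically smaller of itself and its reverse complement;
# 16 palindromic + 120 paired = 136 classes.
tnf_classes <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bases <- c("A", "C", "G", "T")
    kmers <- apply(expand.grid(bases, bases, bases, bases,
                               stringsAsFactors = FALSE)[, 4:1], 1L, paste,
                   collapse = "")
    rc <- chartr("ACGT", "TGCA", kmers)
    rc <- vapply(strsplit(rc, ""), function(x) paste(rev(x), collapse = ""),
                 character(1))
    canon <- ifelse(kmers <= rc, kmers, rc)
    cache <<- list(kmers = kmers, canon = canon,
                   classes = sort(unique(canon)))
    cache
  }
})

#' Canonical tetranucleotide frequency vector
#'
#' Slides a 4 bp window with step 1; windows containing `N` are skipped.
#' Each 4-mer is folded onto the lexicographically smaller of itself and
#' its reverse complement (136 canonical classes), making the signature
#' strand-agnostic. Counts are normalized to frequencies summing to 1;
#' a sequence with no countable window returns the all-zero vector.
#'
#' @param sequence DNA string.
#' @return Named numeric vector of length 136.
#' @export
tnf_vector <- function(sequence) {
  tc <- tnf_classes()
  zero <- stats::setNames(numeric(length(tc$classes)), tc$classes)
  if (nchar(sequence) < 4L) return(zero)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = 4L, step = 1L)
  counts <- counts[tc$kmers]
  folded <- tapply(counts, tc$canon, sum)
  tot <- sum(folded)
  if (tot == 0) return(zero)
  out <- zero
  out[names(folded)] <- folded / tot
  out
}

# Synonymous codon families under table 11, stops and the single-codon
# families (ATG/Met, TGG/Trp) excluded -> 59 codons.
rscu_families <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- genetic_code_11()
    sense <- code[!code %in% "*"]
    fam <- split(names(sense), unname(sense))
    fam <- fam[vapply(fam, length, integer(1)) > 1L]
    cache <<- list(families = fam,
                   codons = sort(unname(unlist(fam))))
    cache
  }
})

#' Relative synonymous codon usage (RSCU) vector
#'
#' Pools the coding-strand codons of all complete ORFs on a contig
#' (stop codons and codons containing `N` excluded). For a codon `c` in a
#' synonymous family of size `k` with family total `T`:
#' `RSCU(c) = k * count(c) / T` when `T > 0`, else 0 for the whole family.
#' The two single-codon families (ATG, TGG) and stops are excluded,
#' leaving 59 entries. Within any observed family the mean RSCU over its
#' `k` codons is exactly 1.
#'
#' @param orfs ORF data frame for one contig ([find_orfs()] layout); may
#'   be empty.
#' @return Named numeric vector of length 59.
#' @export
rscu_vector <- function(orfs) {
  rf <- rscu_families()
  out <- stats::setNames(numeric(length(rf$codons)), rf$codons)
  if (is.null(orfs) || nrow(orfs) == 0L) return(out)
  complete <- orfs[!orfs$partial, , drop = FALSE]
  if (nrow(complete) == 0L) return(out)
  cods <- unlist(lapply(complete$dna, codons_of), use.names = FALSE)
  cods <- cods[!cods %in% STOP_CODONS & !grepl("N", cods, fixed = TRUE)]
  if (length(cods) == 0L) return(out)
  cnt <- table(cods)
  for (fam in rf$families) {
    tot <- sum(cnt[fam], na.rm = TRUE)
    if (tot > 0) {
      obs <- cnt[fam]
      obs[is.na(obs)] <- 0
      out[fam] <- length(fam) * as.numeric(obs) / tot
    }
  }
  out
}
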