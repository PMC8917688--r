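# Independent brute-force oracles and tiny fixture builders shared by the
# suite. The oracles are deliberately naive (position loops, full 256-way
# k-mer counts) and independent of the package's vectorized paths.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

contig_df <- function(id, seq, desc = "") {
  data.frame(contig_id = id, description = desc, sequence = seq,
             stringsAsFactors = FALSE)
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  gc <- sum(ch == "G" | ch == "C")
  at <- sum(ch == "A" | ch == "T")
  if (gc + at == 0) NA_real_ else 100 * gc / (gc + at)
}

# Count all 256 4-mers by a sliding loop, then fold reverse-complement
# pairs onto the lexicographic minimum.
oracle_tnf <- function(seq) {
  counts <- new.env()
  L <- nchar(seq)
  if (L >= 4) {
    for (i in seq_len(L - 3)) {
      w <- substr(seq, i, i + 3)
      if (grepl("N", w, fixed = TRUE)) next
      canon <- min(w, oracle_revcomp(w))
      counts[[canon]] <- (counts[[canon]] %||% 0) + 1
    }
  }
  classes <- names(contigsift::tnf_vector("ACGT"))
  v <- vapply(classes, function(k) counts[[k]] %||% 0, numeric(1))
  if (sum(v) > 0) v <- v / sum(v)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct codon-count RSCU from a set of complete ORF DNA strings.
oracle_rscu <- function(dnas) {
  code <- Biostrings::getGeneticCode("11")
  stops <- names(code)[code == "*"]
  counts <- list()
  for (d in dnas) {
    n <- nchar(d) %/% 3
    for (i in seq_len(n)) {
      cod <- substr(d, 3 * i - 2, 3 * i)
      if (cod %in% stops || grepl("N", cod, fixed = TRUE)) next
      counts[[cod]] <- (counts[[cod]] %||% 0) + 1
    }
  }
  fams <- split(names(code)[code != "*"], code[code != "*"])
  fams <- fams[vapply(fams, length, integer(1)) > 1]
  out <- numeric(0)
  for (fam in fams) {
    tot <- sum(vapply(fam, function(c) counts[[c]] %||% 0, numeric(1)))
    for (c in fam) {
      out[c] <- if (tot > 0) length(fam) * (counts[[c]] %||% 0) / tot else 0
    }
  }
  out[sort(names(out))]
}

# Brute-force six-frame ORF scan implementing the declared rule: per
# frame, ORFs run from the first permitted start after the previous stop
# to the next stop (inclusive); trailing startful segments are partial;
# candidates below min_length are dropped; then a candidate is removed
# iff it overlaps a strictly longer retained candidate by more than
# max_overlap nt.
oracle_orfs <- function(seq, min_length = 90, max_overlap = 60,
                        start_codons = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  cands <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (f in 0:2) {
      i <- f + 1
      start_at <- NA
      while (i + 2 <= L) {
        cod <- substr(s, i, i + 2)
        if (is.na(start_at) && cod %in% start_codons) start_at <- i
        if (cod %in% stops) {
          if (!is.na(start_at)) {
            cands[[length(cands) + 1]] <-
              list(beg = start_at, end = i + 2, strand = strand,
                   partial = FALSE)
          }
          start_at <- NA
        }
        i <- i + 3
      }
      if (!is.na(start_at) && (i - 1 - start_at + 1) >= 3) {
        cands[[length(cands) + 1]] <-
          list(beg = start_at, end = i - 1, strand = strand, partial = TRUE)
      }
    }
  }
  # to forward coordinates, length filter
  recs <- list()
  for (cd in cands) {
    len <- cd$end - cd$beg + 1
    if (len < min_length) next
    if (cd$strand == "+") {
      st <- cd$beg; en <- cd$end
    } else {
      st <- L - cd$end + 1; en <- L - cd$beg + 1
    }
    recs[[length(recs) + 1]] <- data.frame(
      start = st, end = en, strand = cd$strand, partial = cd$partial,
      len = len, stringsAsFactors = FALSE)
  }
  if (!length(recs)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), partial = logical(0)))
  }
  d <- do.call(rbind, recs)
  d <- d[order(-d$len, d$start, d$end, d$strand), , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(i - 1)) {
      if (i == 1) break
      if (!keep[j]) next
      ov <- min(d$end[i], d$end[j]) - max(d$start[i], d$start[j]) + 1
      if (ov > max_overlap && d$len[j] > d$len[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  d <- d[keep, c("start", "end", "strand", "partial")]
  d <- d[order(d$start, d$strand, d$end), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# A tiny two-genus assembly used by several taxonomy/extraction tests.
tiny_two_genus <- function(seed = 7, contamination = 0, n_hits = 10) {
  specs <- list(
    genome_spec("pa", make_lineage("Bacteria", "Proteobacteria",
                                   genus = "Pseudomonas",
                                   species = "Pseudomonas aeruginosa"),
                genome_length = 4e4, target_gc = 62, gene_density = 1.0,
                coverage = 30),
    genome_spec("se", make_lineage("Bacteria", "Proteobacteria",
                                   genus = "Serratia",
                                   species = "Serratia marcescens"),
                genome_length = 4e4, target_gc = 55, gene_density = 1.0,
                coverage = 10))
  mock_community(specs, fragment = TRUE, length_threshold = 2e4,
                 fragment_size = 2e4, n_hits = n_hits,
                 contamination = contamination, seed = seed)
}
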