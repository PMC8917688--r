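# Synthetic assemblies with planted ground truth. These generators let the
# whole pipeline run and be tested offline: genomes with controlled GC,
# codon bias, gene density and coverage; homology-hit tables with
# controlled lineages and identities; depth and marker-count tables.
#
# Spacers between planted genes are deliberately stop-dense (a cassette
# carrying stop codons in all six frames is inserted every <= 40 bp of
# random intergenic sequence) so that naive six-frame ORF calling recovers
# the planted gene count rather than spurious intergenic ORFs. Random
# intergenic bases have their GC chosen to compensate the coding and
# cassette composition, so the realized genome GC lands on target.

# Evaluate expr under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stop codons in all six frames within 16 bp.
STOP_CASSETTE <- "TAACTAACTAACTAAC"

#' Construct a lineage vector
#'
#' @param domain,phylum,class,order,family,genus,species Rank names;
#'   unspecified ranks default to `"unclassified"`.
#' @return Named character vector over the seven canonical ranks.
#' @export
make_lineage <- function(domain = "Bacteria", phylum = "unclassified",
                         class = "unclassified", order = "unclassified",
                         family = "unclassified", genus = "unclassified",
                         species = "unclassified") {
  stats::setNames(c(domain, phylum, class, order, family, genus, species),
                  TAX_RANKS)
}

#' Specify a synthetic genome
#'
#' @param name Genome name (used as contig-id prefix).
#' @param lineage Lineage vector ([make_lineage()]).
#' @param genome_length Genome length in bp.
#' @param target_gc Target GC percent, in (10, 90).
#' @param gene_density Planted genes per kbp, in (0, 1.2].
#' @param coverage Mean read depth assigned to the genome's contigs.
#' @param seed Integer seed; every generator is deterministic per
#'   (spec, seed).
#' @param codon_bias Optional named weight vector over sense codons that
#'   multiplies the GC-tilted default codon weights.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(name, lineage, genome_length = 1e5, target_gc = 50,
                        gene_density = 1.0, coverage = 20, seed = 1,
                        codon_bias = NULL) {
  if (target_gc <= 10 || target_gc >= 90) {
    stop_param("target_gc must be in (10, 90)")
  }
  if (gene_density <= 0 || gene_density > 1.2) {
    stop_param("gene_density must be in (0, 1.2]")
  }
  structure(list(name = name, lineage = lineage,
                 genome_length = as.integer(genome_length),
                 target_gc = target_gc, gene_density = gene_density,
                 coverage = coverage, seed = as.integer(seed),
                 codon_bias = codon_bias), class = "genome_spec")
}

sense_codons <- function() {
  code <- genetic_code_11()
  names(code)[code != "*"]
}

# GC-tilted codon weights: each G/C base multiplies the weight by
# (g/(1-g))^2, pushing coding GC toward the target.
gc_tilted_weights <- function(target_gc) {
  g <- target_gc / 100
  r <- (g / (1 - g))^2
  cods <- sense_codons()
  ngc <- vapply(strsplit(cods, ""), function(b) sum(b %in% c("G", "C")),
                integer(1))
  stats::setNames(r^ngc, cods)
}

spacer_seq <- function(len, p_gc) {
  if (len <= 0L) return("")
  pieces <- character(0)
  remaining <- len
  cassette_turn <- TRUE
  while (remaining > 0L) {
    if (cassette_turn) {
      take <- min(nchar(STOP_CASSETTE), remaining)
      pieces <- c(pieces, substr(STOP_CASSETTE, 1L, take))
    } else {
      take <- min(40L, remaining)
      pieces <- c(pieces, paste(sample(c("G", "C", "A", "T"), take,
                                       replace = TRUE,
                                       prob = c(p_gc / 2, p_gc / 2,
                                                (1 - p_gc) / 2,
                                                (1 - p_gc) / 2)),
                                collapse = ""))
    }
    remaining <- remaining - take
    cassette_turn <- !cassette_turn
  }
  paste(pieces, collapse = "")
}

#' Generate a synthetic genome with planted genes
#'
#' Deterministic per `(spec, spec$seed)`. Genes are placed at the planted
#' density on random strands; their codons are drawn from the spec's
#' (GC-tilted, optionally perturbed) codon bias; intergenic spacers are
#' stop-dense with compensating GC so the whole sequence realizes
#' `target_gc` within about two points.
#'
#' @param spec A [genome_spec()].
#' @return List with `contig` (one-row contig data frame, id
#'   `<name>_c1`), `genes` (truth data frame: `start`, `end`, `strand`)
#'   and `spec`.
#' @export
synth_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    L <- spec$genome_length
    n_genes <- max(1L, as.integer(round(spec$gene_density * L / 1000)))
    cods <- sense_codons()
    w <- gc_tilted_weights(spec$target_gc)
    w <- w * exp(stats::rnorm(length(w), 0, 0.25))  # genome-specific bias
    if (!is.null(spec$codon_bias)) {
      w[names(spec$codon_bias)] <- w[names(spec$codon_bias)] *
        spec$codon_bias
    }
    w <- w / sum(w)
    ncod <- pmin(pmax(as.integer(round(stats::rnorm(n_genes, 250, 70))),
                      80L), 450L)
    coding <- sum(3L * ncod + 6L)
    max_coding <- as.integer(0.90 * L) - 20L * (n_genes + 1L)
    if (coding > max_coding) {
      ncod <- pmax(80L, as.integer(ncod * max_coding / coding))
      coding <- sum(3L * ncod + 6L)
      if (coding > as.integer(0.95 * L)) {
        stop_param("infeasible gene density for this genome length")
      }
    }
    gene_seq <- vapply(ncod, function(n) {
      paste0("ATG",
             paste(sample(cods, n, replace = TRUE, prob = w), collapse = ""),
             sample(STOP_CODONS, 1L))
    }, character(1))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)

    total_sp <- L - coding
    n_sp <- n_genes + 1L
    if (total_sp < 20L * n_sp) stop_param("infeasible gene density")
    props <- stats::runif(n_sp, 0.5, 1.5)
    sp_len <- pmax(20L, as.integer(round(total_sp * props / sum(props))))
    sp_len[n_sp] <- total_sp - sum(sp_len[-n_sp])
    if (sp_len[n_sp] < 0L) {  # redistribute if rounding overshot
      sp_len <- rep(total_sp %/% n_sp, n_sp)
      sp_len[n_sp] <- total_sp - sum(sp_len[-n_sp])
    }

    # GC of fixed parts, then compensate via random spacer bases
    gene_gc <- sum(vapply(gene_seq, function(s)
      sum(strsplit(s, "")[[1L]] %in% c("G", "C")), numeric(1)))
    n_cassette_per <- vapply(sp_len, function(m) {
      # alternating 16 cassette / 40 random
      full <- m %/% 56L
      rem <- m %% 56L
      full * 16L + min(rem, 16L)
    }, integer(1))
    cass_total <- sum(n_cassette_per)
    cass_gc <- cass_total * 0.25
    rand_total <- total_sp - cass_total
    p <- if (rand_total > 0) {
      (spec$target_gc / 100 * L - gene_gc - cass_gc) / rand_total
    } else 0.5
    p <- min(0.98, max(0.02, p))

    pieces <- character(2L * n_genes + 1L)
    genes <- data.frame(start = integer(n_genes), end = integer(n_genes),
                        strand = strands, stringsAsFactors = FALSE)
    pos <- 0L
    for (i in seq_len(n_genes)) {
      sp <- spacer_seq(sp_len[i], p)
      pieces[2L * i - 1L] <- sp
      pos <- pos + nchar(sp)
      gs <- gene_seq[i]
      if (strands[i] == "-") gs <- revcomp(gs)
      pieces[2L * i] <- gs
      genes$start[i] <- pos + 1L
      genes$end[i] <- pos + nchar(gs)
      pos <- pos + nchar(gs)
    }
    pieces[2L * n_genes + 1L] <- spacer_seq(sp_len[n_sp], p)
    seqn <- paste(pieces, collapse = "")
    list(contig = data.frame(contig_id = paste0(spec$name, "_c1"),
                             description = spec$name,
                             sequence = seqn, stringsAsFactors = FALSE),
         genes = genes, spec = spec)
  })
}

DECOY_LINEAGE <- c("Bacteria", "Decoyphyla", "Decoyclassia", "Decoyales",
                   "Decoyaceae", "Decoygenus", "Decoygenus decoyi")

#' Synthesize a homology-hit table with planted lineages
#'
#' For every ORF, `n_hits` rows are generated: bitscores strictly
#' decreasing with rank, percent identities drawn from
#' `Normal(identity_mean, identity_sd)` (mildly decaying with rank,
#' clipped to `[20, 100]`), lineage equal to the ORF's source-genome
#' lineage except that each hit independently switches to
#' `decoy_lineage` with probability `contamination`. `hgt_orfs` plants
#' prokaryote-dominated hit profiles: for a named fraction `f`, exactly
#' `round(f * n_hits)` top-ranked hits of that ORF carry `hgt_lineage`.
#'
#' @param orfs ORF data frame.
#' @param lineage_for Named list/structure: contig id -> lineage vector
#'   (7 ranks), or a single lineage vector applied to all contigs.
#' @param n_hits Hits per ORF (default 20).
#' @param identity_mean,identity_sd Percent-identity distribution of the
#'   hits (defaults 85 and 5).
#' @param contamination Probability a hit carries the decoy lineage
#'   (default 0).
#' @param decoy_lineage Lineage for contaminating hits.
#' @param hgt_orfs Optional named numeric vector, orf id -> prokaryotic
#'   hit fraction to plant.
#' @param hgt_lineage Lineage planted for HGT-supporting hits.
#' @param seed Integer seed.
#' @param path Optional path; when given the table is also written in
#'   the `.blast` dialect.
#' @return Ranked hit data frame ([parse_hit_table()] layout).
#' @export
synth_hit_table <- function(orfs, lineage_for, n_hits = 20L,
                            identity_mean = 85, identity_sd = 5,
                            contamination = 0,
                            decoy_lineage = DECOY_LINEAGE,
                            hgt_orfs = NULL,
                            hgt_lineage = make_lineage(
                              "Bacteria", genus = "Hgtgenus",
                              species = "Hgtgenus transferens"),
                            seed = 1, path = NULL) {
  with_seed(seed, {
    n_orf <- nrow(orfs)
    rows <- vector("list", n_orf)
    for (i in seq_len(n_orf)) {
      oid <- orfs$orf_id[i]
      cid <- orfs$contig_id[i]
      lin <- if (is.list(lineage_for)) lineage_for[[cid]] else lineage_for
      if (is.null(lin)) {
        stop_param(sprintf("no lineage supplied for contig '%s'", cid))
      }
      r <- seq_len(n_hits)
      bits <- 500 - 3 * (r - 1)
      ev <- signif(10^(-bits / 10), 3)
      pid <- pmin(100, pmax(20, identity_mean - 0.1 * (r - 1) +
                              stats::rnorm(n_hits, 0, identity_sd)))
      linm <- matrix(rep(lin, n_hits), nrow = n_hits, byrow = TRUE)
      decoy <- stats::runif(n_hits) < contamination
      if (any(decoy)) {
        linm[decoy, ] <- matrix(rep(decoy_lineage, sum(decoy)),
                                ncol = 7, byrow = TRUE)
      }
      if (!is.null(hgt_orfs) && oid %in% names(hgt_orfs)) {
        k <- as.integer(round(hgt_orfs[[oid]] * n_hits))
        if (k > 0L) {
          linm[seq_len(k), ] <- matrix(rep(hgt_lineage, k),
                                       ncol = 7, byrow = TRUE)
        }
      }
      rows[[i]] <- data.frame(
        orf_id = oid, contig_id = cid,
        sseqid = paste0("ref_", oid, "_", r),
        pident = round(pid, 1), length = 3L * 50L,
        evalue = ev, bitscore = bits,
        stitle = paste0("hypothetical protein [", linm[, 6L], " sp.]"),
        stringsAsFactors = FALSE)
      lin_df <- as.data.frame(linm, stringsAsFactors = FALSE)
      names(lin_df) <- TAX_RANKS
      rows[[i]] <- cbind(rows[[i]], lin_df)
    }
    hits <- if (n_orf) do.call(rbind, rows) else empty_hit_frame()
    hits <- rank_hits(hits)
    if (!is.null(path)) write_tophits_file(hits, path, n = n_hits)
    hits
  })
}

#' Write a depth table in the MetaBAT summary dialect
#'
#' @param contigs Contig data frame.
#' @param depth Named numeric vector contig id -> mean depth.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_depth_table <- function(contigs, depth, path) {
  d <- data.frame(contigName = contigs$contig_id,
                  contigLen = nchar(contigs$sequence),
                  totalAvgDepth = unname(depth[contigs$contig_id]),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a synthetic mock community
#'
#' Concatenates synthetic genomes into one assembly, optionally
#' fragmenting long contigs; synthesizes the matching depth table,
#' marker-count table (every universal marker hit once per prokaryotic
#' genome) and homology-hit table for the ORFs called on the final
#' contigs; and records the contig-to-genome truth.
#'
#' @param specs List of [genome_spec()]s (unique names).
#' @param fragment Apply [fragment_contigs()] (default `FALSE`).
#' @param length_threshold,fragment_size Fragmentation parameters
#'   (defaults 1e6 / 1e5).
#' @param n_hits,identity_mean,identity_sd,contamination Passed to
#'   [synth_hit_table()].
#' @param seed Integer master seed (genome seeds derive from it unless a
#'   spec sets its own).
#' @param dir Optional directory: when given, writes `assembly.fna`,
#'   `depth.tsv`, `markers.tsv`, `hits.blast` and `truth.tsv` there.
#' @return List with `contigs`, `orfs`, `hits`, `depth`, `markers`,
#'   `truth` (contig id, genome, domain, lineage string) and `paths`
#'   (when `dir` given).
#' @export
mock_community <- function(specs, fragment = FALSE,
                           length_threshold = 1e6, fragment_size = 1e5,
                           n_hits = 20L, identity_mean = 85,
                           identity_sd = 5, contamination = 0,
                           seed = 1, dir = NULL) {
  names_ <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(names_)) stop_param("duplicate genome names in specs")
  genomes <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (is.null(sp$seed) || length(specs) > 1L) {
      sp$seed <- (seed * 131L + i * 7L) %% 2147483647L
    }
    genomes[[i]] <- synth_genome(sp)
  }
  contigs <- do.call(rbind, lapply(genomes, `[[`, "contig"))
  if (fragment) {
    contigs <- fragment_contigs(contigs, length_threshold, fragment_size)
  }
  genome_of <- function(cid) {
    hit <- names_[vapply(names_, function(nm)
      startsWith(cid, paste0(nm, "_c")), logical(1))]
    hit[1L]
  }
  truth <- data.frame(contig_id = contigs$contig_id,
                      genome = vapply(contigs$contig_id, genome_of,
                                      character(1), USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
  lin_by_genome <- stats::setNames(lapply(specs, `[[`, "lineage"), names_)
  truth$domain <- vapply(truth$genome, function(g) lin_by_genome[[g]][1L],
                         character(1), USE.NAMES = FALSE)
  truth$lineage <- vapply(truth$genome, function(g)
    paste(lin_by_genome[[g]], collapse = ";"), character(1),
    USE.NAMES = FALSE)

  orfs <- find_orfs_assembly(contigs)
  lineage_for <- stats::setNames(
    lapply(truth$contig_id, function(cid)
      lin_by_genome[[truth$genome[truth$contig_id == cid]]]),
    truth$contig_id)
  hits <- synth_hit_table(orfs, lineage_for, n_hits = n_hits,
                          identity_mean = identity_mean,
                          identity_sd = identity_sd,
                          contamination = contamination,
                          seed = (seed * 977L + 13L) %% 2147483647L)
  cov_by_genome <- stats::setNames(vapply(specs, `[[`, numeric(1),
                                          "coverage"), names_)
  depth <- stats::setNames(unname(cov_by_genome[truth$genome]),
                           truth$contig_id)
  n_prok <- sum(vapply(specs, function(s)
    s$lineage[1L] %in% c("Bacteria", "Archaea"), logical(1)))
  markers <- stats::setNames(rep(as.integer(n_prok), 16L),
                             universal_markers())

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      assembly = file.path(dir, "assembly.fna"),
      depth = file.path(dir, "depth.tsv"),
      markers = file.path(dir, "markers.tsv"),
      hits = file.path(dir, "hits.blast"),
      truth = file.path(dir, "truth.tsv"))
    write_fasta(contigs, paths$assembly)
    write_depth_table(contigs, depth, paths$depth)
    utils::write.table(
      data.frame(marker = names(markers), count = unname(markers)),
      paths$markers, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    write_tophits_file(hits, paths$hits, n = n_hits)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(contigs = contigs, orfs = orfs, hits = hits, depth = depth,
       markers = markers, truth = truth, paths = paths)
}

#' Synthetic eukaryotic assembly with one planted HGT
#'
#' One eukaryote-style genome (sparse gene calls); every ORF receives
#' eukaryotic homologs except one planted ORF whose top hits are
#' `fraction` prokaryotic.
#'
#' @param seed Integer seed.
#' @param fraction Prokaryotic hit fraction of the planted ORF
#'   (default 0.6).
#' @param n_hits Hits per ORF (default 100).
#' @param genome_length Genome length (default 7e4).
#' @return List with `contigs`, `orfs`, `hits`, `planted_orf` (the orf
#'   id) and `lineage`.
#' @export
synth_hgt_assembly <- function(seed = 1, fraction = 0.6, n_hits = 100L,
                               genome_length = 7e4) {
  lin <- make_lineage("Eukaryota", genus = "Hostgenus",
                      species = "Hostgenus hospes")
  sp <- genome_spec("euk", lin, genome_length = genome_length,
                    target_gc = 42, gene_density = 0.35, coverage = 12,
                    seed = seed)
  g <- synth_genome(sp)
  orfs <- find_orfs(g$contig)
  if (nrow(orfs) < 2L) stop_param("fixture genome produced too few ORFs")
  planted <- orfs$orf_id[min(5L, nrow(orfs))]
  hits <- synth_hit_table(
    orfs, lin, n_hits = n_hits, identity_mean = 70, identity_sd = 6,
    hgt_orfs = stats::setNames(fraction, planted),
    seed = (seed * 31L + 5L) %% 2147483647L)
  list(contigs = g$contig, orfs = orfs, hits = hits,
       planted_orf = planted, lineage = lin)
}
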