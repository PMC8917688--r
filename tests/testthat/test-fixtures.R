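test_that("genome synthesis is deterministic and hits its GC target", {
  lin <- make_lineage("Bacteria", genus = "G")
  sp <- genome_spec("g", lin, genome_length = 1e5, target_gc = 60,
                    gene_density = 1.0, coverage = 5, seed = 1)
  g1 <- synth_genome(sp)
  g2 <- synth_genome(sp)
  expect_identical(g1$contig$sequence, g2$contig$sequence)
  expect_equal(nchar(g1$contig$sequence), 1e5)
  gc <- gc_content(g1$contig$sequence)
  expect_gte(gc, 58)
  expect_lte(gc, 62)

  # 50 kb at density 1.0 plants 50 genes
  sp50 <- genome_spec("h", lin, genome_length = 5e4, target_gc = 45,
                      gene_density = 1.0, coverage = 5, seed = 2)
  g50 <- synth_genome(sp50)
  expect_equal(nrow(g50$genes), 50L)

  expect_error(genome_spec("x", lin, target_gc = 95),
               class = "contigsift_parameter_error")
  expect_error(genome_spec("x", lin, gene_density = 2),
               class = "contigsift_parameter_error")
})

test_that("planted genes carry valid structure", {
  sp <- genome_spec("g", make_lineage("Archaea", genus = "A"),
                    genome_length = 4e4, target_gc = 40,
                    gene_density = 0.8, coverage = 5, seed = 3)
  g <- synth_genome(sp)
  for (i in seq_len(nrow(g$genes))) {
    dna <- substr(g$contig$sequence, g$genes$start[i], g$genes$end[i])
    if (g$genes$strand[i] == "-") dna <- oracle_revcomp(dna)
    expect_equal(substr(dna, 1, 3), "ATG")
    expect_true(substr(dna, nchar(dna) - 2, nchar(dna)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_false(grepl("\\*", translate_dna(dna)))
  }
})

test_that("hit tables plant the requested lineages and contamination", {
  fx <- synth_hgt_assembly(seed = 5, fraction = 0.6, n_hits = 20)
  orfs <- fx$orfs[1:4, ]
  lin <- make_lineage("Bacteria", genus = "TrueG", species = "TrueG sp")
  h0 <- synth_hit_table(orfs, lin, n_hits = 10, contamination = 0, seed = 9)
  expect_true(all(h0$genus == "TrueG"))
  expect_true(all(tapply(h0$rank, h0$orf_id, max) == 10))
  expect_true(all(h0$pident >= 20 & h0$pident <= 100))

  # binomial check on the decoy fraction at a fixed seed
  h3 <- synth_hit_table(orfs, lin, n_hits = 100, contamination = 0.3,
                        seed = 10)
  frac <- mean(h3$genus == "Decoygenus")
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.4)

  # determinism and file round-trip
  f <- withr::local_tempfile(fileext = ".blast")
  h1 <- synth_hit_table(orfs, lin, n_hits = 5, seed = 11, path = f)
  h2 <- synth_hit_table(orfs, lin, n_hits = 5, seed = 11)
  expect_equal(h1, h2)
  back <- parse_hit_table(f)
  expect_equal(back$orf_id, h1$orf_id)
  expect_equal(back$bitscore, h1$bitscore)
  expect_equal(back$species, h1$species)
})

test_that("mock communities keep truth bookkeeping through fragmentation", {
  specs <- list(
    genome_spec("g1", make_lineage("Bacteria", genus = "G1"), 5e4, 35, 1.0, 8),
    genome_spec("g2", make_lineage("Bacteria", genus = "G2"), 5e4, 55, 1.0, 4),
    genome_spec("g3", make_lineage("Archaea", genus = "G3"), 5e4, 45, 1.0, 2),
    genome_spec("ge", make_lineage("Eukaryota", genus = "GE"), 5e4, 40, 0.1, 1))
  dir <- withr::local_tempdir()
  mc <- mock_community(specs, fragment = TRUE, length_threshold = 25e3,
                       fragment_size = 25e3, n_hits = 3, seed = 2, dir = dir)
  expect_equal(nrow(mc$contigs), 8L)
  expect_setequal(unique(mc$truth$genome), c("g1", "g2", "g3", "ge"))
  expect_true(all(table(mc$truth$genome) == 2))
  # markers: one hit per prokaryote genome (3 of the 4)
  expect_equal(unname(mc$markers), rep(3L, 16))
  expect_equal(estimate_k(mc$markers), 3L)
  # written artifacts parse back
  expect_equal(read_fasta(dir1 <- mc$paths$assembly)$contig_id,
               mc$contigs$contig_id)
  expect_equal(read_depth_table(mc$paths$depth)[mc$contigs$contig_id],
               mc$depth[mc$contigs$contig_id])
  expect_equal(parse_marker_counts(mc$paths$markers), mc$markers)
  back <- parse_hit_table(mc$paths$hits)
  expect_equal(nrow(back), nrow(mc$hits))

  expect_error(mock_community(specs[c(1, 1)]),
               class = "contigsift_parameter_error")
})

test_that("the eukaryote-like genome is separable by the domain recipe", {
  specs <- list(
    genome_spec("bac", make_lineage("Bacteria", genus = "B"), 6e4, 60, 1.0, 8),
    genome_spec("euk", make_lineage("Eukaryota", genus = "E"), 6e4, 40, 0.1, 2))
  mc <- mock_community(specs, n_hits = 5, seed = 4)
  x <- profile_contigs(mc$contigs, mc$hits)
  sel <- select_contigs(x, extraction_criteria(
    taxon = "Eukaryota", rank = "domain", gc_max = 50, density_max = 0.5))
  truth <- setNames(mc$truth$genome, mc$truth$contig_id)
  expect_setequal(sel$matched, names(truth)[truth == "euk"])
})
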