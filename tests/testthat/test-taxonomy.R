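hit_line <- function(orf, sbj, pid, bits, lineage,
                     title = "hypothetical protein", ev = "1e-80") {
  paste(orf, sbj, pid, 210, ev, bits, title, lineage, sep = "\t")
}

test_that("hit tables parse with lineage padding and rank ordering", {
  f <- withr::local_tempfile(fileext = ".blast")
  writeLines(c(
    hit_line("c1_1", "WP_1", 92.3, 400,
             "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas;Pseudomonas aeruginosa"),
    hit_line("c1_1", "WP_2", 80.0, 500, "Bacteria;Proteobacteria"),
    hit_line("c1_2", "WP_3", 70.0, 300, "Eukaryota")), f)
  h <- parse_hit_table(f)
  expect_equal(nrow(h), 3L)
  h1 <- h[h$orf_id == "c1_1", ]
  expect_equal(h1$bitscore[h1$rank == 1], 500)  # bitscore wins
  expect_equal(h1$genus[h1$rank == 1], "unclassified")  # padded
  expect_equal(h1$genus[h1$rank == 2], "Pseudomonas")
  expect_equal(h$contig_id, rep("c1", 3))
})

test_that("ties break by e-value then input order", {
  f <- withr::local_tempfile(fileext = ".blast")
  writeLines(c(
    hit_line("c1_1", "A", 90, 400, "Bacteria", ev = "1e-50"),
    hit_line("c1_1", "B", 90, 400, "Bacteria", ev = "1e-60"),
    hit_line("c1_1", "C", 90, 400, "Bacteria", ev = "1e-60")), f)
  h <- parse_hit_table(f)
  expect_equal(h$sseqid[order(h$rank)], c("B", "C", "A"))
})

test_that("malformed hit tables fail with line numbers", {
  f <- withr::local_tempfile(fileext = ".blast")
  writeLines(c(hit_line("c1_1", "A", 90, 400, "Bacteria"),
               "c1_1\tonly\tthree"), f)
  expect_error(parse_hit_table(f), "line 2",
               class = "contigsift_format_error")
  writeLines(hit_line("c1_1", "A", "NaNope", 400, "Bacteria"), f)
  expect_error(parse_hit_table(f), "pident",
               class = "contigsift_format_error")
  expect_error(parse_hit_table(file.path(tempdir(), "gone.blast")),
               class = "contigsift_input_error")
})

test_that("top_hits truncates per ORF and is idempotent", {
  mc <- tiny_two_genus(n_hits = 10)
  t3 <- top_hits(mc$hits, 3)
  expect_true(all(tapply(t3$rank, t3$orf_id, max) == 3))
  expect_equal(top_hits(t3, 3), t3)
  few <- top_hits(mc$hits[mc$hits$rank <= 2, ], 100)
  expect_true(all(tapply(few$rank, few$orf_id, length) == 2))
  expect_error(top_hits(mc$hits, 0), class = "contigsift_parameter_error")
})

test_that("contig summaries count top hits per hit-bearing ORF", {
  orfs <- data.frame(orf_id = paste0("c1_", 1:6), contig_id = "c1",
                     partial = FALSE, stringsAsFactors = FALSE)
  lin <- function(g) paste(c("Bacteria", rep("unclassified", 4), g,
                             paste(g, "sp.")), collapse = ";")
  f <- withr::local_tempfile()
  writeLines(c(
    vapply(1:3, function(i) hit_line(paste0("c1_", i), "s", 90, 100,
                                     lin("Pseudomonas")), character(1)),
    vapply(4:5, function(i) hit_line(paste0("c1_", i), "s", 80, 100,
                                     lin("Serratia")), character(1))), f)
  s <- summarize_contig(orfs, parse_hit_table(f))
  expect_equal(s$n_orfs_with_hits, 5L)
  expect_equal(s$n_orfs_without_hits, 1L)
  expect_equal(s$fractions$genus,
               c(Pseudomonas = 0.6, Serratia = 0.4))
  expect_equal(s$mean_aai, (3 * 90 + 2 * 80) / 5)
  # fractions sum to 1 at every rank
  for (r in names(s$fractions)) expect_equal(sum(s$fractions[[r]]), 1)
})

test_that("contigs without hits summarize to missing AAI", {
  orfs <- data.frame(orf_id = "c9_1", contig_id = "c9", partial = FALSE,
                     stringsAsFactors = FALSE)
  s <- summarize_contig(orfs, contigsift:::empty_hit_frame())
  expect_true(is.na(s$mean_aai))
  expect_length(s$fractions$genus, 0)
  expect_false(classify_contig(s, "Pseudomonas", "genus"))
})

test_that("classification uses a strict majority threshold", {
  orfs <- data.frame(orf_id = paste0("c1_", 1:4), contig_id = "c1",
                     partial = FALSE, stringsAsFactors = FALSE)
  lin <- function(g) paste(c("Bacteria", rep("unclassified", 4), g, "sp"),
                           collapse = ";")
  f <- withr::local_tempfile()
  writeLines(c(hit_line("c1_1", "s", 90, 100, lin("Pseudomonas")),
               hit_line("c1_2", "s", 90, 100, lin("Pseudomonas")),
               hit_line("c1_3", "s", 90, 100, lin("Serratia")),
               hit_line("c1_4", "s", 90, 100, lin("Serratia"))), f)
  s <- summarize_contig(orfs, parse_hit_table(f))
  expect_false(classify_contig(s, "Pseudomonas", "genus", perc = 50))
  expect_true(classify_contig(s, "Pseudomonas", "genus", perc = 49))
  expect_true(classify_contig(s, "PSEUDOMONAS", "genus", perc = 49))
  expect_error(classify_contig(s, "Pseudomonas", "tribe"),
               class = "contigsift_parameter_error")
  # monotone in perc
  percs <- c(10, 30, 49, 50, 75, 100)
  res <- vapply(percs, function(p)
    classify_contig(s, "Pseudomonas", "genus", perc = p), logical(1))
  expect_true(all(diff(as.integer(res)) <= 0))
})

test_that("phage semantics require a viral domain plus a taxon token", {
  orfs <- data.frame(orf_id = paste0("c1_", 1:2), contig_id = "c1",
                     partial = FALSE, stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  writeLines(c(
    hit_line("c1_1", "s", 90, 100, "Viruses;Caudovirales",
             title = "portal protein, Bacillus phage SPP1"),
    hit_line("c1_2", "s", 90, 100,
             "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus;Bacillus subtilis")), f)
  s <- summarize_contig(orfs, parse_hit_table(f))
  # plain genus vote: only the non-viral hit carries genus Bacillus
  expect_false(classify_contig(s, "Bacillus", "genus", perc = 50))
  # phage vote: only the viral hit with the Bacillus token counts (1/2)
  expect_false(classify_contig(s, "Bacillus", "genus", perc = 50,
                               phage = TRUE))
  expect_true(classify_contig(s, "Bacillus", "genus", perc = 49,
                              phage = TRUE))
})

test_that("writing then parsing a hit table is the identity on ranked hits", {
  mc <- tiny_two_genus(n_hits = 5)
  f <- withr::local_tempfile(fileext = ".blast")
  write_tophits_file(mc$hits, f, n = 5)
  back <- parse_hit_table(f)
  expect_equal(back$orf_id, mc$hits$orf_id)
  expect_equal(back$rank, mc$hits$rank)
  expect_equal(back$sseqid, mc$hits$sseqid)
  expect_equal(back$pident, mc$hits$pident)
  expect_equal(back$genus, mc$hits$genus)
})
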