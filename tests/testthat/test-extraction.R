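test_that("criteria objects validate their inputs", {
  expect_error(extraction_criteria(), class = "contigsift_parameter_error")
  expect_error(extraction_criteria(gc_min = 60, gc_max = 50),
               class = "contigsift_parameter_error")
  expect_error(extraction_criteria(taxon = "X", rank = "tribe"),
               class = "contigsift_parameter_error")
  expect_s3_class(extraction_criteria(gc_max = 50), "extraction_criteria")
})

test_that("selection partitions the assembly under conjunctive criteria", {
  mc <- tiny_two_genus()
  x <- profile_contigs(mc$contigs, mc$hits, depth = mc$depth)
  sel <- select_contigs(x, extraction_criteria(taxon = "Pseudomonas",
                                               rank = "genus", perc = 50))
  truth <- setNames(mc$truth$genome, mc$truth$contig_id)
  expect_setequal(sel$matched, names(truth)[truth == "pa"])
  expect_setequal(sel$unmatched, names(truth)[truth == "se"])
  expect_length(intersect(sel$matched, sel$unmatched), 0)
  expect_setequal(c(sel$matched, sel$unmatched), x$profiles$contig_id)

  # numeric bounds are inclusive
  gcs <- x$profiles$gc
  at_max <- max(gcs)
  sel2 <- select_contigs(x, extraction_criteria(gc_max = at_max))
  expect_length(sel2$unmatched, 0)
  sel3 <- select_contigs(x, extraction_criteria(gc_min = at_max))
  expect_true(x$profiles$contig_id[which.max(gcs)] %in% sel3$matched)

  # conjunction: genus AND an impossible coverage bound
  sel4 <- select_contigs(x, extraction_criteria(
    taxon = "Pseudomonas", rank = "genus", coverage_min = 1e6))
  expect_length(sel4$matched, 0)
})

test_that("coverage criteria require a depth table", {
  mc <- tiny_two_genus()
  x <- profile_contigs(mc$contigs, mc$hits)  # no depth
  expect_error(select_contigs(x, extraction_criteria(coverage_min = 5)),
               class = "contigsift_parameter_error")
})

test_that("raising perc shrinks (never grows) the matched set", {
  mc <- tiny_two_genus(contamination = 0.35)
  x <- profile_contigs(mc$contigs, mc$hits)
  prev <- NULL
  for (p in c(10, 30, 50, 70, 90)) {
    sel <- select_contigs(x, extraction_criteria(taxon = "Pseudomonas",
                                                 rank = "genus", perc = p))
    if (!is.null(prev)) expect_true(all(sel$matched %in% prev))
    prev <- sel$matched
  }
})

test_that("main report has fixed columns, NA markers, and is deterministic", {
  mc <- tiny_two_genus()
  x <- profile_contigs(mc$contigs, mc$hits)  # no depth -> coverage NA
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_main_report(x, f1)
  write_main_report(x, f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- read.csv(f1, stringsAsFactors = FALSE)
  expect_equal(names(tab),
               c("contig", "length", "gc", "coding_density", "mean_aai",
                 "coverage", "cluster", "n_orfs", "n_orfs_with_hits",
                 "top_hit_taxa"))
  expect_equal(nrow(tab), nrow(mc$contigs))
  expect_true(all(is.na(tab$coverage)))
  expect_true(all(is.na(tab$cluster)))
  # zero-ORF contigs still get a row
  x2 <- profile_contigs(rbind(mc$contigs, contig_df("bare", strrep("C", 120))),
                        mc$hits)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_main_report(x2, f3)
  tab3 <- read.csv(f3, stringsAsFactors = FALSE)
  expect_true("bare" %in% tab3$contig)
  expect_equal(tab3$n_orfs[tab3$contig == "bare"], 0L)
})

test_that("top-hits file truncates to n and round-trips", {
  mc <- tiny_two_genus(n_hits = 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tophits_file(mc$hits, f, n = 2)
  back <- parse_hit_table(f)
  expect_true(all(tapply(back$rank, back$orf_id, max) == 2))
  write_tophits_file(mc$hits, f, n = 1)
  back1 <- parse_hit_table(f)
  expect_equal(nrow(back1), length(unique(mc$hits$orf_id)))
})

test_that("word frequencies follow the coverage weighting rule", {
  orfs <- data.frame(orf_id = c("a_1", "b_1"), contig_id = c("a", "b"),
                     partial = FALSE, stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  writeLines(c(
    "a_1\ts\t90\t100\t1e-50\t100\tp\tBacteria;p;c;o;f;GenA;GenA sp",
    "b_1\ts\t90\t100\t1e-50\t100\tp\tBacteria;p;c;o;f;GenB;GenB sp"), f)
  hits <- parse_hit_table(f)
  contigs <- rbind(contig_df("a", strrep("ACGT", 30)),
                   contig_df("b", strrep("ACGT", 30)))
  x <- profile_contigs(contigs, hits, orfs = orfs,
                       depth = c(a = 10, b = 30))
  wf <- word_frequency_table(x, rank = "genus")
  expect_equal(wf[["GenA"]], 0.25)
  expect_equal(wf[["GenB"]], 0.75)
  expect_equal(sum(wf), 1)
  wf0 <- word_frequency_table(x, rank = "genus", use_coverage = FALSE)
  expect_equal(unname(wf0[c("GenA", "GenB")]), c(0.5, 0.5))
})
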