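---
title: "Profiling, partitioning and screening assembly contigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling, partitioning and screening assembly contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigsift)
```

## The problem

An assembly — an isolate genome with suspected contamination, a
metagenome, a host genome with bacterial symbiont reads mixed in — is a
bag of contigs of unknown provenance. Before any downstream analysis one
wants a quick, per-contig answer to "what is this sequence, roughly, and
does it belong here?". contigsift answers that by combining two
independent kinds of evidence for every contig:

* **homology**: the taxonomic affiliation of the top hit of each
  predicted ORF against a reference protein database, consumed here as a
  pre-computed tabular hit file with lineages already resolved;
* **composition**: GC content, coding density, canonical
  tetranucleotide frequencies (TNF) and relative synonymous codon usage
  (RSCU), which require no database at all.

On top of the per-contig profile the package supports three derived
operations: composition-based putative binning, threshold-based
extraction of contigs into matched/unmatched FASTA subsets, and
screening of eukaryotic contigs for candidate horizontal gene transfers
(HGT) of prokaryotic origin.

## The per-contig metrics

**Mean AAI.** For each contig, the arithmetic mean of the percent
identities of its ORFs' top hits (one hit per ORF — the closest known
relative). Low AAI flags organisms poorly represented in the reference,
not necessarily contamination.

**Coding density.** Called genes per kilobase. Prokaryotic contigs run
near 1 gene/kbp; eukaryotic contigs called with a prokaryote-style gene
finder fall far below, which is precisely what makes density a cheap
domain discriminator — the gene caller's eukaryotic weakness is used as
signal, and 0.5 genes/kbp is the conventional ceiling when selecting
eukaryotic contigs.

**GC content.** Computed over unambiguous bases only; an all-`N` contig
reports a missing value rather than zero.

**Canonical TNF.** All 4-mers in a sliding window (step 1, `N`-containing
windows skipped), folded onto the lexicographically smaller of each
4-mer and its reverse complement: 136 classes (16 palindromic, 120
paired), normalized to sum to 1. Folding makes the signature
strand-agnostic, as in standard binners.

**RSCU.** With `count(c)` the pooled coding-strand codon count over the
contig's complete ORFs, `k` the synonymous family size and `T` the
family total,

$$\mathrm{RSCU}(c) = k \cdot \frac{\mathrm{count}(c)}{T},$$

zero for whole unobserved families; stop codons and the single-codon
families (ATG, TGG) are excluded, giving 59 features. RSCU is scale-free
across contigs with different gene counts, which is why it was chosen as
the codon-usage-bias statistic; note this is an explicit choice, so
numeric values need not match tools that use a different bias measure.
Within every observed family the mean RSCU over its $k$ codons is
exactly 1 — the test suite asserts this invariant.

## Majority-vote classification

A contig is classified as taxon $t$ at rank $r$ when strictly more than
`perc` percent (default 50) of its *hit-bearing* ORFs carry $t$ in their
top hit at rank $r$. Two deliberate decisions:

* ORFs with no database hit are excluded from the denominator (they are
  counted and reported separately); an unknown protein should not vote
  against a classification.
* The inequality is strict, so a 50/50 contig is *not* classified at
  `perc = 50` — thresholds read as "more than".

Classification is monotone in `perc` by construction: raising the
threshold can only shrink the matched set. Phage extraction uses relaxed
matching: a top hit counts when its domain is `Viruses` *and* the taxon
token appears in the subject title or lineage, since phage reference
proteins typically carry their host genus only in free text.

## Putative binning

The number of clusters is not tuned: it is estimated from single-copy
marker-gene hit counts. Each of the 16 universal ribosomal-protein
markers is expected once per genome, so

$$\hat k = \max\!\left(1,\ \left\lfloor \overline{c} + 0.5 \right\rfloor\right)$$

with $\overline{c}$ the mean hit count over the whole marker set,
zero-hit markers included. Half-up rounding is an explicit choice (the
convention is otherwise unstated in the literature this follows); the
floor of 1 covers marker-free assemblies.

Contigs at least 2,000 bp long with at least one complete ORF enter a
feature matrix of 136 TNF + 59 RSCU columns, each standardized to mean
0 / sd 1 (constant columns dropped); 2 kb is standard binning practice —
shorter contigs have noisy TNF. Clustering is agglomerative with Ward
linkage on Euclidean distance (`hclust` method `ward.D2`), cut to
exactly $\hat k$ clusters; `complete` and `average` linkage are
available as options. Coverage and GC are deliberately *not* clustering
features — bins are purely compositional, and coverage stays available
as an independent check on them. Contigs excluded from clustering still
appear in the report with an empty cluster field.

## HGT screening

For each ORF on each *eukaryotic* contig, the top `n` (default 100)
ranked hits are examined; the ORF is flagged when strictly more than
`perc` percent (default 50) are to bacterial or archaeal proteins. The
two prokaryotic domains are pooled — a transfer of archaeal origin is
just as interesting and the evidence rarely distinguishes them cleanly.
Viral hits count in the denominator but not the numerator. A contig is
deemed eukaryotic by the same strict majority rule applied to the domain
rank of top hits, optionally AND-ed with a coding-density ceiling
(0.5 genes/kbp mirrors the eukaryote extraction recipe). This screen
requires a reference spanning all domains of life and is only a
candidate generator: flagged ORFs warrant genomic-context and
phylogenetic follow-up, never direct interpretation.

## The built-in ORF finder

The package ships a deterministic six-frame ORF finder so that it is
self-contained; users with real gene calls import them via
`import_gene_calls()` (GFF3 + protein FASTA). Within each frame an ORF
runs from the first permitted start codon (ATG/GTG/TTG) after the
previous stop to the next stop, inclusive; ORFs shorter than 90 nt
(a common prokaryotic floor, 30 codons including the stop) are dropped;
ORFs that reach the contig edge without a stop are emitted with a
`partial` flag and count toward density. Translation uses the
bacterial/archaeal code (table 11), `N`-containing codons render `X`.

Raw six-frame calling over-counts badly: antisense "shadow" ORFs inside
real genes and chance ORFs in intergenic sequence would inflate coding
density several-fold, destroying its value as a domain discriminator. A
deterministic overlap-resolution step therefore removes any candidate
that overlaps a *strictly longer* retained ORF by more than 60 nt
(either strand). Equal-length overlapping candidates are always both
kept, which preserves exact symmetry under reverse complementation, and
the 60 nt allowance keeps the short opposite-strand overlaps common
between adjacent prokaryotic genes. The test suite checks the whole rule
against an independently written brute-force scanner and checks that
measured density recovers planted density within 20%.

## The synthetic-data generator

`synth_genome()` plants genes at a chosen density: codons are drawn from
a GC-tilted, per-genome-perturbed codon bias; strands are random; ORF
structure is valid (start, stop, no internal stops). Intergenic spacers
are built from random bases interleaved with a short cassette carrying
stop codons in all six reading frames (every ≤ 40 bp of random
sequence), and the random bases' GC is solved so that the whole genome
realizes its target GC (the contract, asserted in tests, is ±2 points).
`synth_hit_table()` fabricates ranked homology hits with controlled
identity, lineage, contamination fraction and planted HGT profiles;
`mock_community()` wires genomes, fragmentation, depth, marker counts
and hits into a complete file set with truth tables.

What the generator does **not** emulate: sequencing and assembly error,
repeats, mobile elements, strain microdiversity, real intergenic
sequence (real spacers are not stop-seeded — that choice exists so the
naive ORF caller's output matches the planted truth), real codon-usage
phylogeny, or hit tables produced by an actual aligner against a real
database. Green tests therefore demonstrate the *machinery* — parsing,
metrics, rules, determinism, recovery of planted structure under clean
conditions — not field performance on real assemblies.

## Numerical and interface choices

* All majority thresholds are strict (`>`); all numeric range bounds in
  extraction criteria are inclusive (`≥`/`≤`), so "maximum GC 50%"
  admits exactly 50.
* Hit ranking ties break by bitscore, then e-value, then input order —
  outputs are deterministic and reruns from a saved hit table are
  byte-identical to the original run.
* Fragmentation splits only contigs *strictly* longer than the
  threshold (default 1 Mb) into fixed pieces (default 100 kb) plus a
  kept remainder; concatenating fragments reproduces the original
  exactly.
* Non-ACGTN characters are coerced to `N` on FASTA ingest (with a
  warning count) rather than rejected, so assemblies with IUPAC codes
  load.
* Contigs with no hit-bearing ORFs are never classified, never
  eukaryotic, and report missing AAI rather than 0.

## Problem sizes in the shipped tests

The suite and the acceptance script run on communities of 2–4 genomes of
40–150 kb (fragmented to 20–50 kb), 10–100 hits per ORF, and 100-replicate
random-sequence oracle sweeps — sizes chosen so planted structure is
comfortably recoverable and the whole suite runs in about a minute while
still exercising every code path end to end.

## Known limitations

* The ORF finder is not a trained gene caller; its coordinates shift
  upstream when a spurious in-frame start precedes the true one, and it
  should be replaced by imported Prodigal calls for real analyses.
* Lineages must arrive pre-resolved in the hit table; there is no
  taxonomy-database handling.
* Binning is composition-only and unsuitable for closely related
  genomes of similar GC/codon usage; no completeness or contamination
  scoring is performed — bin quality assessment belongs to dedicated
  tools.
* HGT calls are statistical candidates from hit-taxonomy distributions
  only.
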