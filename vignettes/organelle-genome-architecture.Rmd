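---
title: "Dissecting organelle genome architecture with organellarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting organelle genome architecture with organellarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organellarch)
```

## Scope and model

Chlamydomonadalean green algae carry some of the most inflated organelle
genomes known: circular-mapping mitochondrial and plastid DNAs in which more
than half of the sequence is noncoding, intron densities are extreme, and
the noncoding fraction is structured — a large inverted repeat dividing the
plastid genome into quadripartite regions, AT-rich dispersed repeat
families, and clusters of palindromic (hairpin-forming) elements punctuating
intergenic mitochondrial DNA. `organellarch` implements the computational
workflow for dissecting such genomes end to end:

1. **Assembly from a trace archive** (`recruit_traces()`, `assemble()`,
   `walk()`, `detect_circularity()`) — mining organelle reads out of a mixed
   whole-genome shotgun archive by bait similarity, assembling them by
   greedy overlap-layout-consensus, walking the archive to extend contigs,
   and closing the circle.
2. **Annotation-driven accounting** (`partition_genome()`, `gc_content()`,
   `gc_by_category()`, `gc_by_codon_position()`, `cumulative_gc_skew()`,
   `intron_gene_ratio()`, `gene_inventory()`, `gene_set_compare()`).
3. **Structural dissection** (`find_inverted_repeat()`,
   `partition_quadripartite()`, `find_maximal_repeats()`,
   `cluster_repeats()`, `dotplot()`, `find_hairpins()`,
   `cluster_hairpins()`, `build_consensus()`, `loop_motif_tally()`).
4. **A synthetic-genome simulator** (`generate_genome()`,
   `shred_traces()`) that plants all of the above with known truth, so
   every analysis can be validated as a round trip against its generator.

## The coding/noncoding accounting

The accounting rests on four interlocking, annotation-driven definitions:

* **coding** — the union length of annotated protein-, rRNA- and
  tRNA-coding regions, excluding positions that are also annotated as
  introns. Intronic ORFs (maturase/endonuclease-like frames inside group-I
  and group-II introns) count with the introns, not the coding total, and
  pseudogenes are excluded entirely.
* **noncoding** — genome length minus coding.
* **intergenic** — genome length minus the union length of gene regions
  (gene spans including their introns and intronic ORFs).
* **intronic** — noncoding minus intergenic.

Both conservation identities (`coding + noncoding = length`,
`intergenic + intronic = noncoding`) hold by construction, and the
implementation (interval arithmetic on `IRanges`) is tested against an
independent per-position classifier on every random genome in the suite.
Two consequences of taking the definitions literally are worth noting:
a free-standing *intergenic intron* (an intron-like element located between
genes) falls in the intergenic class, because it belongs to no gene region;
and pseudogene positions are intergenic, because a pseudogene is not a
coding region and not a gene. Positions inside a gene span that are neither
coding nor annotated intron (rare in practice) land in the intronic class
by arithmetic.

```{r toy}
tf <- toy_fixture()
partition_genome(tf$genome)
```

Coordinates are 1-based inclusive throughout — the shared convention of
GenBank and the Bioconductor interval stack — so feature locations pass
through `read_genbank()` unchanged, and only the BED writer converts (to
0-based half-open) at its boundary. A feature part crossing the origin of a
circular genome is kept as a single wrapping interval and never silently
linearized; every statistic in the package is invariant under rotation of a
circular genome, which the suite asserts.

## Composition statistics

GC content is `(G+C)/(A+C+G+T)` with `N` excluded from both numerator and
denominator. Codon-position GC pools all spliced, strand-resolved,
frame-corrected protein-coding sequence and tallies sites 1/2/3. Cumulative
GC-skew — used to locate replication origins and shifts of transcriptional
polarity — is the running sum of per-window `(G-C)/(G+C)`. No single
convention for window size exists in the literature, so it is a parameter:
the default is a 1-kb window and 1-kb step, which resolves the gene-cluster
scale of a 28-kb mitochondrial genome without letting single-window noise
dominate; a window with `G+C = 0` contributes skew 0.

The intron/gene ratio divides annotated intron count by gene count. The
defaults keep inverted-repeat duplicates (both copies of a duplicated gene
or intron count) and include intergenic introns, because that is the
convention under which the headline ratios of inflated plastid genomes are
quoted; both choices are flags. Genes fragmented into coding modules (e.g.
an rRNA split into S1–S3 or L1–L6 modules, recognized by a `_S1`/`_L1`-style
suffix, a `fragment_of` qualifier, or a user-supplied fragment map) count
once per locus, with the module count reported separately.

## Inverted-repeat detection

`find_inverted_repeat()` generates candidates by exact 25-mer seed matching
between the doubled forward strand and its reverse complement (doubling
makes the search rotation-invariant), groups seeds into runs per diagonal,
and extends each run outwards. The boundary rule has two parts: a local
stop — extension halts once 3 of the last 10 positions mismatch, a density
far above any plausible arm divergence and reached almost immediately in
unrelated flanking sequence — and a global budget, the farthest extent
whose cumulative mismatch fraction stays within `max_mismatch_frac`
(default 1%). Boundaries always end on a matching position. Planted exact
arms are recovered to within a couple of nucleotides (the only slack being
flanking positions that pair by chance); arms at 1% divergence are
recovered within `divergence × length + 10` nt. The two single-copy gaps
are labelled LSC/SSC by size, and `partition_quadripartite()` assigns genes
to regions by the majority of their span.

## Dispersed repeats and dotplots

`find_maximal_repeats()` reports maximal pairs under all four transforms —
forward, reverse, complement, reverse complement — either exact or within a
Hamming budget `k` of 0–3. Seeds use the pigeonhole length
`floor((min_len - k)/(k + 1))`, which guarantees every qualifying maximal
interval contains an exact seed; around each seed the maximal intervals are
enumerated directly from the positions of the flanking mismatches, so the
output is provably complete for the configured `(min_len, k)` and is tested
for exact equality against an exhaustive all-diagonals oracle. Counts of
"repeats" are convention-laden: a family of `c` identical copies yields
`c(c-1)/2` maximal pairs, and instances extended into chance-matching
flanking sequence are distinct instances. The package therefore reports
matches, instances and families separately and exposes every parameter.
Family clustering is single-linkage on instance identity, with links taken
from the matches themselves, from genomic co-location, and from alignment
of the remaining family representatives. `dotplot()` computes the classic
sliding-window identity matrix (window 50 by default) as a dense integer
matrix with a sparse-TSV export; it is intended for sequences up to a few
tens of kilobases.

## Palindromic hairpin elements

Hairpin detection is a combinatorial stem-loop scan, not thermodynamic
folding: an element is a left arm, a loop of 3–12 nt, and a right arm
reverse-complementary to the left within at most one mismatched pair. The
innermost and outermost pairs must pair — a mismatched innermost pair is
the same structure with a longer loop, and a stem ending on a mismatch is
not maximal. G:T wobble pairs do not count as pairing. The default minimum
stem of 8 admits the 23–38-nt element range observed in mitochondrial
palindrome clusters (minimum element `2×8+3 = 19` nt). Overlapping calls
resolve to the longest stem, then leftmost. Clusters are single-linkage
chains with gaps of at most 30 nt; families of clusters are built strand-
agnostically (a cluster and its reverse complement are the same object) and
summarized by a column-majority IUPAC consensus in which ties produce the
ambiguity code.

A permissive combinatorial scanner necessarily calls chance stem-loops in
random DNA — roughly one per few hundred nucleotides at the default
parameters in AT-rich sequence. Isolated chance calls are mostly
singletons, so reporting conventions matter: summaries in the acceptance
script count a *cluster region* only when at least two elements chain
together in intergenic context. Planted clusters are still recovered
exactly, but background singletons (and occasional AT-rich chance
clusters) remain visible in the raw output, and they dilute the mean
cluster GC a few points below the 50% of the planted elements — a known
property of the scanner, not of the planted architecture.

## Bait-and-walk assembly

Recruitment finds, for each trace, the best match to any bait by exact
11-mer seeding; the modal shared diagonal is evaluated as an ungapped local
alignment (maximum-scoring segment under match 2, mismatch −3), with a
gapped local alignment under the same scores plus gap costs 5 (open) and 2
(extend) as a fallback when the seed evidence is strong (≥ 20 shared seeds)
but no ungapped segment qualifies. A trace is recruited when identity over
the aligned span exceeds 80% on a span of at least 100 nt; the minimum span
exists because similarity thresholds without a span floor admit spurious
short hits. BLAST-style E-values are deliberately not reproduced — they
depend on database-size semantics that have no analogue here.

Assembly is greedy overlap-layout-consensus honoring a minimum overlap of
500 nt, minimum overlap identity of 98%, and overlap scores of match 1 /
mismatch −2 (gap −2 with an additional −3 for the first gap applies in
gapped evaluations). The pair with the best-scoring overlap is merged
repeatedly, ties breaking by score, overlap length, then lexicographic ids,
so output is deterministic given the input. The consensus is a
coverage-weighted per-column majority with deterministic tie-breaks;
quality values are ignored. Overlap placement and the consensus are
substitution-only (a gapless diagonal model), which matches the simulator's
substitution-only error process; on real traces with indels the gapped
recruitment fallback still finds the reads, but indel errors would reach
the consensus, which is the main simplification to keep in mind. Walking
re-baits the archive with 1-kb terminal windows of each contig and
re-assembles; recruited traces that fail to merge into an existing contig
are returned to the pool rather than promoted to contigs, because repeat-
carrying reads recruited through a shared palindrome or dispersed repeat
would otherwise seed unrelated neighbourhoods. Total assembled length is
non-decreasing and walking stops when no contig grows. Circular closure
requires the two contig ends to overlap at assembly stringency (≥ 500 nt,
≥ 98%); the overlap is trimmed with its coverage folded back, and the
circle is rotated to the lexicographically minimal rotation of the
canonical strand, making the result independent of where the source circle
was cut. An inverted repeat longer than the reads will collapse in a
greedy overlap assembler; the evaluator reports it, and resolving such
repeats is out of scope.

## The simulator and what passing tests mean

`generate_genome()` plants the full architecture with exact length
budgeting: gene sets with fixed or solved lengths (protein-gene length is
solved from the coding budget), introns with or without intronic ORFs,
intergenic introns, a quadripartite layout whose IR duplicates its genes
and introns, dispersed repeat families, palindromic clusters, pseudogene
fragments, and per-category GC targets (protein-coding sequence is sampled
per codon position; intergenic filler GC is solved so the category average
meets its target after the AT-rich repeat elements are accounted for). The
two presets encode the architectures such studies report: a 28.3-kb
mitochondrial genome (12 genes on one strand — 7 protein, rRNAs fragmented
into 3 and 6 modules, 3 tRNAs — 18 introns, 58% noncoding split
29.5/28.5%, 18 palindrome cluster regions, GC 33/34/37% by category and
38/38/19% by codon position) and a 269-kb plastid genome (14.4-kb IR arms
with 127.3/112.9-kb single-copy regions, 97 unique genes with 5 IR
duplicates, 43 introns of which 11 are IR duplicates and 7 intergenic,
~100 AT-rich dispersed repeat families, 65.5% noncoding split 52/13.5%).
`shred_traces()` draws uniformly-placed, strand-random reads (default mean
750 nt, sd 80) with i.i.d. substitutions and an optional random "nuclear"
decoy at its own fold-coverage, optionally carrying a planted
organelle-like insertion to stress recruitment purity.

The simulator is i.i.d. at the nucleotide level: it does not emulate
chromatogram noise models, vector contamination, indel sequencing errors,
codon usage of real genes, or the homopolymer-driven similarity structure
of real plastid repeats. Passing round trips therefore demonstrate that
the analysis modules recover what the generator planted under realistic
size/composition regimes — not that the defaults are optimal for any
particular real genome, where parameters should be reviewed against the
annotation at hand.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data:
random annotated genomes up to 10 kb against the per-position oracle,
500-nt sequences against the exhaustive repeat oracle (all four types,
k ≤ 1), planted IR arms of 1–14.4 kb at 0–1% divergence, the full 28.3-kb
and 269-kb presets for the architecture statistics, and a 30-kb circle
shredded at 30× with 1% error plus 3× nuclear decoys for the
bait-and-walk round trip (one circular contig, ≥ 99.9% identity to truth,
100% recruitment purity). These sizes were chosen as the smallest at which
each property is meaningfully exercised at the presets' own scale.

## A worked example

```{r example}
g <- generate_genome(mt_genome_spec(seed = 42, length = 12000,
                                    gene_introns = 6,
                                    palindromes = list(regions = 4)))
report_genome(g, find_ir = FALSE)
```

## Known limitations

* Intron discovery and classification are annotation-driven; the package
  never predicts genes or introns from sequence.
* Hamming-only repeat matching: gapped (indel) repeat alignment is not
  performed.
* No thermodynamic folding; hairpin calls are combinatorial and include
  chance stem-loops at a predictable background rate.
* The assembler's consensus is substitution-only and greedy; long inverted
  repeats collapse, and Phred-weighted consensus calling is not
  implemented.
* Dotplots are dense matrices, practical only to a few tens of kilobases.
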