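---
title: "Detecting full-length and split homologs between a host proteome and a gut microbial catalog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting full-length and split homologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splithom)
```

## The model

`splithom` asks, for every host protein, whether a microbial genome encodes
a homolog of it — either as a single gene (**full-length homolog**) or as a
set of adjacent genes whose products jointly reconstruct it (**split
homolog**, the genomic signature of gene fusion in the host lineage or
fission in the microbial one). The search space is a clustered microbial
protein-family catalog: alignments are computed once at the family level
(query = family representative, subject = host protein) and families are
then mapped back to their member genes and genomes, where gene order,
strand, and contig information lives.

Input alignments must be in the 14-column extended tabular form
(`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
evalue bitscore qlen slen`). The two length columns are not optional
decoration: they are the denominators of every coverage fraction, and the
reader rejects files without them. All coordinates are 1-based inclusive;
an interval covers `end − start + 1` positions.

## Filtering parameters

| parameter | default | meaning |
|---|---|---|
| `microbe_cov_min` | 0.67 | minimum fraction of the microbial protein covered by the alignment |
| `min_microbe_len` | 80 aa | minimum microbial protein length |
| `human_cov_min` | 0.70 | minimum host-protein coverage (individual for full-length, joint for split) |
| `contamination_sd_mult` | 3 | SD multiplier for the identity cutoff |
| `max_feature_distance` | 3 | maximum feature-rank gap between split members |

The two-thirds/70% coverage pair follows the range conventionally used by
systematic ortholog surveys (50–80% depending on the study); because the
choice is consequential, `sensitivity_grid()` re-runs the entire pipeline
over microbe coverage ∈ {50, 67, 75}% × host coverage ∈ {60, 70, 80}% — 9
parameter combinations — refitting the contamination model each time, and
reports per-protein consensus across the grid.

## The contamination model

Metagenome-assembled genomes can carry fragments of host DNA. A microbial
gene that is *really* a mis-binned host gene produces a near-perfect
alignment, so unusually high percent identity is treated as evidence of
contamination rather than of homology. The model is deliberately simple:
the mean and sample standard deviation (n − 1 denominator) of `pident` over
all alignments that survive the host-coverage step, with cutoff
mean + 3 SD. The model is fitted once, on the full-length candidate set
(before best-per-genome reduction, i.e. in enumerated step order), and the
same fitted cutoff is reused by the split branch's final filter, so both
branches apply one consistent definition of "suspiciously identical".
Degenerate inputs (all identities equal) give SD 0 and a warning; fewer
than two alignments are a hard error.

## Split-homolog detection choices

Several rules in the split branch were genuinely open and are fixed here as
follows:

* **Adjacency is chained.** "At most 3 features apart" is a pairwise
  criterion; we take its transitive closure, so members at ranks 2, 4, 6
  form one three-member neighborhood even though the outer pair is 4
  apart. Components are computed per (contig, strand) by splitting sorted
  ranks at gaps > 3.
* **Jointly but *not* individually.** A (host protein, genome) pair with
  any member individually covering ≥ `human_cov_min` is routed to the
  full-length branch only — it is never reported as split, even if other
  members exist. This is the literal reading of the joint-coverage rule
  and avoids double-reporting the same locus under both call types.
* **Distinct families.** A neighborhood needs ≥ 2 *distinct* protein
  families. A family occurring at two loci contributes both loci to the
  adjacency graph, but two copies of one family alone do not constitute a
  split homolog (tandem duplication is not fission).
* **Single-pass re-checks.** Joint coverage is re-tested once after the
  adjacency filter and once after the contamination filter (removals only
  shrink coverage, so one pass per stage suffices for the stated
  sequence). After the contamination removal the surviving neighborhood is
  re-tested for family count and coverage but not re-partitioned by
  adjacency.
* **Tie-breaks everywhere** (best host hit, best call per genome) are
  bitscore descending, then e-value ascending, then lexicographic
  accession — purely for determinism.
* **The 80-aa minimum** applies to the family representative's length
  (`qlen`), since that is the sequence the alignment was computed against;
  member genes inherit the family's fate.

`nFull` counts distinct genomes with a full-length call (the full-length
step keeps one best call per genome, making the genome the natural unit)
and `nSplit` counts distinct neighborhoods; `tally_homologs()` exposes a
`unit` switch (genome / family / species) because other rollups are
defensible. A protein is split-dominant iff `nSplit > nFull`.

## Downstream summaries

**Xenobiotic classes.** Host enzymes are partitioned into ten classes
(short-chain reductases, aldo-keto reductases, cytochrome P450s, GSTs,
UDP-glycosyltransferases, arylamine N-acetyltransferases, 'GDXG' lipolytic
enzymes, type-B carboxylesterases, flavin monoamine oxidases/FMOs, quinone
oxidoreductases) by regular-expression match on family description
strings, in a fixed table order with first match winning, so a
multi-matching description is still deterministic. Per class,
`presence_matrix()` counts distinct species and distinct microbial protein
families per bacterial family, and `rank_classes_by_pd()` orders classes by
Faith's PD of the species carrying them, computed on the midpoint-rooted
species tree (`phangorn::midpoint`, `picante::pd`). `include_root = TRUE`
is the default, matching the cited PD implementation; PD is then monotone
under subset growth and PD(all tips) equals total tree length.

**GO enrichment.** Annotations are propagated to all `is_a`/`part_of`
ancestors before counting, so a protein annotated to a leaf also counts for
every ancestor (closure is idempotent and monotone). Enrichment is a
classic per-term two-sided Fisher's exact test over biological-process
terms with ≥ 1 study annotation, BH-corrected across that tested family,
with the conditional-MLE odds ratio. The decorrelating `weight01`-style
algorithms of DAG-aware enrichment tools are intentionally *not*
reimplemented; results for deep, redundant ontologies will therefore show
the usual parent-term shadowing, and exact p-values from such tools are not
comparable. Evidence-code subsets: `noIEA` (drops electronic annotations)
and `expOnly` (keeps EXP/IDA/IPI/IMP/IGI/IEP only). Mitochondrial
localization is flagged by the `[Mm]itochondr` regex on cellular-component
strings and tested the same way. GO-defined gene sets (`build_go_gene_set`)
take a root term plus excluded subtrees — e.g. nucleobase-containing
compound metabolism (GO:0006139) minus the acyl-CoA/CoA/FMN/FAD/pyridine
nucleotide branches, or the plain oxidoreductase set (GO:0016491) — all
reduced to membership tests on the closed annotation sets.

**Drug cross-reference.** A PharmGKB-style reaction table is filtered to
reactions where reactant ≠ product, the type is not Transport, the
controller is known, and a reactant or product is a chemical of interest
(Drug / Drug Class / Prodrug / Metabolite — excluding endogenous
biological intermediates). Controllers are mapped to host proteins through
an explicit two-column table (identifier-authority mapping is out of
scope), joined to the tallies, and the distinct chemicals of interest per
enzyme are aggregated.

## The synthetic fixture

`generate_fixture()` writes every input the pipeline reads, from one RNG
stream keyed by the seed (draw order: host lengths, then per-case
coordinates/identities/gaps in case order, then the species tree), so the
bundle is byte-identical across runs. It emulates the *logical* structure
of real data: planted full-length cases (alignment covering 82–95% of the
host protein at 25–45% identity), planted split pairs and trios (members
each covering 40–48%, jointly ≥ 83% — chosen so calls are stable across
the whole sensitivity grid, since every member stays below the loosest 60%
individual threshold and every union above the strictest 80%), and a decoy
panel in which each decoy violates exactly one predicate: rank gap 4,
opposite strands, different contigs, 65% joint coverage, 66% microbe
coverage, a 79-aa protein, a 90%-identity contaminant, an
individually-covering member (which must convert to a full-length call),
plus a best-hit distractor and a split member stranded without its
partner. On this bundle the pipeline must achieve precision = recall = 1.0
for both call types, and the test suite verifies each decoy disappears at
its intended stage.

What the generator does **not** emulate: real sequence evolution (host
FASTA sequences are random residues; alignments are synthesized
analytically rather than produced by an aligner), assembly fragmentation,
overlapping paralog families, biased genome sampling, and ontologies of
realistic depth. Passing tests therefore demonstrate the *logic* of every
filter and summary on exactly specified inputs — not calibration of the
thresholds against biological truth, which at full scale depends on the
catalog and proteome used.

## Problem sizes and costs

The default fixture uses 55 host proteins, 12 genomes across 10 species
and 3 bacterial families, and ~77 alignment rows — small enough that the
full test suite, including a 200-trial exhaustive-enumeration
cross-validation of the neighborhood search, a full enumeration of Fisher
tables to N = 30, and two complete 9-run sensitivity grids, runs in about
a minute. All components scale linearly in alignment rows except the
neighborhood search, which is linear in instances after sorting within
(host, genome, contig, strand) groups.

## Known limitations

* The classic Fisher test over the propagated DAG inflates ancestor terms
  relative to decorrelating algorithms (see above).
* The contamination model is global; lineage-specific identity
  distributions (e.g. for recently transferred genes) are not modeled.
* Split detection is within-contig by design: fission products split
  across contigs or genomes are out of scope, as is internal domain
  shuffling within one gene.
* Feature ranks are positional (order by start coordinate within contig,
  regardless of strand), so "3 features apart" counts intervening genes on
  either strand.
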