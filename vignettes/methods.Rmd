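---
title: "Methods: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
and procedures it implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite does
not itself compute.

## The measurement model

The atom is a strand-resolved cytosine with a methylated read count
`m` and a total read count `t` (CGmap rows). A CpG dyad contributes
two atoms, one per strand. We never trust a precomputed level column:
counts are the primitive data and levels are always recomputed, so
that pooling is exact. All coordinates are 0-based half-open
internally; CGmap (1-based) and GFF3 (1-based closed) are converted at
the I/O boundary, which keeps off-by-one errors confined to two
well-tested readers.

**Weighted levels.** The level of any site set is
$\sum_i m_i / \sum_i t_i$, i.e. read-count weighted, not the mean of
per-site fractions. Rationale: at uneven coverage the mean-of-fractions
estimator is dominated by its shallowest sites; the pooled estimator is
the maximum-likelihood binomial estimate and satisfies an exact
conservation property (pooling a disjoint partition reproduces the
whole-region level bit for bit), which the suite asserts. A level over
zero qualifying reads is explicitly *undefined*, never silently 0 —
downstream code treats such features as "undetermined" and excludes
them from threshold fitting and enrichment denominators.

**Sequence context.** Dinucleotide context is the cytosine plus the
next base on the same strand (CA/CC/CG/CT); trinucleotide context is
CG if the next base is G, else CHG if the base after next is G, else
CHH. Contexts are NA when the window leaves the contig or contains an
ambiguous base; note CG needs only a 2-bp window, so a CpG at the
penultimate position is still classified. The context mode used for
gene classification is a per-species choice: CG for CpG-dominated
methylomes, CX (all cytosines) where all contexts carry signal, CHG or
non-CG where those mark silencing. The package implements generic
context-set filters and deliberately leaves the species default to the
caller; in particular a published "non-CGC" convention is ambiguous
(non-CG vs an exclusion of the CGC trinucleotide) and is not
special-cased.

**Spike-in QC.** Non-conversion is the all-cytosine weighted level of
a fully unmethylated control (lambda phage); the false-negative rate
is one minus the CpG-context level of a fully methylated control
(pUC19). Both are binomial proportions, so their sampling error is
known and the tests check recovery within three binomial standard
errors.

**Dyad symmetry.** Pearson correlation of the two per-strand levels
across CpG dyads. Default minimum coverage is 5 reads per strand
member: per-site level estimates at 1–4 reads are so noisy that the
correlation is attenuation-dominated. The filter is a config key
because published values do not state theirs.

## Gene classification

Per-gene levels (full annotated span, introns included; promoters are
not masked because silencing-type methylation extends across body and
promoter alike) form a bimodal distribution: a large mode at the
non-conversion floor and a small hypermethylated mode. Two routes give
a threshold:

1. **Valley.** A fixed-width histogram (default bin width 0.05 — the
   resolution at which such histograms are visually inspected; KDE
   would introduce a bandwidth choice and non-determinism) is scanned
   for its two highest-density modes (plateau runs collapsed to their
   centre); the threshold is the midpoint of the lowest-density bin
   strictly between them. On cleanly separated data the valley is a
   run of tied empty bins; the tie-break takes the bin whose midpoint
   is closest to the midpoint of the mean levels on either side — the
   cut that *best separates* the two populations, which is how such
   thresholds are chosen by eye. Bimodality is declared when the
   valley count is below half the smaller mode's count and the modes
   are not adjacent.
2. **k-means, k = 2**, on the 1-D levels. Initialisation is
   deterministic (centres at the data min and max), Lloyd iterations
   to convergence, ties assigned to the lower centre; the boundary is
   the midpoint of the final centres. For a 1-D two-cluster problem
   this removes any seed dependence.

The chosen threshold is the valley when the distribution is bimodal,
otherwise the k-means boundary. On well-separated simulations the two
routes agree within one bin width (asserted in the suite), mirroring
the validation practice of checking histogram-derived cut-offs against
clustering. Classification uses `level >= threshold`, matching the
">= x%" convention of published per-species cut-offs, and is monotone
in the threshold by construction.

TE reporting drops insertions under 500 bp (spurious small
annotations) and keeps a family only with at least 20 methylated
insertions, so per-family averages are not driven by a handful of
copies.

## Hypermethylated regions

Windows of 500 bp every 250 bp, kept when the weighted level is
*strictly* above 10% mC ("more than 10%") and the window holds at
least `min_sites` covered cytosines. The site-count floor (default 5)
is our addition — the published procedure is silent — because a single
covered cytosine can push an otherwise empty window over any level
threshold; it is config-exposed and the acceptance oracle uses the
same parameter. Retained windows that overlap *or abut* are merged
(with a 250-bp step adjacent passing windows always overlap; the
book-ended case only arises at clipped chromosome ends), and the
region's mean level is recomputed from pooled counts over the merged
span rather than averaged over windows. The caller is tested for exact
equality against a quadratic enumerate–filter–merge oracle on 200
random genomes.

## TE ages

Kimura 2-parameter distance from consensus-vs-insertion alignments:
transition proportion P, transversion proportion Q over comparable
(non-gap, non-N) columns, $d = -\tfrac12\ln((1-2P-Q)\sqrt{1-2Q})$.
Non-positive logarithm arguments flag saturation (d undefined, the
insertion lands in an overflow age bin) instead of raising. The
CpG-modified variant discounts transitions whose consensus column
belongs to a CpG of the ungapped consensus — both the C and the G —
to weight 1/10, since methylated CpGs are hypermutable and would
inflate apparent age. The exact discount used by repeat-annotation
tools has dialect variants; 1/10 is pinned and documented, and
`cpg_weight = 0` gives the "ignore CpG transitions" alternative. The
estimator is validated against the closed form on constructed counts
and against sequences evolved under the exact K2P site probabilities
(consistency within 10% relative error at 5,000 columns).

## Taxonomic origin and enrichment

Hit tables are ingested with at most 10 best-scoring records per gene
after discarding within-genus hits (self-matches). Categories operate
on superkingdom labels only — Eukaryota; Bacteria+Archaea as
Prokaryote; Viruses — because the categories are defined "at the
highest level". A domain is represented when it holds at least 20% of
a gene's hits; one represented domain gives a pure category, two a
named combination, three Mixed. The 20% rule is our
operationalisation of "combinations" and is config-exposed; with at
most three domains the majority domain always reaches 1/3, so a gene
with hits is never category-less. Genes whose hits were all discarded
are Unassigned and are excluded from enrichment denominators (both
denominators are reported).

Enrichment uses the two-sided Fisher exact test: the p-value sums all
hypergeometric point probabilities not exceeding the observed one
(with a 1e-7 relative slack against floating-point ties), α = 0.001
per category without multiplicity correction (a Bonferroni toggle
exists). The sample odds ratio gets a Haldane 0.5 correction only
when a zero cell exists, flagged; a zero margin yields p = 1 and an
undefined odds ratio. The implementation is checked against an
independent `lchoose` enumeration on every 2×2 table with n ≤ 60 to
1e-10 relative error.

Viral neighborhoods (GEVE candidates) chain Virus and Virus-combination
genes greedily along each chromosome, extending while the next viral
gene is within 3 intervening non-viral genes *and* 20 kb, and emitting
chains of at least 3 viral members. All three defaults are our choice
— no published numbers exist — sized so that a handful of host-gene
calls inside an integrated element (annotation noise, nested insertions)
does not split it, while isolated viral hits never chain across gene
deserts. The dominant taxon is the modal genus among the member genes'
viral hits. "Mixed" genes do not seed chains: a gene with substantial
eukaryotic *and* prokaryotic *and* viral support is weak evidence of
viral origin.

## Dollo reconstruction

Under Dollo parsimony (one gain, unlimited losses) the reconstruction
is closed-form: the gain node is the MRCA of the present leaves, a
node is present iff it lies on a path from the gain to a present leaf,
and the losses are the maximal absent subtrees below the gain. This is
the unique minimum-loss single-gain assignment, verified by exhaustive
enumeration over all ancestral-state vectors on 500 random profiles.
Polytomies are allowed. "Potential" presences (atypical domain
architecture, weak support) are a third input state collapsed by an
explicit toggle; reporting both treatments brackets the answer, and
treating them as absent can never increase ancestral presence (a
tested monotonicity). The species tree is user input; rootedness is
required and enforced at read time.

## The synthetic world

`simulate_methylome()` emulates the statistical structure of a real
protist methylome study so that every stage is testable offline:

* a few-Mb random genome (8 × 600 kb, GC 0.5) with ~5,000 genes
  (lognormal lengths, median 500 bp — compact protist-like genes kept
  small so the default bundle simulates in seconds) and exponential
  intergenic gaps;
* 2% of host genes methylated: their true per-feature level is one
  Beta(10, 2.5) draw (mean 0.8) plus bounded ±0.05 per-site jitter —
  a single draw per feature, not per site, which produces the
  intermediate, partially methylated feature levels seen in real
  protist methylomes rather than an all-or-nothing pattern;
* background apparent methylation at the non-conversion rate
  ε = 0.003 (matching the ~0.3% lambda floor of enzymatic conversion
  libraries); coverage Poisson(30), per-site counts Binomial(depth,
  p); a feature whose true level is 0 is background, receiving no
  jitter;
* three TE families (60 insertions each) generated by mutating a
  family consensus at per-family divergence 0.02–0.35 with a 2:1
  transition bias; methylation interpolates from 0.8 (youngest) to
  0.1 (oldest), giving the young-TE-hypermethylation gradient;
* three clusters of 8 consecutive virus-derived genes, hypermethylated
  and tagged with a Nucleocytoviricota-like lineage, so category
  enrichment and neighborhood detection have planted truth;
* spike-ins: a 48.5-kb lambda-like contig at ε and a 2,686-bp
  pUC19-like plasmid with CpG methylation 1 − φ, φ = 0.02 (the ~98%
  mCG of a methylated control);
* a hit table with 10 hits per gene: viral lineages for cluster genes,
  eukaryotic otherwise, 10% of host genes with a mixed
  eukaryote+prokaryote profile and 2% with only within-genus hits
  (Unassigned after ingest).

One integer seed fans out to per-phase substreams (placement, truth,
genome, counts, hits), so the bundle is byte-identical under the same
seed and components are independently reproducible.

**What a green test does not establish.** The generator draws
independent sites at homogeneous coverage from a literal
two-population model. It does not emulate mapping bias, conversion
chemistry, copy-number variation, cell-to-cell heterogeneity beyond
the per-feature jitter, context-dependent coverage, annotation error,
or phylogenetic signal in the hit tables. Green parameter-recovery
tests therefore establish correctness of the estimators under the
stated model, not performance on any particular real dataset; the
paper-scale headline numbers depend on the deposited sequencing data
and are out of scope by design.

## Numerical and degenerate-input choices

* `min_cov` defaults: 0 at CGmap ingest (no silent filtering), 1 for
  regional levels, 5 per strand for dyad symmetry.
* Metaprofiles pool read counts across features within a bin —
  consistent with weighted levels everywhere else — rather than
  averaging per-feature means as coverage-track tools do; features
  shorter than the bin count map sites through the fractional
  position and are never dropped. Minus-strand features are reversed
  so bin 1 is 5′.
* Constant level vectors cannot yield a threshold (error); fewer than
  20 defined levels likewise.
* Windows with no covered cytosine are dropped before level
  comparison; an empty site stream yields an empty region set, not an
  error.
* Saturated K2P distances are flagged, not thrown.
* Fisher with a zero margin returns p = 1 with an undefined odds
  ratio.
* The hit-table reader skips records with unresolvable taxonomy with
  a warning; it never fails on them.

## Known limitations

* The HMR caller assumes windows fit in memory per chromosome (fine
  up to hundreds of Mb at typical site densities).
* `detect_viral_neighborhoods` chains on gene order and distance only;
  it does not use synteny or strand runs.
* The Dollo module reconstructs each family independently; correlated
  loss (e.g. whole-pathway loss) is not modelled.
* The CLI is a thin convenience wrapper; programmatic use is the
  primary interface.
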