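---
title: "Genus-wide GATA family analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genus-wide GATA family analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatafam)
```

# The problem

GATA transcription factors are eukaryote-wide regulators whose DNA-binding
domain is a class-IV zinc finger: four cysteines spaced
C-X(2-4)-C-X(17-20)-C-X(2)-C, followed by a basic (K/R-rich) region that
contacts the WGATAR consensus. A genus-wide survey of such a family asks,
per species and across species: which genes carry the domain, what spacing
type each domain has, how alternative splicing reshapes the family, how
the domains group into subfamilies and multi-species orthogroup clusters,
which residues the genus conserves, and which members are candidate
membrane-bound factors. `gatafam` implements that survey as composable,
tested operations plus a synthetic-genome generator that plants ground
truth for each of them.

# Models and procedures

## Domain detection and typing

Complete domains are found by exhaustive enumeration of cysteine
quadruples satisfying the spacing bounds (s1 in 2–4, s2 in 17–20, s3 = 2).
Overlapping candidate quadruples are resolved deterministically: leftmost
first cysteine wins, then the shorter first spacer, then the shorter
second spacer; the survivor suppresses overlapping candidates and
scanning continues to its right. This tie-break is a package convention —
most plant GATA proteins carry a single domain, so it rarely matters, but
it makes the scanner a pure function of the sequence. `X` never matches a
cysteine. Types are named by the spacer triple: (2,17,2) IV_a, (2,18,2)
IV_b, (2,20,2) IV_c, (4,18,2) IV_4, anything else in bounds
`IV_other(s1,s2,s3)`.

Partial (IV_p) domains — degraded tetrads that survey tools still
annotate — are called with a position-specific log-odds profile built
from aligned complete reference domains (Laplace pseudocount 1, scores
normalised against the reference background composition; residues outside
the 20-letter alphabet score the background-weighted position mean). The
calling threshold defaults to the minimum reference self-score minus a
margin of 1; a window at or above threshold without a complete tetrad is
an IV_p call, and a complete hit always takes precedence. The profile
threshold is a surrogate for an external annotation tool's undocumented
score cutoff, and is deliberately conservative: on shuffled sequences of
reference composition it stays silent in at least 95 of 100 trials.

The basic-region fraction (K/R share of the 15 residues after C4) and the
N/C-terminal class (side of the protein midpoint holding the domain
midpoint, exact midpoint going to C) are annotations only — membership in
the family keys on the domain, never on these.

## Alternative-splicing classification

The canonical isoform of a gene is its longest protein, ties broken by
transcript id — the survey never defines a reference isoform, so the
package uses the deterministic convention. Other coding isoforms are
labelled: `identical_protein` when the protein string equals the
canonical one (with a `utr_only` flag when the CDS intervals also match
while the exon set differs — identical protein from identical CDS with
different UTR structure satisfies both readings); `utr_only_variant` when
the CDS matches but the protein somehow differs (annotation quirks);
`domain_loss` when the canonical is domain-bearing and the isoform is
not; `other` otherwise, with `domain_loss` taking precedence over
`other`. Genes whose isoforms all lack the domain are excluded from the
family; a member's domain-less isoforms still count among its splice
forms, flagged as putative negative-regulator forms.

Summary arithmetic follows the printed-table conventions: B/A splice
ratios and family proportions are half-up rounded to two decimals, and
the genus-level ratio supports an excluded denominator (summing B over
all species but A only over the non-excluded ones) because the original
census prints its total that way; both behaviours are exposed and the
mixed denominator is documented on `genusSpliceRatio()`.

## Alignment, tree, subfamilies, clusters

Complete domains are aligned on their cysteine anchors: the four
cysteines are pinned to common columns, spacer residues are
left-justified with gaps inserted immediately before the next cysteine,
and 7 N-flank plus 25 C-flank residues (covering the basic region) are
carried along, end-gap padded. IV_p hits cannot be anchored and are
excluded, mirroring their exclusion from the published alignment figure.

Distances are p-distances with pairwise deletion — the simplest
defensible choice given that the upstream tool's distance model is not
printed. Neighbor joining is implemented in the package because the
procedure's determinism contract matters downstream: Q-matrix ties break
to the smallest (row, column) pair in current matrix order, and negative
branch estimates are clamped to zero with the deficit moved to the sister
edge so pair totals are preserved. On additive matrices the
implementation reproduces the generating tree exactly (topology and
lengths, n ≤ 12), and tests cross-check it against an independent NJ
implementation and, at n = 6, against brute-force least-squares over all
105 topologies. Bootstrap support resamples alignment columns with a
seeded RNG and scores each reference bipartition by its replicate
frequency; supports are properties of bipartitions, hence invariant to
leaf relabelling. The default of 100–1000 replicates is a desk-scale
choice; the published tree used 10,000 and the replicate count is a
parameter.

Subfamilies come from anchor (reference) leaves with known labels: each
member takes the subfamily of its nearest anchor by patristic distance,
with exact ties (relative tolerance 1e-9) reported `unresolved`.

Gene clusters ("PCs") were drawn by eye in the original figure; the
package operationalises them as maximal clades of the midpoint-rooted
tree whose leaves are all in-genus, span at least `minSpecies` (default
5 of 7) species, and whose bipartition has at least `minSupport`
(default 50) bootstrap support — thresholds chosen because they
reproduce the published qualitative structure (most clusters span all
species, one spans five) on synthetic analogues; both are parameters.
Cluster numbering follows tree traversal order within subfamily,
subfamily III first, matching the published numbering convention; it is
a convention, not a reproduction. Midpoint rooting is the default, with
an outgroup option.

## Conservation, statistics, expression, TMH

Per-column distinct-residue counts (gaps excluded) drive the pattern
tables; the motif-region variability percentage counts, over the
per-cluster pattern rows, the motif-span positions whose residue set
exceeds one. The published "556 positions" figure arises as this sum of
motif-region positions across cluster rows; whether the original count
included flanking columns is not stated, so the motif-only reading is
used and documented.

The domain-type census is TF-level (per coding isoform, typed by its
best hit) because the published denominators count TFs, not genes.
Cluster evenness requires both full species coverage and equal
per-species counts. The 19-feature species PCA uses a documented
surrogate feature set (counts, length statistics, type and subfamily
fractions, domain position, ChrUn share, basic-region fraction) since
the original 19 characteristics are not enumerated; features are
standardized, constant features dropped, and each component's
largest-magnitude loading is made positive so signs are reproducible.

Expression profiles are log2(FPKM+1)-transformed by default and
clustered with `hclust` (euclidean, complete linkage — the stated tool's
defaults). Because the published co-expression boxes were drawn by eye,
coherence is operationalised by cutting the dendrogram into k flat
clusters (default: the number of clusters with expressed members):
`full` if all expressed members of a gene cluster share one flat
cluster, `partial` if at least two do, `none` otherwise,
`not_assessable` under two expressed members.

The TMH predictor is a clearly-labelled hydropathy stand-in for HMM
predictors whose parameters are not redistributable: a 19-residue
Kyte–Doolittle window, spans as maximal runs of at least 15 positions at
or above 1.6, ends truncated. A TSV import path lets real-data runs use
an external predictor's spans instead. TMHs are counted per isoform.

# The synthetic generator

`simConfig()` defaults are the emulated study regime: 7 species; 21
orthogroups (one with 4 and two with 2 gene copies per species, so each
species carries ~27 family genes plus a few species-specific ones);
subfamily-III clusters carry IV_c domains and one subfamily-II cluster
carries IV_4, the rest IV_b, approximating the published type census;
~30% of genes have splice variants; the membrane-bound fraction is
5/389; genes spread over 19 chromosomes with ~3% on unassigned
scaffolds; expression covers two species in four tissues.

Cluster ancestors are drawn from synthetic subfamily consensus domains.
The consensus sequences are invented — only their documented constraints
are meaningful: the cysteine tetrad, subfamily III showing M/E at the
two diagnostic spacer positions where I/II/IV show W/G, and a K/R-rich
region after C4. Cysteines and the two diagnostic positions are
protected from every mutation step so planted type and subfamily labels
remain well-defined truth; substitutions never introduce new cysteines,
and flanking sequence is drawn from a polar-biased, cysteine-free
alphabet, so each planted protein contains exactly one C-tetrad and
soluble proteins contain no spurious hydrophobic run. These are
generator simplifications: real flanks contain cysteines and hydrophobic
stretches, so passing closed-loop tests demonstrates correctness of the
operations under identifiable conditions, not scanner specificity on
real proteomes.

Anchors are emitted in two layers: one partner anchor per cluster,
diverged from the cluster ancestor at a higher rate (0.25) — emulating
an outgroup genus whose reference genes interleave with the clusters on
the domain tree, which is also what makes maximal-clade cluster
extraction identifiable — plus two free anchors per subfamily near the
consensus. Splice variants are planted as coordinate edits on the gene
locus: an extra UTR exon (CDS unchanged — the identical-protein
phenomenon), a CDS truncation removing the domain, or an in-frame
deletion placed outside the domain and its aligned flanks, since splice
variation in this family leaves the DNA-binding region intact.
Transmembrane helices are planted as 23-residue I/L/V/F stretches after
the basic region. Expression uses a Gaussian copula on the latent scale
(within-block correlation 0.9, between 0) with exponential marginals
whose per-tissue scales give each block one strongly expressed signature
tissue (~two orders of magnitude over baseline) — the simplest structure
that is both tissue-specific in the published sense and identifiable by
the default clustering; with that design the full-coherence rate
averages just above 0.9 over ten seeds, and individual seeds range
roughly 0.86–0.95.

Every emitted gene round-trips through the GFF3/FASTA writers and the
parser to byte-identical proteins, and the whole bundle is
byte-deterministic in the seed.

# Numerical choices and degenerate inputs

Half-up rounding to two decimals for all printed percentages (R's
`round()` is half-to-even); profile normalisation enforced to 1e-9;
patristic-tie tolerance 1e-9 relative; malformed CDS (length not a
multiple of three, or internal stop) kept but flagged and excluded from
all downstream analyses; transcripts without CDS retained as non-coding
isoforms, never counted as TFs; a pair of alignment rows with no
comparable columns is an error rather than a silent zero; zero-variance
genes are an error under the correlation distance; empty inputs error
early with the offending record named.

# Problem sizes in the test-suite

Module tests run on 3-species/4-cluster families; the closed-loop
recovery properties run at the regime the generator defaults encode
(7 species, 20–21 orthogroups, drift 0.05) with 20 seeds for cluster
recovery and 10 for expression coherence and subfamily recovery; the
scanner oracle covers 500 random proteins up to length 400. These sizes
keep the full suite within a coffee break on one CPU while still
exercising the genus-scale code paths.

# Known limitations

The scanner's specificity on real proteomes is untested here (synthetic
flanks are cysteine-free); the IV_p threshold is a surrogate for an
external tool's filter; p-distance NJ is a deliberate simplification of
the original alignment-tool pipeline; cluster extraction reproduces the
published structure qualitatively but the numbering and thresholds are
conventions; the expression coherence rule replaces a by-eye judgement;
and the hydropathy TMH caller is not an HMM — import external predictions
for real analyses.
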