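---
title: "Models and methods behind ychrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ychrtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ychrtools)
```

This vignette explains the statistical models, parameter choices and
numerical conventions the package is built on, in the spirit of the methods
sections of mature omics packages: enough detail that a user can judge what
a passing test suite does — and does not — establish about their own data.

## Coordinate conventions

All in-memory coordinates are 1-based closed intervals, the
GenomicRanges/IRanges convention that the rest of the R genomics stack
expects. Conversion happens once, at the file boundary: BED input (0-based
half-open) is converted by `rtracklayer` on import and export; VCF
positions are already 1-based; the nanopolish-style methylation dialect
(0-based) is shifted by `load_frequency_table()` and shifted back by
`write_frequency_table()`. These conversions are bijective and covered by
round-trip tests, so no coordinate ever crosses a boundary twice.

## Enrichment model

For chromosome $c$ with mapped bases $m_c$, non-N size $s_c$ (assembly
length minus gap bases) and ploidy $n_c$,

$$\mathrm{coverage}(c) = \frac{m_c}{s_c}, \qquad
\mathrm{EF}(c) = \frac{m_c / \sum_j m_j}{s_c n_c / \sum_j s_j n_j}.$$

Excluding N gaps matters because a large fraction of a Y-chromosome
reference is unresolved sequence that can never attract alignments; the
ploidy weight accounts for each chromosome's true target space in a male
genome (autosomes 2, X and Y 1). $\mathrm{EF} = 1$ is the no-enrichment
baseline, and the factors always satisfy $\sum_c \mathrm{EF}(c)\,w_c = 1$
with $w_c = s_c n_c / \sum_j s_j n_j$ — a conservation identity the suite
checks on random inputs, along with invariance under uniform rescaling of
the mapped bases.

The synthetic mapping generator allocates a total base budget
multinomially with probabilities proportional to $s_c n_c$, multiplied by
a fold $f$ for the target. Under this model the target's expected factor
has the closed form

$$\mathrm{EF}_\mathrm{target} = \frac{f}{w f + 1 - w},$$

which the tests use as an independent oracle: at target share $w = 0.01$
and $f = 50$ the expectation is 33.67, and the mean over simulation
replicates must sit within three standard errors of it. Note the
saturation: as $w f$ grows, the factor is bounded by $1/w$, which is why
empirical enrichment factors are always far below the raw fold.

Only primary alignments are counted by the BAM adapter
(`ingest_alignments()`): secondary and supplementary records describe the
same molecule again and would inflate the numerator. This is a package
decision; summaries produced by other tools can be supplied directly as
TSV if a different convention is wanted.

## Assembly metrics

N50/L50 use the dominant "descending cumulative sum $\ge$ span/2"
convention, so Table-style comparisons between assemblies are well defined
at the boundary. One subtlety the test suite documents: N50 is *not*
monotone under lengthening an arbitrary sequence (lengthening a short
contig raises the half-span threshold faster than the leading cumulative
sum; `[12, 5, 5] -> [12, 9, 5]` drops N50 from 12 to 9). Lengthening the
*longest* sequence is monotone, and that is the property asserted. The
downsampling helper returns $100\cdot\min/\max$ rounded to one decimal and
names the larger set, matching the usual base-matched comparison workflow.

## Structural-variant processing

The post-caller pipeline mirrors common long-read practice: drop
IMPRECISE records; merge insertions and deletions *separately*, per
chromosome, by single-linkage chaining of start positions at a maximum
permitted distance of 100 bp; mask genotypes with quality strictly below
25; drop events reference-or-missing in every sample; bin indel lengths at
10/50/500 bp with a 10 bp panel floor.

Design choices worth knowing:

* Clustering compares start positions only, not lengths — the "maximum
  permitted distance" semantics. Because a cluster's representative is its
  first member and consecutive clusters are separated by more than the
  distance, merging is idempotent, and the number of events is
  non-increasing in the distance; both are property-tested.
* When two members of one cluster carry conflicting genotypes for the same
  sample, the higher-quality genotype wins and the conflict is reported —
  the upstream tools do not define this case, so the package makes the
  deterministic choice explicit.
* DUP/TRA records pass through filters untouched but never join indel
  clusters or size bins; such events are rare in these panels.
* Genotype quality is read from the per-sample `GQ` field when present,
  else the record `QUAL`; the threshold applies to whichever was read.

Repeat content of a variant is the covered fraction of its footprint
(`pos` to `pos + length − 1`) under the reduced repeat annotation, with
the dominant class decided by covered bases and lexicographic tie-break.
For insertions this footprint is a reference-side proxy (the inserted
sequence itself is not available post-merge), which is the standard
compromise when annotating merged panels.

## Concordance

Genotypes are binarized before comparison (hemizygous chromosome: any
alternative call = present). Phi is computed from the 2×2 table and is
algebraically the Pearson correlation of the 0/1 vectors; the suite checks
that identity to 1e-12 and the companion identity $\chi^2 = n\,\phi^2$.
When a margin is zero phi is undefined and reported as missing, never as
0 — conflating the two would bias averages of concordance matrices.

Significance uses Fisher's exact test by default (robust for the small,
sparse tables typical of SV panels) with a chi-square option, and
Bonferroni correction with family size equal to the number of pairs
actually tested. Missingness is handled by pairwise-complete deletion for
phi; the sharing profile, by contrast, restricts to variants genotyped in
*every* sample, since a pattern with missing entries is not a pattern.
Population presence uses a strict threshold: frequency must exceed 0.2.

## Methylome pipeline

Sites below 4x coverage are removed per sample; masked positions
(alternative alleles over a reference cytosine) are removed everywhere.
Quantile normalization operates on complete cases only — sites passing
filters in all samples — because the rank-mean target is undefined with
missing entries. The computation is delegated to
`limma::normalizeQuantiles(ties = TRUE)` and clamped to $[0,1]$ (values
can exit the interval only by floating-point rounding). Normalization is
idempotent, preserves within-sample rank order up to ties, and leaves
every column with the identical sorted multiset; all three are tested,
plus an exact three-site hand example.

CpG categories form a partition with fixed geometry: islands; shores up to
2 kb from an island end; shelves up to 2 kb beyond the shores; open sea
elsewhere, with island > shore > shelf priority where flanks of
neighbouring islands collide. Gene features are strand-aware with the
priority TSS (exactly 200 bp upstream of the transcription start) >
5'UTR > 3'UTR > first exon > non-first exons > introns > upstream; the
last two collapse to "intragenic" in figure-style summaries. The width of
the upstream region is not standardized anywhere; the package uses 2 kb
beyond the TSS window as the conventional promoter-proximal span.

Window tracks default to non-overlapping 250 kb tiles anchored at
position 1. Tiling (rather than a sliding step) keeps neighbouring SD
values independent, which the dispersion scan relies on; a smaller `step`
gives sliding windows when a smoother track is wanted. Per-window medians
are computed per sample and the cross-sample SD is taken over those
medians; the SD is missing with fewer than two sample medians. The
dispersion scan ranks windows by SD, keeps the top-k (default 10) that
also exceed an SD z-score of 3, merges adjacent survivors and reports the
overlapping genes and the deviating sample. The z-threshold is calibrated
by the null behaviour of the scan, under which no window typically reaches
z = 3; with a planted 250 kb hypomethylated region (one sample shifted by
−0.3 at 10x coverage) the planted window separates from the null by more
than an order of magnitude in SD, so detection is essentially
deterministic — the acceptance suite requires the planted region to be
top-ranked in at least 95% of seeds and the deviating sample to be
identified.

The methylome tree uses $1 - r$ (Pearson, pairwise-complete) as the
distance and UPGMA (average linkage) for the tree, compared to the
reference phylogeny by Robinson–Foulds distance on unrooted topologies.
These are package decisions, not community standards for methylation data;
they are chosen to pair with the generator below.

## What the synthetic data emulates — and what it does not

`make_genome()` builds a desk-scale male genome: four diploid autosomes, a
haploid X and a haploid target holding ~1% of the ploidy-weighted genome
(the share chrY has in a human reference), with a configurable N-gap
fraction (default 0.3, reflecting how gap-rich Y references are), five
sequence classes tiling the target, CpG islands, labelled repeats and
multi-exon genes. Determinism is byte-level for a fixed seed, and one
global seed fans out to independent per-stage streams (`derive_seed()`) so
stages can be re-run alone.

The SV generator drops each variant on a uniformly chosen branch of an
ultrametric haplogroup-style tree (a root pseudo-branch yields variants
shared by all samples); all leaves below the branch are hemizygous
carriers. A second panel applies genotype-flip noise (default rates in the
10–15% range, the regime where cross-platform phi lands well below 1) and
both panels receive missing calls at a configurable rate. Branch-uniform
placement is a stand-in, not a population-genetic model: it produces the
qualitative structure (basal lineages accumulate private variants; some
variants are universal) without claiming realistic allele-frequency
spectra.

The methylome generator draws a per-site true frequency from a beta
distribution parameterized by mean and concentration per CpG category
(island 0.10, shore 0.40, shelf 0.55, open sea 0.70, concentration 10),
with the X-degenerate open sea raised to 0.75 — the landmark methylation
level of single-copy, autosome-like sequence. The genome-wide bimodality
of real methylomes arises here from the category mixture, not from
bimodality within a category. Observation noise is Poisson coverage and
binomial methylated counts. A planted region adds a per-sample shift; a
supplied tree adds per-branch Gaussian site effects with variance
proportional to branch length, so expected between-sample distances are
ultrametric and UPGMA recovery of the generating topology is consistent —
that is precisely why tree recovery succeeds on this signal while real
single-replicate methylomes, whose variation is dominated by culture and
environment rather than phylogeny, need not recapitulate any tree.

Consequently, passing tests show that the *computations* are correct and
that parameter recovery works under the stated generative models; they do
not show that real methylation is beta-distributed, that real SV sharing
is branch-uniform, or that a real experiment will recover its phylogeny.

## Problem sizes and numerical choices

The suite runs the heavy recoveries at deliberately modest sizes chosen
once as realistic desk-scale renditions: 5 Mb target chromosomes at ~150 bp
CpG spacing (~33k sites), 200 multinomial replicates of 10 Mb of mapped
bases for enrichment recovery, 500 random panels for merge invariants,
1000 random length lists for the N50 oracle, 100k sampled positions for
the CpG partition, and 50/20 seeds for the planted-region and
tree-recovery checks. Ties are broken deterministically everywhere
(lexicographic repeat classes, first-member cluster representatives,
`ties = TRUE` rank means), and degenerate inputs (empty panels, empty
windows, zero margins, fully-gapped chromosomes with data) either produce
defined missing values or fail loudly with the offending name in the
error.
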