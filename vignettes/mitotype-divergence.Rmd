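---
title: "Methods: heteroplasmy-aware mitotype divergence profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heteroplasmy-aware mitotype divergence profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotyper)
```

This vignette documents the models, parameter choices and numerical
conventions behind `mitotyper`, in the spirit of a methods supplement.
It states no empirical result that the test suite and acceptance script
do not themselves compute.

## The analysis problem

Two mitochondrial haplotype lineages ("mitotypes", here labelled TNP and
ENA after the stickleback system) segregate within one species. Given an
aligned set of complete mitogenome coding regions — control region
excluded — with per-sample mitotype and population labels, we want to
know: how divergent are the mitotypes genome-wide; where in the genome
the divergence sits (per gene, per OXPHOS complex); whether the
protein-coding divergence bears signatures of selection
(McDonald–Kreitman, Tajima's D); and whether samples cluster by mitotype
rather than geography (phylogeny).

Two practical complications shape everything:

1. **Heteroplasmy.** Some individuals carry more than one mitochondrial
   haplotype; their consensus sequences contain IUPAC ambiguity codes.
2. **No phasing.** Without population-scale read data the ambiguities
   cannot be resolved, so every statistic must either *credit* the
   ambiguity fairly (identity scoring), *ignore* the site entirely
   (site-count statistics), or *collapse* it conservatively (distances).

## Identity scoring with ambiguities

`site_identity(a, b)` returns `|S_a ∩ S_b| / (|S_a| |S_b|)` where `S_x`
is the base set of the IUPAC symbol. This is the probability that two
bases drawn uniformly from the two sets match. It satisfies the
published ordering constraint — a Y (C/T) has more identity with C or T
(0.5) than with G or A (0) — and fixes the magnitudes with the simplest
formula that does so. The commercial tool used in the original analysis
does not document its internal scheme; equivalence with it is *not*
claimed, only the stated ordering.

Gap columns are excluded pairwise (from numerator and denominator), so a
pair's identity never depends on third samples. Zero comparable columns
is an error, not a silent NA.

`profile_elements()` scores every pair at three scopes: each of the 37
elements, each OXPHOS complex (pooling its CDS columns: ND1–ND6 + ND4L
= complex I, CytB = III, COI–COIII = IV, ATPase6/8 = V), and the whole
alignment ("genome"), whose mean across pairs is the baseline horizontal
line of the classic per-element profile figure. The default pairing
(`vs-reference`) compares each focal-mitotype (ENA) sample against the
TNP reference sample, mirroring the published design; an all-pairs
`between-mitotypes` mode exists.

## Site-count statistics

For fixed/polymorphic counts the conservative rule is: **every column
containing an ambiguity in any sample is removed for all samples**
(`mask_ambiguous`), deliberately lowering divergence estimates. Columns
with gaps in any sample are likewise excluded from counts (the default
behaviour of the reference popgen tool; internally the columns are
flagged rather than spliced out so element coordinates stay valid).

A usable column is *fixed* when both mitotype groups are monomorphic for
different bases, and *polymorphic* in a group when that group is
variable. CDS variants are classified synonymous/nonsynonymous under the
vertebrate mitochondrial code (translation table 2) in the
focal-consensus codon context, substituting one alternate base at a
time. This reference-context convention matches per-site counting; we
explicitly reject enumeration of multi-hit mutational paths as
under-determined. Minus-strand genes (ND6 and eight tRNAs in the default
layout) are reverse-complemented first. The 1–2 trailing bases of CDSs
whose length is not divisible by three (e.g. ND4 at 1,381 bp; completed
to a stop by polyadenylation in vivo) are excluded from codon
classification but retained in identity calculations.

Polymorphism for the MK table is counted **within the focal (ENA)
group only** by default, matching the published table design
("polymorphic within ENA"); `polymorphism = "pooled"` is available.
`NI = (P_N/P_S)/(D_N/D_S)` is undefined unless `D_N > 0`, `D_S > 0` and
`P_S > 0`; it is reported at 2 decimals. Significance uses both the
Yates-corrected chi-square (1 df) and Fisher's exact test; the printed
p-values of the source table are *not* treated as targets because its
software's exact test variant is unspecified (its ND1 p of 0.015 is
smaller than the canonical Yates p ≈ 0.019 for the same counts); the
suite instead verifies that both of our tests reproduce the published
*significance pattern* at α = 0.05. MK p-values are reported raw — the
source applied no multiple-testing correction — with Benjamini–Hochberg
available downstream if wanted.

Tajima's D uses the standard 1989 constants; `S = 0` yields an undefined
D (reported, not an error), and `|D| > 2` flags conventional
significance.

## The conservative tree

For phylogeny the heterozygote coding is *conservative*: a site
contributes distance 0 whenever the two base sets intersect (a Y is
identical to a C or a T), else 1, divided by gap-free columns. This can
only lower divergence, and for >2-state columns the rule is applied per
pair, which may make the matrix slightly non-additive — accepted as-is.
Neighbor joining (via `ape`) replaces the original maximum-likelihood
search: the claim used downstream is topological (reciprocal mitotype
monophyly), which NJ recovers, and an ML implementation would be
disproportionate. Negative NJ branch estimates are clamped to zero with
the excess moved to the sibling branch. A `drop_heteroplasmic` mode
removes every sample containing any ambiguity before tree building,
reproducing the "clean individuals only" tree.

## The synthetic generator: what it emulates, and what not

`simulate_mitotypes()` generates the *stated world* the pipeline is
validated against:

- A reference mitogenome on the standard vertebrate gene order with the
  published element lengths (13 CDS totalling 11,433 bp, 22 tRNAs, 2
  rRNAs, 65 bp intergenic; 15,682 bp coding region). CDSs have valid
  start codons (ATG/ATA/GTG), no internal stop under table 2, and a stop
  (or incomplete terminal T/TA) at the end. Unpublished details —
  unlisted tRNA lengths, placement of the 65 intergenic bp — are fixed
  arbitrary choices (the largest spacer, 35 bp, stands in for the
  light-strand replication origin between tRNA-asn and tRNA-cys).
- One between-mitotype branch receives `Poisson(d_between × L)`
  single-nucleotide substitutions; `d_between` defaults to 0.033, the
  midpoint of the published 0.032–0.034 genome-wide band.
- Each sample sits on its own branch of a **star genealogy** with
  `Poisson(theta_within/2 × L)` private substitutions, so two samples of
  a clade differ at `theta_within` per site in expectation. The default
  0.002 is a generator choice (the source reports no within-mitotype
  diversity figure): low within-clade diversity, an order of magnitude
  under the between-clade signal. Consequently the expected
  between-clade *pairwise* divergence is `d_between + theta_within` =
  0.035, which is what the recovery tests check against.
- A CDS substitution is drawn nonsynonymous with probability
  `omega_by_complex[complex]` (defaults I = 0.15, III = 0.10, IV = 0.03,
  V = 0.05, anchored to the published nonsynonymous fractions with
  complex I elevated); synonymous draws land only where a synonymous
  single-base alternative exists, otherwise the site is re-drawn
  elsewhere. A side effect of this re-drawing is that elements demanding
  many synonymous changes (low omega) reject more sites, so complex IV/V
  genes end up *less* divergent than complex I genes — the direction the
  real data shows across complexes — while non-coding elements, which
  never reject, accumulate slightly more than CDSs. The generator
  therefore reproduces the complex-I ordering but **not** the real
  data's coding-above-noncoding divergence excess; a green directional
  test establishes the former only.
- Heteroplasmy is applied last: each carrier-scope sample (default: ENA
  only, as observed) converts bases to two-base IUPAC symbols containing
  the pre-existing allele at `het_rate` per site (default 5e-5, under
  one site per genome, leaving an appreciable fraction of samples
  entirely clean — as required for a meaningful "no-heteroplasmy" tree).
- All draws flow from one seeded generator per call; runs are
  byte-deterministic. No indels, no recombination, no mutation-spectrum
  bias (sequences are already aligned by construction), no coalescent
  topology within clades.

The truth record (fixed/private substitutions with classifications,
heteroplasmy placements) is written alongside the FASTA/GFF3/sample
sheet and is what the truth-oracle tests re-scan.

## Numerical and interface conventions

- Coordinates are 0-based half-open internally; GFF3 is written 1-based
  inclusive and BED 0-based half-open (via `rtracklayer`), giving
  bit-exact IO round trips.
- Strand is not published for the system; the default layout follows
  the universal vertebrate arrangement (ND6 and tRNAs gln, ala, asn,
  cys, tyr, ser-UCN, glu, pro on the light strand).
- Consensus at a column is the majority base with IUPAC symbols
  contributing fractional weight to each base of their set; ties break
  alphabetically (deterministic).
- ANOVA/Tukey run on per-pair identity values (not per-element means):
  more data, and it matches the spread shown by the published box plots.
  The α = 0.05 convention is used throughout.
- Adjusted R² for the identity~length regression is
  `1 − (1 − R²)(n − 1)/(n − 2)`; it may legitimately be negative.
- Pipeline outputs contain no timestamps, so identical configs produce
  byte-identical bundles; the run log echoes the seed and full config.
- The CLI config format is JSON (no YAML parser in the supported
  dependency set).

## Known limitations

- Identity magnitudes for ambiguous pairs follow this package's
  expected-match formula; other tools may scale differently while
  preserving the same ordering.
- The generator's uniform per-site rate cannot reproduce every
  qualitative feature of the real data simultaneously (see above);
  tests are directional where the mechanism warrants direction, and
  band/recovery checks elsewhere.
- NJ branch lengths are method artefacts once negative-length clamping
  fires; only topology should be interpreted.
- Real-data figures that depend on the original sample set (exact
  per-gene counts, printed regression/ANOVA statistics, the published
  p-values) are out of reach of a synthetic world and are deliberately
  not asserted.
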