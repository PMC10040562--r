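---
title: "Methods: context-resolved methylome analysis and window-based DMR detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-resolved methylome analysis and window-based DMR detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscan)
```

## Scope and data model

methylscan analyses plant whole-genome bisulfite sequencing at the level
of per-cytosine call tables: one row per strand-resolved cytosine with
methylated and unmethylated read counts, a sequence context (CG, CHG or
CHH — `H` being A, C or T) and a trinucleotide. A `methylome_sample`
couples such a table with genotype/replicate labels and chromosome
lengths; a `feature_set` couples gene bodies (first to last exon, from
GFF3), their 200-bp promoters, and TEs with family/superfamily labels.

Two representation choices run through the whole package:

* **Coordinates are 1-based inclusive internally**, matching the CX
  report convention on disk and the GenomicRanges/IRanges containers the
  implementation is built on. BED output alone is converted to 0-based
  half-open. Keeping the Bioconductor convention internally avoids a
  second, package-private coordinate dialect; every boundary format
  (CX report, GFF3, TE table in; BED out) is converted exactly once.
* **Cytosines are strand-resolved and never symmetrised.** A CG
  dinucleotide contributes two independent sites, one per strand; all
  counting, binning and testing treats them independently. Zero-coverage
  cytosines are kept in memory — they distinguish "no cytosine here"
  from "cytosine present but unobserved" — but contribute to no level.

## Weighted methylation levels

Every aggregation in the package is *count-pooled* (weighted): the level
of any collection of sites is

$$\bar m \;=\; \frac{\sum_i \text{meth}_i}{\sum_i (\text{meth}_i + \text{unmeth}_i)},$$

never the unweighted mean of per-site frequencies. This makes deeply
covered sites weigh more, makes the estimate identical whether sites are
pooled directly or first binned and then pooled (an identity the test
suite asserts), and makes replicate pooling by count summation exactly
equivalent to a coverage-weighted combination of replicate levels.
Levels are computed at three tiers: per site (`site_frequency`, `NA` at
zero coverage rather than 0), per 50-nt tiling bin (`bin_levels`), and
genome-wide per context (`global_levels`, printed as percentages with
two decimals). No minimum-coverage filter is applied to level
computation: any covered site counts, since an uncovered site
contributes nothing to a pooled ratio either way. `relative_reduction`
expresses a mutant's loss as `100 * (ref - test) / ref`.

## End-anchored metaprofiles

`compute_metaprofile` averages methylation around one end of a feature
class. Each feature defines an oriented frame: offset 0 at the anchored
end (5′ or 3′ in the biological orientation; minus-strand features are
flipped), offsets spanning ±5 kb, pooled into 100-bp intervals. Two
choices deserve note:

* **The opposite-end discard is a mask, not a feature filter.** Body
  positions within 1500 nt (genes) or 250 nt (TEs) of the end opposite
  the anchor are excluded from all interval sums, so that the profile
  near the anchor is not contaminated by the signal of the other end.
  Features shorter than the discard keep their flanks and lose only the
  body. Flank positions are never masked, even where they overlap a
  neighbouring feature — no exclusion rule is imposed beyond the body
  mask, which keeps the estimator simple and means dense TE clusters
  leak into each other's flanks (visible as slightly elevated flank
  levels in the simulated checks).
* **Pooling across features, not averaging per-feature means.** Counts
  are summed over all (feature, position) pairs in an interval and
  divided once. A cytosine inside two features' windows contributes once
  per frame. The per-feature-mean alternative would weight a sparse
  short feature equally with a long covered one; the pooled version is
  consistent with the weighted-level convention above.

The correctness of the frame arithmetic (strand flips, masks, interval
binning) is pinned by a brute-force oracle that enumerates every
(feature, offset) pair on small genomes.

## DMR calling

`call_dmrs` detects differentially methylated regions between two pooled
methylomes for one context:

1. **Scan**: non-overlapping 50-nt windows; a window is a candidate when
   both samples cover ≥ 1 cytosine of the context in it and the absolute
   difference of pooled window levels reaches the per-context minimum —
   0.10 (CHH), 0.20 (CHG), 0.40 (CG). The thresholds ascend with the
   baseline dynamic range of each context.
2. **Merge**: candidate windows separated by ≤ 100 nt join one region;
   a gap > 100 nt starts an independent region. Windows tile without
   overlap (step = width), which keeps "separated by" well defined;
   merging is idempotent.
3. **Filter and test**: each merged region is re-scored over *all*
   covered context cytosines it spans and kept when (i) it spans
   ≥ 100 nt, (ii) it contains ≥ 20 cytosine positions covered in both
   samples, (iii) its region-level absolute difference again clears the
   context minimum, and (iv) a two-sided Fisher's exact test on the
   pooled table (wt meth/unmeth vs mutant meth/unmeth) gives p < 0.001.
   No multiple-testing correction is applied; the raw cutoff is part of
   the procedure's definition. Direction is `hypo` when the mutant is
   below wild-type.

Interpretation choices made where the procedure leaves room: replicates
are pooled by count summation before calling (consistent with weighted
levels; a dispersion-aware per-replicate test such as beta-binomial
regression is deliberately out of scope); "sites" in the ≥ 20-site rule
are cytosine positions covered in **both** genotypes, since a position
unobserved in either sample carries no differential evidence; the
difference filter is re-applied at region level because the region — not
only its seed windows — is the unit being reported; and the 2×2 table
pools counts over the region, the standard construction when the test is
named but the table is not.

`fisher_exact_2x2` is implemented in-package with the minimum-likelihood
two-sided rule: all tables with the observed margins whose
hypergeometric probability does not exceed that of the observed table
(with a `1 + 1e-7` relative guard against ties lost to floating point)
contribute to p. The test suite checks it against `stats::fisher.test`
and against direct `choose()`-based enumeration — exhaustively for all
tables with margins ≤ 12, and over all ~1.6 × 10⁵ tables with margins
≤ 30 in the acceptance runs. A zero row or column margin returns p = 1.

## DMR annotation and overlap summaries

`assign_dmrs` maps each DMR to genomic categories by a ≥ 50%-of-DMR
overlap rule against promoters (200 bp upstream of the first exon,
clipped at chromosome ends), gene bodies and TEs. The 50% threshold is
read as a fraction of the *DMR's* length for all three feature classes
(the grammatically parallel reading; `min_overlap` is exposed for the
alternative). When both a promoter and a gene body reach 50%, the
promoter wins the gene-side label — the category tables report the two
as disjoint columns, so a precedence is required. A DMR matching both a
gene element and a TE is categorised `gene_element_and_te` and counted
in the gene-element and TE columns *and* in its own column, so the
category table satisfies
`gene_elements + te - gene_element_and_te + other = total`; DMRs with
only sub-50% overlaps land in `other`. `superfamily_summary` and
`family_representation` count *distinct* targeted TEs (a TE hit by
several DMRs counts once); family representation uses a strict
`> min_fraction` rule (default 10% of family members). `overlap_summary`
enumerates all disjoint Venn cells over any number of genotype sets and
formats fractions as `"NN.NN% (num/den)"` with two decimals.

## Replicate QC

`shared_sites` extracts CG sites covered (≥ 1 read by default) in every
sample and `pca_samples` runs a column-centred PCA on the frequency
matrix without unit-variance scaling — frequencies already share the
[0, 1] scale, and scaling would inflate near-constant sites. The
decomposition is the deterministic eigen path of `prcomp` (the sample
dimension is tiny), with each component's sign fixed by making its
largest-magnitude loading positive so results do not depend on column
order.

## The synthetic-data generator

`simulate_scenario` builds complete ground-truth scenarios: a one-
chromosome genome with non-overlapping genes (1–4 kb) and TEs (bimodal:
200–800 nt short, 3–8 kb long), cytosines placed per context at fixed
densities, and per-site counts drawn as Poisson coverage plus
beta-binomial methylated counts. Defaults — chosen once as a plausible
plant-methylome caricature, and not tuned thereafter:

| parameter | default | rationale |
|---|---|---|
| compartment levels | TE CG 0.75/0.85 (short/long), TE CHG 0.45/0.55, TE CHH 0.10; gene body CG 0.25; intergenic ≈ 0.02–0.05 | qualitative ordering of plant methylomes: TEs high in CG/CHG, modest CHH; CG-only gene-body methylation |
| cytosine density | CG 0.04, CHG 0.04, CHH 0.15 per nt (both strands) | approximate per-context densities of a ~36%-GC plant genome |
| coverage | Poisson, mean 20× | typical WGBS depth |
| dispersion | beta-binomial ρ = 0.02 | small replicate overdispersion, so replicate pooling is exercised on non-ideal data; ρ = 0 gives pure binomial |
| planted regions | 60 CHH regions, 250–600 nt, +0.3…+0.6 shift, 80% inside TEs, ≥ 1 kb apart | 250 nt × 0.15/nt ≈ 37 expected sites, comfortably above the caller's 20-site rule; separation prevents merge fusion of two planted regions |

The default planted direction is hypermethylating because the default TE
CHH baseline (0.10) leaves no room for a −0.3 shift; hypomethylating
scenarios are simulated in the CG/CHG contexts where baselines are high
(as in the replicate-QC scenario). Shifts are applied to the mutant's
site-level means and clipped to [0, 1]. One scenario seed fans out to
per-stage child streams (genome, planting, positions, counts per
genotype × replicate), so replicates share cytosine positions — as one
genome demands — while counts differ, and any stage can be regenerated
independently. Given a seed, the emitted CX reports are byte-identical
across runs.

What the generator does *not* emulate: sequence-derived cytosine
spacing (positions are uniform within the density), bisulfite
conversion failure, mapping bias, copy-number variation, chromosome-
scale methylation gradients (pericentromeres), and correlated
methylation states of neighbouring cytosines. Passing recovery tests
therefore demonstrates the correctness of the counting, merging and
testing machinery under the stated sampling model — not calling
performance on real libraries, where dispersion is larger and artefacts
are structured.

`evaluate_calls` scores calls against truth by reciprocal overlap
(≥ 50% of both lengths, same context and direction): sensitivity is the
recovered fraction of planted regions, the false-discovery proportion
the fraction of calls matching nothing.

## Numerical choices and degenerate inputs

* Fisher ties: probabilities within a `1e-7` relative factor of the
  observed table count as "as extreme" (the same guard `fisher.test`
  uses); p-values are capped at 1.
* BED scores: `round(-10·log10 p)` capped at 1000; p = 0 (underflow)
  maps to 1000.
* Zero-coverage bins and profile intervals are `NA`, never 0; profile
  comparison propagates `NA` and summarises over intervals present in
  both.
* Promoters are clipped at chromosome bounds rather than rejected;
  fully clipped promoters become zero-width and match nothing.
* Empty inputs return empty, correctly-typed results (empty DMR table
  with a warning; empty BED file; all-zero category table); a zero
  reference level makes `relative_reduction` an error rather than an
  infinity.
* Percentages are rounded half-even by R's `round`: summary tables use
  1 decimal, genome-wide levels and overlap fractions 2 decimals.

## Problem sizes used in the checks

The validation suite runs the full caller on a 1-Mb scenario (60 planted
regions, ~230 k cytosines per sample, four samples), the profile oracles
on 5-feature genomes, the Fisher enumeration up to margin 30, and the
recovery sweeps at 5×/20×/50× on 200-kb genomes — sizes chosen so the
entire suite completes in about a minute while every code path,
including merging, masking and strand flips, is exercised at realistic
densities.

## Known limitations

* One caller mode: pooled counts + Fisher. No beta-binomial dispersion
  modelling, no HMM/kernel smoothing, no joint multi-genotype calling.
* The ≥ 20-site rule counts covered-in-both positions; with very uneven
  coverage between genotypes this is stricter than counting annotated
  cytosines (the reading is configurable at the call site only through
  the parameter object, not per region).
* Metaprofile flanks are not masked against neighbouring features.
* `read_gff3` resolves exon parents through at most one intermediate
  transcript tier, which covers standard gene→mRNA→exon GFF3 but not
  deeper nestings.
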