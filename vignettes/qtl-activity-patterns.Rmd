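---
title: "Mapping treatment-dependent QTL activity patterns in recombinant inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping treatment-dependent QTL activity patterns in recombinant inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlactivity)
```

## The problem

Genetic control of gene expression and behavior is rarely constant across
environments. When the same mapping population is phenotyped under several
treatment conditions, a locus may drive a trait strongly under one treatment
and not at all under another. This package implements an analysis of that
phenomenon for recombinant inbred (RI) mouse panels measured under four
treatment arms — SC (saline control), EC (ethanol), SR (saline + restraint
stress) and ER (ethanol + restraint) — in two panels at once, so that every
association can be compared across eight panel-by-condition combinations.

The unit of analysis is the *QTL activity pattern*: for a trait–locus pair,
the vector of association strengths across the four conditions, and the
binary vector recording in which conditions the association clears the
panel's significance threshold. With four conditions there are
`2^4 - 1 = 15` possible non-null patterns
(`enumerate_patterns(4)`).

## The mapping statistic

RI strains are homozygous at every locus, so a marker splits the panel into
two allele groups. For a strain-mean trait $y$ over $N$ usable strains the
likelihood ratio statistic at a marker is

$$\mathrm{LRS} = N \,\ln\!\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1}
             = -N \,\ln\!\left(1 - r^2\right),$$

where $\mathrm{RSS}_0$ is the residual sum of squares about the grand mean,
$\mathrm{RSS}_1$ about the two genotype-group means, and $r$ is the Pearson
correlation between the trait and the 0/1-coded genotype. The LOD score is
$\mathrm{LRS} / (2\ln 10)$; the constant $2\ln 10 = 4.605\ldots$ is exposed
as `lrs_per_lod()`. Both closed forms are implemented and tested against a
`stats::lm`/`logLik` maximum-likelihood oracle; they agree to $10^{-9}$ on
random instances.

Conventions that matter downstream:

* **Effect sign.** `effect_sign = sign(mean(B) - mean(A))`, where B is the
  second parental allele (ILS/DBA2-like). It is 0 only on exact equality.
* **Missing data** are dropped pairwise per marker; a marker needs at least
  2 usable strains per allele group, otherwise it is skipped with a reason
  code. Markers with fewer than 2 carriers of either allele panel-wide are
  flagged uninformative up front.
* **Perfect fits.** When $\mathrm{RSS}_1 = 0$ the LRS is reported as a
  configurable cap (default 300) with a `capped` flag rather than infinity.
  The cap only matters for near-noise-free synthetic data.
* **QTL calling.** One QTL per chromosome per trait: the marker with the
  maximum LRS, ties broken toward the smaller genomic position
  (`chromosome_max_qtls()`).
* **Strictness.** Significance is strict (`LRS > threshold`) everywhere,
  including conservation checks; an LRS exactly at the threshold is not
  significant.

## Permutation significance

Two permutation constructions are provided:

* `genomewide_pvalue()` for a single (behavioral) trait: the empirical
  genome-wide p-value $p = (1 + \#\{\text{permuted max} \ge
  \text{observed max}\}) / (n_{perm} + 1)$, with 1000 permutations as the
  study default.
* `permutation_fdr()` for transcriptome-wide scans: all per-trait
  per-chromosome maxima are recomputed under permutations of the strain
  labels, and for each threshold $\theta$ the false discovery rate is
  estimated as the mean permuted count above $\theta$ divided by the
  observed count above $\theta$. By default one shared shuffle is applied to
  all traits per iteration, which preserves the co-expression structure of
  the trait matrix; a switch (`shared_permutation = FALSE`) permutes each
  trait independently, since the original construction is not fully
  determined and both are defensible.

The estimated FDR curve is forced non-increasing in $\theta$ by a running
minimum over the ascending grid — the raw estimator can wiggle at high
thresholds where counts are tiny, and threshold selection should not exploit
that. `significance_threshold(fdr, rate, method = "fdr")` returns the
smallest grid $\theta$ with FDR at or below the target.

One subtlety: under a *global null* (no signal at all) the observed and
permuted counts estimate the same quantity, the FDR estimator is ~1
everywhere, and no threshold attains a 5% FDR — correctly so, since every
discovery would be false. Calibration of the permutation machinery is
therefore assessed with `method = "null-quantile"`: the 95th percentile of
the pooled permuted trait-chromosome maxima, i.e. the per-comparison 5%
threshold implied by the same permutations. On pure-noise studies the
realized proportion of observed maxima above that threshold sits inside the
binomial 95% band around 0.05 (this is one of the packaged acceptance
checks). On studies with signal, the FDR-based threshold is the one used by
the pipeline; fixed replication-style thresholds (e.g. 24 and 26 LRS units
for the two panels of the emulated study) can be supplied instead via
`run_pipeline(..., thresholds = )`.

## eQTL classes and activity patterns

Significant eQTLs are classified by gene–marker geometry
(`classify_eqtl()`): *cis* when gene and marker are on the same chromosome
within 5 Mb (boundary inclusive — "within 5 Mb" is read as $\le$), *syntenic
trans* on the same chromosome but farther, *non-syntenic trans* on different
chromosomes. The gene "position" is a single annotation-supplied coordinate;
for synthetic data it is the planted gene position. Behavioral traits are
`not_applicable`.

For every significant (trait, marker) pair, `activity_patterns()` recomputes
the LRS under all four conditions at that fixed marker and thresholds the
vector into bits. The pattern index packs the bits with SC as the most
significant bit (so bits SC,EC = 1,1 give index 12); the encoding is an
arbitrary but fixed convention — nothing downstream depends on it beyond
bijectivity, which is tested.

An optional probe-level filter (`filter_probe_snp_cis()`) removes cis-eQTLs
that look like hybridization artifacts: probe contains a segregating SNP,
expression is higher for the reference-allele strains (sign $-1$ under the
B-coded convention), and the pattern is significant in all four conditions.
In the emulated study this filter was only applicable to the panel with
sequenced parents, so it is exposed as an explicit per-panel step rather
than wired into the pipeline.

## Cross-population conservation

Panels have different marker maps, so a hit in one panel is matched into the
other by the nearest marker on the same chromosome (ties toward the lower
position); a sensitivity mode restricts to identical marker ids. The trait's
per-condition LRS is recomputed at the matched marker and thresholded with
the *other* panel's threshold. `conserved_any` means at least one condition
is significant there; `pattern_identical` requires identical bits.

Genome-wide structure in conservation is summarized by
`sliding_conservation_ratio()`: half-open windows $[x, x + 50)$ Mb stepped
by 5 Mb (the window width follows the emulated study; the step is this
package's choice — the study does not print one), with

$$\text{ratio} = \frac{\#\text{conserved in window}}
                      {\#\text{features in window} \times
                       \text{global conserved fraction}}.$$

Windows overhanging a chromosome end are kept and flagged; empty windows get
a missing ratio rather than zero. The same operation serves eQTLs (feature
position = marker position of the hit) and SNP panels, and
`track_correlation()` gives the Pearson correlation of the two tracks over
windows defined in both.

## Candidate genes and pattern-correlation networks

Given a behavioral QTL region (`region_spec()`), `select_candidates()` keeps
genes whose region eQTLs satisfy three criteria: not significant in SC,
significant in EC, and not conserved in the other panel. Genes whose
cross-panel record could not be computed cannot satisfy the third criterion
and are excluded.

`build_pattern_network()` generalizes the binary matching: each trait is
summarized by an 8-entry vector of region-maximum LRS values (both panels ×
four conditions, `region_lrs_vector()`; the region max is the natural
reading of scoring a locus rather than a single marker, with a single-marker
alternative available by narrowing the region). Transcripts with focal-panel
EC region LRS > 20 (FDR roughly 25% in the emulated study) are candidates;
those correlating with the phenotype's vector at $r > 0.7$ become nodes, and
edges (phenotype–transcript and transcript–transcript, distinguished by a
column) are drawn at $r > 0.8$. Correlations use pairwise-complete entries
and pairs sharing fewer than 4 entries yield no edge.

## The synthetic-data generator

`make_two_panel_study()` generates the full study: genotypes, conditioned
trait sets, a SNP panel and ground truth. It emulates the design of the
motivating study; its defaults are the study conditions, not tuning knobs:

* **Panels.** 31 and 30 strains (the two panels' expression-study sizes),
  2659 and 3796 markers on 19 autosomes + X with approximate mouse
  chromosome lengths.
* **Genotypes.** Each strain–chromosome is a two-state Markov chain: first
  marker A/B with probability ½, transition probability between adjacent
  markers $d$ Mb apart $p = \tfrac12(1 - e^{-2rd})$, capped at ½. The
  breakpoint rate defaults to $r = 0.02$/Mb, i.e. roughly 0.5 cM/Mb scaled
  by the ~4-fold map expansion of RI panels. Map expansion is not modeled
  explicitly (no $4r/(1+6r)$ correction) because the analysis never uses
  genetic distances — only the linkage structure matters for testing the
  statistics.
* **Traits.** Strain means: baseline per trait from Normal(8, 1)
  (log-intensity-like units), plus an additive shift of B-allele carriers
  per condition, plus Normal(0, $\sigma$) noise per strain × condition,
  $\sigma = 1$. Planted effect sizes default to $3\sigma$ (well separated:
  about 70% of trait variance at the causal marker). Replicate-level noise
  is not modeled — the emulated study analyzed strain means directly.
* **Patterns by class.** Cis effects are active in all four conditions with
  probability 0.6, otherwise a random non-null pattern; non-syntenic trans
  effects are single-condition with probability 0.85 (EC-biased), matching
  the qualitative direction reported for real panels (cis mostly conserved,
  trans mostly treatment-specific). Behavioral traits get an EC-only QTL in
  panel 1.
* **Sharing.** Each causal variant is shared between panels with probability
  `sharing_fn(chr, pos)`; shared effects are planted at each panel's nearest
  marker to a common position with equal effect sizes, private effects leave
  the trait null in the other panel. SNP conserved flags follow the same
  function, so eQTL and SNP conservation tracks are positively associated by
  construction. The default is a patchy function alternating 0.8/0.1 over
  50-Mb blocks; tests also use constant and step functions.

What the generator does *not* emulate: probe-level microarray noise, batch
effects, sex, non-additive (dominance/epistatic) effects, polygenic
background and kinship structure, and realistic linkage disequilibrium with
the SNP panel. Passing tests on this generator therefore demonstrate that
the statistics and bookkeeping are implemented correctly and are calibrated
under the stated model — not that the thresholds or power would transfer
unchanged to real microarray data.

## Numerical and design choices

* Positions are Mb throughout; no genome-build conversion is attempted.
* Heterozygous or unknown genotype codes are read as no-calls: RI strains
  are homozygous in theory, so residual heterozygosity is treated as
  missing rather than as a third genotype class.
* Chromosome ordering for output is 1..19 then X; chromosomes are
  categorical strings.
* The FDR grid default is LRS 5–50 by 0.5; `theta_at_target` is missing when
  the curve never reaches the target, never extrapolated.
* `run_pipeline()` derives per-stage seeds from the global seed by a fixed
  counter scheme, so stages are individually re-runnable and a rerun with
  the same config is byte-identical (checked on file digests).
* Test and acceptance runs use scaled-down designs (40–60 strains, 100–200
  markers over 4–5 chromosomes, 40–60 traits, 60–200 permutations, 50–200
  replicates) chosen once as sizes at which the Monte-Carlo checks are
  informative; the generator's own defaults stay at the emulated study's
  scale.

## Known limitations

* Single-marker regression only: no interval mapping, no multi-QTL models,
  no kinship correction (the emulated analysis used none).
* The FDR estimator is the ratio-of-counts construction; it is accurate in
  the signal-rich transcriptome setting it was designed for and
  uninformative under a global null (see above).
* Cross-panel matching assumes shared trait identifiers; traits absent from
  the other panel produce records with missing conservation flags and are
  counted, not silently dropped.
* The conservation-ratio track carries no significance bands; it is a
  descriptive statistic.
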