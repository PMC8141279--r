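---
title: "Methods: differential methylation calling and regulatory integration in rrbsdml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation calling and regulatory integration in rrbsdml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsdml)
```

## Scope and data model

rrbsdml analyses replicated two-group RRBS count data: for each sample, a
table of CpG sites with methylated and total read counts (Bismark-style
cytosine reports, kept strand-specific — the two cytosines of a CpG dyad
are never merged, because cytosine reports are per-cytosine and merging is
an analysis decision the user should make explicitly). Cytosine positions
are 1-based; all interval work (BED, bedGraph, peaks, windows) is 0-based
half-open, with the conversion (`pos - 1`) centralised, so off-by-one
behaviour is fixed in one place and tested there.

The two groups are called "CD8" (reference, the precursor population) and
"DN" (case). The methylation difference Δ is always case minus reference,
so demethylation in the case group gives Δ < 0 ("hypo").

## Coverage filtering and QC

A CpG enters testing only if its coverage, **summed over the replicates of
a group**, reaches `min_cov = 10` in *each* group. The group-pooled reading
(rather than a per-sample rule) is the default because the rule is stated
per group and because pooled-coverage filters are what beta-binomial
callers in this field typically assume; the stricter per-sample mode is
available via `coverage_filter(..., per_sample = TRUE)`. The filter is
idempotent and monotone in `min_cov`, and both properties are tested.

Conversion efficiency is the pooled converted fraction over the spike-in
control's unmethylated-context cytosines; a run passes QC when it exceeds
0.99 (configurable). With 1,000 sites at 50x depth the estimator's binomial
standard error is about 0.03%, so a true rate of 0.995 essentially always
clears the bar — the check guards against gross conversion failure, not
small drifts.

Global methylation summaries average per-CpG fractions **unweighted** per
sample (the quantity a violin plot of per-CpG methylation shows), then
average samples within groups. Group-level per-CpG fractions elsewhere use
pooled counts (ΣX/ΣN), which weight reads, not sites; the two conventions
serve different purposes and are deliberately not unified.

## The beta-binomial Wald test

Replicate methylation proportions are overdispersed relative to binomial
sampling; the beta-binomial dispersion φ captures this
(Var = Nμ(1−μ)(1+(N−1)φ)). The test has three parts.

**Raw dispersion.** A per-CpG method-of-moments estimate pools squared
deviations of replicate proportions from their group mean over both groups
and equates them to their beta-binomial expectation:

$$\hat\phi_i \;=\; \frac{\sum_{g,r}(\hat p_{gr}-\hat\mu_g)^2 \;-\;
\sum_{g,r}\hat\mu_g(1-\hat\mu_g)/N_{gr}}
{\sum_{g,r}\hat\mu_g(1-\hat\mu_g)(N_{gr}-1)/N_{gr}},$$

clamped at zero. With three replicates per group this is extremely noisy,
which motivates shrinkage.

**Shrinkage.** Log dispersions are shrunk towards an empirical log-normal
prior: \((m_0, r_0^2)\) are the mean and variance of \(\log\hat\phi\) over
CpGs with finite positive \(\hat\phi\), and
\(\log\tilde\phi_i = w_i\log\hat\phi_i + (1-w_i)m_0\) with
\(w_i = r_0^2/(r_0^2+s_i^2)\) and \(s_i^2 = 2/(n_i-1)\), where \(n_i\)
counts replicates with nonzero coverage — a simple information-monotone
approximation to the sampling variance of a log variance-ratio that only
enters through the weight. CpGs whose raw estimate is zero or undefined
receive the prior mean \(\exp(m_0)\). If no CpG yields a usable raw
estimate (degenerate inputs), the weakly informative fallback
\((m_0, r_0^2) = (\log 0.01, 1)\) applies; 0.01 is a typical replicate
dispersion for sorted-cell bisulfite libraries and the unit prior variance
keeps the fallback weak.

Restricting the prior to *positive* raw estimates biases \(m_0\) slightly
upward (the clamped-at-zero half of the noise distribution is excluded),
which makes the test err on the conservative side; simulation shows the
effect is mild at the default design (see Calibration).

**Wald statistic.** Group means are pooled-count estimates with the
beta-binomial variance given in the README; the two-sided p comes from the
standard normal, the usual Wald convention — no small-sample t correction
is applied, and no positional smoothing is used (single-CpG resolution is
the target). Two numerical edge cases are handled explicitly: identical
pooled counts give t = 0, p = 1 by symmetry; and when both group means are
exactly 0 or 1 the plug-in variance collapses to zero, so it is recomputed
with \(\hat\mu\) replaced by \((\Sigma X + 0.5)/(\Sigma N + 1)\), which
keeps t finite and preserves its sign. p-values are clamped into
\((0, 1]\) so that downstream BH never sees an exact zero.

**Calling.** FDR is Benjamini–Hochberg (via `stats::p.adjust`); a CpG is
significant iff FDR < 0.05 **and** |Δ| > 0.20, both strict, so ties at
either threshold are non-significant. One wording note for users comparing
against the published description of this workflow: the methods text there
says "<20% change" where the results and all summaries use ">20% change";
this package implements the latter, which is the only reading under which
an effect-size filter makes sense.

This caller is a self-contained implementation of the beta-binomial Wald
family that DSS-style callers belong to; numerical identity with any
particular external tool is *not* claimed — correctness is established by
formula-level oracle tests and by simulation calibration instead.

## Calibration and recovery (what the tests show)

All calibration statements below are computed by the test suite itself, on
data from the package's own generator.

* **Type-I error.** On null simulations at the study design scale (two
  groups of three replicates, mean coverage 20x, φ = 0.02, ~50,000 CpGs,
  three seeds), the fraction of CpGs with raw p < 0.05 falls in
  [0.03, 0.07], and the significant fraction at the default double
  threshold is ~0. The test is mildly conservative at CpGs with extreme
  methylation (near 0 or 1), where pooled counts are small and discrete —
  the same behaviour any normal-approximation test shows there.
* **Recovery.** With spiked |Δ| = 0.5 at 30x coverage, sensitivity on
  truth DMLs is ≥ 0.8 and precision ≥ 0.9 across seeds, and the
  hypo:hyper split of the calls tracks the generator's 96:4 mixture within
  3 points.
* **Permutation and motif p-values.** Under null peak placement the
  permutation p is approximately uniform (the strictly-greater counting
  rule makes it conservative under count ties, so only the upper
  rejection-rate bound binds); exchangeable foreground/background windows
  give approximately uniform motif-enrichment p.

## Interval enrichment

`bedtools`-style semantics are implemented directly: window overlap
extends every peak by w on both sides and counts loci (points) falling in
the union, so each locus counts at most once; merging coalesces
overlapping *and* book-ended intervals; shuffling preserves every
interval's length and re-places it uniformly genome-wide, the chromosome
drawn proportionally to its length among chromosomes that can hold the
interval, with shuffled intervals free to overlap one another. Genome-wide
(rather than within-chromosome) re-placement is the shuffle default here
as in bedtools. The empirical p counts permutations whose overlap
**strictly exceeds** the observed count; an add-one ("(k+1)/(n+1)")
convention is *not* used because the reporting convention for zero
exceedances is the bound "<1/n_perm" (stored numerically as 0 alongside
the bound string, and the full permuted-count vector is exported for
reanalysis).

Signal aggregation computes exact bin means of the piecewise-constant
bedGraph track via its cumulative integral — equivalent to per-base
averaging (tested against it) but O(log n) per bin edge. Gaps count as
zero; windows truncated at chromosome edges are zero-padded and flagged.
Anchor-level condition comparisons use the equal-variance two-tailed
Student t test on per-anchor window means.

A no-op `liftover_identity` hook marks the place where assembly liftover
would sit in a workflow whose peak atlas and methylome use different
genome builds; the synthetic pipeline shares one coordinate system, so
conversion is a non-goal here.

## Annotation and expression integration

Each DML is assigned to the gene with the nearest TSS on its chromosome by
absolute point distance, strand-ignored — the minimal assumption when no
orientation rule is given — with ties broken by lexicographically smallest
gene id and the signed distance (pos − TSS) reported. No maximum distance
is applied by default. The input table carries one TSS per gene; collapsing
transcript-level TSS to genes is the caller's responsibility and the
generator emits gene-level tables. Because every DML gets exactly one
gene, per-gene DML counts add up to the number of annotated DML, which
makes the demethylation-burden gene ranking (descending hypo-DML count,
ties by id) well defined.

## Motif analysis

Windows are 400 bp total (±200 bp) around hypomethylated DML — the window
half-width is a parameter, but 400 bp is the default because that is the
standard scan size for this analysis and matches the motif-centred profile
width. Scanning is additive log2-odds over pseudocount-adjusted
probabilities (default pseudocount 0.01, uniform background), both
strands, with the hit threshold defaulting to 0.8 of the maximum
attainable score. Enrichment compares the fraction of foreground windows
containing ≥ 1 hit with the background fraction by one-sided binomial
test; a zero background fraction with foreground hits is
continuity-corrected to 1/(2·n_bg). A hypergeometric variant was
considered and not implemented: with backgrounds twice the foreground size
the binomial tail is the standard choice and the two agree closely at
these sizes.

Background windows are CpG-anchored, sampled at least 1 kb from any
foreground anchor and matched to the foreground GC distribution in
quintile bins. CpG anchoring matters in RRBS-like data: enzyme-digest
libraries are enriched for MspI (CCGG) and TaqI (TCGA) sites, so those
sequences are abundant around *any* CpG-anchored window. The bundled PWM
library ships both restriction-site "motifs" as positive controls —
matched backgrounds should score them near parity between foreground and
background, and the tests assert exactly that, rather than masking the
artifact.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
conditions every calibration number above refers to.

* **Design**: two groups × three replicates, emulating three independent
  cell purifications per population.
* **Genome**: one or more uniform-length chromosomes with CpG sites placed
  uniformly at a configurable density (default 0.005/bp at 1 Mb for smoke
  runs; the calibration tests use up to 10 Mb), minimum 2 bp apart so CG
  dinucleotides never overlap; optional random sequence with CG written at
  every site. No attempt is made to model CpG islands, isochores or real
  chromosome lengths.
* **Baseline methylation**: a two-component Beta mixture, Beta(3, 39) and
  Beta(39, 3) (modes exactly at 0.05 and 0.95) with 30% weight on the low
  mode, reproducing the strongly bimodal genome-wide distribution of
  mammalian CpG methylation in which most sites are highly methylated.
* **Coverage**: shifted negative binomial, 1 + NB(mu = 19, size = 5) at the
  default 20x mean — overdispersed, with a realistic loss of CpGs at the
  ≥ 10-reads-per-group filter when coverage is set low.
* **Dispersion**: beta-binomial with φ = 0.02 by default; φ = 0 degenerates
  to plain binomial counts (tested by moment checks against the
  closed-form variance).
* **DMRs**: non-overlapping fixed-length regions (default 40 × 1 kb),
  hypo:hyper mixture 96:4, hypo baseline 0.9 shifted by −0.5 — the
  "nearly fully methylated in precursors, intermediate in cases" pattern.
  Every CpG inside a DMR with nonzero shift is recorded in a truth table
  for recovery scoring. Validation uses the direction-aware bound
  (baseline + delta must stay in [0, 1]); overlapping DMRs with
  conflicting directions are rejected.
* **Peaks and signal**: each truth DML receives, with probability 0.9, an
  "effector" peak centred within ±500 bp, on top of uniform background
  peaks; a "naive" peak set is uniform. Signal tracks are gamma background
  noise elevated inside that condition's peaks, binned at 50 bp.
* **Expression**: genes nearest to ≥ 1 hypo truth DML are upregulated with
  probability `coupling` (default 0.8) — unambiguously above the
  log-fold-change and p thresholds — others draw from a zero-centred null.
* **Motifs**: a consensus (default TGACTCA) is planted within ±200 bp of
  hypo-DML anchors at a configurable rate, never overwriting a declared
  CpG (sites are re-drawn, then skipped and logged if no CpG-free
  placement exists).

Determinism: every generator takes a seed, and the pipeline derives a
named substream seed per stage from one master seed, so stages can be
regenerated independently and full reruns are byte-identical (verified by
digest comparison in the tests). All randomness is restored-state local:
library calls never disturb the caller's RNG.

What the generator does **not** emulate: read-level error, alignment
artifacts, real CpG spatial clustering, strand-asymmetric coverage,
batch effects, and biological covariance between neighbouring CpGs beyond
shared DMR membership. Passing calibration on this generator therefore
demonstrates statistical correctness of the estimators under the stated
model, not robustness to every failure mode of real libraries.

## Problem sizes

The default configuration (1 Mb genome, ~5,000 CpGs, 40 DMRs, 1000
permutations) runs the full pipeline in a few seconds on one CPU; the
calibration suites use up to 50,000 CpGs per seed. These sizes were chosen
so the whole test suite doubles as a quick regression check while still
estimating the calibration fractions with standard errors well inside the
asserted bands.

## Known limitations

* The Wald test is conservative at extreme methylation fractions under
  small pooled counts; if most of a genome sits at the bimodal extremes
  the realised type-I rate runs below nominal.
* No DMR segmentation is provided — the unit of inference is the CpG; the
  truth table's DMR structure is used only for simulation and scoring.
* No multi-factor designs or paired tests; exactly two groups.
* The motif stage scans known PWMs only; no de novo discovery.
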