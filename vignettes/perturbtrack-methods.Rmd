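---
title: "Analytic scoring of mutationally perturbed functional tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic scoring of mutationally perturbed functional tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbtrack)
```

## The model

Cancer driver genes tend to accumulate somatic missense mutations in the
parts of their protein products that do something: ligand-binding interfaces,
domains, evolutionarily conserved positions — or simply across the whole gene
more often than its natural variability predicts. `perturbtrack` encodes each
kind of evidence as a *track*: a set of 1-based protein positions $W$ with
weights $w_j \in [0,1]$ measuring one flavor of per-site functionality.

Given $n$ missense mutations landing in a track, each carrying a subclonal
fraction $f_i \in (0,1]$ (the fraction of sequencing reads supporting the
mutation) and hitting a position with weight $z_i$, the track score is

$$S_W = \sum_{i=1}^{n} f_i\, z_i .$$

Under neutrality the $z_i$ are i.i.d. draws from the background distribution
of positions, so no permutations are needed: with $\lambda^W_j$ the
per-position background probability rescaled to sum to 1 over the track,

$$E[S_W] = \sum_i f_i \sum_{j\in W} \lambda^W_j w_j , \qquad
\sigma^2_{S_W} = \sum_i f_i^2 \Big( \sum_{j\in W} \lambda^W_j w_j^2 -
\big(\sum_{j\in W} \lambda^W_j w_j\big)^2 \Big),$$

and the enrichment statistic is $Z_W = (S_W - E[S_W])/\sigma_{S_W}$. Both
moments factor as a track-fixed constant times $\sum_i f_i$ or
$\sum_i f_i^2$, which is what `precompute_tracks()` / `score_batch()`
exploit: constants are computed once, then any mutation batch is scored by
rescaling. The same factorization holds for the covariance between two tracks
$V, W$ sharing positions $X = V \cap W$: conditional on the $q$ mutations
observed in $X$ with $F = \sum f^2$ over them,

$$\mathrm{cov}(S_V, S_W) = F \Big( \sum_{j\in X} \lambda^X_j v_j w_j -
\sum_{j\in X} \lambda^X_j v_j \sum_{j\in X} \lambda^X_j w_j \Big),$$

zero for disjoint tracks. We renormalize $\lambda$ over $X$ (notation
$\lambda^X$) for consistency with the per-track rescaling.

Per-track Z scores are combined per isoform with a weighted Z-transform with
correlation correction,

$$Z = \frac{\sum_i c_i Z_i}{\sqrt{\sum_i c_i^2 + 2\sum_{i<j} c_i c_j r_{ij}}},$$

where $r_{ij}$ is the between-track correlation from the closed-form
covariance and $c_i$ are confidence weights. Each functionality group present
(interaction, domain, conservation, natural variation) receives an equal
share of the total confidence; within the interaction and domain groups,
track confidence scales with $\sqrt{m}$, $m$ being the number of mutations at
positively weighted positions ($\propto m$ is available via
`weight_rule = "linear"`). A gene's score is the maximum combined Z over its
isoforms, ties broken lexicographically.

## Background mutation model

Position-level mutability comes from codon structure: for each codon, the
nine single-nucleotide substitutions are enumerated and the amino-acid
changing ones counted, weighting positions whose reference base is C or G by
a bias factor $b$ (default 3.063, the relative C/G versus A/T mutation
frequency in tumors; it is a configuration constant, not re-estimated).
Synonymous changes and changes to stop codons do not count. When no coding
sequence is available a uniform background over the track is used.

The whole-gene (natural variation) background is built from variant counts of
healthy individuals: per individual, genes are min-ranked by count, ranks are
scaled to $[0,1]$ as $(\text{rank}-1)/(N-1)$, floored into 0.01-wide bins,
averaged across individuals, and normalized to sum to 1. Two numerical
choices: a small floor (default $10^{-4}$, added before normalization)
prevents the lowest-ranked gene from having exactly zero background
probability, which would make any observed mutation there infinitely
surprising; and bin flooring adds $10^{-9}$ before `floor()` because, e.g.,
$0.5/0.01$ is slightly below 50 in binary floating point. The whole-gene
track is one-hot, so its score moments simplify, and the total mutation
count is subsampled by $s$ (default $1/\sqrt{n}$, configurable) to keep
whole-gene Z scores on the scale of subgene tracks; the text we follow here
is ambiguous about the exact factor, so it is exposed as a parameter.
Whole-gene tracks have zero covariance with all subgene tracks.

## Track construction

* **Interaction tracks** transfer per-match-state ligand binding frequencies
  from domain annotations. Families repeated within a protein also get an
  *aggregate* track over the union of instance positions; at 40+ repeats the
  individual tracks are replaced by the aggregate. When instances overlap at
  a position the aggregate keeps the maximum weight (the strongest binding
  signal; the choice is not dictated by the method).
* **Domain tracks** span the whole protein with weight 1 inside the instance
  and 0 outside.
* **Conservation tracks** score each alignment column as (fraction of
  non-gap rows) × JSD(column residue distribution, BLOSUM62 background).
  We use the plain base-2 Jensen–Shannon divergence with ½/½ mixture weights
  so weights stay in $[0,1]$, empirical column frequencies without
  pseudo-counts or sequence weighting (richer estimators exist; the simple
  one keeps the weight contract exact and is the default), and treat
  non-standard residue letters as gaps.

## Minimum-mutation calibration

$Z_W$ is only meaningful once $S_W$ is close to normal. For each track we
draw 1,000 random score sums per mutation count $n = 1, 2, \ldots$ under the
track background and apply a Shapiro–Wilk test at $\alpha = 5\times10^{-5}$;
the calibrated minimum $n^*$ is the smallest count from which three
consecutive counts fail to reject (the run-of-three requirement guards
against single-count noise). Tracks that never look normal within the probed
range are flagged and excluded from combination; constant-weight
(degenerate) tracks are excluded outright since their score variance is
zero. In cohort scoring the probe range is capped at the track's observed
mutation count — a larger $n^*$ could never be satisfied — which bounds the
computation without changing any eligibility decision. Calibrations are
cached to JSON sidecars keyed by a content hash of the weights, background
and protocol. Whole-gene tracks get $n^* = 1$: their score is a sum over the
*total* cohort mutation count, which is what the central limit theorem
operates through, not the per-gene count.

In practice the calibration orders track shapes as expected: smooth
real-valued tracks calibrate at a handful of mutations, while 0/1 tracks
produce discrete binomial-type scores that the Shapiro–Wilk test rejects up
to hundreds of mutations — heavily skewed ones (tiny background mass on the
weight-1 positions) never pass at desk-scale mutation counts and simply do
not participate in combination.

## Positive-only combination and null calibration

Following the enrichment-detection design, only tracks with positive Z
scores enter the combination by default (`positive_only = TRUE`): the method
looks for excesses, and negative tracks would dilute independent positive
evidence. The cost is that the combined score is *not* N(0,1) under the
null — restricting to positive terms truncates the distribution and shifts
its mean up by construction. The calibration property belongs to the
untruncated statistic: with `positive_only = FALSE` the combined Z of the
full pipeline on 2,000 synthetic null genes has mean ≈ 0, SD ≈ 1 and
P(Z > 2) ≈ 0.02 (the acceptance suite recomputes this). Rankings should use
the default; null-calibration checks should use the untruncated switch.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` builds per gene: 1–2 contiguous domain-like regions, each
carrying an interaction track with beta(2,2) binding weights and a 0/1 domain
track; a full-length conservation track with beta(1.5,3) weights (right-
skewed, as conservation scores are); a codon-based background from a random
coding sequence; and 30 missense mutations per gene with subclonal fractions
uniform on (0.2, 1]. Driver genes draw mutation positions from the background
with its mass multiplied by the effect size (default 5×) on high-weight
functional sites — positions where a site-resolution weighted track
(interaction or conservation) reaches the cutoff (default 0.5). Domain tracks
are 0/1 membership indicators, not per-site strengths, and deliberately do
not define sites. Problem sizes used in the shipped validation: 2,000 null
genes for calibration, 1,000 null + 50 driver genes for ranking power, 30
mutations per gene, 20,000 shuffles per oracle fixture.

The generator does not emulate: trinucleotide signature structure (the bias
enters only through the codon-level C/G factor), correlation between
conservation and interaction weights, copy number or indels, multiple
isoforms per gene, or per-sample mutation burden heterogeneity. Passing the
synthetic validation therefore demonstrates the statistical machinery —
closed forms, calibration, combination, ranking — under the stated generative
model, not performance on real tumor cohorts.

## Degenerate inputs and numerical conventions

* Coordinates are 1-based inclusive protein positions everywhere.
* Mutations with missing $f$ default to 1; silent and nonsense mutations are
  parsed and retained but never scored.
* All-zero backgrounds over a track, constant-weight tracks, and empty
  overlap sets are handled explicitly (errors or zero covariance, as
  documented per function).
* Between-track correlation matrices are symmetrized and, when conditioning
  noise produces a slightly indefinite matrix, projected to the nearest
  positive semi-definite correlation matrix by eigenvalue clipping before
  Eq.-style combination; a non-positive combined variance is an error, not a
  silent fix.
* Expression filtering removes a mutation only when its gene's TPM in the
  matching sample (or, for samples without expression data, the gene's mean
  TPM over other samples of the same cancer type) is strictly below 0.1;
  genes absent from the expression table pass, since only measured
  non-expression is evidence.

## Known limitations

The analytic covariance conditions on the mutations observed in each overlap,
so the per-track and cross-track conditioning are not drawn from one joint
model; the permutation oracle in the test suite quantifies exactly where the
closed forms and a shared-draw Monte-Carlo scheme agree (full-span tracks)
and where the conventions differ (disjoint tracks under shared draws are
mutually exclusive rather than independent). Combined scores are ranks, not
p-values: no multiple-testing control is provided or implied.
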