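# perturbtrack

Analytic detection of genes whose somatic missense mutations are enriched in
weighted functional sites — ligand-binding interfaces, protein domains,
conserved positions — or across the whole gene.

## Who this is for

Cancer genomicists ranking candidate driver genes from cohort-level somatic
mutation tables, and methodologists who need closed-form per-region mutation
enrichment statistics instead of permutation tests.

## The statistic

Each kind of per-site functionality is a *track*: positions `W` of a protein
with weights `w_j ∈ [0,1]`. For `n` missense mutations in the track with
subclonal fractions `f_i` hitting weights `z_i`, the track score is
`S_W = Σ f_i z_i`. Modeling mutation positions as i.i.d. draws from a
codon-aware background `λ` (C/G sites weighted by a bias factor b = 3.063),
the score's mean and variance are closed-form:

    E[S_W] = Σ f_i · Σ_j λ^W_j w_j
    var    = Σ f_i² · ( Σ_j λ^W_j w_j² − (Σ_j λ^W_j w_j)² )
    Z_W    = (S_W − E[S_W]) / sd(S_W)

Tracks sharing positions `X = V ∩ W` get a closed-form covariance
`F · ( Σ_X λ^X v w − Σ_X λ^X v · Σ_X λ^X w )` with `F = Σ f²` over the
overlap mutations. Per-track Z scores (each gated by a Shapiro–Wilk-calibrated
minimum mutation count) are combined with a weighted Z-transform with
correlation correction,

    Z = Σ c_i Z_i / sqrt( Σ c_i² + 2 Σ_{i<j} c_i c_j r_ij ),

with the four track groups (interaction, domain, conservation, natural
variation) sharing confidence equally, and a gene scored by the maximum over
its isoforms. A one-hot whole-gene track built from healthy-population
variant counts captures overall mutation excess.

## Worked example

Simulate a 30-gene cohort in which 5 driver genes draw mutations with 5×
background mass on high-weight functional sites, then score it:

```r
library(perturbtrack)

cfg <- synthetic_config(seed = 42, n_genes = 30, n_drivers = 5, effect = 5)
coh <- generate_cohort(cfg)
res <- score_cohort(coh$tracks, coh$mutations, lambda = coh$lambda, seed = 42)
res
#> <gene_results> 30 genes scored (900 missense mutations)
#>        gene best_isoform combined_z n_tracks_included n_mutations
#> 1  GENE0010    ISO0010.1   4.260157                 2          30
#> 2  GENE0001    ISO0001.1   3.762513                 1          30
#> 3  GENE0021    ISO0021.1   2.829943                 2          30
#> 4  GENE0017    ISO0017.1   2.437665                 2          30
#> 5  GENE0025    ISO0025.1   2.404458                 2          30
#> ...
```

`combined_z` is the correlation-corrected combination of the gene's
calibrated, positively scoring tracks (larger = more enrichment of mutations
in functional sites than the codon-aware background predicts);
`n_tracks_included` counts the tracks that entered the combination. Four of
the five top-ranked genes above are true drivers. Downstream analyses work
off the same objects:

```r
# are the top gene's interface mutations hotspot-like or spread out?
interaction_entropy(
  Filter(function(t) t$isoform_id == res$genes$best_isoform[1], coh$tracks),
  coh$mutations[coh$mutations$gene == res$genes$gene[1], ])
#> <entropy_result> normalized entropy 0.4715 over 62 interaction sites (7 mutations)

# which mechanism does each gene's signal come from?
head(mechanism_report(res, threshold = 0.5), 3)
```

A normalized entropy of 0.47 means the top gene's interface mutations are
moderately concentrated (0 = one hotspot site, 1 = uniform across all 62
interaction sites). `enrichment_curve()` and `jaccard_overlap()` evaluate
rankings against a gold-standard gene list; `read_mutations()`,
`read_tracks()`, `read_expression()` and `expression_filter()` handle the
file formats (tab-separated; expression filtering removes mutations in genes
below 0.1 TPM in the matching tumor sample, with a tissue-average fallback).
A command-line wrapper for the same steps ships at
`inst/cli/perturbtrack.R` (subcommands `score`, `evaluate`, `entropy`,
`report`, `simulate`).

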