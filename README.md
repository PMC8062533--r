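# chromactivity

Transcription-factor activity inference from ATAC-seq chromatin
accessibility, as a tidyverse-native R package.

## The problem

Bulk ATAC-seq between two conditions — here the postnatal maturation of
pancreatic islet cells, contrasting immature (P10) and adult samples —
yields tens of thousands of accessible chromatin sites (ACS) whose Tn5
insertion counts change as regulatory programs rewire. The scientific
question is *which transcription factors drive those changes*: a factor
whose binding motif is concentrated in sites that close during maturation
behaves like a repressor of the mature state (the SCRT1-like pattern); one
whose motif sits in opening sites behaves like an activator.

chromactivity implements the full inference chain on plain tabular data:

1. **Quantify** — two Tn5 insertion points per fragment (its ends),
   counted per site per sample; fragment-size QC histograms.
2. **Differential accessibility** — TMM normalisation, a common negative
   binomial dispersion $\phi$ (variance $\mu + \phi\mu^2$) by Cox–Reid
   adjusted profile likelihood, a conditional NB exact test per site
   (two-sided by summing outcomes no more likely than the observed one),
   BH correction, and Up / Down / Stable calls at p < 0.05, FDR < 0.2.
3. **Motif scanning** — JASPAR-format PFMs to log-odds PSSMs; exact
   match p-values from the score distribution of random background words
   (exact support for short motifs, fine discretised convolution for wide
   ones); both strands scanned at p ≤ 1e-4 into an ACS × motif match
   matrix.
4. **Motif set enrichment** — preranked GSEA over sites ranked by
   accessibility log2FC: weighted Kolmogorov–Smirnov enrichment score,
   permutation null, NES, BH across motifs.
5. **Motif activity** — elastic-net regression (cyclic coordinate
   descent, cross-validated penalty) of site log2FC on the match matrix;
   the coefficient β per motif is its activity, negative for
   repressor-like factors.
6. **Integration** — nearest-TSS linking (TSS ± 1 kb / proximal ≤ 10 kb /
   distal), enhancer/repressor role calls by fold-change concordance with
   the linked gene, hypergeometric motif-target enrichment, and Pearson
   fold-change correlation.

A first-class synthetic-data module generates the whole study shape —
motifs, sequences with planted instances, NB counts under a linear
activity model, concordant gene tables — with serialisable ground truth,
so every stage is testable offline.

## Worked example

Simulate a 400-site universe in which motif SM001 drives opening
(activity +0.9) and SM002 drives closing (−0.9), then run the chain:

```r
library(chromactivity)

motifs   <- sample_motif_set(8, information_content = 1.6, seed = 1)
planting <- tibble::tibble(
  motif_id = motifs$motif_id,
  prob     = 0.15,
  activity = c(0.9, -0.9, rep(0, 6))
)
acs <- simulate_acs_set(400, motifs, planting, noise_sd = 0.25, seed = 2)
sim <- simulate_counts(acs$truth, n_per_group = 3, dispersion = 0.1, seed = 3)

res <- diff_accessibility(sim$counts, sim$samples)
glance(res)
#> # A tibble: 1 × 7
#>   n_acs dispersion p_threshold fdr_threshold frac_up frac_down frac_stable
#>   <int>      <dbl>       <dbl>         <dbl>   <dbl>     <dbl>       <dbl>
#> 1   400      0.101        0.05           0.2   0.128     0.128       0.745
```

The dispersion estimate (0.101) recovers the simulated 0.1, and ~26% of
sites are called differential. Scanning and the activity model then
recover the planted regulators with the right signs and magnitudes:

```r
mm  <- build_match_matrix(acs$sequences, motifs, threshold_p = 1e-4)
fit <- motif_activity(mm, res, alpha = 0.5, seed = 4)
head(tidy(fit), 4)
#> # A tibble: 4 × 4
#>   motif_id activity n_matches selected
#>   <chr>       <dbl>     <dbl> <lgl>
#> 1 SM001      0.560         68 TRUE
#> 2 SM002     -0.518         88 TRUE
#> 3 SM006      0.146         78 TRUE
#> 4 SM005      0.0552        82 TRUE
```

Preranked enrichment over the significantly changing sites tells the same
story from the rank side — SM001 enriched among opening sites, SM002 among
closing sites (negative NES, the repressor signature), nothing else
significant:

```r
sig  <- dplyr::filter(res, class != "Stable")
sets <- purrr::map(setNames(motifs$motif_id, motifs$motif_id),
                   function(m) mm$acs_id[mm[[m]] == 1])
enr  <- gsea_prerank(tibble::tibble(id = sig$acs_id, stat = sig$log2_fc),
                     sets, n_perm = 1000, seed = 5)
head(enr, 4)
#> # A tibble: 4 × 7
#>   set_id  size     es   nes p_value   adj_p leading_edge_size
#>   <chr>  <int>  <dbl> <dbl>   <dbl>   <dbl>             <int>
#> 1 SM001     33  0.548  2.75 0.00191 0.00835                26
#> 2 SM002     43 -0.550 -3.02 0.00209 0.00835                28
#> 3 SM006     26  0.297  1.40 0.115   0.307                  19
#> 4 SM003     22 -0.243 -1.11 0.315   0.631                  8
```

`autoplot()` methods (volcano, NES bars, activity bars) and broom-style
`tidy()` / `glance()` accessors cover each result type. The whole chain —
plus nearest-TSS linking and enhancer/repressor role calls — can also be
driven from a YAML config via `run_pipeline()`, which writes one TSV per
stage and a JSON manifest with the seed, the thresholds applied and output
checksums; `inst/scripts/run_pipeline.R` is a thin command-line wrapper.

## The methods vignette

`vignettes/motif-activity-methods.Rmd` documents the models and every
numerical choice: the exact-test conditioning, the Cox–Reid dispersion
adjustment, exact-versus-grid score distributions, the GSEA permutation
convention, elastic-net standardisation, tie-breaks, boundary rules, and
what the synthetic generator does and does not emulate.
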