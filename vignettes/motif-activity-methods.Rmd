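---
title: "Methods: from accessibility counts to motif activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from accessibility counts to motif activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromactivity)
```

chromactivity infers transcription-factor activity from chromatin
accessibility. Its unit of analysis is the accessible chromatin site (ACS):
an interval called open from ATAC-seq signal, quantified per sample by Tn5
insertion counts. The chain is: count insertions, test each site for
differential accessibility between two conditions (here labelled P10 and
adult, after the postnatal beta-cell maturation contrast the defaults
emulate), scan site sequences for transcription-factor motifs, summarise
motifs by rank-based set enrichment and by penalised regression, and link
sites to nearby genes to call enhancer- or repressor-like roles. This
vignette records the models, the tunable parameters, and the numerical and
design choices, in the order the pipeline runs them.

## Insertion counting

Each sequenced fragment implies two transposase insertion events, one at
each end. `count_insertions()` therefore adds the fragment's 5' coordinate
(`start`) and its last covered base (`end - 1`) as insertion points; a point
`p` is counted for a site `[start, end)` iff `start <= p < end`, and
overlapping sites each receive the insertion. Fragments are assumed already
Tn5-shifted; `shift = TRUE` applies the conventional +4/−5 shift to raw
intervals. The two-endpoint convention is a documented choice — quantifiers
differ on it, and nothing downstream depends on the factor of two.
`fragment_size_histogram()` provides the standard library QC view
(sub-nucleosomal mode below 100 bp, nucleosomal modes above).

## Differential accessibility

Counts are modelled as negative binomial with variance
$\mu + \phi \mu^2$ (the edgeR-style parameterisation; $\phi$ is the common
dispersion). The steps:

* **TMM normalisation** (`tmm_factors()`): per-sample factors from the
  weighted trimmed mean of M-values against a reference sample (the one
  whose upper-quartile count fraction is closest to the mean). Log-ratios
  are trimmed 30% on each side, average intensities 5%, and the surviving
  M-values averaged with inverse delta-method variance weights; factors are
  rescaled to geometric mean 1. Tests verify exact agreement with the
  established implementation.
* **Common dispersion** (`estimate_common_dispersion()`): $\phi$ maximises
  the summed NB log-likelihood with per-site group means profiled out at
  offsets $\log(\text{lib} \times \text{factor})$, **with the Cox–Reid
  adjustment** $-\tfrac12 \log I(\hat m)$ per profiled mean. The adjustment
  matters: plain profiling loses the degrees of freedom absorbed by the
  group means and biases $\phi$ low by roughly $(n - g)/n$ (about 2/3 in a
  3-vs-3 design) — simulation at truth 0.4 recovers ~0.26 unadjusted
  versus ~0.39 adjusted. The search is golden-section on $\log\phi$ over
  $[10^{-6}, 10]$ with tolerance $10^{-4}$; the profiled means use a
  safeguarded Newton iteration, vectorised across sites.
* **Exact test** (`nb_exact_test()`): counts are first scaled to the
  geometric-mean effective library and rounded (a documented approximation
  standing in for full quantile adjustment). Conditional on the total
  $t = a + b$ of the two group sums, the two-sided p-value sums the
  probabilities of all splits **no more likely than the observed one** —
  the "sum of smaller likelihoods" rule, not a doubled tail. At $\phi = 0$
  with equal libraries this reduces to the conditional binomial, which the
  tests assert (e.g. a 1-vs-1 split of (30, 0) gives
  $p = 2 \cdot 2^{-30}$). Group sums under a common $\phi$ give a
  negative-hypergeometric conditional law with sizes $n_g/\phi$, free of
  the unknown mean.
* **Fold-change** (`log2_fold_change()`): log2 ratio of prior-augmented
  normalised group means (prior 0.5 at the common library scale), adult
  minus P10, so positive means opening during maturation.
* **Classification** (`classify_acs()`): `Up` / `Down` require p below
  `p_threshold` (default 0.05) and Benjamini–Hochberg FDR below
  `fdr_threshold` (default 0.2), matching the accessibility literature's
  permissive-FDR convention for this design; both are configuration
  parameters, not constants.

Calibration is tested, not assumed: under a 3-vs-3 null at $\phi = 0.1$
over 2000 sites, the empirical type-I error at $\alpha = 0.05$ must fall in
[0.03, 0.07] and the p-value distribution must pass a KS uniformity check.

## Motif scanning

`pfm_to_pssm()` turns a position frequency matrix into log2-odds scores
against a mononucleotide background,
$\text{prob} = (\text{count} + \text{pc} \cdot \text{bg}) / (\text{total} + \text{pc})$
with a total pseudocount `pc = 0.1` per column distributed proportionally
to the background. The background defaults to the empirical composition of
the scanned sequence set; `"uniform"` is available.

P-values are survival probabilities of the window score for a random
background word. `pssm_score_distribution()` convolves the per-column score
distributions:

* **Exact support** for widths up to 9 (at most $4^9$ values, merged at
  ties): p-values are exact, and the convolution accumulates column sums in
  scan order so window scores match support values bit for bit. The
  oracle tests compare against exhaustive enumeration of all $4^w$ words
  and agree to machine precision.
* **Discretised grid** for wider motifs: integer scores on a common step
  giving 10,000 levels across the widest column's span (FIMO-style).
  Scanning then evaluates the *integer* window score on the same grid, so
  reported p-values are exactly the grid tail probabilities; the
  approximation error relative to continuous scores is bounded by mass
  within half a step per column.

Scanning (`scan_sequence()`, `build_match_matrix()`) covers both strands
(minus-strand matches score the reverse-complement matrix at the same
offset), skips windows containing N (treated as unscorable rather than
background-averaged), and reports every window with
$p \le$ `threshold_p` (default $10^{-4}$, the common FIMO default). The
match matrix is binary by default — "at least one match" — with a count
mode exposed; binary presence is the predictor encoding the activity model
uses. Detectability sets a real floor here: an instance sampled from a
motif with per-column information content IC scores about IC × width bits
on average, and must clear roughly $\log_2(1/\text{threshold}) \approx 13.3$
bits to be reported, so high recall (≥ 0.95) requires IC × width
comfortably above that — the packaged recall tests use IC 1.6 and widths
10–14 for this reason, and weak short motifs are expected to be missed.

## Motif set enrichment

`gsea_prerank()` ranks sites by accessibility log2FC — by default only the
significantly changing sites, mirroring the idea that the stable majority
carries no directional information; `rank_all_acs` ranks everything as a
sensitivity mode. Each motif's set is the sites it matches. The enrichment
score is the signed extremum of the weighted Kolmogorov–Smirnov running
sum (hits add $|r_i|^w / \sum |r|^w$ with $w = 1$, misses subtract
$1/(n - k)$); ties in the ranking are broken by stable input order, and an
exact tie between the maximum and the negated minimum reports the positive
extremum. The null is the ES of random same-size member sets from the same
ranking; one shared index permutation per iteration serves all sets.
P-values are one-sided on the observed sign with denominator
1 + (same-sign permutations) — the convention under which null p-values
are uniform, which the tests verify by KS across 200 seeded replicates —
and are floored at $1/(n_\text{perm}+1)$, never zero. NES divides ES by
the mean absolute same-sign null ES; BH adjusts across sets. Defaults:
1000 permutations (the adjusted p < 0.05 regime used downstream is
reachable well above the floor), set-size bounds 5 and 5000.

`hypergeom_test()` is the exact upper tail $P(X \ge k)$, used for
motif-target over-representation.

## Motif activity

`motif_activity()` regresses per-site log2FC on the binary match matrix
over **all** sites with an elastic-net penalty:
$\tfrac{1}{2n}\lVert y - \beta_0 - X\beta \rVert^2 +
\lambda(\alpha \lVert\beta\rVert_1 + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2)$,
solved by cyclic coordinate descent with soft-thresholding on internally
standardised predictors (population SD; binary columns standardised like
any other, documented), coefficients returned on the original scale, and
convergence declared when the largest standardised coefficient change in a
sweep falls below $10^{-7}$. Coefficients below $10^{-10}$ are snapped to
exact zero so the selected set is meaningful. KKT conditions at the
solution are asserted in tests, and solutions match the reference solver
to $10^{-6}$ on unit-variance responses (the reference standardises the
response internally, which rescales its effective L1 penalty — the
comparison must account for that).

$\alpha$ defaults to 0.5: motif predictors are heavily correlated (shared
matches, overlapping consensus), and the ridge component spreads weight
across near-duplicates instead of picking one arbitrarily — the grouping
property the tests check with a duplicated column. $\alpha = 1$ recovers
the lasso. $\lambda$ comes from 10-fold seeded cross-validation over a
geometric grid of 100 values from $\lambda_{\max}$ (smallest all-zero
penalty) down by $10^{-4}$, with warm starts; the default rule is
`"min"` (CV-minimising), with `"1se"` available — on pure noise the 1-SE
rule returns an empty support in ≥ 90% of seeds, which is tested. Motifs
matching fewer than `min_matches = 10` sites are dropped with a warning.
A positive activity means presence of the motif is associated with opening
in adult; negative with closing — the repressor-like signature.

## Gene integration

`nearest_tss()` links each site to the gene whose TSS is closest to the
site midpoint (`floor((start+end)/2)`); ties go to the lexicographically
smallest gene id, and the sign is strand-oriented (positive = downstream).
`location_class()` cuts |distance| at 1 kb (TSS) and 10 kb (proximal), the
boundaries belonging to the smaller class — the stated ranges are
ambiguous at exactly 1 kb and 10 kb, and inclusive-on-the-smaller-class is
the documented resolution. `classify_regulatory_role()` calls a linked
site an enhancer when the site changes (class not Stable), the gene is
significant (FDR < 0.05 by default) and the two log2FCs share a sign;
repressor when opposed; unlinked otherwise. The role is invariant to
negating both sign conventions simultaneously, which is tested.
`motif_target_enrichment()` asks, per motif, whether genes with a linked
motif-carrying site are over-represented among differentially expressed
genes (exact hypergeometric over a user-supplied universe; "vicinity"
means the nearest-gene link). `foldchange_correlation()` is the Pearson
test via the $t = r\sqrt{n-2}/\sqrt{1-r^2}$ transform.

## Synthetic data: what it emulates, and what it does not

The generator produces the study conditions every test runs under:

* `sample_pwm()` / `sample_motif_set()`: per-column mixtures of uniform
  background and a point mass on a random consensus, with the mixing
  weight solved so each column hits the requested information content
  (default 1.3 bits/column, widths 8–14 — typical of curated vertebrate
  motifs).
* `simulate_acs_set()`: i.i.d. background letters at configurable GC
  (default 0.45; no dinucleotide structure, deliberately — planted-truth
  tests need no more), one planting draw per (site, motif) pair at the
  configured probability, uniform position and strand, overlap-rejecting
  so every planted instance survives verbatim (or reverse-complemented).
  The true site log2FC is the linear activity model
  $N\beta^* + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ with
  $\sigma = 0.25$ by default; the stored residuals make it exactly
  recomputable.
* `simulate_counts()`: NB counts at `mean = lib_j · mu_i · 2^{x_j · lfc_i}`
  with $x = 1$ for adult, 3 replicates per group, median baseline 100,
  log-normal baseline spread 0.8, dispersion 0.1, relative library sizes
  uniform in [0.7, 1.3] — a 3-vs-3 bulk ATAC-seq shape. Effect-size
  distributions of real maturation changes are not published, so the
  defaults are configurable rather than calibrated; the fraction of sites
  with |log2FC| > 0.5 is steered to ~20% through the planting design.
* `simulate_expression()`: enhancer links give the gene
  $+c \cdot \text{lfc}$, repressor links $-c \cdot \text{lfc}$, unlinked
  genes pure noise; driven genes are marked significant. This separates
  role identifiability from expression-pipeline noise on purpose.

Not emulated: read-level artefacts (the pipeline starts at fragments),
mitochondrial contamination, dinucleotide or repeat structure,
peak-calling uncertainty (regions are taken as given), and realistic gene
significance calling. Passing tests therefore demonstrate correctness of
the inference chain under its stated model, not robustness to every
property of real libraries.

## Determinism and problem sizes

Every stochastic function takes a `seed` and restores the caller's RNG
state; `run_pipeline()` fans one global seed out to per-stage seeds by a
fixed affine hash, so stages are individually reproducible and a rerun is
byte-identical (tested via file checksums). The packaged test suite runs
the chain at deliberately modest sizes — 2000–2500 sites for calibration
and classification, a 5000-site × 100-motif fixture for activity
recovery, 600 sites end-to-end — chosen so the whole suite completes in a
few minutes while keeping every statistical check well-powered.

## Known limitations

* The exact test equalises libraries by scaling and rounding rather than
  full quantile adjustment; at very small counts this loses a little
  accuracy relative to the reference implementation (their p-values agree
  to Spearman > 0.97 in tests, not identically).
* Common dispersion only — no tagwise or trended estimation, no GLM with
  covariates or batch terms.
* Wide-motif (> 9 bp) match p-values are grid approximations; knife-edge
  scores adjacent to heavy tied word masses can shift by the local bin
  mass.
* TMM assumes a mostly-stable site universe; designs where most sites
  change in one direction will mis-centre fold-changes (a property, not a
  bug, of trimmed-mean normalisation — and visible in our own early test
  designs).
* Nearest-TSS linking is midpoint-based and single-gene; no exon/intron
  annotation, no chromatin-loop evidence.
* GSEA uses a simple permutation null with a p-value floor of
  $1/(n_\text{perm}+1)$; extremely small p-values are reported at the
  floor rather than extrapolated.
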