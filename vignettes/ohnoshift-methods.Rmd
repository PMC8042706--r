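---
title: "Detecting adaptive expression shifts after whole genome duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adaptive expression shifts after whole genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohnoshift)
```

## The scientific problem

A whole genome duplication (WGD) leaves a lineage with two copies
(*ohnologs*) of almost every gene. Over the tens of millions of years that
follow, most duplicate pairs resolve: one copy drifts towards lower
expression and eventual pseudogenization, both copies shift down together,
or one copy acquires a new, sometimes tissue-specific, expression level.
Distinguishing these *adaptive optimum shifts* from ordinary drift requires
a phylogenetic null model: expression divergence accumulates with
evolutionary time even under stabilizing selection, so a simple
salmon-versus-pike fold change is not evidence of selection.

`ohnoshift` implements the full desk-scale analysis around this question:
cross-species normalization of replicate expression panels, gene-tree
topology filtering, a multi-individual phylogenetic Ornstein-Uhlenbeck (OU)
shift test applied per duplicate clade, classification of ohnolog pairs
into regulatory-evolution categories, promoter/TE/bound-TFBS context
statistics, and the association tests used downstream. A synthetic-cohort
generator with known ground truth makes every stage testable end to end.

## The model

Log2 expression of a gene evolves along the species tree as an OU process
with optimum $\theta$, pull strength $\alpha$ (per unit branch length) and
drift variance rate $\sigma^2$. At stationarity the between-species
covariance is

$$\mathrm{Cov}(x_i, x_j) = \frac{\sigma^2}{2\alpha}\,
  e^{-\alpha\, d_{ij}},$$

with $d_{ij}$ the patristic distance between species $i$ and $j$, and the
root is drawn from the stationary distribution around the base optimum.
Biological replicates within a species add independent noise of variance
$\beta\,\sigma^2/(2\alpha)$, so $\beta$ is the within- to between-species
variance ratio. The expectation of a tip under a painted optimum regime is
the path integral of the piecewise-constant optimum,

$$\mathbb{E}[x_{\mathrm{tip}}] = \theta_{\mathrm{root}}e^{-\alpha T}
  + \sum_{\mathrm{segments}} \theta_{\mathrm{seg}}
  \left(e^{-\alpha(T - t_1)} - e^{-\alpha(T - t_0)}\right),$$

which is linear in the regime optima — the package exploits this heavily.

The **two-optima shift test** paints the stem branch of a duplicate clade
and all its descendants as a second regime and compares, by likelihood
ratio, the model with separate optima $(\theta_{\mathrm{base}},
\theta_{\mathrm{shift}})$ against the single-optimum null. The statistic
$\mathrm{LRT} = 2(\ell_1 - \ell_0)$ (clamped at zero) is referred to
$\chi^2_1$; calls above the 95% quantile (3.8415) are significant, and the
sign of $\hat\theta_{\mathrm{shift}} - \hat\theta_{\mathrm{base}}$ gives
the direction. For an ohnolog tree each duplicate clade is tested
separately, with the other clade removed, so the two tests share outgroup
data. Whether to include the stem branch in the shifted regime is an
interpretation choice; the stem is included here, since a shift in the
clade's ancestor is exactly the hypothesis being tested.

### Estimation

Because the mean is linear in $\theta$ given $\alpha$, and the whole
covariance scales with $s = \sigma^2/(2\alpha)$ given $(\alpha, \beta)$,
both are profiled out analytically (GLS for $\theta$, closed-form ML for
$s$), leaving a two-dimensional bounded quasi-Newton search over
$(\log\alpha, \log\beta)$ started from a deterministic grid
($\alpha \in \{0.5, 2, 8\}/T$ with $T$ the root depth; $\beta \in \{0.2,
\hat\beta_{\mathrm{anova}}\}$, the latter a one-way within/between variance
decomposition of the data). The likelihood itself is evaluated on
species-level sufficient statistics — replicate means carry the
phylogenetic covariance $s\,[e^{-\alpha D} + \beta\,\mathrm{diag}(1/n_s)]$
while within-species sums of squares enter through the iid noise — which
reduces every evaluation from an $n$-individual to a $k$-species
factorization and is verified against direct multivariate-normal
evaluation to $10^{-8}$ in the test suite.

Numerical guards: $\alpha$ is bounded in $[10^{-3}, 2\times10^{3}]/T$ and
$\beta$ in $[10^{-4}, 10^{4}]$; a non-positive-definite correlation matrix
or rank-deficient design marks the start as failed; all-failed starts flag
the gene non-converged and it is excluded downstream with a reason;
constant data yields $\hat\theta$ equal to the constant with the variance
floored at $10^{-12}$. Units: $\alpha$ is interpreted in the branch-length
units of the supplied species tree; fewer than three species with data
refuse to fit (the model is unidentifiable).

### Calibration at a seven-species design — a real limitation

The $\chi^2_1$ reference for this LRT is an asymptotic result, and the
effective sample size for the optimum contrast is the number of species,
not the number of genes. The acceptance checks simulate null genes under
the fitted model's own study design (7 species, 4 replicates) and compute
the realized type-I rate; it comes out roughly three times the nominal
0.05. The excess is driven by re-estimating $(\alpha, \beta)$ separately
under the null and alternative: among false positives the alternative fit
systematically escapes to large $\alpha$, where the model degenerates into
a two-group comparison of species means. Bounding $\alpha$ does not remove
the effect, and with the nuisance parameters fixed at their true values
the rate falls to the $\sim$0.06–0.07 explained by the residual
$F$-versus-$\chi^2$ small-sample gap. A related effect is an upward
small-sample bias in $\hat\alpha$, which attenuates
$\hat\theta_{\mathrm{shift}}$ towards the observed clade mean (the shift
weight $1 - e^{-\alpha(T - t_{\mathrm{stem}})}$ saturates at 1), while
$\hat\theta_{\mathrm{base}}$ stays essentially unbiased.

The package keeps the published procedure exactly — full ML for both
models, plain $\chi^2_1$, no boundary mixture, no Bartlett-type correction
— and reports these operating characteristics honestly in its acceptance
output rather than recalibrating. Practically this means significance
calls at this design are liberal, and shift-size estimates are
conservative; rank orderings (which genes shift hardest, which categories
are down-biased) are much more stable than the absolute rates.

## Normalization

Expression enters as TPM. Normalization is two-stage trimmed mean of
M-values (TMM):

1. **within species** — each replicate against a per-species reference
   replicate (the one whose upper quartile is closest to the species
   mean upper quartile), factors geometric-mean-centered to 1 within the
   species;
2. **between species** — one factor per species, computed on a
   singleton-orthogroup $\times$ species matrix of replicate means.
   Singleton orthogroups have exactly one gene per species, so their
   profiles are the only directly comparable anchor across species;
   ohnolog genes never influence the factors. Factors are centered by
   geometric mean across species so the global scale is preserved.

TMM itself is the doubly-trimmed (30% on M, 5% on A), inverse-variance
weighted mean of per-gene log ratios, with zeros removed pairwise. Because
TPM already removes sequencing depth, the library sizes entering M default
to equal nominal totals of $10^6$ (a `"column-sum"` rule is available for
count input); with fewer than 10 genes surviving the trims the factor
falls back to the untrimmed weighted mean with a warning. Finally all
values are transformed as $\log_2(\mathrm{TPM} + 0.01)$. A small state
machine (`raw -> within-normalized -> between-normalized -> logged`)
refuses stages out of order or twice.

## Tree filtering

Gene trees arrive pre-split into monophyletic clades with `SPECIES|gene`
tip labels. `classify_tree()` rejects trees with more than two maximal
ingroup clades, paralogs inside an ingroup clade, or duplicated outgroup
species; the duplication node of an ohnolog tree is recognized as the top
of a maximal ingroup-only subtree containing more than one gene of some
species, and its two children are the duplicate clades. Trees are
`complete` when every expected ingroup species is present in each clade.
Expression filters then drop trees whose duplicate clade is entirely
unexpressed (every replicate at zero TPM, threshold configurable), whose
sister-outgroup anchor is missing or unexpressed, or whose two distant
outgroup anchors are both missing or unexpressed. Re-rooting is not
attempted; input trees are taken as rooted.

## Pair classification and tissue statistics

Per-copy calls combine into the six unordered categories `cons+cons`,
`up+cons`, `down+cons`, `up+up`, `down+down`, `up+down` (`cons` = not
significant; `up+down` kept distinct rather than merged into
"asymmetric"). Expression asymmetry is the absolute mean within-species
difference between the copies' log2 values over all ingroup samples —
invariant to shifts affecting both copies. Tissue concordance counts, over
the non-focal tissues of an atlas, where the shifted copy is strictly
lower/higher than its conserved partner (ties count in neither — a
declared interpretation, the source analyses do not state a margin).
Tissue specificity uses $\tau = \sum_i (1 - x_i/\max x)/(N-1)$ on linear
expression, and "liver-specific" genes require focal expression at or
above 90% of the gene's maximum plus $\tau > 0.6$; a variant reading the
cut as the 90% quantile of the per-tissue values is available by flag
because the two phrasings circulate.

## Genomic context

Promoters are strand-aware windows around the TSS, 0-based half-open,
clipped to the chromosome. Two windows are in use: $-3000/+200$ for
bound-TFBS analyses and $2000$ upstream / $200$ downstream for TE load
(the printed sign convention of the latter is ambiguous; upstream-heavy is
implemented and the window is a parameter). TE load is the fraction of
promoter bases covered by the union of TE annotations (merged before
measuring, strand-blind, $\ge 1$ shared base counts as overlap); an exact
per-base bitmap oracle backs this in the tests. The liver-network cascade
filters candidate TFs (top 4 homology hits per motif at E < 1e-10 and
alignment length > 100), requires bound sites in at least 20 target
promoters, requires liver-specific expression, then reduces: per motif the
TF with the largest $|\mathrm{LRT}|$ ("strongest expression shift" is not
defined in the source; largest LRT is the declared, configurable choice),
motifs with > 80% target overlap (overlap coefficient) merged keeping the
stronger-shift TF, multi-motif TFs collapsed, and TFs ranked by up-shift
bias (bound up-copies minus bound conserved copies, ties by total bound
targets then name) keeping the top 9.

## Association statistics

The signed-rank test is exact for $n \le 25$ — computed by a rank
convolution equivalent to enumerating all $2^n$ sign assignments, with
average ranks under ties — and a tie/continuity-corrected normal
approximation above. Fisher's exact test uses the sum-of-less-probable-
tables two-sided rule. Pathway enrichment is a one-sided hypergeometric
upper tail per term against a user-supplied background. The
complex-composition test permutes singleton/ohnolog labels
(default 10,000 times) and reports the add-one empirical p-value
$(1 + \#\{perm \ge obs\})/(1 + n_{\mathrm{perm}})$, which is conservative
and never exactly zero. The per-block fractionation-bias test is a
two-sided exact binomial test of losses on copy A against
$\mathrm{Bin}(A+B, 1/2)$ — the source defers the exact form to
supplementary material, so this is a declared stand-in isolated behind one
function. No multiple-testing correction is applied anywhere unless
configured, matching the raw-p reporting convention of the analyses this
package mirrors.

## The synthetic cohort

The generator's defaults encode the study design the package targets:
4 ingroup (duplicated-lineage) species and 3 outgroups on an ultrametric
tree with root depth normalized to 1, the ingroup crown at 0.7 (the
WGD/shift stem spans 0.3–0.7, with the duplication node placed mid-stem at
0.55), 4 replicates per species, OU parameters $\alpha = 2$ (so
$\alpha \times$ root depth $= 2$), $\sigma^2 = 2$ (stationary variance
0.5 log2² units) and $\beta = 0.3$, baseline optima
$\mathcal{N}(5, 1.5^2)$ log2-TPM. The planted shift spectrum is
null-dominant and down-biased (10% `up+cons`, 15% `down+cons`, 5%
`up+up`, 7% `down+down`, 3% `up+down`; singletons 10% up, 8% down; all at
$|\Delta\theta| = 2$ log2 units — the magnitude distribution of real
shifts is unknown, so this is a free parameter, not an estimate), and a
quarter of trees are partial. Expression for an ohnolog orthogroup is
drawn jointly on the duplicated gene tree, so the two duplicate clades and
the shared outgroups have the exact covariance the analysis assumes.
Values are stored as TPM via the inverse log transform, floored at zero
(floor events are counted). Promoter/TE/TFBS tables plant a 2.5-fold TE
rate in down-shifted copies and a 2-fold bound liver-TF site rate in
up-shifted copies; one pathway is enriched among down-shifted orthogroups
and protein complexes are biased towards single-class membership.

What the generator does **not** emulate: read-level sampling noise and
mapping artifacts, expression-level-dependent variance (every gene shares
one $\sigma^2$), substitution-unit branch lengths, gene-tree estimation
error, correlated expression between genes, and real TE/TFBS sequence
structure. Passing recovery tests therefore demonstrates correctness of
the machinery under the model's own assumptions — not robustness to their
violation in real data.

All stage draws come from sub-streams derived deterministically from the
master seed, so identical configs give byte-identical cohorts and any
stage can be re-run alone.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations for a
single CPU: 100 random trees for the likelihood oracle, 500 null genes for
the type-I check, 200 genes per shift size for recovery, and a default
cohort of 60 singleton + 90 ohnolog orthogroups end to end; the
determinism check runs two full pipelines and compares manifest checksums
byte for byte. `run_pipeline()` writes every stage as TSV plus a manifest
(config hash, seed, per-stage counts, per-file MD5) and refuses to
recompute a completed run directory unless forced.

## Known limitations

* Significance calls are liberal at few-species designs (see the
  calibration section); treat the 5% level as nominal, not realized.
* $\hat\theta_{\mathrm{shift}}$ is attenuated when $\hat\alpha$ runs
  high; direction calls are unaffected.
* Maximal ingroup clades are computed under the input rooting; re-rooting
  ambiguities are the caller's responsibility.
* The tissue atlas is an input; the package does not model tissue
  covariance.
* The `eve`-style phylogenetic ANOVA (shared-$\beta$ diversity test) is
  out of scope; only the two-optima shift test is provided.
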