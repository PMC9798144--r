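---
title: "Quantifying substoichiometric tRNA/tsRNA modifications"
author: "trnamod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying substoichiometric tRNA/tsRNA modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnamod)
```

## The measurement problem

Many tRNA modification sites are *substoichiometric*: only a fraction
$\theta \in [0,1]$ of the molecules of a tRNA species carry the
modification. Comparing that fraction across cell lines, between intact
tRNAs and tRNA-derived small RNAs (tsRNAs), and under angiogenin (ANG)
treatment requires (i) scores that are monotone — ideally linear — in
$\theta$, (ii) noise-calibrated thresholds to decide which sites are
quantifiable at all, and (iii) curation against enzymology, because
chemical artifacts mimic signal at positions where no modification enzyme
acts. `trnamod` implements this workflow for three mapping chemistries and
validates it end to end on synthetic data with known $\theta$.

All positions are expressed in Sprinzl numbering (1–76, optional D-loop
residues 17a/20a/20b, variable-loop residues e1–e27), assigned to each
family consensus by a deterministic template walk. Families come from
single-linkage clustering of predicted tRNA genes under the one-hot
Euclidean distance $d = \sqrt{2\,n_\mathrm{diff}}$ after global alignment
(Needleman–Wunsch, match 1 / mismatch 0 / gap −1). The default cutoff 2
merges genes differing by at most two substitutions, which is what
collapses near-identical isodecoders into one family; both the cutoff and
the encoding are configuration, since no canonical choice exists.

## Scores

RiboMethSeq reads out protection of the phosphodiester bond 3′ of a
2′-O-methylated ribose against alkaline cleavage. The cleavage profile
$n_i$ merges the 3′-end count at $i$ with the 5′-end count at $i+1$ (the
two observable sides of the same cleavage; a 5′-only mode is available).
With left/right windows of half-width $\delta = 2$ and distance weights
$\omega(d) = 1 - 0.1(d-1)$:

- **Score A** $= 1 - \dfrac{2 n_i + 1}{\tfrac12|\mu_l - \sigma_l| + n_i +
  \tfrac12|\mu_r - \sigma_r| + 1}$ — specific, used for detection;
- **Score B** $= \dfrac{|\,n_i - \tfrac12(\bar n_l^\omega + \bar
  n_r^\omega)\,|}{n_i + 1}$ — reported for completeness only;
- **MethScore (Score C)** $= 1 - \dfrac{n_i}{\tfrac12(\bar n_l^\omega +
  \bar n_r^\omega)}$ — linear in $\theta$ under the protection model, the
  quantification score;
- **Score Mean** — built from the end-count ratios $r_i = n_i/n_{i-1}$,
  $f_i = n_i/n_{i+1}$ normalized by their window means; ratios with zero
  denominators are dropped from the averages.

The published formula block for these scores is typographically corrupted
in its source; the forms above follow the stated symbol definitions and
the established published score definitions, and each implementation
carries the formula in its documentation. Whether Score B's numerator
carries an absolute value is illegible in the source; it is implemented
with one. Scores A, C and Mean are clipped to $[0,1]$ by default (a
stoichiometry must be a fraction); unclipped values are kept alongside in
every score track because noise calibration needs them (clipping at zero
would collapse a median/MAD fit). Positions within $\delta$ of either
terminus are never scored — this deliberately excludes, e.g., Nm at
position 4, which sits too close to the 5′ end for reliable quantification.

**Score Angle** has no public formula. It is a plugin slot: the shipped
surrogate (`angle_scaled_c`, 1000 × MethScore) matches the original's
order of magnitude and conventional threshold of 300, but is *not* the
original score; any function `(n, cfg) -> numeric` can replace it, and its
threshold is recalibrated from the data like Score A's.

AlkAnilineSeq produces 5′-phosphates at abasic sites derived from m7G,
m3C and D; the **stop ratio** is reads starting at a position over all
reads passing through it. Bisulfite sequencing converts unmodified C to U;
the **non-conversion rate** is $C/(C+T)$ at a cytidine. Both are in
$[0,1]$ by construction and directly proportional to $\theta$.

## Detection and curation

Thresholds are background mean $+\,k\cdot$SD. For the single-score
chemistries $k = 3$ (the analytical-chemistry custom): with the published
background moments this yields 0.228 for NonConv (mean 0.0252, SD 0.0677,
from unmodified rRNA cytidines), and per-nucleotide stop-ratio thresholds
— 0.322 for D (0.0329/0.0964) and 0.398 for the A channel (0.0473/0.117),
which acts as a negative control since no adenosine derivative responds to
the chemistry. For RiboMethSeq, all signal lies within 3 SD of the noise,
so detection uses $k = 2$ (excluding $\Phi(2) = 97.7\%$ of Gaussian noise)
and requires Score A *and* Score Angle to both pass — the specific and the
sensitive score. The RiboMethSeq background is fitted robustly
(median/MAD) on the genome-wide unclipped score distribution, because the
fit must resist contamination by true sites; with a designated unmodified
background family the other chemistries use a plain Gaussian fit.

A site is *evaluable* in a sample when covered by ≥ 30 reads; sites
evaluable in fewer than half of the sample universe are dropped as
unquantifiable, and a quantifiable site becomes a candidate when its
detection score exceeds threshold in ≥ 50% of its evaluable samples. The
universe defaults to the tRNA-species samples (12 in the full design);
quantification then extends to all samples. Candidates are curated against
per-modification position whitelists (m5C: 38/48/49/50/72; Nm:
18/32/34/39/44/54; m7G: 46; m3C: 20/32/e2; D: 16/17/20/20a/47), a
known-unmodified discard list, and a documented-site list; documented
sites that fail the thresholds but are quantifiable are added back —
substoichiometric but real sites (the Gm18 case) must not silently vanish.
Every discard and add-back carries a machine-readable reason.

## Comparative analyses

The stoichiometry matrix holds, per site × condition, the median over
replicates of the type-specific quantification score (NonConv / MethScore /
stop ratio); replicate values are retained so medians stay recomputable.
Group differences use the two-sided Mann–Whitney–Wilcoxon test — an exact
enumeration null (mid-ranks under ties, doubling rule) for group sizes up
to 8, since the standard implementation refuses exact p-values under ties,
and the normal approximation with continuity correction beyond. Raw
p-values are flagged at 0.05/0.01 with no multiplicity correction by
default (Benjamini–Hochberg behind a flag), matching common reporting
practice for these panel sizes.

Variability categories use a numeric rule that had to be fixed by decision
(no canonical boundaries exist): (i) high-stable — grand median ≥ 0.8 and
cross-condition SD ≤ 0.1; (ii) low-stable — grand median ≤ 0.3, SD ≤ 0.1;
(iii) variable — cross-condition range ≥ 0.25; otherwise unclassified.
Categories are assigned in that order, making them mutually exclusive.
Heatmap clustering is agglomerative on Euclidean distances with complete
linkage (compact blocks; configurable).

The PCA treats **conditions as observations and sites as standardized
variables** (correlation-PCA). The orientation is a decision: it is the
one under which a site's "loading" can be reported as the Pearson
correlation between its condition profile and the component scores, i.e.
a value in $[-1,1]$ comparable across sites, and under which the
|correlation| > 0.70 signature rule has its intended meaning. m7G sites
are excluded before the PCA — they are constantly near-saturated and
contribute only noise. Sites with missing or constant condition profiles
are dropped (listed, median imputation behind a flag); a constant site's
loading is reported as 0, since it carries no directional information.
Signature sets use strict inequality at the cutoff, and the pairwise
overlap matrix is reported so disjointness can be verified rather than
assumed.

## The synthetic generator

`sim_config(seed = ...)` fixes the emulated study: 8 modified families
plus an unmodified decoy family (76-nt canonical consensi; planted
positions carry the base their modification requires), 2 cell lines ×
{tRNA, tsRNA} × {untreated, ANG} × 3 replicates, depth 10⁴. Planted
effects: tsRNA hypomodification $\Delta = 0.4$ at the species-effect sites
(the majority of variable sites), cell-line $\Delta = 0.15$, treatment
$\Delta = 0.1$ — treatment responses are processing-coupled (ANG lowers
the tRNA level and raises the tsRNA level at responsive sites, the D47
pattern). Stable-high, stable-low (documented, exercising the add-back
path) and documented/undocumented variants cover every curation route.
ANG effect sizes are not quantified anywhere — "mild" is the only
guidance — so the default is small and configurable.

Count models: RiboMethSeq bond intensities are log-normal around
depth/length (sdlog 0.1) with both observable ends Poisson at intensity
$\lambda_b(1 - \theta\eta)$; AlkAnilineSeq starts are Binomial with
$p = \theta s + (1-\theta s)\,b$, where the per-nucleotide background $b$
is Gamma with the channel moments above (background cleavage can only act
on molecules not already cleaved at the site, which keeps $p$ a
probability and the stop ratio unbiased at $b = 0$); bisulfite C counts
are Binomial with $p = \theta + (1-\theta)\,bg$, $bg$ Beta with moments
0.0252/0.0677. The dispersion default 0.1 was set by error propagation:
MethScore inherits roughly $(1-\theta)\sqrt{\sigma_{\log}^2(1 + 1/(2\delta))}$
absolute error from positional baseline variation, so 0.1 keeps
quantification error near 0.03 while still exercising non-flat profiles.

All backgrounds are drawn independently per position *and per sample*.
This is a deliberate modeling decision: the ≥ 50%-of-samples rule — the
pipeline's main specificity lever — only has power against noise that is
not reproduced across samples. Real libraries also carry *sequence-driven*
background (structure-dependent bisulfite resistance, ligation bias,
spontaneous depurination) that recurs in every sample and can only be
removed by the plausibility curation, not by the sample-fraction rule.
The generator models that class only via the optional `artifact_mode`
(spurious A-channel stops near the anticodon, which curation must
discard). Consequently, passing the synthetic validation shows that the
scores, thresholds, filters and multivariate analyses do what they claim
under the assumed noise model — it does not certify false-positive rates
on real libraries, where correlated artifacts are the dominant risk.
Other non-emulated features: read-level simulation (counts are generated
directly), cross-chemistry interference (e.g. m7G46 affecting RiboMethSeq
profiles), modification-aware alignment, and tsRNA-specific coverage
truncation.

All randomness flows from one seed through fixed per-module streams
(truth, then one stream per sample and chemistry), so any stage can be
regenerated independently; `emit_fixture()` output is byte-identical under
a fixed seed.

## Numerical choices and degenerate inputs

- Consensus ties resolve to the first member's base, with a warning
  (determinism over cleverness); member insertions relative to the family
  reference are dropped with a warning (center-star, no full MSA).
- Ratios with zero denominators are flagged undefined and dropped from
  Score Mean's averages; MethScore is `NA` when both window averages are
  zero; stop ratio and NonConv are `NA` at zero depth.
- Sprinzl assignment for non-canonical lengths fills the D-loop optionals
  first (overridable via `n_dloop_extra`); lengths outside 76–106 error.
- Exact rank-sum enumeration caps at group size 8
  ($\binom{16}{8} = 12870$ assignments); beyond that the continuity-
  corrected normal approximation takes over.
- The `>` in every threshold and cutoff comparison is strict (a score
  exactly at threshold does not pass), including the 0.70 signature rule.

## Problem sizes used in the shipped validation

The test suite validates scores exhaustively on all length-5 and length-7
profiles over counts {0, 10, 100} plus 1200 random profiles up to length
12, against independently written brute-force oracles. The pipeline tests
run a 4-family study at depth 2000; the acceptance workflow runs the full
8-family design at depth 10⁴ and twenty 8-family null studies at depth
3000. These sizes were chosen as the smallest at which the binomial/Poisson
sampling error is clearly below the recovery error bands being asserted
(MAE < 0.05 for NonConv and stop ratio, < 0.08 for MethScore).

## Known limitations

- Score Angle is a surrogate; results that depend on its exact shape
  (rather than on "a sensitive second score") do not transfer.
- The Sprinzl template walk uses length arithmetic, not a covariance-model
  alignment; highly unusual architectures need the manual override.
- Curation is whitelist-driven: genuinely novel positions are reported but
  discarded as implausible by design, never silently promoted.
- Published headline biology (the 149-site human catalog, the published
  PC variance shares and loadings) derives from the original raw
  sequencing data and is not reproducible from synthetic fixtures; the
  shipped reference tables carry those printed values as worked-example
  inputs, and the package reproduces the *arithmetic* on them plus all
  analytic calibration numbers exactly.
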