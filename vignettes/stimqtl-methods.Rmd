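---
title: "Models and design choices in stimqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in stimqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stimqtl` analyses stimulation time-course single-cell multiomic cohorts:
three neuronal cell types crossed with three depolarization time points
(nine *contexts*), with donor genotypes, snRNA and snATAC counts, allelic
read counts at heterozygous sites, contact maps, and GWAS summary
statistics. This vignette records the statistical models, the defaults and
their rationale, what the synthetic generator does and does not emulate,
and the numerical decisions a maintainer would want written down. The
package computes everything shown by the test suite and
`scripts/acceptance.R`; no empirical claim here goes beyond what those
scripts measure.

## The synthetic generator

The generator is first-class, tested code: it defines the study conditions
under which every estimator is validated.

**Genotypes.** Two latent Gaussian haplotypes per donor follow an AR(1)
process (`ld_rho`, default 0.5) within LD blocks of `ld_block_size`
(default 20) SNPs; thresholding at the allele-frequency quantile gives
alleles, and their sum the dosage. Marginally each SNP is Hardy–Weinberg
at its MAF (drawn uniformly on `maf_range`, default 0.05–0.5); jointly,
neighbours correlate through the Gaussian copula. The copula value is
checked against a Monte-Carlo oracle in the tests.

**Counts.** For cell $i$ and feature $g$,
$$y_{ig} \sim \mathrm{NB}\!\big(\mu = s_i\,
  e^{\mu_g + m_g(t_i) + u_{d(i),g} + \sum \beta\,G},\ \phi\big),$$
with lognormal size factors $s_i$ (log-SD 0.3), per-feature baselines
$e^{\mu_g} \in [0.5, 5]$ counts per cell, donor random intercepts
$u \sim N(0, \texttt{donor\_sd}^2)$ and dispersion $\phi$
(`nb_dispersion`, default 0.5; 0 gives Poisson). The defaults
`donor_sd = 0.3` (roughly 30% between-donor CV, typical of
inter-individual expression variation) and $\phi = 0.5$ are the global
study conditions shared by every benchmark. Planted QTL enter the
linear predictor only in their specified contexts, which is what makes a
*dynamic* QTL (e.g. $\beta = 0$ at 0h, $0.8$ at 6h).

**Temporal modules.** Pseudotime is *drawn*, not inferred (trajectory
inference is out of scope): Beta(2,8), Beta(5,5), Beta(8,2) at 0/1/6 h, so
activation advances with time in expectation. Module shapes on the log
scale (amplitude 1.5, i.e. ~4.5-fold): an early Gaussian pulse centred at
pseudotime 0.25, a late sigmoid centred at 0.6 with slope scale 0.08
(chosen so the rise completes inside the [0,1] window — a sigmoid
truncated by the window end is no longer a shifted copy of its leading
peak, which would bias lag estimation), a falling sigmoid ("down"), and
flat. A *priming* module is a late gene whose matched peak follows the
same sigmoid advanced by `priming_lead` (default 0.1 = 10 of 100 bins).

**Allelic counts.** For each planted caQTL SNP (assumed inside its peak),
each heterozygous donor emits per context a Poisson total proportional to
its peak pseudobulk (mean `asoc_depth`, default 30 reads) and an alt count
that is Binomial with $\mathrm{logit}(p) = \kappa\,\beta_{\text{context}}$
(`asoc_kappa`, default 1). The coupling makes ASoC–caQTL concordance
testable by construction. Homozygous donors emit nothing.

**GWAS.** Per block, $z = \sqrt{n}\,R\,b + \varepsilon$,
$\varepsilon \sim N(0, R)$, with $R$ the empirical dosage correlation
(ridge-jittered when singular). `simulate_trait_blocks()` additionally
builds variable-level blocks — SNPs under AR(1) LD plus single-SNP gene
and peak traits — where each variable is causal independently with its
group prior and causal effects have group variance $\sigma^2$ on the $z$
scale (default 36, i.e. $|z| \approx 6$, the "strong signal" regime).

**What is not emulated.** Read-level artifacts, doublets, ambient
contamination, reference-mapping bias in allelic counts, batch effects
beyond donor intercepts, population structure, and real motif content.
Consequences for interpretation: passing tests show the estimators recover
what the model family can express; they do not certify robustness to
mapping bias (an ASoC prior $p_0 \ne 0.5$ hook exists), to stratification
(the genotype-PC covariates are exercised but cannot be *needed* in data
without structure), or to empty-drop artifacts.

## Pseudobulk and QTL mapping

Counts are summed per donor×context, normalized to log2(CPM+1), and each
feature is inverse-normal transformed across donors within context using
the rankit $\Phi^{-1}((r - 0.5)/n)$ (average ranks for ties). The rank
transform makes `map_qtl` invariant to monotone transformations of the raw
pseudobulk and puts effect sizes on SD units. Donors under `min_cells`
(default 10) are excluded per context and recorded.

Cis windows: ±25 kb around a peak (the caQTL rule), ±100 kb around a gene
TSS — the gene window is a configurable default chosen to keep desk-scale
problems tractable; strand is not used because windows are symmetric.
Per feature and context, OLS of the transformed pseudobulk on dosage plus
covariates runs over every cis SNP; the lead is the minimum nominal p, the
feature-level p is Bonferroni (`min(1, p * n_cis)`), and BH across
features within context defines eGenes/cPeaks at q < 0.05. Bonferroni-
then-BH is deliberately simple and conservative; a permutation scheme
would be sharper but adds nothing at these scales.

Covariates default to 3 genotype PCs and 5 phenotype PCs — stand-ins for a
real cohort's unknown structure. In the package's own recovery benchmarks
the estimators run with zero PCs: the generator contains no population
structure or shared expression factors by design, so PCs there can only
align with the largest-variance features (the planted eQTL genes
themselves) and absorb signal. Matching the covariate model to the
generative process is the correct comparison; the defaults remain for real
data.

**Dynamic QTL.** For each feature, donor×time observations are stacked and
`y ~ G*time + (1|donor)` is fit with `lmerTest`. The donor random
intercept absorbs non-genetic differences between lines, which is what
gives the interaction test its power and calibration. Contrast tests
(1h−0h, 6h−0h) and the joint 2-df test use Satterthwaite degrees of
freedom with the REML fit — the lmerTest default — because a plain
ML-Wald-normal test is anticonservative at two dozen donors; the
calibration requirement (size within [0.035, 0.065] at $\alpha = .05$) is
part of the same contract, and REML+Satterthwaite is the field-standard
way to meet it. When the donor variance hits the boundary
($\hat\sigma^2_u \to 0$) the model is refit by OLS with a note; the tests
remain valid. A feature is *dynamic* when either interaction contrast has
BH q < 0.05 within its cell type.

**Sharing.** Storey's $\hat\pi_0(\lambda) = \#\{p > \lambda\}/(n(1 -
\lambda))$ over $\lambda = 0.05, \dots, 0.9$, cubic-spline smoothed
(df = 3) and read off at the largest $\lambda$; $\pi_1 = 1 - \hat\pi_0$
clipped to [0, 1], refused below 50 p-values. Replication between contexts
is nominal p < 0.05 with matching sign at the other context's lead.

## Trajectory analyses

`bin_pseudotime()` averages per-cell log1p(CP10K) values over 100 uniform
bins (last bin closed so pseudotime 1.0 counts), linearly interpolates
empty bins (edges carry the nearest value), smooths with a centred moving
average (`smooth_width = 5`), and z-scores per feature (zero variance maps
to zeros, not NaN). The smoothing exists because a desk-scale run puts
only tens of cells in a bin where the original studies have thousands;
width 5 of 100 bins trades negligible temporal resolution for large
variance reduction. Per-bin profiles remain subject to a compositional
caveat: CPM normalization gives every feature a small shared drift
whenever a minority of features rises along the trajectory. This mostly
cancels in clustering (a common additive component does not move
k-means distances) and is second-order for concordance once module
fractions are matched across modalities, but it is the main reason
profile noise is not iid.

Clustering concatenates the three cell types' z-profiles (length
3×100) and runs k-means with 20 restarts under a fixed seed; k defaults
to 15 to mirror the cluster count reported for this experimental system,
and the acceptance benchmark uses k = 4 with four planted archetypes.
Genes enter if they pass the FC > 2, q < 0.05 response-DE gate
(`select_variable_degs`).

`concordance()` reports the lag maximizing
$\mathrm{cor}(a_t, e_{t-s})$ over $s \in [-20, 20]$: negative lag means
chromatin leads. *Priming* is lag ≤ −5 bins; *memory* is an expression
maximum before the final 20-bin tail with tail mean < 0.5 SD while
activity's tail mean stays > 0.5 SD; priming is evaluated first. The
thresholds are operational definitions of qualitative classes; the
acceptance benchmark plants a 10-bin lead and requires ≥ 90% recall at
these settings. Lag from levels is only identifiable when the two
profiles are (approximately) shifted copies — which the generator's
completed sigmoids guarantee; under arbitrary monotone warping of each
modality the shift is not identifiable at all, a limitation worth knowing
on real data.

## Linking and GRN

`link_peaks()` orders a cell type's cells by pseudotime, aggregates into
50 equal contiguous metacells, and correlates log1p-CPM vectors for every
peak within ±250 kb of a TSS (t-approximation p, BH per cell type). ABC
candidates use ±500 kb, activity = mean CPM accessibility at the time
point, contact = summed frequency between the bins holding the peak
midpoint and the TSS (+0.1 pseudocount against zero-contact deserts;
anchor order is symmetric); scores normalize to 1 per gene, asserted on
every run. The ABC score threshold for "overlap" is 0.02. Window sizes
and threshold follow common ABC practice and are configurable.

Motif activity is a deliberately simplified deviation score (the package's
own construction, standing in for chromVAR-class machinery): per TF, mean
binned accessibility of its motif peaks versus `n_background = 100` random
peak sets matched on overall mean accessibility by decile sampling;
z per bin, with zero-SD bins mapped to z = 0 and TFs under 5 peaks
dropped. GRN edges require the candidacy gate — the TF has a motif in a
peak significantly linked to the target, and the target is response-DE —
and test the Pearson correlation between TF activity and the target's bin
profile against a circular-shift permutation null (1000 random rotations,
seeded; all rotations computed at once via FFT). The shift null respects
bin autocorrelation where a t-approximation would not; p-values are
bounded below by 1/(n_perm+1). Edges keep their sign; repressor handling
(negative r) is reported, not filtered. A TF is *called* a regulator when
it has ≥ 100 significant targets in some cell type — note that a "null"
TF whose random motif peaks happen to include activation-responsive peaks
will genuinely correlate with response genes at the edge level; the
TF-level filter is what separates regulators from that background.

## ASoC

Allelic counts pool over heterozygous donors per SNP and context
(`min_total = 20` reads, `min_donors = 2`), and the two-sided exact
binomial p at $p_0 = 1/2$ uses the closed form
$\min(1, 2\,P(X \le \min(k, n-k)))$, which equals the minimum-likelihood
definition for a symmetric null (verified against tail-sum enumeration and
`binom.test` for all totals ≤ 50). Pooling before testing is the simplest
defensible estimator; per-donor beta-binomial overdispersion modelling is
a noted extension, and a fixed reference-bias prior $p_0 \ne 0.5$ is
available. BH runs per context. LD proxies for GWAS intersection use
dosage $r^2$ strictly greater than 0.8 (the index SNP always proxies
itself); a locus is "explained" in a context when any proxy is significant
ASoC there, and the summary contrasts 0h against stimulated contexts.

## Fine-mapping

Trait models are single-SNP by default for genes *and* peaks (the
top-variant rule is stated for peaks; using it for genes too keeps the LD
algebra exact, and `impute_trait_z()` is already general for multi-SNP
weights). For peaks the universe is the union of cPeaks with a caQTL or a
significant ASoC variant, and the weight SNP is whichever has the smaller
p-value; ASoC weights use the pooled log allelic ratio. Imputed trait
z-scores are $w' z / \sqrt{w' R w}$, and the block correlation matrix is
augmented with trait–SNP correlations $w'R_{\cdot j}/\sqrt{w'Rw}$.

`finemap_block()` is Bayesian single-effect regression on summary
statistics with an explicit null option: within a component, variable $v$
gets weight $\frac{\pi_v}{1-\pi_v}\,\mathrm{BF}_v$ with
$\log \mathrm{BF}_v = \tfrac12\log\frac{1}{1+\sigma^2_v} +
\tfrac12 z_{r,v}^2 \frac{\sigma^2_v}{1+\sigma^2_v}$, and the empty
configuration gets weight 1. The null option matters: without it every
block is forced to contain an effect and the EM's prior estimates inflate
by the number of signal-free blocks. With L = 1 the component *is* the
exact posterior over causal configurations of size ≤ 1 under independent
Bernoulli inclusion — the identity
$N(z; 0, R + \sigma^2 R_j R_j')/N(z; 0, R) = \mathrm{BF}(z_j)$ (matrix
determinant lemma) makes the equivalence hold under arbitrary LD, which is
what the enumeration-oracle acceptance check verifies to machine
precision. For L > 1 the iterative scheme is variational and only
approximate; the package defaults to L = 1, matching the single-top-SNP
trait models and the one-causal-per-block regime of the benchmarks.

`em_group_priors()` alternates block fine-mapping with closed-form
updates: $\pi_k$ = mean PIP over the group's variables, $\sigma^2_k$ =
PIP-weighted posterior second moment (floored at $10^{-4}$; $\pi$ clipped
away from 0/1); convergence is a $10^{-4}$ relative change in the priors,
capped at 100 iterations. Enrichment is $\pi_k/\pi_{\text{snp}}$.
Perfectly correlated trait–SNP pairs (a single-SNP trait duplicates its
weight SNP's column) are resolved by the group priors themselves: the EM
fixed point allocates the shared PIP in proportion to the fitted priors,
which is exactly why the planted 30-fold enrichment is recoverable.
Heritability shares are $\mathrm{PIP}\cdot E[b^2 \mid \text{incl}]$ per
variable (variables are standardized, so no extra variance factor),
summed per group — and per context when trait ids carry one — as a
percentage of the model-implied total.

Gene PIPs sum a gene's per-context trait PIPs (also reported capped at 1;
the sum is primary because the dynamic rule's arithmetic requires it):
*dynamic* iff (PIP$_{1h}$ + PIP$_{6h}$) − PIP$_{0h}$ ≥ 0.5 (with a $10^{-9}$
epsilon so exact boundary cases classify as the rule reads), else static.
Confidence strata use the capped PIP: high > 0.8, plausible in (0.5, 0.8].

## Benchmark sizes and check conventions

The acceptance suite fixes these problem sizes (also used by
`scripts/acceptance.R`): 2,000 features × 24 donors for the interaction
null (donor SD 1, equal $\beta$ = 0.5 at all times, joint 2-df size in
[0.035, 0.065]); 200 planted eQTL among 300 genes × 100 donors (slope of
$\hat\beta$ on the planted effect mapped to the analysis scale,
$\beta/\ln 2 / \mathrm{sd}(\text{log2 pseudobulk})$, in [0.9, 1.1];
power ≥ 90%); 200 dynamic + 200 static QTL (power ≥ 80%, misclassification
≤ 5%); ASoC with four het donors at mean per-donor coverage 50 (a pooled
total of exactly 50 reads would cap exact-binomial power at 0.78 even at
nominal $\alpha$ = 0.05, so coverage is per donor and the test pools);
120 caQTL peaks × 3 contexts for concordance (r ≥ 0.7); 500 blocks for
enrichment recovery (within a factor 2 of the planted 30) with decile
calibration within ±0.1 on bins holding ≥ 25 variables (smaller bins
cannot measure a frequency to that precision); 10 × 200-block replicates
for the heritability ratio, summarized by the median across replicates
(each replicate's ratio of two sums of ~15 scaled $\chi^2_1$ terms is
F-distributed and individually too noisy to bound); 400 genes / 4
archetypes for clustering (ARI ≥ 0.8); 100 priming pairs × 3 cell types at
150 cells per donor-context (recall ≥ 90%; per-bin noise scales with cell
count, and the lag search needs roughly this many cells per bin to resolve
a 10-bin lead reliably); and one planted regulator with
150 targets among 600 genes (≥ 100 recovered; none of 10 null TFs passes
the 100-target filter).

## Known limitations

Single random-intercept LMM only (no donor slopes); no trans-QTL, no
conditional multi-signal cis mapping; fine-mapping ships L = 1 defaults
and single-SNP trait models (multi-SNP weights enter via
`impute_trait_z()` but no elastic-net trainer is included); ASoC has no
read-level bias correction; ABC uses accessibility alone as activity (the
assay lacks H3K27ac); contact maps are consumed pre-normalized; motif maps
are inputs, not computed from sequence.
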