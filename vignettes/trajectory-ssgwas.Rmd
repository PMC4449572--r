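---
title: "Random-regression single-step GWAS for growth and feed-intake trajectories"
author: "rrgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-regression single-step GWAS for growth and feed-intake trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`rrgwas` analyses longitudinal records (daily body weight, adjusted daily
feed intake) with a random-regression animal model on order-2 Legendre
polynomials of standardized age:

$$
y = \mu + CG_i + Parity_j + \sum_{k=0}^{2}\varphi_k(t)\,\beta_k
  + \sum_{k=0}^{2}\varphi_k(t)\,u_{mk}
  + \sum_{k=0}^{2}\varphi_k(t)\,pe_{mk} + e,
$$

where age $t$ is mapped linearly onto $[-1,1]$, $u_m \sim N(0,
\mathbf{H}\otimes\mathbf{G}_a)$ are animal genetic coefficient effects over
the single-step relationship matrix $\mathbf{H}$, $pe_m \sim N(0,
\mathbf{I}\otimes\mathbf{P})$ are permanent-environment coefficient
effects, and the residual is homogeneous. $\mathbf{G}_a$ and $\mathbf{P}$
are unstructured $3\times 3$ coefficient covariances, so heritability and
genetic correlations vary freely along the trajectory:

$$
h^2(t) = \frac{\varphi(t)'\mathbf{G}_a\varphi(t)}
  {\varphi(t)'\mathbf{G}_a\varphi(t) + \varphi(t)'\mathbf{P}\varphi(t) +
   \sigma_e^2},
\qquad
r_g(t,s) = \frac{\varphi(t)'\mathbf{G}_a\varphi(s)}
  {\sqrt{\varphi(t)'\mathbf{G}_a\varphi(t)\;
         \varphi(s)'\mathbf{G}_a\varphi(s)}}.
$$

Phase summaries average these over integer ages 90–118, 119–146 and
147–175 d, the three on-test phases conventionally reported for finishing
pigs.

## Basis and identifiability

The orthonormal (Kirkpatrick) scaling $\varphi_k = \sqrt{(2k+1)/2}\,P_k$ is
the default; a raw-polynomial switch is provided. The two conventions are a
diagonal reparameterization $\mathbf{G}_a^{raw} = C\,\mathbf{G}_a^{norm}C$
with $C = \mathrm{diag}\{\sqrt{(2k+1)/2}\}$, so every reported quantity —
$h^2(t)$, $r_g(t,s)$, fitted trajectories, window statistics — is invariant
to the choice; the test suite asserts this to $10^{-10}$.

The overall mean, the first contemporary-group level and the fixed
intercept regression $\beta_0$ are mutually confounded ($\varphi_0$ is
constant). The package uses treatment contrasts for CG and parity and
absorbs $\beta_0$ into the intercept: one constraint per confounded fixed
term, and a full-rank fixed design is required (rank deficiency beyond
these declared constraints is an error, not silently aliased).

The age standardizer defaults to the observed record range, is stored in
the fit, and is reused verbatim by every downstream stage. Whether the
endpoints should instead be a fixed window is genuinely open; the observed
range is the default and an override (`age_range`) is provided.

## The H matrix

$\mathbf{A}$ is built by the tabular method with inbreeding on a pedigree
pruned to 3 ancestor generations of the phenotyped animals.
$\mathbf{G} = \mathbf{Z}\mathbf{D}\mathbf{Z}'$ uses gene content centered
at observed allele frequencies and expected-variance weights
$d_i = 1/(m\,2p_iq_i)$, so $\sum_i d_i\,2p_iq_i = 1$ and
$\mathrm{diag}(\mathbf{G})$ averages about 1. Blending
$\mathbf{G}_b = w\mathbf{G} + (1-w)\mathbf{A}_{22}$ with $w = 0.995$
precedes inversion, and

$$
\mathbf{H}^{-1} = \mathbf{A}^{-1} +
\begin{bmatrix} 0 & 0 \\ 0 & \mathbf{G}_b^{-1} - \mathbf{A}_{22}^{-1}
\end{bmatrix}.
$$

One numerical point deserves emphasis: with frequencies estimated from the
genotyped set, the centered gene-content columns sum to zero, so
$\mathbf{Z}\mathbf{D}\mathbf{Z}'$ is singular *regardless of SNP count* —
this is why $w<1$ blending is not optional in practice. The
GBLUP$\leftrightarrow$SNP-BLUP equivalence checks, which need $w = 1$,
center at frequencies shrunken toward 0.5 by a pseudo-count,
$(2np_i+1)/(2n+2)$, which restores full rank; observed frequencies remain
the analysis default.

# EM-REML

Variance components are estimated by EM-REML. Each iteration solves
Henderson's mixed-model equations once. The permanent-environment block is
block-diagonal ($3\times 3$ per animal) and is absorbed analytically, so
the dense factorization only touches the (fixed, genetic) Schur complement;
the exact inverse blocks needed for the EM traces are recovered from it.
The classical updates are

$$
\mathbf{G}_a \leftarrow \tfrac{1}{q}\left(\hat{U}'\mathbf{H}^{-1}\hat{U}
 + \sigma_e^2\,\mathrm{tr}\!\left(\mathbf{H}^{-1}C^{u_ku_l}\right)\right),
\quad
\mathbf{P} \leftarrow \tfrac{1}{p}\left(\hat{PE}'\hat{PE}
 + \sigma_e^2 \textstyle\sum_a C^{pe_a pe_a}\right),
\quad
\sigma_e^2 \leftarrow \frac{y'y - \hat\theta'W'y}{N - r(X)} .
$$

The restricted log-likelihood is computed at every iteration from the same
factorization and must be non-decreasing; a decrease aborts the run with
diagnostics. The likelihood formula was validated against the direct
$V$-matrix expression (they agree including the additive constant) and the
EM fixed point against a derivative-free optimization of the exact
restricted likelihood on a small instance.

Two devices address EM's notoriously slow tail without touching its
guarantees:

* **Moment initialization.** Per-animal OLS Legendre fits give coefficient
  estimates $c_i$ with $\mathrm{Cov}(c_i, c_j) = A_{ij}\mathbf{G}_a$ for
  $i \ne j$; a Haseman–Elston-style contraction over informative relative
  pairs ($A_{ij} \ge 0.2$) pre-estimates $\mathbf{G}_a$, and the remainder
  of the coefficient scatter initializes $\mathbf{P}$.
* **Safeguarded component-wise Aitken extrapolation.** Each variance
  parameter decays at its own geometric rate (the small components are the
  slow ones), so each is extrapolated by its own Aitken factor (capped at
  12), backtracked to the PSD cone, and *accepted only if* the next
  likelihood evaluation confirms no decrease — otherwise the iterate falls
  back to the plain EM update, which is always safe. Monotonicity of the
  recorded trace is therefore preserved by construction.

Convergence uses the per-component relative parameter change (floored at
2% of the largest parameter so near-zero components neither dominate nor
are ignored), default tolerance $10^{-6}$, cap 500 iterations. The solver
itself applies iterative refinement when the relative MME residual exceeds
$10^{-8}$, which matters when $\mathbf{G}_b$ is ill-conditioned.

# Single-step GWAS

SNP effects are back-solved from the genotyped animals' coefficient GEBV
with the *same* $\mathbf{Z}$, $\mathbf{D}$ and blended $\mathbf{G}_b$ used
in the MME, $\hat{u} = \mathbf{D}\mathbf{Z}'\mathbf{G}_b^{-1}\hat{a}$, per
coefficient independently — the linear map is then the exact adjoint of the
fitted model, and with $w=1$, $\mathbf{Z}\hat{u}$ reproduces the GEBV
identically. Reweighting replaces each SNP's weight by its realized
variance $2p_iq_i\hat{u}_i^2$, renormalized to $\sum d_i 2p_iq_i = 1$
(constant trace scale across rounds) with a floor of $10^{-8}$ times the
mean weight so no SNP is ever expelled from $\mathbf{G}$. Two rounds are
the default. The GEBV are held fixed across rounds (effects-only
iteration); re-running the evaluation between rounds would multiply the
bootstrap cost a thousand-fold for no observed change in the effect ranking
— the weight share of a planted signal SNP reaches its fixed point after
the first round.

## Windows and selection

For each window of 10 consecutive SNPs (step 1, never spanning
chromosomes) and each animal, the window GEBV is
$\sum_{i\in w} z_{ai}\hat{u}_i$; its across-animal variance is the scan
statistic. Selection is two-stage: per coefficient, the top 5% of windows
by variance survive (ceiling on fractional counts, so at least one always
survives); survivors sharing at least one SNP index merge into regions;
regions rank by their peak member window, and the top 10% are putative
QTL. Under these defaults two isolated regions can never both be flagged
(⌈0.1·2⌉ = 1); the package reports ranks so permissive fractions are one
argument away. Coordinates are 1-based inclusive in all outputs.

## Bootstrap significance

For a putative region, the null phenotype is

$$
\tilde{y} = \hat{y} - \hat{u} + \tilde{u} + e,
$$

i.e. fixed part + permanent-environment part + the genomic trajectory value
computed from the back-solved SNP effects *with the region's SNPs removed*
(from all three coefficients by default; a per-coefficient exclusion mode
exists), plus a fresh homogeneous residual at the full-model
$\hat\sigma_e^2$. Each replicate re-solves the MME **at the full-data
variance components** (the coefficient matrix is factored once and reused),
re-runs the two reweighting rounds and recomputes the region's peak-window
variance; the empirical p-value is the fraction of replicates at or above
the observed statistic, and p = 0 is reported as "< 1/n_reps". Replicate
seeds derive deterministically from the master seed and a replicate
counter, so any subset of replicates is individually reproducible and
results are independent of execution order. Variance components are not
re-estimated inside replicates: the construction reuses the full model's
residual scale, and a thousand REML runs per region would be both
infeasible and inconsistent with that construction.

The test statistic is carried by the region's peak window while the
exclusion removes the region's whole span; the p-value is reported per
coefficient from the per-coefficient statistic.

# The synthetic-data generator

The generator is the exact stochastic counterpart of the fitted model:
a multi-generation pedigree (founders plus `n_generations` batches with
parents drawn from the previous generation); gene-dropped biallelic
genotypes (founders Hardy–Weinberg at MAF ~ U(0.05, 0.5), one allele
inherited per parent per locus); polygenic coefficient vectors gene-dropped
as founder $\sim N(0, \mathbf{G}_a)$ and offspring = parent average +
Mendelian sampling $N(0, \mathbf{G}_a/2)$; optional QTL effects
$(\text{code} - 2p)\times\text{effect}$ superimposed on a chosen
coefficient; i.i.d. permanent-environment vectors; round-robin contemporary
groups with $N(0, \sigma_{cg}^2)$ effects; uniform parity 1/2/3+; and
per-animal observation windows (onset 90 ± 5 d, length 85 ± 7 d, daily
recording probability 0.7, ≈ 60 records per animal) covering roughly ages
90–175 d.

Default variance components are $\mathbf{G}_a = \mathrm{diag}(4, 1, 0.25)$,
$\mathbf{P} = \mathrm{diag}(2, 0.5, 0.1)$, $\sigma_e^2 = 4$ — intercept
heritability 0.40 on a body-weight-like mean curve rising from about 40 to
120 kg, consistent with finishing-pig weight trajectories.

What the generator deliberately does **not** emulate, and what that means
for the tests:

* **No founder linkage disequilibrium** (association between adjacent SNPs
  arises only from pedigree co-segregation). A 10-SNP window therefore
  carries only its causal SNP's own signal, never LD tagging — window
  localization and bootstrap power against a QTL are *harder* here than in
  real SNP-chip data, where windows exist precisely to pool LD. Passing
  localization/power tests under these conditions says the machinery works;
  it does not calibrate real-data power.
* **Mendelian-sampling variance ignores inbreeding** ($\mathbf{G}_a/2$
  regardless of parental $F$), while the analysis $\mathbf{A}$ accounts for
  it; at the shallow pedigrees used, realized $F$ is a few percent and the
  validation oracles use realized values, so A-based checks remain exact.
* **QTL variance is superimposed on** (not carved out of) the polygenic
  covariance, so total genetic variance exceeds `genetic_cov` unless the
  user compensates — the fitted model is agnostic to the source of genetic
  variance, so this only matters when comparing estimates to `genetic_cov`
  under large planted QTL.
* No selection, no recombination map, no heterogeneous residual.

# Study conditions used by the automated checks

Problem sizes are the package's own desk-scale choices, fixed once:

* **Parameter recovery**: 600 animals (60 founders + 3 generations of 180),
  ≈ 60 records each, 10 seeds, EM tolerance 2×10⁻⁴, cap 100 iterations;
  seed-averaged estimates compared to the generating components at 15%.
  The per-seed REML optimum for the small components
  ($\mathbf{P}_{22} = 0.1$) swings by 30–100% at any desk scale — verified
  by converging single seeds to 2×10⁻⁵ — so the seed-averaged estimator is
  the quantity that recovery can meaningfully constrain; the genetic/PE
  partition of the intercept is the slowest-mixing, widest-swinging
  direction.
* **Localization**: a single QTL on a common variant (MAF near 0.5) at 25%
  of the intercept genetic variance, 600 animals, 1000 SNPs, 40 seeds. The
  power curve (share 0.1 → ~40%, 0.2 → ~92%, 0.3 → ~100% at n = 400–600)
  sits where the no-LD argument predicts: the QTL window must clear the
  maximum of ~950 polygenic noise windows on its own. A rare large-effect
  variant (MAF ≈ 0.1) back-solves to a few percent of its true effect and
  is essentially unlocalizable at this scale — a documented limitation of
  G-based back-solving, not of the window scan.
* **Bootstrap**: 300 animals, 1000 SNPs, 200 replicates. Calibration uses a
  QTL-free genome and five random windows; power uses a common QTL at 15%
  share tested on its own window (end-to-end selection of small-share QTL
  is a detection question the no-LD generator answers pessimistically — at
  5% share the QTL never survives two-stage selection); monotonicity uses
  an effect ladder (3%, 10%, 25%) under common replicate seed streams.

# Numerical choices and degenerate inputs

* Dense Cholesky everywhere; MME relative residual checked at $10^{-8}$
  with iterative refinement; symmetric matrices re-symmetrized after
  assembly.
* PSD validation accepts eigenvalues down to $-10^{-8}$ of scale
  (semi-definite covariances, e.g. exact zeros, are legal generator
  inputs); matrix square roots clamp negatives at zero.
* The bisquare IRLS (tuning constant 4.685, convergence on max weight
  change < 10⁻⁶, ≤ 50 iterations, MAD scale) returns unit weights for
  zero-residual series instead of dividing by a zero scale. The
  "drop weight < 0.5" rule is not exactly idempotent under Gaussian noise
  (removing a point shrinks the robust scale), which is a property of the
  published rule, not of this implementation.
* Genotype QC order: animal call rate → SNP call rate → MAF ≤ 0.02 → HWE
  χ² p < 10⁻⁴ → analysis-subset MAF < 0.002; the order is a declared
  choice (logged), since the source procedure does not state one.
* The per-visit error criteria behind feed-intake editing are a
  configurable rule registry (implausible intake, negative intake,
  occupancy-time bounds); the count of triggered rules per animal-day
  enters the adjustment model as covariates, and adjustments are clamped
  non-negative (an adjustment never reduces a daily intake).
* Zero bootstrap replicates skips the bootstrap stage with a notice; a
  chromosome with fewer than 10 SNPs yields no windows (logged, not fatal).

# Known limitations

* EM-REML at dense desk scale: ≈ 1 s per iteration at 800 animals on one
  core; thousands of animals want AI-REML or sparse factorizations.
* The genetic/permanent-environment partition of small higher-order
  coefficients is weakly identified in any design of this size; report
  seed-averaged or interval summaries, not single-seed point estimates.
* Back-solved effects of rare large-effect variants are strongly shrunken;
  single-variant inference should not be read off the window scan.
* The bootstrap null is anti-conservative under a polygenic architecture.
  Excluding a window's SNPs tests "this window contributes nothing", but on
  a genome with no QTL and purely polygenic variance *every* 10-SNP window
  truly carries a small share (≈ 1% here) of the genetic variance, and the
  replicate statistics are further deflated because the null phenotype's
  genomic part is the shrunken estimate re-analysed at the full-data
  variance components. Both effects push observed statistics above the
  replicate distribution, most visibly for the intercept coefficient
  (largest variance): on QTL-free data the intercept p-values cluster low,
  and a Kolmogorov–Smirnov uniformity check on pooled p-values can reject
  outright at the 300-animal scale. Empirical p-values from this procedure
  should be read as "window contribution beyond the null reconstruction",
  not as exactly calibrated genome-wide error rates; the stringent
  empirical cutoff (p below 1/replicates) partly compensates in practice.
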