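---
title: "Joint immune-cell and microbial profiling from bulk RNA-seq: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint immune-cell and microbial profiling from bulk RNA-seq: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmijoint)
```

## The problem

A bulk RNA-seq library from a tissue biopsy carries two layers of
tumor-microenvironment information at once. Reads that map to the host
genome measure a mixture of transcriptomes across cell types, from which
the proportions of infiltrating immune cells can be recovered by
deconvolution. Reads that *fail* to map to the host ("foreign" reads) are
candidate microbial signal, from which the relative abundance of
infiltrating bacteria can be estimated. `tmijoint` implements both
estimators plus the downstream comparisons: per-feature differential
abundance between tumor and adjacent-normal samples, and a penalized
logistic classifier that asks whether the two feature layers are jointly
more informative about pathological status than either alone.

## Deconvolution by support vector regression

The expression model is linear: with a signature matrix $S_{n \times m}$
(reference expression of $n$ genes in $m$ immune cell types) and a bulk
profile $x \in \mathbb{R}^n$,

$$ x = S f + \varepsilon, \qquad f \ge 0, \ \textstyle\sum_j f_j = 1 . $$

Each sample column is fit by $\epsilon$-insensitive support vector
regression with a linear kernel: minimize
$\tfrac12\lVert w\rVert^2 + C \sum_i \max(0, |x_i - s_i^\top w| - \epsilon)$
over the cell-type weights $w$, where the genes play the role of training
points. Residuals inside the $\epsilon$-tube cost nothing, so a minority of
outlying genes (the usual situation in bulk profiles) does not dominate the
fit; $C$ trades the flatness of $w$ against violations.

Design points worth knowing:

* **Normalization.** Mixture and signature are restricted to shared genes
  and each globally z-scored (subtract the matrix mean, divide by the
  matrix standard deviation) before fitting — the convention established by
  SVR-based deconvolution tools. This makes fractions invariant to library
  scale; the test suite asserts that rescaling the mixture by any positive
  constant leaves the output unchanged.
* **Solver.** The bias-free linear dual is solved by cyclic coordinate
  descent with a closed-form soft-threshold-and-clip update per gene —
  deterministic, no internal randomness. Convergence is declared on the
  weight vector $w$, not on the dual variables: the gram matrix has rank
  $m \ll n$, so the duals can drift along its null space long after $w$ is
  stationary to machine precision.
* **Simplex mapping.** Raw coefficients are clamped at zero and
  renormalized to sum to one. An all-non-positive coefficient vector (e.g.
  an all-zero sample) falls back to uniform $1/m$ with a warning rather
  than failing.
* **Defaults.** $C = 3$, $\epsilon = 1.203564\times 10^{-5}$,
  $\phi = 0.04545455$ — the reference converged values. $\phi$ is accepted
  because the tuner searches it, but it is inert under the fixed linear
  kernel $k(x,y) = x\cdot y$; it is retained purely for interface fidelity.

## Hyperparameter search by particle swarm

The triple $(\epsilon, C, \phi)$ is tuned by a canonical global-best
particle swarm. Velocities follow

$$ v_{i+1} = q\,v_i + c_1 r_1 (p_{ibest} - x_i) + c_2 r_2 (g_{best} - x_i),
   \qquad x_{i+1} = x_i + v_{i+1}, $$

with $r_1, r_2 \sim U[0,1]$ drawn per particle and dimension, learning
factors $c_1 = c_2 = 2$, and the inertia $q$ decayed linearly from $0.9$ to
$0.4$ over the run (the decay shape is a package choice; only the endpoints
are given). Velocities are clamped at $0.2\times$ the box width per
dimension and positions are clamped to the box
$\epsilon \in (0, 0.2)$, $C \in (1, 100)$, $\phi \in (0.01, 2.0)$.
Defaults are 30 particles and 100 iterations. $C$ is searched on a log10
scale internally because its plausible range spans orders of magnitude, and
reported on the natural scale.

The swarm needs a fitness. None is prescribed beyond "reconstruction
quality", so the package uses 5-fold *gene*-holdout reconstruction error:
folds are drawn once (seeded) over genes; for a candidate triple, SVR
coefficients are fit per sample on the training genes and the fitness is
the mean across folds of the RMSE between held-out expression and
$S_{held}\,w$. The raw coefficients — not the simplex-mapped fractions —
are used in the reconstruction, because clamp-and-renormalize destroys the
regression scale in z-scored space (a noiseless mixture would otherwise
never reach near-zero fitness).

One note on fidelity: the source description speaks of treating each gene's
expression row as a particle, which cannot be reconciled with a
three-dimensional parameter search; here particles are parameter triples.

## Microbial abundance by EM over ambiguous mappings

Foreign reads are extracted from alignments by flag logic
(`-f 4 -F 264` for one-end-anchored singles, `-f 12 -F 256` for fully
unmapped pairs), filtered (drop reads shorter than 36 bp, with more than
5 `N` bases, or with more than 40% of bases below Q15), and singletons are
given a synthetic reverse-complement mate so that everything can be
remapped through one paired-end path. After remapping against a microbial
reference, a read may align to several genomes — short reads plus
homologous references make this ambiguity the rule, not the exception.

Abundance is the maximum-likelihood mixture over genomes: with mixture
weights $\pi$ and candidate mismatch count $m_{rj}$ for read $r$ on genome
$j$ of length $L_j$,

$$ p(r \mid j) \propto \frac{1}{L_j}\,
   \varepsilon^{m_{rj}} (1-\varepsilon)^{\ell - m_{rj}}, $$

with per-base error rate $\varepsilon$ (default 0.01) and read length
$\ell$ (which cancels across genomes). EM alternates read responsibilities
(E) with $\pi_j \leftarrow$ mean responsibility (M), in log space, from a
uniform start, stopping when the log-likelihood gains less than $10^{-8}$
(at most 1000 iterations). The trace is non-decreasing by construction and
asserted in the tests. The *reported* abundance is the genome-length
corrected weight $a_j \propto \pi_j / L_j$: the relative abundance of
genomes, not of reads. Shannon diversity $H = -\sum a_j \ln a_j$ (nats,
zero terms contribute zero) summarizes each profile.

## Differential abundance

Per feature, an unpaired Mann–Whitney U test with mid-rank ties compares
tumor against normal samples: $U_A = N_A N_B + N_A(N_A+1)/2 - T_A$, with
the smaller of $U_A, U_B$ reported and $U_A + U_B = N_A N_B$ always. The
p-value is exact (null distribution of $U$ by counting, or full enumeration
of group assignments when ties are present and enumeration is feasible) for
small untied samples, else a tie-corrected normal approximation with
continuity correction. Two-sided by default; one-sided alternatives are a
flag. The paired structure of the cohort is deliberately *not* exploited
(no signed-rank variant), matching the original analysis design.
Benjamini–Hochberg adjustment runs across features.

The reported percent difference is
$|\bar{x}_t - \bar{x}_n| / \min(\bar{x}_t, \bar{x}_n) \times 100$ —
division by the *smaller* group mean. This is the only definition
consistent with published differences exceeding 100%, but the exact
formula behind those values is not stated anywhere; treat the column as
descriptive.

## Joint classification

The elastic-net logistic model minimizes

$$ -\frac1n \sum_i \left[ y_i(\beta_0 + x_i^\top\beta)
   - \log(1 + e^{\beta_0 + x_i^\top\beta}) \right]
   + \mu\left[ (1-\alpha)\tfrac12\lVert\beta\rVert_2^2
   + \alpha\lVert\beta\rVert_1 \right] $$

by proximal gradient descent with a fixed Lipschitz step, which makes the
objective trace provably non-increasing — an invariant the tests assert.
Features are standardized internally; the intercept is unpenalized;
coefficients are returned on the original scale. $\alpha$ defaults to 0.5;
$\mu$, when not given, is selected by 5-fold cross-validated deviance over
a log grid — once per feature case, not once per split repeat, which would
be slower and noisier.

Three feature cases are compared — bacterial abundances only, immune-cell
fractions only, and their union — on stratified 75/25 train/test splits.
A single split at cohort scale (98 samples) is dominated by sampling noise,
so the evaluation repeats the split across seeds (default 50) and reports
mean ± sd per case. The qualitative expectation, reproduced on synthetic
cohorts with complementary planted signal in both blocks, is that the joint
case dominates both single-block cases.

## What the synthetic generators emulate — and what they don't

All validation runs on generators in `synth_spec()` and friends, which are
pure functions of their spec (same seed, same bytes):

* `make_signature()` / `make_mixtures()`: a marker-block signature
  (each cell type's markers elevated 5-fold over a lognormal baseline;
  5 types × 200 genes by default), flat-Dirichlet fractions over 20
  samples, Gaussian noise at a fraction (default 5%) of the mean signal,
  truncated at zero. Real signatures have correlated, partially
  overlapping marker sets and heteroskedastic noise; a green recovery test
  establishes correctness of the estimator on its own model, not
  performance on any real tissue.
* `make_read_set()`: three equal-length 10 kb genomes sharing a common
  prefix whose length sets the ambiguous-read share (default 20%); 10,000
  75 bp reads at 1% per-base error drawn at proportions (0.5, 0.3, 0.2).
  Real references differ in length, share scattered homology rather than
  one block, and have coverage bias. Equal lengths make read and genome
  abundance coincide, which is exactly what makes planted truth checkable.
* `make_cohort()`: 49 tumor/normal pairs (the study's cohort size) with a
  shared per-pair random effect, lognormal biological noise (sd 0.4 on the
  log scale), planted fold changes (default 2×) on selected tumor-arm
  features, and compositional closure after planting. It mimics effect
  *orders of magnitude*, not any real effect-size distribution.

## Numerical choices and degenerate inputs

* SVR: convergence on $\max|\Delta w| < 10^{-9}$ per sweep, at most 1000
  sweeps; hitting the cap with movement above $\sqrt{\text{tol}}$ raises.
* EM: log-space likelihoods throughout; a non-finite log-likelihood raises
  rather than silently renormalizing.
* Mann–Whitney with every value tied: variance 0, $p = 1$.
* Constant features in `differential_table()`: $p = 1$ and a `constant`
  flag instead of an error.
* BH on an empty vector returns an empty vector; p-values outside
  $[0,1]$ raise.
* All-zero samples deconvolve to uniform fractions with a warning.
* Orphaned mates (one end lost to filtering) demote to the singleton
  stream with a warning, mirroring truncated real-world alignment files.
* PSO particles whose fitness evaluates non-finite are re-initialized
  uniformly inside the bounds, with a warning.

## Known limitations

* No signature-matrix construction, batch correction, or deconvolution
  p-values; the signature is an input.
* The EM likelihood is mismatch-count based; whether the original analysis
  used mismatch-based or hit/no-hit likelihoods is unknown.
* No taxonomy aggregation — genomes are the unit of abundance.
* The classifier reports accuracy only (no AUROC/calibration), matching
  the scope of the original comparison.
* Quantitative results from the original study depend on external
  datasets and are out of reach of this package's test fixtures; the
  validation here is property-based by design.
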