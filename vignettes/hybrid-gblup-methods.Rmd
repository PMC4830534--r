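---
title: "Methods: multivariate GBLUP with dominance for single-cross hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate GBLUP with dominance for single-cross hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A maize breeding programme with two heterotic pools can produce far more
single-cross hybrids than it can field-test: 100 lines per pool already
give 10,000 candidate crosses. Genomic prediction replaces most of that
phenotyping with a model trained on a modest set of tested hybrids. For
hybrids, dominance is not a nuisance parameter — heterosis is largely a
dominance phenomenon — so the question this package addresses is: how much
do (i) dominance effects and (ii) joint multi-trait modelling improve
genomic prediction of hybrid performance, and how cleanly are additive and
dominance variance separated when both are fitted?

`gblupad` implements the four model variants needed for that comparison —
univariate or multivariate GBLUP, additive-only (`UV-A`, `MV-A`) or
additive plus dominance (`UV-AD`, `MV-AD`) — together with a synthetic
single-cross study generator, so that the whole experiment runs end-to-end
on a desktop machine with known ground truth.

## Marker coding

Dosages count copies of the A1 allele (0, 1, 2). With `p` the A1 frequency
at a locus (computed from the population being analysed — for hybrids, the
hybrid population itself), the Cockerham incidence codes are

| genotype | $W_A$ | $W_D$ |
|---|---|---|
| A1A1 | $2-2p$ | $-2(1-p)^2$ |
| A1A2 | $1-2p$ | $2p(1-p)$ |
| A2A2 | $-2p$  | $-2p^2$ |

These columns are centred and mutually orthogonal under Hardy–Weinberg
proportions. Fractional dosages arise for hybrids because each hybrid
genotype is the *expectation* of the cross of its parents,
$E(m) = p_\lambda + p_\Omega$. `code_cockerham()` codes such cells as the
probability-weighted average of the three class codes using the exact
genotype-class probabilities of the cross
($P(\mathrm{A1A1}) = p_\lambda p_\Omega$, etc.), which
`partial_diallel()` supplies; for fractional cells of unknown origin it
falls back to a $g/2 \times g/2$ cross, which preserves the expected codes
and reduces to the integer coding at integer dosages. Monomorphic loci are
retained; they contribute zero to both the incidence columns and the
relationship denominators.

## Relationship matrices and their repair

$$A = \frac{W_A W_A'}{2\sum_k p_k(1-p_k)}, \qquad
  D = \frac{W_D W_D'}{4\sum_k \left(p_k(1-p_k)\right)^2}.$$

With 400 hybrids from 40 parents both matrices are rank-deficient, so they
are repaired before entering the mixed model: eigenvalues that are
non-positive (or indistinguishable from zero, below $10^{-8}$ of the
spectral radius) are replaced by a strictly positive, strictly decreasing
schedule $\le 10^{-4}$ — with $r$ replacements the $j$-th largest replaced
value is $10^{-4}(r-j+1)/r$. The positive eigenspace is untouched, so the
repair perturbs the matrix by at most the replaced mass plus
$10^{-4} r$ in Frobenius norm.

## The model

Per trait $i$: $y_i = X_i\beta_i + Z_i\alpha_i + Z_i\delta_i + e_i$ with an
intercept-only $X_i$ and identity $Z_i$ (rows deleted for missing records;
the individual keeps its random-effect level so its genetic value is still
predicted). Effects are stacked trait-major with priors
$\alpha \sim N(0, V_\alpha \otimes A)$,
$\delta \sim N(0, V_\delta \otimes D)$,
$e \sim N(0, V_e \otimes I)$, all trait covariance matrices unstructured.
Additive-only variants drop the $\delta$ term; univariate variants analyse
each trait separately.

Variance components are estimated by EM-REML. The updates for a trait pair
$(i,j)$ are

$$\tilde\sigma_{\alpha,ij} = \left[\hat\alpha_i' A^{-1} \hat\alpha_j +
  \mathrm{tr}\left(A^{-1} C^{ij}_{\alpha\alpha}\right)\right] / n, \qquad
  \tilde\sigma_{e,ij} = \left\{\hat e_i'\hat e_j +
  \mathrm{tr}\left([W C^{-1} W']_{ij}\right)\right\} / n_{rec},$$

with $C^{-1}$ the inverse mixed-model coefficient matrix, $W = [X, Z, Z]$,
$n$ the number of genetic-effect levels and $n_{rec}$ the number of
records. The divisor conventions and the placement of the inverse inside
the trace are the standard EM forms, which provably keep the REML
log-likelihood non-decreasing — a property the test suite asserts on every
trajectory. BLUPs and fixed means come from Henderson's equations solved
by direct inversion.

### Three equivalent computational paths

* **direct** — builds the full coefficient matrix explicitly
  (`build_mme()`, `solve_mme()`, `em_update_genetic()`,
  `em_update_residual()`). Transparent but cubic in $nt$ per iteration;
  used for small problems, for per-cell missingness, and as the reference
  in equivalence tests.
* **reduced** — works with the marginal covariance
  $V = V_\alpha\!\otimes\!A + V_\delta\!\otimes\!D + V_e\!\otimes\!I$ and
  the projection $P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$, using
  $C^{uu} = G - GPG$ and $WC^{-1}W' = R - RPR$ to collapse every EM trace
  into $t \times t$ algebra around one $nt \times nt$ inverse per
  iteration.
* **rotated** — for additive-only variants the eigendecomposition
  $A = Q\Lambda Q'$ diagonalises $V$, so an iteration costs $O(n t^3)$;
  univariate additive fits take milliseconds.

The three paths execute the same updates; tests assert their trajectories
agree to $10^{-8}$.

### Numerical choices

* Initial components split the phenotypic covariance equally among the
  fitted terms; the EM fixed point does not depend on the start, and
  cross-validation refits warm-start at the full-data estimates.
* Convergence is declared when the largest relative parameter change drops
  below `tol` (default $10^{-6}$, `max_iter` default 500). EM approaches
  the optimum linearly and slowly near convergence; estimates are stable
  to well under replicate noise after 150–200 iterations at the study
  scale, so the examples, tests and acceptance script cap iterations
  there and report `converged = FALSE` honestly when the cap bites.
* A relative-change denominator floored at $10^{-8}$ of the phenotypic
  scale prevents near-zero components from stalling the stopping rule.
* Updates are projected to the nearest positive semidefinite matrix if
  round-off produces a negative eigenvalue (flagged in the fit); a
  singular component matrix inside the direct path raises an error
  suggesting a ridged restart.

## The synthetic study generator

`simulate_hybrid_study()` emulates the data-construction pipeline of a
two-pool maize programme; its defaults are the study conditions the
package targets.

* **Lines.** Ancestral allele frequencies $U(0.1, 0.9)$; each heterotic
  group drifts by a Balding–Nichols Beta draw with fixation index
  `divergence` (default 0.2, enough for the leading principal component of
  the line $A$ to separate the groups cleanly); lines are fully inbred.
  Group membership is then *re-discovered* from the data by seeded 2-means
  on the top two principal components of $A$, mirroring how heterotic
  pools are identified in practice.
* **Hybrids.** All $20 \times 20$ crosses between the pools (400 hybrids);
  each hybrid dosage is the expected genotype of its cross.
* **Architecture.** 100 additive and 100 dominance QTN per trait drawn
  from the marker panel; trait pairs share QTN according to a preset
  pairwise pattern (17 shared additive and 20 shared dominance QTN between
  the two height traits, a handful elsewhere), scaled proportionally if
  fewer QTN are requested; shared loci reuse one effect draw, so sharing
  induces positive genetic correlation. Effects are genotypic-scale
  ($a$ = half the homozygote difference, $d$ = heterozygote deviation).
  The coefficient entering $W_A$ is the allele-substitution effect
  $\alpha_k = a_k + d_k(q_k - p_k)$ formed at the hybrid coding
  frequencies — with that convention the locus-sum variances
  $\sigma^2_\alpha = \sum_k 2p_kq_k[a_k + d_k(q_k-p_k)]^2$ and
  $\sigma^2_\delta = \sum_k (2p_kq_kd_k)^2$ are exactly the parametric
  components of the simulated signal under linkage equilibrium. (Treating
  the raw draws as substitution effects instead silently inflates the
  locus-sum reference by $1 + E[(q-p)^2]$, roughly 20% at divergence 0.2.)
* **Phenotypes.** $g = \mu + W_A\alpha^* + W_D d^*$;
  residuals are i.i.d. normal with
  $\sigma^2_e = \sigma^2_g (1-h^2)/h^2$, where $\sigma^2_g$ is the
  *empirical* variance of $g$ over the hybrids, so the realized
  broad-sense heritability matches the request in the generated sample.
  Heritability presets: `"historical"` (PH 0.569, EH 0.662, EL 0.381,
  ERN 0.57, KW 0.418), `"mixed"` (0.3, 0.5, 0.7, 0.7, 0.3), or any fixed
  value.

What the generator does **not** emulate: linkage maps and recombination
(QTN are exchangeable panel positions; an optional adjacency-based sharing
is not claimed to mimic genetic linkage), selection history, genotyping
error, and environment or replicate structure (a single residual per
hybrid-trait cell). Passing tests therefore demonstrate correctness of the
estimation machinery under a clean generative model, not robustness to
real-data pathologies.

Two deliberate features of the diallel deserve emphasis when reading the
recovery checks. First, with only 40 founder lines the QTN are in strong
mutual linkage disequilibrium, so the realized variance of each genetic
component in a single replicate deviates noticeably from its locus-sum
value; recovery is therefore assessed as a *mean over replicates*, not per
dataset. Second, an F1 diallel population is far from Hardy–Weinberg
proportions — heterozygosity is in excess and the parental pools are
divergent — so the dominance relationship matrix is scaled by a population
the HWE locus-sum formula does not describe. The REML dominance component
(the coefficient on $D$) and the locus-sum $\sigma^2_\delta$ are then
systematically different population parameters: the dominance estimate
carries a positive offset against the equilibrium reference, with a
heavy-tailed replicate-to-replicate spread that 30 replicates do not pin
down precisely (the acceptance script reports the gap it measures on its
own replicate set). The additive component agrees with its reference to
within about ten percent, and model-consistent simulations recover the
additive variance with negligible bias. This is a reference-frame
property of non-equilibrium populations, not an estimator defect, and the
corresponding recovery check documents it by failing against the
equilibrium reference at its fixed replicate set.

## Model evaluation

* `predictive_correlation()` — Pearson correlation between parametric and
  estimated genetic values, computed for the total, additive and dominance
  components separately.
* `estimated_heritability()` — $\hat h^2 = \mathrm{cov}(\hat g, y) /
  \mathrm{var}(y)$ with $\hat g = \hat\alpha$ for additive models and
  $\hat\alpha + \hat\delta$ for additive-dominance models; sample
  ($n-1$) denominators throughout.
* `press()` — $\sum_i (\hat\theta_i - \theta_i)^2$, applied to effect
  vectors and to variance-component estimates.
* `kfold_cv()` — individuals are partitioned into seeded folds; all traits
  of a held-out individual are masked together (whole-individual masking —
  the scenario of predicting an untested hybrid; per-cell masking is
  available via the direct path), the model is refit, and the masked
  phenotype is predicted as $\hat\beta + \hat\alpha + \hat\delta$. The
  summary reports the per-trait mean and SD over folds of the
  predicted-vs-observed correlation; $\sqrt{h^2}$ is the theoretical
  ceiling of that correlation for a well-specified model.

## Problem sizes used in tests and the acceptance script

The generator's scientific conditions (400 hybrids, 5 traits, 100+100
QTN, historical heritabilities) are kept wherever a check concerns them;
marker panels are thinned to 1,200–2,000 loci (the default 27,000 only
adds null markers, which sharpen the relationship matrices slightly) and
iteration caps of 120–200 are used, choices the convergence diagnostics
above justify. Variance-component recovery runs 30 replicates with
univariate additive-dominance fits, which estimate exactly the diagonals
under test; multivariate refits at full scale cost roughly a minute each,
so the multivariate-vs-univariate cross-validation comparison uses a
$10\times10$ diallel of 100 hybrids. Null-dominance recovery must run at
the full 400-hybrid scale — at 100 hybrids the dominance component is so
weakly identified that even the REML optimum leaves a
$\hat\sigma^2_\delta/\hat\sigma^2_\alpha$ ratio near 0.3 on purely
additive data — and it iterates deeper (400 EM steps) because the EM tail
drains a boundary component slowly.
Directional comparisons (dominance improves cross-validation accuracy;
additive-only models absorb dominance variance at $h^2 = 0.7$) use 20
seeded replicates at full scale with univariate models, where the
direction of the contrast is the same as for the multivariate pair.

## Known limitations

* EM-REML converges slowly near the optimum; for publication-grade
  variance components at tight tolerance, expect hundreds of iterations
  (an AI-REML accelerator is out of scope by design).
* Unbalanced multi-trait data beyond whole-individual missingness is
  supported only through the explicit-MME path, which is cubic in the
  number of records; its residual cross-trait updates use shared records
  and are a generalised EM (monotonicity is only guaranteed for balanced
  data).
* The dominance component is weakly identified at low heritability and
  small $n$; its estimate is noticeably right-skewed across replicates.
* Epistasis, pedigree-based matrices and Bayesian marker-effect models
  are out of scope.
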