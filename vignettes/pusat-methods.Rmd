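---
title: "Joint association tests for multiple phenotypes in family samples: models and methods"
author: "pusat package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint association tests for multiple phenotypes in family samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pusat)
```

## The problem

Genome-wide association studies routinely measure several correlated
quantitative traits — for example two blood-lipid levels — on the same
individuals, and many of those individuals are relatives. Testing one trait at
a time ignores the cross-trait correlation (losing power and any view of
pleiotropy), and ignoring relatedness inflates test statistics. `pusat`
implements a family of joint single-variant tests that handle both:

* the **marginal linear mixed model (LMM)**, one trait at a time, with a
  polygenic random effect whose covariance is proportional to a relatedness
  matrix;
* the **SSU test**, which combines the marginal statistics by summing their
  squares;
* the **multivariate LMM (mvLMM)**, a K-degree-of-freedom joint test from a
  matrix-variate mixed model;
* **USAT/pUSAT**, a min-p combination of the MANOVA-type and SSU statistics
  over a weight grid, with a numerical-integration p-value. USAT is the
  unrelated-sample version; pUSAT feeds the combination with kinship-adjusted
  statistics.

A gene-dropping simulator generates pedigrees, Mendelian genotypes and
matrix-variate null phenotypes so that Type I error can be studied without
access to restricted cohort data.

## Models

### Marginal linear mixed model

For trait $k$ and one variant with dosage vector $G$ (minor-allele counts
0/1/2),
$$ Y_k = \alpha + G\beta_k + C\gamma_k + Q_k + \epsilon_k,\qquad
   Q_k \sim N(0, \sigma_g^2 \Phi),\quad \epsilon_k \sim N(0, \sigma_e^2 I), $$
with $C$ the covariate matrix and $\Phi$ the $N\times N$ relatedness matrix.
Writing $\Phi = U\Lambda U^\top$ and premultiplying by $U^\top$ gives
independent residuals with variances $\sigma_e^2(\delta\lambda_i + 1)$,
$\delta = \sigma_g^2/\sigma_e^2$, so the restricted likelihood is profiled
over the single ratio $\delta$. `fitNullReml()` evaluates the profile on a
64-point log grid over $[10^{-5}, 10^5]$, refines the bracketed maximum with
bounded scalar optimization (tolerance $10^{-8}$), and always compares against
the boundary candidates $\delta = 0$ and the grid maximum; ties break toward
the smallest $\delta$, so a flat profile (e.g. $\Phi = I$, where only
$\sigma_g^2 + \sigma_e^2$ is identified) deterministically returns the
no-genetic-variance boundary.

Per-variant statistics fix the variance components at the null fit (the
score-test / EMMAX convention) and compute the generalized-least-squares
effect and its standard error; $t_k = \hat\beta_k/\mathrm{se}$ is referenced
to the standard normal rather than a t distribution because the joint-test
distribution theory below treats $t = (t_1,\dots,t_K)$ as asymptotically
multivariate normal. Re-fitting REML per variant is not offered: it is orders
of magnitude slower and asymptotically equivalent under the null.

### SSU test

The sum-of-squared-score statistic is $S = t^\top t = \sum_k t_k^2$. Under
$H_0$, $t \sim N(0, \Sigma)$ and $S$ is distributed as
$\sum_k c_k \chi^2_1$ with $c_k$ the eigenvalues of $\Sigma$. The p-value uses
the three-moment match to a scaled chi-square $a\chi^2_d + b$ with
$$ a = \frac{\sum c^3}{\sum c^2},\qquad
   b = \sum c - \frac{(\sum c^2)^2}{\sum c^3},\qquad
   d = \frac{(\sum c^2)^3}{(\sum c^3)^2}. $$
The match is exact when all eigenvalues are equal. Its CDF error for unequal
eigenvalues peaks near the median (around 0.01–0.02 sup-norm for eigenvalue
ratios of 2–5) and shrinks in the survival tail where association p-values
live; the test suite measures both against Monte-Carlo mixtures. Because the
approximating CDF is $F(q) = P(\chi^2_d \le (q-b)/a)$, its quantile function
is available in closed form, which the min-p integration below exploits.

$\Sigma$ is estimated once per trait set and reused genome-wide: each trait's
null-model residuals are rotated to the eigenbasis and whitened by
$(\hat\delta\lambda_i + 1)^{-1/2}$, and $\hat\Sigma$ is the sample correlation
of the whitened residual vectors. A $10^{-6}$ diagonal ridge (renormalized to
unit diagonal) keeps $\hat\Sigma$ positive definite when traits are nearly
duplicated. The whitened-residual estimator is this package's choice; with an
identity kinship it reduces exactly to the ordinary residual correlation.

### Multivariate LMM

The K traits jointly follow
$$ Y = X\Gamma + Q + E,\qquad Q \sim MVN_{N\times K}(0, \Phi, V_g),\quad
   E \sim MVN_{N\times K}(0, I, V_e). $$
After the same row rotation, row $i$ has covariance
$\lambda_i V_g + V_e$. `fitMvNull()` estimates $(V_g, V_e)$ by maximum
likelihood with an EM algorithm (the model statement admits either ML or
REML; ML-EM is used because each iteration provably increases the objective,
which the fit records and the tests assert). Each iteration simultaneously
diagonalizes the pair — $V_e^{-1/2} V_g V_e^{-1/2} = PDP^\top$, transform
$T = P^\top V_e^{-1/2}$ — so posterior moments and the M-step are elementwise
over an $N \times K$ grid, and the fixed effects are re-profiled by weighted
least squares per transformed component. Convergence is declared at relative
log-likelihood change below $10^{-6}$ (cap 500 iterations; non-convergence
returns the best iterate with a warning). $V_e$'s eigenvalues are floored at
$10^{-8}\,\mathrm{tr}(V_e)/K$ to keep row covariances invertible. A $K = 1$
input delegates to the univariate REML fit.

`mvTest()` fixes $(\hat V_g, \hat V_e)$ and tests
$H_0: \beta_1 = \dots = \beta_K = 0$ with the GLS Wald statistic
$\hat\beta^\top \mathrm{cov}(\hat\beta)^{-1}\hat\beta \sim \chi^2_K$, again in
the transformed coordinates where the K components decouple.

### USAT and pUSAT

Neither the MANOVA-type test (strong when effects oppose the trait
correlation) nor SSU (robust to strong correlation with concordant effects)
dominates. The unified test takes, for each weight $w$ on the grid
$\{0, 0.1, \dots, 1\}$,
$$ T_w = w\,T_M + (1-w)\,T_S, \qquad
   T_M = t^\top \Sigma^{-1} t,\quad T_S = t^\top t, $$
and the statistic is $T_{min} = \min_w p_w$. Writing $t = \Sigma^{1/2} z$,
$T_w$ is the quadratic form $z^\top(wI + (1-w)\Sigma)z$, so its null
distribution is $\sum_i \kappa_i \chi^2_1$ with
$\kappa_i = w + (1-w)\lambda_i(\Sigma)$ and $p_w$ comes from the same
moment-matching as SSU. In the pedigree version the inputs $t$ and $\Sigma$
are the kinship-adjusted marginal statistics and their whitened-residual
correlation; in the unrelated version they come from ordinary least squares.
With $\Phi = I$ the two pipelines coincide identically, which the tests
assert to $10^{-6}$.

Inside the combination, the MANOVA-type component is represented as the
quadratic form $t^\top\Sigma^{-1}t$ of the marginal mixed-model statistics
(asymptotically the mvLMM K-df test) rather than the EM-based statistic: the
shared-eigenstructure distribution theory for $T_w$ requires both components
to be quadratic forms in the same vector. The standalone EM-based mvLMM test
is reported alongside, not inside, the combination.

**The integrated p-value.** The observed $T_{min} = t_{min}$ converts to its
own p-value via
$$ p = 1 - P\!\left(T_{w_1} < q_{min}(w_1), \dots, T_{w_B} < q_{min}(w_B)\right), $$
where $q_{min}(w)$ is the $(1 - t_{min})$ quantile of $T_w$'s null mixture —
computed in closed form from the moment-matched chi-square. The joint event
is equivalent to $T_M < q_{min}(1)$ together with
$T_S < \delta(T_M)$, $\delta(x) = \min_{w<1} (q_{min}(w) - wx)/(1-w)$
($w = 1$ is excluded from the minimization, where the expression is
undefined; its constraint is exactly the upper limit of integration), so
$$ p = 1 - \int_0^{q_{min}(1)} F_{T_S \mid T_M = x}\big(\delta(x)\big)\,
        f_{\chi^2_K}(x)\, dx. $$
The conditional law is handled exactly: given $z^\top z = x$, the vector
$z^2/x$ is Dirichlet$(1/2,\dots,1/2)$, so
$T_S \mid T_M = x \;=\; x\sum_i \lambda_i d_i$, which at $K = 2$ is exactly
$x\,(\lambda_{min} + (\lambda_{max}-\lambda_{min})\,\mathrm{Beta}(1/2,1/2))$;
for $K > 2$ a Beta on $[\lambda_{min}x, \lambda_{max}x]$ is moment-matched to
the Dirichlet mean and variance (reproducing the exact law at $K = 2$). The
integrand is then the exact $\chi^2_K$ density below the point where
$\delta(x) \ge \lambda_{max}x$ (conditional CDF saturates at 1) and zero
beyond $\delta(x) \le \lambda_{min}x$, so the quadrature runs only over the
interior window (adaptive, absolute tolerance $10^{-8}$, with a 20k-point
trapezoid fallback). Treating $T_M$ and $T_S$ as independent instead —
evaluating the unconditional CDF of $T_S$ at $\delta(x)$ — is available as
`conditional = FALSE`; it is markedly conservative as $\Sigma \to I$ (where
$T_S \equiv T_M$ makes the independence assumption maximally wrong, yielding
roughly $2\,t_{min}$), and is retained for sensitivity analysis because that
conservative behaviour matches how the approach has historically been
reported. The conditional form is the default: it is validated against
Monte-Carlo simulation of $\min_w p_w$ in the acceptance tests and satisfies
the exactness limit $p \to t_{min}$ as $\Sigma \to I$.

Two exact inequalities always hold and the result is clamped into them:
$t_{min} \le p \le \min(1, B\,t_{min})$ with $B = 11$ grid points (min-p
versus Bonferroni). Ties in the argmin over $w$ break toward the smallest
weight.

## Quality control and data handling

Variants are excluded at call rate below 0.95, minor allele frequency below
0.05, or a Hardy-Weinberg equilibrium p-value below $10^{-6}$ (a plain 1-df
Pearson chi-square on genotype counts, no continuity correction, computed on
all retained individuals — the founders-only alternative is not attempted
because a generic filter over a family sample is the intended behaviour).
Samples with more than 5% missing genotypes are removed (strictly greater).
Remaining missing dosages are mean-imputed per column, which preserves each
column's allele frequency; the LMMs require complete dosages. Dosage columns
are always oriented to count the minor allele (ties at frequency 0.5 keep the
file's allele order; orientation is deterministic). Coordinates are 1-based;
no strand flipping is attempted; multi-allelic VCF records are skipped with a
message.

The empirical relatedness matrix is the centered GRM $WW^\top/M$ ($W$
column-centered dosages), matching the common mixed-model-software default; a
standardized variant is behind a flag. The pedigree relationship matrix uses
the standard additive recursion (diagonal 1 for non-inbred individuals), so
$\sigma_g^2$ retains its usual heritability interpretation. All kinship
inputs are symmetrized, eigendecomposed once, and negative numerical
eigenvalues are clamped to zero (warning when below $-10^{-8}$ relative); the
stored matrix is the clamped reconstruction so the cached decomposition is
exact.

## The simulator and the Type I error harness

`simulateDataset()` builds nuclear families (two founders plus a configurable
number of offspring; a three-generation option adds a founder spouse and two
grandchildren), drops founder alleles from Hardy-Weinberg proportions at a
MAF drawn uniformly from $[0.052, 0.5]$, transmits alleles by Mendelian
sampling, and redraws any column whose realized MAF falls below the 0.05
analysis floor. Null phenotypes follow the matrix-variate model
$$ Y \sim MVN(0, \Phi, V_g) + MVN(0, I, V_e),\qquad
   V_g = h^2 B(\rho),\quad V_e = (1-h^2)E, $$
with $B(\rho) = E$ compound-symmetry correlation matrices, sampled as
$L_\Phi Z_1 L_g^\top + Z_2 L_e^\top$ via eigen/Cholesky square roots — exact
at these scales. Under this design founder trait variances are 1 and the
founder cross-trait correlation is exactly $\rho$ (since
$h^2\rho + (1-h^2)\rho = \rho$), which the tests verify, along with a direct
comparison of the vectorized covariance against the dense Kronecker form
$V_g \otimes \Phi + V_e \otimes I$ at small N.

Defaults mirror the emulated study: about 820 pedigree-based individuals
(205 families of 4), two traits, heritability $h^2 = 0.5$, $\rho$ in
$\{0, 0.25, 0.5, 0.75\}$, 1000 null replicates, nominal level 0.05. The
written description of the emulated study gives heritability as "0.5%", an
ambiguous reading; 0.5 is adopted as the conventional magnitude for lipid-like
traits and the harness accepts any value. The harness (`type1Harness()`) keeps
one pedigree (eigendecomposition computed once) and one gene-dropped variant
panel per run, draws fresh phenotypes each replicate, runs the full pUSAT
pipeline, pools all per-variant integrated p-values, and reports the rejection
fraction with its binomial standard error. The nominal level is a parameter
throughout.

What the simulator does **not** emulate: linkage disequilibrium between
variants (loci are independent), ascertainment, non-normal trait
distributions, missing phenotypes, and genuinely associated variants (no
power mode). Passing tests therefore demonstrate calibration and internal
consistency under idealized family structure, not performance on real
cohort data.

## Calibration note

With the conditional (default) integration, the integrated pUSAT p-value is
essentially exact under its asymptotic model, so the harness estimates
rejection rates near the nominal level at every $\rho$. With
`conditional = FALSE` the test is conservative, most strongly at low $\rho$.
Earlier reports of this approach describe it as "slightly conservative";
that behaviour corresponds to the independence approximation, and users who
need to reproduce it can select it explicitly. Both variants respect the
min-p/Bonferroni sandwich by construction.

## Problem sizes used by the shipped tests

The test suite and acceptance script run entirely on synthetic data at desk
scale, chosen so the full suite completes in minutes while keeping
Monte-Carlo error well inside the asserted tolerances: 200 four-person
families (N = 800) with 20 variants and 1000 replicates per correlation for
the Type I error study; 200 replicates for univariate heritability recovery
and 100 for bivariate EM recovery; $10^6$-draw Monte-Carlo oracles for the
chi-square-mixture CDF and the min-p null law; 500 unrelated samples for the
identity-kinship equivalence check.

## Known limitations

* Binary traits, dosage/imputation formats (BGEN), X-chromosome handling,
  rare-variant region tests and LD-aware simulation are out of scope.
* The weight grid is fixed and finite (no continuous optimization over $w$).
* Per-variant statistics reuse null-model variance components; exact per-SNP
  REML refits (and hence bit-identical agreement with implementations that
  refit) are not provided.
* The cross-trait statistic covariance for related samples uses the
  whitened-residual correlation described above; other estimators are
  conceivable and would perturb borderline p-values.
* The three-moment chi-square match used for all mixture p-values has its
  worst error near the distribution's median (~0.01–0.02 for moderately
  spread eigenvalues); tail p-values are substantially more accurate.
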