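---
title: "Predicting the accuracy of genomic EBV in selection candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the accuracy of genomic EBV in selection candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gebvacc)
```

## The problem

Deterministic models of breeding programs need the accuracy of selection —
the correlation between estimated and true breeding values of the selection
candidates — as an input. For pedigree BLUP this accuracy is well predicted
by classical selection-index (pseudoBLUP) theory. For genomic BLUP it is
not: GEBV mix two sources of information with very different dynamics,

* pedigree information, which every relative contributes and which erodes
  quickly across generations (halving each meiosis), and
* linkage-disequilibrium and co-segregation information carried by the
  markers, which erodes slowly, through recombination of chromosome
  segments.

`gebvacc` implements a deterministic prediction of the accuracy of GEBV for
candidates that are one or more generations removed from the reference
(training) population, by explicitly separating these two components,
propagating each across generations with its own decay, and recombining
them.

## Model

### Partitioning GEBV information

Write $\hat g_A$ for the pedigree-BLUP EBV, $\hat g_G$ for the GEBV, and
$\hat g_D$ for a conceptual EBV based on genomic **deviations** from
pedigree relationships ($\mathbf G - \mathbf A$ as relationship matrix).
Population accuracies are denoted $r_A$, $r_G$, $r_D$. Sampling errors of
$\hat g_A$ and $\hat g_D$ are assumed independent, because pedigree
relationships and deviations of genomic from pedigree relationships are
(nearly) independent sources.

Two equivalent currencies connect the accuracies:

* **Fisher information.** Each EBV carries an information statistic
  $\theta$ about the true breeding value,
  $$\theta = \frac{r^2\,(1 - r^2 q^2 h^2)}{q^2 - r^2},$$
  where $h^2$ is the heritability of the training phenotypes and $q^2$ the
  fraction of genetic variance the information source can capture
  ($q_A^2 = q_G^2 = 1$ since pedigree covers the whole genome;
  $q_D^2 = M/(M + M_e) < 1$ for a panel of $M$ markers). Information from
  independent sources adds: $\theta_G = \theta_A + \theta_D$. The inverse
  mapping is the root of a quadratic,
  $$r^2 = \frac{1 + \theta - \sqrt{(1+\theta)^2 - 4 h^2 q^4 \theta}}{2 q^2 h^2}.$$
  Implemented in `theta_from_r2()` / `r2_from_theta()` (exact roundtrip,
  tested to $10^{-10}$).

* **Selection index.** The optimal index of two EBV with independent errors
  has squared accuracy
  $$r_G^2 = \frac{r_A^2 + r_D^2 - 2 r_A^2 r_D^2}{1 - r_A^2 r_D^2},$$
  inverted by `index_extract_rD2()`. The two routes deliberately do *not*
  give the same $r_D$ for the same $(r_A, r_G)$.

### The effective number of chromosome segments

$M_e$ — the number of independent genomic effects the reference data
estimate — is the central population parameter. The deviation information
grows linearly with reference size $N$:
$$\theta_D = N q_D^2 h^2 / M_e.$$
Four estimators are provided:

| estimator | function | input |
|---|---|---|
| Fisher route | `me_fisher()` | observed $r_A$, $r_G$ (positive root of $\theta_D M_e^2 + \theta_D M M_e - N M h^2 = 0$) |
| Index route | `me_index()` | $r_D$ extracted by the index formula; solved jointly with $q_D^2 = M/(M+M_e)$ |
| relationship variance | `me_from_relationship_variance()` | $1/\mathrm{var}$ of off-diagonal $\mathbf G - \mathbf A$ |
| theoretical | `me_theoretical()` | $2 N_e L k$, or $2 N_e L k / \ln(N_e L)$ |

The Index-route fixed point oscillates when iterated plainly, so
`me_index()` damps the iteration by averaging successive iterates
(relative tolerance $10^{-8}$, at most 500 iterations) and falls back to
bracketed root finding on $[1, 100M]$ if damping fails to settle.

### Erosion of genomic information across generations

A target individual $l_p$ ($l_m$) generations below its closest paternal
(maternal) reference ancestor keeps a segment's predictive accuracy only if
both inherited haplotypes in that segment are unrecombined since the
reference. With average segment size $\gamma k L / M_e$ Morgan,
$$p_{rt} = \left(1 - \frac{\gamma k L}{M_e}\right)^{l_p + l_m},
  \qquad r_{D_t} = p_{rt}\, r_{D_r}.$$
The inflation factor $\gamma$ (default 2, obtained by calibration;
`calibrate_gamma()` re-estimates it from observed target accuracies)
accounts for within-family co-segregation information, which spans larger
distances than LD and is lost faster. The target GEBV accuracy follows by
combining $r_{D_t}$ with the target pedigree accuracy $r_{A_t}$ on either
route (`predict_target_accuracy()`). $r_{A_t}$ itself is an *input*:
supplied by the user (e.g. from pseudoBLUP software) or measured in the
simulator — the package deliberately does not re-implement pseudoBLUP
recursions.

Two reading notes on the decline model, both decided here and consequential:

* Since each generation adds one meiosis on *each* side, the exponent
  $l_p + l_m$ grows by **2** per generation; the per-generation decline of
  $r_D$ is the squared factor $(1 - \gamma k L / M_e)^2$.
  `decline_regression()` equates $\exp(\text{slope})$ of the
  $\ln r_D$-on-gap regression to this squared factor. Reading the decline
  as the unsquared factor would imply $M_e \approx 116$ instead of
  $\approx 3700$ in the worked chicken example and is inconsistent with the
  reported estimates.
* When $\gamma k L \ge M_e$ the base turns non-positive; `p_rt()` returns 0
  with a warning (the average segment is certain to recombine) rather than
  a negative base raised to an integer power.

In the Fisher route the deviation component's $r \leftrightarrow \theta$
mapping uses its own capture fraction $q_D^2 = M/(M + M_e)$, while
information is added on the whole-genome ($q^2 = 1$) scale; with $M_e$
derived from the same reference accuracies both routes reproduce the
observed reference $r_G$ exactly, which is also an acceptance-level test.

### Accuracy under selection

Selection reduces the genetic variance (Bulmer effect) while leaving
prediction error variance unchanged under the infinitesimal model, so
unselected-population accuracies $r'$ translate to selected-population
correlations via `selection_adjusted_r2()`:
$r^2 = 1 - (1 - r'^2)\,\sigma'^2_G/\sigma^2_G$.

## Empirical accuracy estimation

`solve_blup()` solves the single-trait animal model (overall mean as the
only fixed effect, variance ratio $\lambda = (1-h^2)/h^2$) in the GLS form
$\hat{\mathbf g} = \mathbf K \mathbf Z' \mathbf V^{-1}(\mathbf y - \hat\mu\mathbf 1)$,
$\mathbf V = \mathbf Z\mathbf K\mathbf Z' + \lambda\mathbf I$ — identical to
the mixed-model equations (a test verifies the MME residual) but requiring
no inverse of $\mathbf K$, so singular genomic matrices and unphenotyped
candidates need no special casing. Solvers are dense and direct; the
population sizes in scope (up to ~20k) fit comfortably in memory, and
exactness keeps oracle tests sharp.

Leave-one-out cross-validation (`loo_ebv()`) estimates the overall mean
once by GLS on the full data, pre-adjusts the phenotypes, and then applies
the exact downdating identity
$\hat g_{\text{loo},i} = (\hat g_i - H_{ii} y^*_i)/(1 - H_{ii})$ with
$H = \mathbf K_{oo}\mathbf V^{-1}$, which equals refitting without record
$i$ (tested against naive refits on 20 random instances). The LOO accuracy
is $\mathrm{cor}(\hat g_{\text{loo}}, y^*)/h$; `add_own_phenotype()` then
restores the individual's own record through a two-source selection index,
$$r^2 = \frac{r_{\text{loo}}^2 + h^2 - 2h^2 r_{\text{loo}}^2}{1 - h^2 r_{\text{loo}}^2}.$$

`lr_accuracy()` implements the part-whole (LR) estimator
$\hat r_G = \hat r_A / \mathrm{cor}(\hat g_A, \hat g_G)$. A practical
caveat found while validating it: the part-whole identity treats the GEBV
as the "whole" information, which requires a marker panel dense enough
that $q_D^2 \approx 1$. In simulations with ~3000 markers the estimator is
unbiased within Monte-Carlo error; with ~1000 markers ($q_D^2 \approx
0.8$) it acquires an upward bias of several accuracy points because the
pedigree EBV is no longer information-nested in the genomic EBV.

Estimated accuracies above 1 (possible with sampling noise) are capped at 1
with a warning by default; a strict mode raises instead. Likewise, when
sampling noise produces $r_G < r_A$, `index_extract_rD2()` clamps $r_D$ to
0 with a warning by default.

## The simulator

The stochastic simulator is the package's validation oracle. It emulates:

* a **historical phase** (`simulate_historical()`): constant-size
  random-mating population, bi-allelic loci starting at frequency 0.5 in
  linkage equilibrium, crossover counts Poisson($L$) per chromosome without
  interference, recurrent mutation at $10^{-8}$ per locus and gamete —
  building drift–recombination LD;
* **locus assignment** (`assign_loci()`): loci with MAF > 0.1 split into
  markers and QTL (equal QTL numbers per chromosome), normal QTL effects,
  true breeding values centered and scaled to SD 1 in generation 0;
* a **breeding phase** (`simulate_breeding()`): generation 0 by broad
  random mating of the historical pool (so it inherits the historical
  population's relationship structure; the narrow design starts at
  generation 1), then hierarchical matings of `n_sires` males to `n_dams`
  females (dams nested within sires), litters half male/half female,
  phenotypes = TBV + normal noise with variance $(1-h^2)/h^2$, and either
  random selection or truncation selection on GBLUP EBV computed before the
  candidates are phenotyped.

Default study sizes are desk-scale: 9 chromosomes × 1.5 Morgan, 5000
starting loci, historical phase of 200 generations at $N_e = 250$, breeding
generations of 480 individuals (10 sires × 48 dams × 10 progeny), ~2000
markers and 270 QTL, and 10 replicates with accuracies averaged over
replicates *before* Me estimation and prediction. These reproduce the
method's qualitative and quantitative behaviour; they are not a full-size
reproduction of a commercial program (which would use thousands of
individuals per generation, ~19k markers, 50 replicates and a much longer
history). Features of real data the simulator does not emulate: crossover
interference, sequence-level mutation processes, non-normal QTL effect
distributions, shared environmental (litter) effects, and overlapping
generations. Passing validation therefore shows the *method's internal
consistency* under its own assumptions, not robustness to these
real-data complications.

With random selection the breeding path consumes no phenotype information,
so running matched seeds at two heritabilities yields identical genomes and
pedigrees with only phenotypic noise differing — this is how the stability
comparison of Me across $h^2$ is made exactly paired.

## Experiment drivers

`run_single_gen_experiment()` uses one generation at a time as reference
and a fixed later generation as target (gap 1–5);
`run_accumulating_experiment()` accumulates the reference from generation 0
onward, targeting the next generation each time, mimicking an ongoing
program. Both return per-configuration empirical accuracies, all Me
estimates, and Fisher/Index target predictions.
`decline_regression()` runs the real-data workflow: extract $r_D$ per
validation generation, regress $\ln r_D$ on the gap, and convert slope and
intercept into two independent Me estimates.

At desk scale the Fisher- and Index-route target predictions agree to about
0.005–0.01 in accuracy units; the residual gap scales with
$\gamma k L / M_e$ (here $\approx 0.03$, versus $\approx 0.01$ at
commercial scale where the routes become visually indistinguishable).

## Known limitations

* $r_{A_t}$ for the target population must be supplied or simulated; no
  pseudoBLUP recursion is included.
* Single trait, overall mean as the only fixed effect (a design hook
  exists but is untested against external references).
* No variable-selection (Bayesian alphabet) genomic prediction models; the
  accuracy model assumes GBLUP-like shrinkage of many small effects.
* The erosion model sets a recombined segment's accuracy to zero — a
  conservative assumption awaiting further validation.
* Heterogeneous multi-generation references use the closest-ancestor
  distance $(l_p, l_m)$; a weighted-average distance may be preferable but
  is not implemented.
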