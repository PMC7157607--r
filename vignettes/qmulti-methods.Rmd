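---
title: "Models and methods behind qmulti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qmulti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmulti)
library(dplyr)
```

qmulti analyses Q-sort preference data collected over factorial stimulus
designs. A participant receives the full factorial set of stimuli — by
default 32 interactive objects crossing Size (Small/Large), Surface texture
(Smooth/Rough), Contour (Round/Angular) and autonomous Behaviour
(Light/Sound/Vibrate/Quiescent) — and rank-orders all of them into a single
bell-shaped grid of columns running from least preferred (−5) to most
preferred (+5), with a fixed quota of cells per column. Because every sort
fills the same forced distribution, participants are directly comparable:
the data are a participants × stimuli matrix of integer column values.

This vignette describes the statistical machinery, the choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The forced-distribution grid

A `grid_spec` is an increasing vector of column values plus per-column
quotas. The default, `study_grid()`, uses values −5…+5 with quotas
1,2,3,4,4,4,4,4,3,2,1 (32 cells). The exact quota profile of a given study
is the researcher's design choice; only the −5…+5 range and the 32-cell
total are treated as fixed here, and any symmetric or asymmetric profile
can be supplied. Every analysis takes the grid as an explicit input, and
`validate_qsorts()` reports quota, coverage and range violations rather
than throwing, so malformed files can be triaged in one pass.

## Preference: the ordered-probit model

Which level of a variable is liked better is modelled with a cumulative
probit regression on the pooled (participant, stimulus) observations. The
latent model is

$$y^* = x'\beta + \varepsilon,\qquad \varepsilon \sim N(0,1),$$

with the observed grid column $k$ whenever
$\tau_{k-1} < y^* \le \tau_k$, i.e. $P(\text{col} \le k) = \Phi(\tau_k - x'\beta)$.
Predictors are dummy indicators for every non-reference level; reference
levels default to the first level of each variable (Small, Smooth, Round,
Light) and are configurable — the coding is arbitrary but must be fixed for
signs to be interpretable. A positive coefficient means the level is
preferred over its variable's reference level on the latent scale.

Estimation maximises the likelihood by BFGS with an analytic score. The
cutpoints are reparameterised as the first cutpoint plus log increments, so
the ordering constraint $\tau_1 < \cdots < \tau_{K-1}$ holds at every
iterate. Starting values are the closed-form null-model cutpoints
$\tau_k = \Phi^{-1}(\hat F_k)$ (the probit-transformed empirical cumulative
category frequencies) with zero slopes; for an intercept-only model this
start is already the MLE, which the tests exploit as an exact oracle. The
reported covariance is the inverse observed information at the optimum,
obtained by differentiating the analytic score, over slopes and cutpoints
jointly.

Hypotheses about a variable are Wald block tests: for the coefficient block
$b$ with covariance block $V$, $X^2 = b'V^{-1}b$ on df = block size. A
variable with $m$ levels contributes $m-1$ dummies, so its main-effect test
has df $m-1$ (3 for Behaviour, 1 for the others). The p-value is always
computed from the chi-square distribution; it is never transcribed from
anywhere else.

Two modelling caveats are deliberate. First, observations are pooled across
participants with no random effects: the protocol names the plain
ordered-probit model, and the forced distribution induces within-participant
dependence that the pooled standard errors ignore. The Wald statistics are
therefore descriptive orderings of evidence rather than calibrated
population tests; the simulation suite checks sign and rank recovery, not
nominal coverage. Second, the cluster × preference analysis fits one pooled
model per run containing variable main effects, a cluster (factor) main
effect, and all cluster × level products, with each variable's interaction
tested as a Wald block of df
$(\text{clusters}-1)(\text{levels}-1)$ — giving the 2, 2, 2, 6 df column
for three clusters. Only participants flagged on some factor enter this
model, since cluster labels are undefined for the rest.

## Dominance: grid-spread weights

Preference and dominance are distinct: two participants may disagree on
*which* texture they like while agreeing that texture is what *drives*
their sorting. Dominance is measured from the sort geometry directly. For
participant $p$ and variable $v$ with levels $\ell$,

$$\mathrm{raw}_p(v) \;=\; \frac{1}{n_{\text{stim}}}\sum_{\ell}
  n_\ell\,\bigl(\bar r_{p\ell} - \bar r_{\text{grid}}\bigr)^2,$$

where $\bar r_{p\ell}$ is the mean grid column of the stimuli carrying
level $\ell$ and $\bar r_{\text{grid}}$ is the quota-weighted grid mean
(0 for the default grid). This is the count-weighted between-level variance
of level positions: it is zero when a variable's levels are interchangeable
across the grid and grows as levels separate toward the extremes. Weights
normalise the raw spreads to sum to one within each participant
(`weight = raw / sum(raw)`; uniform if all spreads are zero), which is what
makes per-cluster weight tables sum to ≈1 column-wise. The raw spreads are
exposed alongside the weights because the normalisation, while convenient,
discards overall sort "decisiveness".

The underlying protocol literature does not print the spread formula;
between-level variance was chosen because it is the standard spread measure
over level positions, it rewards extreme placements quadratically, and it
reproduces the sum-to-one weight structure. The choice is isolated in
`dominance_weights()` should an alternative (range, absolute deviation) be
wanted.

Variable importance is tested with ANOVA on the weights: one-way
(groups = variables; df $3, 68$ for 18 participants × 4 variables) for the
overall question, and two-way (cluster, variable, interaction) on flagged
participants for the cluster × dominance question (interaction df
$(c-1)(v-1) = 6$, error df 56 for flagged counts 8/6/3). Weights are
compositional (they sum to one within a participant), which inflates
negative dependence between variables; as with the probit pooling, the
F statistics are treated as descriptive orderings, validated by recovery
simulations. The ANOVA itself is delegated to `stats::aov`, with a
hand-computed sums-of-squares oracle in the test suite.

## Individual differences: by-person factor analysis

Q-factor analysis transposes the usual factor-analysis question:
participants, not items, are correlated. `sort_correlations()` builds the
participants × participants Pearson matrix of rank vectors;
`extract_and_rotate()` performs principal-component extraction
(eigendecomposition; loading = eigenvector × √eigenvalue) of the leading
components followed by varimax rotation with Kaiser normalization
(`stats::varimax`). PCA was preferred over Stephenson's centroid method
because the protocol literature does not fix the method and PCA makes the
eigenvalue identities exact: the full spectrum sums to the number of
participants, and explained variance is exactly
$100\,\lambda_j / n_{\text{participants}}$.

Two eigenvalue notions coexist and are kept separate on purpose:

* **extraction eigenvalues** — the unrotated eigenvalues of the correlation
  matrix, used for retention decisions (Kaiser–Guttman bound);
* **rotated eigenvalues** — column sums of squared rotated loadings,
  reported per factor and feeding the explained-variance identity.

Retention must use the former: varimax conserves only the total variance of
the retained block, and happily redistributes one strong factor's variance
so that every rotated factor exceeds 1.0 even when the data are plainly
one-dimensional. With the unrotated bound, homogeneous single-viewpoint
data correctly resolve to one factor.

A participant is **flagged** as an exemplar of factor $f$ when (i) the
loading exceeds $1.96/\sqrt{n_{\text{stim}}}$ (= 0.3465 for 32 stimuli; the
p < .05 significance rule on a loading standard error of
$1/\sqrt{n_{\text{stim}}}$) and (ii) the squared loading strictly exceeds
half the participant's communality, so the factor explains a majority of
the participant's common variance. Rule (ii) makes double-flagging
impossible. Both constants are configurable; different studies are known to
apply different flagging conventions.

Each factor's **idealized array** is built from its exemplars: sorts are
weighted by $w = l/(1-l^2)$ (loadings closer to 1 count disproportionately
more), the weighted mean rank of every stimulus is standardized to a
z-score across stimuli, and the z-scores are force-sorted back into the
study grid — so a factor array is itself a valid sort, directly comparable
to any participant's grid. A factor with a single exemplar reproduces that
exemplar's sort exactly.

`choose_q_solution()` automates the solution comparison: for each candidate
count it reports extraction eigenvalues, total explained variance and
flagged counts, and selects the largest candidate whose factors all pass
the Kaiser–Guttman bound with at least two exemplars each. Automated
selection cannot judge the *meaningfulness* of factor scores, which is
intrinsically a human call, so a `force` override is provided and the full
candidate report is always returned.

Ties in loadings or utilities are broken deterministically (lexicographic
stimulus id; first factor in column order), never randomly: every result in
the pipeline is reproducible from the dataset alone.

## The synthetic-data generator

No raw sorts are distributed with the original study, so the generator is
the package's test bed: it plants known structure and the test suite asks
every stage to recover it. The generative model is a latent-utility linear
model chosen to match the ordered-probit analysis assumptions: participant
$p$ in cluster $c$ assigns stimulus $s$ the utility

$$u_{ps} = \sum_{v} \theta_{c,v,\ell_v(s)} + \epsilon_{ps},
  \qquad \epsilon_{ps} \sim N(0, \sigma^2_{\text{noise}}),$$

and sorts by deterministic forced binning of the utilities (ties
lexicographic). Only within-variable utility contrasts matter; shifting a
variable's utilities by a constant leaves every sort unchanged. Note one
consequence of forced sorting: the grid standardises each participant's
utilities, so a cluster's effective contrast on the rank scale is its
utility contrast *divided by the cluster's total utility spread*. Clusters
with many strong preferences express each one more weakly in ranks.

`study_sim_config()` fixes the default scenario to the study's shape:
18 participants — clusters of 8, 6 and 3 plus one idiosyncratic noise-only
sorter (its analogue was flagged on no factor in the original study) — with
`noise_sd = 0.3` latent units against level contrasts of roughly 0.2–2.7.
The cluster profiles encode three distinct viewpoints: C1 likes smooth,
lighting-up objects and strongly dislikes sound; C2 likes rough, round,
vibrating objects and dislikes sound; C3 attends almost only to behaviour
(vibrate ≫ sound > light > quiescent). Summed over the sample the planted
contrasts give an overall preference for rough texture, round contour and
vibration, no size preference, and behaviour as the dominant variable in
every cluster and overall. The magnitudes were chosen once so that each
cluster's dominance ordering is faithful (behaviour first; texture a clear
second in C1 and C2) while the overall rough-over-smooth contrast survives
the per-cluster standardisation described above.

What the generator does **not** emulate: sequential sorting dynamics
(participants refine placements as they go), any within-sort dependence
beyond the forced quotas, heavy-tailed or participant-specific noise, and
partial or free distributions. Passing recovery tests therefore show the
pipeline is a consistent estimator of its own generative model under the
study's geometry — not that the model captures everything in real sorting
behaviour.

## Numerical choices and degenerate inputs

* Probit optimisation: BFGS, `reltol = 1e-12`, max 500 iterations;
  non-convergence is an error carrying the optimizer diagnostics, and
  coefficient magnitudes above 10 trigger a separation warning.
* The observed information occasionally loses symmetry to rounding; it is
  symmetrised before inversion, and a singular information matrix degrades
  to an `NA` covariance with a warning rather than an error.
* Empty outcome categories (a grid column no observation uses) are refused
  with a pointer to re-specify the grid, since their cutpoints are
  unidentified.
* All dominance raw spreads zero → uniform weights; zero within- and
  between-group variance in the dominance ANOVA → F reported as 0 with a
  degenerate-data warning.
* Correlation matrices are symmetrised and checked for positive
  semi-definiteness before eigendecomposition; factor sign is fixed by
  making each column's largest-magnitude loading positive.
* With $n$ participants at most $n-1$ factors are extractable; with two
  participants the pipeline runs a one-factor analysis and records the
  cluster-level stages as skipped, with reasons, in the report.

## Problem sizes used by the automated checks

The packaged checks simulate at the study's own scale — 18 participants,
32 stimuli, 576 pooled observations — and the recovery study uses 100
replicates of that scenario; the goodness-of-fit property for the
generator's null distribution uses 2000 simulated participants. A single
pipeline run takes on the order of a second on one core.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_qsorts(study_sim_config(), seed = 1)
report <- run_qmulti(ds)
report
write_qmulti_report(report, "report")
```

## Known limitations

* Pooled probit and compositional ANOVA inference, as discussed above.
* Negative loadings are never flagged: a participant whose sort mirrors a
  factor is left unflagged rather than treated as a bipolar exemplar, and
  two perfectly opposed viewpoints resolve to one bipolar factor.
* The automatic solution rule can neither detect meaningless-but-admissible
  factors nor rescue a meaningful solution with a single exemplar; the
  candidate report and the `force` argument exist for exactly those calls.
* No oblique or judgmental rotation, no bootstrapped loading intervals, no
  Bayesian variant of the preference model.
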