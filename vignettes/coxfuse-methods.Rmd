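---
title: "Graph-guided fusion of miRNA and mRNA expression for Cox risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-guided fusion of miRNA and mRNA expression for Cox risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Matched mRNA and miRNA expression profiles from the same tumor cohort carry
complementary prognostic information. miRNAs repress their target
transcripts — by translational blocking or degradation — so a miRNA that
drives outcome often announces itself twice: directly in its own expression,
and indirectly through negatively correlated target transcripts. A risk
model that treats the two layers as one long, anonymous feature vector
ignores this structure; with tens of thousands of features, a handful of
events and heavy censoring, the feature selection is then both unstable and
suboptimal.

`coxfuse` fuses the two layers through a bipartite *weight graph* connecting
transcripts to miRNAs, and lets that graph steer the penalty schedule of
componentwise likelihood-based Cox boosting. The package covers the whole
pipeline: graph assembly from correlation tests and target predictions,
penalized boosting with graph-adaptive penalties, inverse-probability-of-
censoring-weighted (IPCW) prediction error curves, `.632` bootstrap
estimation of prediction error, and a synthetic-data generator with known
ground truth.

## The fusion graph

For each transcript $m_i$ and each miRNA $mi_j$ the Pearson correlation
$\rho(m_i, mi_j)$ across the shared samples is tested against zero with the
exact $t$-transform $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom,
giving a p-value $p^{cor}_{ij}$ per pair. The test is two-sided: repression
shows up as negative correlation, but indirect regulation can produce
positive associations, and the direction is not assumed. Because $p_1
\times p_2$ tests are performed, the whole matrix is corrected as one
flattened family with Benjamini–Hochberg.

The second evidence source is a sequence-based target prediction database.
Its per-pair p-values $p^{pred}_{ij}$ enter as follows:

* a listed pair keeps its p-value;
* an unlisted pair whose transcript *and* miRNA both appear somewhere in the
  source gets $p^{pred}_{ij} = 1$ — the source looked and found nothing
  (databases of this kind typically retain only pairs below a threshold,
  e.g. 0.05);
* a pair with either feature absent from the source is *uncovered*: the
  source is silent, not negative, so the pair bypasses combination entirely
  and keeps its (adjusted) correlation p-value.

Covered pairs are combined by the equal-weight Stouffer rule
$$p^{comb} = 1 - \Phi\!\left(\tfrac{1}{\sqrt2}\left[\Phi^{-1}(1-p^{cor}) +
\Phi^{-1}(1-p^{pred})\right]\right),$$
and the weight matrix is $w_{ij} = 1 - p^{comb}_{ij}$, read as the adjacency
matrix of a directed bipartite graph with edges from mRNAs to miRNAs.
Before the normal-quantile transform all p-values are clamped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-15}$ (configurable),
so the $p^{pred} = 1$ convention yields a finite, near-one combined p-value
(weight near zero) rather than an infinite z-score.

The coverage semantics above reconcile two superficially conflicting
conventions — "unlisted pairs get p = 1" versus "unlisted features fall back
to correlation p-values" — by distinguishing a *pair* the source rejected
from a *feature* the source never assessed. Both the clamping constant and
the correction method are exposed in `fusion_graph()`.

## Componentwise boosting with graph-adaptive penalties

The Cox model $h(t \mid x) = h_0(t)\exp(x^\top\beta)$ is fitted by
componentwise likelihood-based boosting. Starting at $\beta = 0$, step $k$
computes for every covariate $j$ the score $U_j$ and observed Fisher
information $F_j$ of the partial log-likelihood with respect to a single new
coefficient at the current linear predictor (Breslow handling of ties), and
the penalized one-parameter update $\hat\gamma_j = U_j/(F_j + \lambda_j)$.
The covariate maximizing the penalized score statistic $U_j^2/(F_j +
\lambda_j)$ is updated; everything else stays untouched. The number of
nonzero coefficients after $M$ steps is at most $M$ — implicit feature
selection. The selection criterion is the standard one-step-equivalent
surrogate for the penalized log-likelihood gain; the exact gain is available
as `criterion = "plgain"` (it evaluates the partial likelihood once per
covariate and step, so it is intended for small problems), and ties break
towards the lowest feature index.

Features are standardized internally to mean 0, variance 1, with the
training statistics stored for prediction. This is what makes a *common*
initial penalty $\lambda$ meaningful across covariates and across layers
measured on different scales. The default $\lambda = 9 \cdot \#\text{events}$
corresponds to a conservative initial stepsize factor $\nu = F/(F+\lambda)$
of roughly 0.1 for a standardized covariate; on real data $\lambda$ should
be chosen so that cross-validation selects comfortably more than ~50 steps,
which keeps individual updates small and the comparison across model
variants fair.

In graph mode two penalty updates fire after each selection, both stated as
exact algebraic contracts and unit-tested as identities:

* **Escalation** of the selected feature:
  $\lambda_{j^*} \leftarrow (1/c_f - 1)F_{j^*} + \lambda_{j^*}/c_f$, which
  multiplies the stepsize factor $\nu = F/(F+\lambda)$ by exactly $c_f$.
  A feature that keeps getting selected takes geometrically shrinking steps,
  leaving room for connected partners.
* **Relaxation** of connected miRNAs when the selected feature is an mRNA:
  with shrinkage fraction $s = \lambda/(F+\lambda)$ and edge-modulated
  factor $c_w = 1 - w(1 - c_f)$, set
  $\lambda_{j^+} \leftarrow F_{j^+}\, s c_w / (1 - s c_w)$, which multiplies
  $s$ by exactly $c_w$. A full-weight edge applies the full factor $c_f$; a
  zero-weight edge does nothing. The linear interpolation in $w$ is the
  package's choice for "proportional to the connection weight"; $c_f^w$ is
  available via `weight_mode = "power"`.

The graph is directed: selecting a miRNA relaxes nothing, matching its
interpretation as regulator evidence flowing from transcripts to their
regulators. Escalation is active only in graph mode (plain boosting keeps
the textbook constant penalty), and `escalate = FALSE` disables it
separately. With $c_f = 1$ both updates are mathematical identities, and the
implementation short-circuits them so a neutral graph reproduces the plain
fit *bit for bit* — a property the test suite checks end-to-end through the
bootstrap. The relaxation uses the connected miRNA's Fisher information at
the current step's offset, the freshest curvature available. The default
$c_f = 0.9$ is a mild nudge per selection; values far below 1 let a single
strong transcript flood its miRNA neighbourhood.

The baseline hazard is the Breslow estimator
$\hat H_0(t) = \sum_{t_e \le t} d_e / \sum_{i \in R(t_e)} e^{\hat\eta_i}$,
consistent with the Breslow tie handling in the fitting criterion, and risk
predictions are $\hat r(t \mid x) = \exp(-\hat H_0(t) e^{x^\top\hat\beta})$.
The number of steps $M$ can be tuned by `cv_coxfuse()`, which maximizes the
summed held-out partial log-likelihood over event-stratified folds along the
boosting path.

## Measuring prediction error

The time-resolved prediction error is the IPCW Brier score
$$\mathrm{PEC}(t) = \frac1n \sum_i \left[
\frac{\hat r(t\mid x_i)^2\, 1\{t_i \le t, \delta_i = 1\}}{\hat G(t_i^-)} +
\frac{(1-\hat r(t\mid x_i))^2\, 1\{t_i > t\}}{\hat G(t)} \right],$$
with $\hat G$ the reverse Kaplan–Meier estimate of the censoring survival
function (censorings as events; at tied times, events precede censorings in
the risk-set bookkeeping). Subjects censored before $t$ contribute nothing.
The event-term weight uses the left limit $\hat G(t_i^-)$: evaluating at
$t_i$ itself would zero the weight of an event at the largest observation
time; `left_limit = FALSE` restores the literal form. The integrated error
(IPEC) is the exact integral of the right-continuous step function over
$[0, \tau]$ — no trapezoid smoothing, since the estimator is genuinely
piecewise constant. The default grid is 0 plus the distinct event times up
to $\tau$, with $\tau$ the largest event time at which $\hat G > 0$. IPEC
values are comparable only within one grid/$\tau$ configuration, so $\tau$
is recorded on every curve and output.

`bootstrap_632()` estimates out-of-sample error without a test split: the
apparent curve (full model on full data, computed once) is combined
pointwise with each replicate's out-of-bag curve as $0.368\,\mathrm{app} +
0.632\,\mathrm{oob}_b$, and integrated to one IPEC per replicate. Censoring
weights for an out-of-bag evaluation come from the out-of-bag samples
themselves. Replicates with no out-of-bag (or in-bag) event are redrawn and
logged; the whole procedure, including redraw history, is reproducible from
the seed. The number of boosting steps is held fixed across replicates and
model variants for comparability; per-replicate re-tuning can be done by
supplying a trainer closure that calls `cv_coxfuse()`. Model variants are
compared on the *same* bootstrap samples (same seed) with a paired one-sided
Wilcoxon signed-rank test on the IPECs — zeros dropped, exact null below 26
informative pairs, normal approximation with continuity correction above —
and feature-selection stability is summarized by the number of replicates in
which each feature enters the model. The `.632+` estimator is a known,
costlier refinement and is left as an extension point. For protection
against information leak through the graph itself, `coxfuse_trainer(
rebuild_graph = TRUE)` reassembles the graph inside every replicate from
in-bag samples only.

## What the synthetic data emulate — and what they do not

`simulate_fusion_data()` generates the package's reference study condition,
shaped like a matched two-layer tumor cohort at desk scale: $n = 100$
samples, $p_1 = 300$ transcripts, $p_2 = 30$ miRNAs, and ~80% censoring
(heavy censoring is the regime this methodology is designed for). Each
miRNA is standard normal and regulates 5 disjoint transcripts as
$m = -a \cdot mi + \sigma \epsilon$; with the default $a = \sigma = 1$ a
true pair has correlation $-1/\sqrt2 \approx -0.71$, a strong but not
degenerate signal. Three miRNAs are prognostic with coefficient 1 on the
standardized scale, and each contributes its first target transcript with
coefficient $-0.5$ — so the outcome signal lives primarily in regulators
whose targets echo it, exactly the configuration graph guidance is meant to
exploit. Event times are inverse-transform draws from an exponential
baseline (rate 0.1; the simplest proportional-hazards generator), and the
uniform censoring bound is solved numerically so the expected censored
fraction matches the target given the realized linear predictors —
censoring independent of covariates, matching the IPCW assumption. The
prediction table lists 80% of true edges and 1% of non-edges, each with a
p-value uniform on (0, 0.05), and drops 10% of miRNAs from the source
entirely to exercise the coverage-fallback path. The generator regulates
negatively only (the biology of degradation) while the analysis stays
sign-agnostic — a deliberate asymmetry that tests the two-sided pipeline
under the realistic signed truth.

Passing tests on these data demonstrate the machinery — recovery of planted
edges, benefit of graph guidance, correctness of the error estimators —
not performance on real cohorts: the generator has no array artifacts, no
correlated noise between unrelated features, no shared-pathway correlation
structure among transcripts, one regulator per transcript, and far fewer
features than a real experiment. Absolute IPEC values depend on the time
unit and $\tau$ and do not transfer across datasets.

## Numerical choices and degenerate inputs

* p-value clamping at $\varepsilon = 10^{-15}$ bounds all z-scores;
  weights therefore live in $[\varepsilon, 1-\varepsilon]$ around their
  ideal values.
* Perfect correlations ($|r| = 1$) map to p = 0 before clamping.
* Duplicate prediction records keep the minimum p-value (strongest evidence,
  deterministic).
* Zero-variance features are an error (named), not silently dropped: they
  cannot be standardized and carry no information.
* A boosting step in which every score is exactly zero records a stop and
  ends the fit early with a message.
* All-censored outcomes are rejected at validation.
* $\hat G = 0$ inside the requested horizon raises an error advising a
  smaller $\tau$ whenever a nonzero weight would actually be needed; terms
  whose indicator is already zero are simply zero.
* Fold assignment, bootstrap draws and all generators consume a single
  seeded RNG stream; equal seeds give byte-identical outputs.

## Problem sizes used by the test suite

The packaged checks run the reference condition ($n = 100$, $p_1 = 300$,
$p_2 = 30$) with $B = 20$ bootstrap replicates for the neutrality check and
$B = 50$ for the graph-benefit comparison, plus many small fixtures
($n \le 60$) for the oracle equivalences; the whole suite completes in a few
minutes on one core. These sizes are the package's reference configuration
for reproducible self-checks; all generators and evaluators scale to larger
problems linearly in $n \cdot p$ per boosting step.

## Known limitations

* Transcript-level identifiers only: no gene-to-transcript mapping is
  attempted, so the prediction source must share the expression matrix's
  namespace.
* The Lasso and random survival forest comparators, `.632+`, concordance
  and time-dependent AUC metrics are out of scope.
* The exact-gain selection criterion is quadratic in cost and meant for
  small $p$.
* The graph influences only future penalties; it does not constrain which
  features *can* be selected, and a sufficiently strong uncorrelated
  feature will still enter the model.
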