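---
title: "Stopping criteria for screening in DTA meta-analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stopping criteria for screening in DTA meta-analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtastop)
```

This vignette documents the models behind `dtastop`, the parameters that
matter, the design choices made where several readings were defensible, and
the limits of what the synthetic experiments can show about real screening
data.

## The setting

A systematic review of diagnostic test accuracy screens a pool of $N$
candidate references, of which an unknown subset is relevant. The relevant
studies report 2x2 tables (TP, FP, FN, TN) that feed one or more
meta-analyses of summary sensitivity and specificity. Screening
prioritization reorders the pool so relevant references surface early; the
open question is when screening can stop without materially changing the
meta-analysis. `dtastop` simulates the whole process — ranking, incremental
re-estimation, stopping — so rules and cutoffs can be studied before they
are trusted in a live review.

## The bivariate random-effects model

Each study $i$ contributes observed logits
$y_i = (\mathrm{logit}\,\widehat{se}_i,\ \mathrm{logit}\,\widehat{sp}_i)$
with delta-method within-study variances
$1/tp_i + 1/fn_i$ and $1/tn_i + 1/fp_i$ (diagonal $V_i$). The model is

$$y_i \sim N_2(\mu,\ \Psi + V_i),$$

with $\mu$ the logit-scale summary and $\Psi$ the between-study covariance.
`fit_bivariate()` maximizes the marginal likelihood directly: $\mu$ is
profiled out by generalized least squares and $\Psi$ is optimized (BFGS,
relative tolerance $10^{-8}$, at most 500 iterations) in a log-Cholesky
parameterization, so every proposal is positive semidefinite by
construction rather than by post-hoc clipping. Summary sensitivity and
specificity are the inverse logits of $\hat\mu$; 95% intervals are Wald
intervals on the logit scale, back-transformed. This is plain ML, not REML,
and no small-sample (Knapp–Hartung-type) adjustment is applied. The test
suite cross-checks the fit against `metafor::rma.mv` (bivariate
unstructured random effects, ML) on synthetic groups.

**Continuity correction.** By default 0.5 is added to all four cells of any
study containing a zero cell, and only to such studies (`correction_policy
= "only0"`); both the value and the policy (`"all"`, `"none"`) are
arguments. **Minimum size.** Summary estimates from fewer than three
studies are refused everywhere (`is_analyzable()`); leave-one-out
diagnostics additionally need four, so every reduced fit is itself
analyzable.

**A bias worth knowing about.** With small studies (e.g. 50 subjects per
arm) the delta-method variances are larger exactly for the studies that
observe high accuracy, so the weighted logit means are attenuated — on the
order of 0.1–0.17 logits at sensitivity 0.85 / specificity 0.92 with
between-study SD 0.4. This is a property of the two-stage normal
approximation itself (reference implementations show the same shift), not
of the optimizer. Parameter-recovery and CI-coverage tests therefore use
500-subject arms, where the approximation is accurate; simulations of
screening behavior keep the realistic 50-subject default, because the
stopping criteria compare estimates *to each other* and to the final
estimate, which inherits the same bias and cancels in the comparison.

## Loss, displacement, and the truth convention

The "truth" $(\mu, \nu)$ for a meta-analysis is its final estimate over all
relevant pool studies; the loss of any interim estimate is the Euclidean
distance between the (sens, spec) pairs. This convention makes the final
loss exactly zero and presumes the complete set is large enough to have
converged — for small meta-analyses the "truth" is itself noisy, which is
precisely why the displacement diagnostics exist. The displacement at an
update is the distance between consecutive estimates; its 2-window moving
average (MA2) smooths single-study jolts. MA2 uses full windows only: it is
undefined at the first displacement, so the MA2 rule cannot fire before
five relevant studies are found. The LOOCV displacement of a found set $S$
is the median over $s \in S$ of the distance between the full-set fit and
the fit without $s$ (median of an even count = midpoint of the central
order statistics).

## The stopping criteria

Retrospective rules need the finished trace or loss curve and serve
evaluation; prospective rules can run live. All threshold comparisons are
strict, matching the inequality direction of each rule's definition.

- **Recall** ($R$): effort at which the $\lceil R f_{total}\rceil$-th
  relevant reference is screened.
- **Knee/elbow**: the point of the effort/loss curve farthest from the
  chord between its endpoints, after min–max normalization of both axes
  (otherwise the answer depends on units). Ties go to the earliest point.
  The knee operates on the *raw* curve; the hull is specific to the
  loss/effort rule.
- **Loss/effort** ($\Lambda/E$): first segment of the curve's lower convex
  envelope whose slope exceeds $-\Lambda/E$; triggers at the segment's left
  endpoint. The raw curve is not monotone (a single study often shifts the
  estimate away from truth), so the rule is evaluated on the lower convex
  hull restricted to its non-increasing part; flat segments are kept, and a
  flat tail triggers at its start.
- **Relevant found** ($n$): effort at which the $n$-th relevant is found.
- **Found/effort** ($F/E$): stop once finding $F$ more relevant would cost
  at least $E$ effort — equivalently, once no relevant has appeared among
  the last $E/F$ screened, paying a constant $E/F$ penalty after the last
  find. Evaluated at every screened reference (the gap formulation requires
  it), and suppressed until `min_found` relevant are identified (default 3)
  so the rule cannot fire in pools with almost nothing to find.
- **Displacement MA2 / LOOCV** (threshold): fire when the respective
  diagnostic falls below the threshold. Both are conservative by
  construction: with fewer than five (MA2) or four (LOOCV) relevant studies
  they simply never trigger.

`combine_or()` implements joint monitoring: stop at the earliest member
trigger, reporting the losses recorded at that effort.

## The active-learning ranker

The simulated screener follows a relevance-feedback loop: the review
protocol text is a single artificial positive example until the first real
relevant reference is screened; each iteration draws fresh pseudo-negatives
uniformly from the *unscreened* pool (never from screened references),
topping the negative class up to at least 100; a classifier is refit and
the top $B_k$ unscreened references are screened, with $B_1 = 1$ and
$B_{k+1} = B_k + \lceil B_k/10 \rceil$. Features are case-folded unigrams
and adjacent bigrams of title + abstract, tf-idf weighted and
document-normalized; bigrams must occur in at least two documents to enter
the vocabulary (rare bigrams are almost pure noise and triple the feature
space). The classifier is ridge-penalized logistic regression
($\lambda = 10^{-4}$) fit by `glmnet` along a short warm-start path — a
deterministic minimizer of the same penalized log-loss a stochastic
gradient scheme would target, chosen for exact reproducibility and speed.
Ties in score break by original pool position. If a fit is impossible
(degenerate training set), scoring falls back to cosine similarity against
the protocol vector rather than crashing. Traces always cover the full
pool: stopping rules are applied on top of the trace, never inside the
ranker, so one trace serves every criterion and cutoff.

Label hygiene is tested, not assumed: an audit test flips the labels of
references outside the early screened set and checks the early ordering is
unchanged, and on signal-free pools the relative order of relevant
references is checked to be near-uniform (an unbiased ranker is the
assumption under which retrospective loss guarantees transfer to other
rankers).

## The synthetic-data generator

`synthetic_spec()` describes the study conditions; `gen_pool()` realizes
them. Per-study true logits are bivariate normal with means
$(\mathrm{logit}\,0.85, \mathrm{logit}\,0.92)$, between-study SDs 0.4 and
correlation $-0.3$ (accuracy typically trades sensitivity against
specificity); observed cells are binomial with 50 subjects per arm, so
$tp + fn$ and $fp + tn$ are exact by construction. Text is a two-component
mixture over pseudo-word vocabularies: relevant documents draw each token
from a 50-word signal vocabulary with probability `signal_weight` (default
0.6; 0.8 in the end-to-end experiments, a clearly separable review), else
from a 1000-word background; irrelevant documents use background only; the
protocol is composed from the signal vocabulary. The default pool holds
2000 candidates with 60 relevant and meta-analyses of 20/12/6 studies.

What this emulates: learnable relevance signal, realistic binomial noise
and heterogeneity, meta-analyses of realistic size. What it does not:
natural-language structure (the bigram distribution is adjacency noise, not
phrases), near-duplicate references, topic drift, publication bias, or
reviewers disagreeing with themselves. Passing tests therefore demonstrate
the *mechanics* — criteria fire where their definitions say, estimates
converge, prioritization helps on separable pools — not performance claims
for any particular real corpus; on real data the ranker's strength, and
with it every effort-dependent criterion, must be recalibrated.

## Simulation sizes and numerics

`run_simulation()` defaults to 20 prioritized and 50 randomized replicates
per review — enough for stable means of trigger efforts and losses on the
default corpus while keeping a full run in the low minutes on one core;
both counts are arguments. Per-replicate seeds derive deterministically
from `base_seed`, and identical seeds reproduce reports byte for byte.
Updates whose fit does not converge are skipped and tallied
(`n_skipped`), so a transient non-convergence costs one curve point, not
the replicate. The LOOCV series costs one extra fit per found study per
update (quadratic in group size) and is computed only when a LOOCV
criterion is present, or on request. Percentile bands across replicates use
step interpolation (last estimate carried forward) on the union grid of
update efforts, and quantiles of order statistics, so bands cannot cross.

## Known limitations

- The truth-as-final-estimate convention understates loss when the complete
  study set is itself too small to have converged.
- ML (not REML) variance components are slightly biased low in small
  groups; the Wald intervals ignore uncertainty in $\Psi$.
- The ranker is one reasonable member of the relevance-feedback family;
  absolute effort numbers depend on it, and only the relative behavior of
  criteria on top of it is the object of study here.
- Boundary fits ($\hat\Psi$ near singular) are reported as converged when
  the optimizer terminates cleanly; the log-Cholesky parameterization makes
  the boundary an interior limit, which is benign for the summary means but
  makes the fitted correlation unstable in tiny groups.
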