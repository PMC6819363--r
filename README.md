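# dtastop

Stopping criteria and screening simulation for meta-analyses of diagnostic
test accuracy (DTA).

## The problem

Systematic reviews of diagnostic tests screen thousands of candidate
references to find the handful of studies that feed the meta-analysis of
summary sensitivity and specificity. Screening prioritization (active
learning with relevance feedback) surfaces most relevant studies early — but
reviewers still screen everything, because nobody knows when it is safe to
stop. `dtastop` is a simulator and decision-support toolkit for exactly that
question: if screening is interrupted early, how much does the summary
estimate move, and which stopping rules bound that loss?

The package provides:

- **Screening simulation** — an active-learning ranker (seed document =
  review protocol, pseudo-negative sampling, growing screening batches,
  ridge-penalized logistic regression on tf-idf uni/bigram features) plus a
  randomized-order control (`rank_active()`, `rank_random()`).
- **Continuous meta-analysis** — a bivariate random-effects model of
  per-study (logit sensitivity, logit specificity), `y_i ~ N2(mu, Psi + V_i)`,
  refit every time a relevant study is identified (`fit_bivariate()`,
  `effort_loss_trace()`). The final estimate over all relevant studies is
  the "truth" `(mu, nu)`; the loss of an interim estimate `(mu_hat, nu_hat)`
  is the Euclidean distance
  `L2 = sqrt((mu - mu_hat)^2 + (nu - nu_hat)^2)`.
- **Seven stopping criteria** — retrospective: target recall, knee/elbow of
  the effort/loss curve, loss/effort slope on its monotone convex hull;
  prospective: relevant-found count, found/effort gap rule, displacement
  MA2 (moving average of consecutive-estimate shifts), displacement LOOCV
  (median leave-one-out shift). Criteria can be monitored jointly with OR
  logic (`combine_or()`).
- **A synthetic-review generator** (`synthetic_spec()`, `gen_pool()`) so the
  whole pipeline is testable without external corpora, plus readers for
  TREC-style qrels files and flat 2x2-table CSV exports.

## Worked example

```r
library(dtastop)

# a synthetic review: 2000 candidates, 60 relevant, three meta-analyses
ds <- gen_pool(synthetic_spec(seed = 101))
ds
#> <dta_review_dataset> review 'SYNTH': 2000 candidates (60 relevant), 3 meta-analysis group(s)

ranked <- rank_active(ds, seed = 7)
random <- rank_random(ds, seed = 7)
recall_at(ranked, 0.1, frac = TRUE)   # recall after screening 10% of the pool
#> [1] 1
recall_at(random, 0.1, frac = TRUE)
#> [1] 0.08333333

# replay the largest meta-analysis along the ranked trace
elt <- effort_loss_trace(ranked, ds$groups[[1]], compute_loocv = FALSE)
tail(elt$curve[, c("effort", "found", "loss", "sens", "spec")], 2)
#>    effort found        loss      sens      spec
#> 17     57    19 0.005183965 0.8627847 0.9244655
#> 18     59    20 0.000000000 0.8576772 0.9253525

# when would stopping rules have fired, and at what loss?
trigger_relevant_found(ranked, 10)          # effort to find 10 relevant
#> [1] 10
trigger_displacement_ma2(elt$series, 0.02)  # estimate stabilized within 0.02
#> [1] 21
```

The effort/loss curve shows the estimate converging to its final value: at
full effort the loss is 0 by construction, and the displacement rules detect
when consecutive updates stop moving the estimate. `run_simulation()`
repeats this over replicates and criteria and aggregates trigger rates,
efforts, recalls and losses into a per-criterion table (`write_report()`).

A thin command-line wrapper with subcommands `synth`, `rank`, `fit` and
`simulate` is installed under `inst/scripts/dtastop`.

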