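test_that("effort/loss curve ends at zero loss and counts updates from the third study", {
  ds <- small_review(seed = 12, n_candidates = 200, n_relevant = 15,
                     group_sizes = c(8))
  tr <- rank_active(ds, seed = 2)
  elt <- effort_loss_trace(tr, ds$groups[[1]], compute_loocv = FALSE)
  expect_equal(nrow(elt$curve), 8 - 2)
  expect_equal(elt$curve$loss[nrow(elt$curve)], 0, tolerance = 1e-8)
  expect_true(all(diff(elt$curve$effort) > 0))
  # displacement entries start at the 4th found study
  expect_equal(elt$series$found[1], 4)
  expect_equal(nrow(elt$series), 8 - 3)
})

test_that("curves depend only on the found set, not on interleaved irrelevant refs", {
  ds <- small_review(seed = 13, n_candidates = 100, n_relevant = 10,
                     group_sizes = c(6))
  g <- ds$groups[[1]]
  srefs <- vapply(g$studies, `[[`, character(1), "study_ref")
  ids <- pool_ids_of(ds)
  rel <- vapply(ds$pool, `[[`, logical(1), "is_relevant")
  # trace A: group studies first, then everything else
  orderA <- c(srefs, setdiff(ids, srefs))
  trA <- screening_trace(orderA, rel[match(orderA, ids)])
  # trace B: group studies at spread-out positions
  rest <- setdiff(ids, srefs)
  orderB <- rest
  for (i in seq_along(srefs)) orderB <- append(orderB, srefs[i], after = 12 * i)
  trB <- screening_trace(orderB, rel[match(orderB, ids)])
  eA <- effort_loss_trace(trA, g, compute_loocv = FALSE)
  eB <- effort_loss_trace(trB, g, compute_loocv = FALSE)
  expect_equal(eA$curve$loss, eB$curve$loss, tolerance = 1e-10)
  expect_equal(eA$curve$sens, eB$curve$sens, tolerance = 1e-10)
  expect_true(all(eA$curve$effort <= eB$curve$effort))
})

test_that("simulation report has the expected cardinality and conditioning", {
  ds <- small_review(seed = 14, n_candidates = 150, n_relevant = 14,
                     group_sizes = c(6))
  crits <- list(criterion("recall", R = 1),
                criterion("relevant_found", n = 4))
  rep <- run_simulation(ds, crits, methods = "random", reps = 2, base_seed = 9)
  expect_equal(nrow(rep$events), 2 * 2 * 1)
  # recall criterion at R = 1: full recall, zero loss
  r1 <- rep$events[rep$events$criterion == "recall(R=1)", ]
  expect_true(all(r1$recall == 1))
  expect_true(all(r1$l2 < 1e-8))
  # aggregates recomputed from raw events match the stored aggregates
  for (i in seq_len(nrow(rep$aggregates))) {
    a <- rep$aggregates[i, ]
    e <- rep$events[rep$events$method == a$method &
                      rep$events$criterion == a$criterion, ]
    trig <- e[e$triggered, ]
    expect_equal(a$triggered_ma, sum(e$triggered))
    expect_equal(a$effort_abs, mean(trig$trigger_effort))
    expect_equal(a$l2_mean, mean(trig$l2, na.rm = TRUE))
  }
})

test_that("identical base seeds give identical reports", {
  ds <- small_review(seed = 15, n_candidates = 120, n_relevant = 10,
                     group_sizes = c(5))
  crits <- list(criterion("relevant_found", n = 3))
  r1 <- run_simulation(ds, crits, methods = c("ranked", "random"),
                       reps = c(ranked = 1, random = 2), base_seed = 4)
  r2 <- run_simulation(ds, crits, methods = c("ranked", "random"),
                       reps = c(ranked = 1, random = 2), base_seed = 4)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$aggregates, r2$aggregates)
})

test_that("reviews without analyzable meta-analyses are flagged as excluded", {
  ds <- small_review(seed = 16, n_candidates = 60, n_relevant = 6,
                     group_sizes = c(2))
  rep <- run_simulation(ds, list(criterion("relevant_found", n = 2)),
                        methods = "random", reps = 1, base_seed = 1)
  expect_true(rep$meta$excluded)
  expect_equal(nrow(rep$events), 0)
})

test_that("percentile bands are non-crossing and converge to the truth", {
  ds <- small_review(seed = 17, n_candidates = 150, n_relevant = 12,
                     group_sizes = c(7))
  g <- ds$groups[[1]]
  elts <- lapply(1:5, function(s) {
    effort_loss_trace(rank_random(ds, seed = s), g, compute_loocv = FALSE)
  })
  bands <- percentile_bands(elts)
  expect_true(all(bands$p25 <= bands$p50 + 1e-12))
  expect_true(all(bands$p50 <= bands$p75 + 1e-12))
  truth <- truth_estimate(g)
  last <- bands[bands$effort == max(bands$effort), ]
  expect_equal(last$p50[last$axis == "sens"], truth$sens, tolerance = 1e-6)
  expect_equal(last$p25[last$axis == "spec"], truth$spec, tolerance = 1e-6)
  # identical replicates: all bands coincide
  same <- percentile_bands(list(elts[[1]], elts[[1]]))
  expect_equal(same$p25, same$p75)
})

test_that("displacement/loss correlation behaves on degenerate input", {
  # exactly proportional pairs -> 1
  fake <- list(list(
    series = data.frame(effort = 1:5 * 10, found = 4:8,
                        displacement = c(0.5, 0.4, 0.3, 0.2, 0.1),
                        ma2 = NA),
    curve = data.frame(effort = 1:5 * 10,
                       loss = 2 * c(0.5, 0.4, 0.3, 0.2, 0.1))
  ))
  expect_equal(displacement_loss_correlation(fake), 1)
  const <- list(list(
    series = data.frame(effort = 1:4 * 10, found = 4:7,
                        displacement = rep(0.2, 4), ma2 = NA),
    curve = data.frame(effort = 1:4 * 10, loss = c(0.4, 0.3, 0.2, 0.1))
  ))
  expect_message(r <- displacement_loss_correlation(const), "zero variance")
  expect_true(is.na(r))
})

test_that("displacement correlates positively with loss on synthetic reviews", {
  cors <- vapply(1:5, function(s) {
    ds <- small_review(seed = 500 + s, n_candidates = 100, n_relevant = 16,
                       group_sizes = c(12))
    elts <- lapply(1:4, function(r) {
      effort_loss_trace(rank_random(ds, seed = 10 * s + r), ds$groups[[1]],
                        compute_loocv = FALSE)
    })
    displacement_loss_correlation(elts)
  }, numeric(1))
  expect_gt(mean(cors > 0), 0.5)  # sign test: positive in most corpora
})
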