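test_that("L2 loss matches the Euclidean definition", {
  expect_equal(l2_loss(c(0.8, 0.9), c(0.8, 0.9)), 0)
  expect_equal(l2_loss(c(0.83, 0.86), c(0.8, 0.9)), 0.05)
  expect_equal(l2_loss(c(0, 1), c(1, 0)), sqrt(2))
  expect_error(l2_loss(c(1.2, 0.5), c(0.5, 0.5)), "\\[0, 1\\]")
})

test_that("displacement is the estimate-to-estimate distance, NA without a predecessor", {
  expect_equal(displacement(c(0.75, 0.80), c(0.72, 0.84)), 0.05)
  expect_equal(displacement(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_true(is.na(displacement(c(0.5, 0.5), NULL)))
})

test_that("monotone hull removes bumps and keeps slopes non-decreasing", {
  # already convex and decreasing: fixed point
  conv <- cbind(c(0, 1, 3, 6), c(1, 0.5, 0.2, 0.1))
  expect_equal(unname(monotone_hull(conv)), unname(conv))
  # upward bump removed
  bump <- cbind(c(0, 1, 2), c(0.5, 0.6, 0.1))
  expect_equal(unname(monotone_hull(bump)), cbind(c(0, 2), c(0.5, 0.1)))
  # oracle equivalence + slope property on random curves
  for (s in 1:100) {
    pts <- withr::with_seed(s, cbind(cumsum(runif(12, 0.5, 3)),
                                     abs(rnorm(12, 0.3, 0.2))))
    h <- monotone_hull(pts)
    expect_equal(unname(h), unname(hull_oracle(pts)), info = paste("seed", s))
    if (nrow(h) > 2) {
      slopes <- diff(h[, 2]) / diff(h[, 1])
      expect_true(all(diff(slopes) >= -1e-12))
    }
    # every input point lies on or above the hull polyline
    if (nrow(h) >= 2) {
      lam <- approx(h[, 1], h[, 2], xout = pts[, 1], rule = 2)$y
      expect_true(all(pts[, 2] >= lam - 1e-12))
    }
  }
})

test_that("knee point maximizes normalized chord distance", {
  # collinear: all distances zero, first index by tie-break
  expect_equal(knee_point(cbind(0:4, seq(1, 0, length.out = 5))), 1L)
  # L-shaped curve: knee at the corner
  expect_equal(knee_point(cbind(c(0, 0.1, 1), c(1, 0.05, 0))), 2L)
  expect_true(is.na(knee_point(cbind(c(0, 1), c(1, 0)))))
  for (s in 1:100) {
    pts <- withr::with_seed(s, cbind(sort(runif(10, 0, 100)),
                                     rev(sort(runif(10)))))
    expect_equal(knee_point(pts), knee_oracle(pts), info = paste("seed", s))
  }
})

test_that("recall trigger fires at the ceiling(R * f_total)-th relevant", {
  tr <- toy_trace(seq(5, 100, by = 5), 200)  # 20 relevant
  expect_equal(trigger_recall(tr, 0.95), 95)   # 19th relevant at effort 95
  expect_equal(trigger_recall(tr, 1), 100)
  one <- toy_trace(7, 50)
  expect_equal(trigger_recall(one, 0.95), 7)   # ceiling(0.95) = 1
  empty <- screening_trace(sprintf("R%d", 1:10), rep(FALSE, 10))
  expect_true(is.na(trigger_recall(empty, 0.95)))
  # monotone in R
  efforts <- vapply(seq(0.05, 1, by = 0.05), function(R) {
    trigger_recall(tr, R)
  }, numeric(1))
  expect_true(all(diff(efforts) >= 0))
})

test_that("loss/effort slope rule triggers on the printed toy hull", {
  hull <- cbind(c(0, 100, 300), c(0.5, 0.1, 0.09))
  # slopes -0.004 and -5e-05; Lambda/E = 0.001 -> second segment qualifies
  expect_equal(trigger_loss_effort(hull, Lambda = 0.001, E = 1), 100)
  # all slopes steeper than -Lambda/E: never triggers
  steep <- cbind(c(0, 10, 20), c(1, 0.5, 0.05))
  expect_true(is.na(trigger_loss_effort(steep, Lambda = 1e-9, E = 1)))
  # flat tail: slope 0 qualifies immediately at the start of the tail
  flat <- cbind(c(0, 50, 100), c(0.4, 0.2, 0.2))
  expect_equal(trigger_loss_effort(flat, Lambda = 0.001, E = 10), 50)
})

test_that("relevant-found trigger honors count and conservatism", {
  tr <- toy_trace(c(2, 5, 9), 20)
  expect_equal(trigger_relevant_found(tr, 2), 5)
  expect_equal(trigger_relevant_found(tr, 1), 2)
  expect_true(is.na(trigger_relevant_found(tr, 10)))
})

test_that("found/effort gap rule matches the stated equivalence", {
  tr <- toy_trace(c(1, 2, 3), 600)
  expect_equal(trigger_found_effort(tr, F = 1, E = 500), 503)
  tr2 <- toy_trace(c(1, 400), 1200)
  expect_equal(trigger_found_effort(tr2, F = 1, E = 500, min_found = 2), 900)
  tr3 <- toy_trace(550, 600)
  expect_true(is.na(trigger_found_effort(tr3, F = 1, E = 500, min_found = 1)))
})

test_that("found/effort slope and gap formulations agree on random traces", {
  for (s in 1:500) {
    tr <- withr::with_seed(s, {
      n <- sample(50:400, 1)
      k <- sample(0:12, 1)
      toy_trace(if (k) sort(sample.int(n, k)) else integer(0), n)
    })
    F <- withr::with_seed(s + 1000, sample(1:3, 1))
    E <- withr::with_seed(s + 2000, sample(c(20, 50, 100, 151), 1))
    mf <- withr::with_seed(s + 3000, sample(0:4, 1))
    expect_equal(trigger_found_effort(tr, F = F, E = E, min_found = mf),
                 found_effort_oracle(tr, F = F, E = E, min_found = mf),
                 info = paste("seed", s))
  }
})

test_that("larger E/F never triggers earlier on the same trace", {
  for (s in 1:30) {
    tr <- withr::with_seed(s, toy_trace(sort(sample.int(300, 8)), 300))
    e1 <- trigger_found_effort(tr, F = 1, E = 30)
    e2 <- trigger_found_effort(tr, F = 1, E = 60)
    if (!is.na(e1) && !is.na(e2)) expect_gte(e2, e1)
    if (is.na(e1)) expect_true(is.na(e2))
  }
})

test_that("displacement MA2 rule averages pairs and is conservative", {
  s <- data.frame(effort = c(120, 140), found = 4:5,
                  displacement = c(0.05, 0.019),
                  ma2 = c(NA, (0.05 + 0.019) / 2))
  expect_true(is.na(trigger_displacement_ma2(s, 0.02)))  # 0.0345 >= 0.02
  s2 <- data.frame(effort = c(120, 140), found = 4:5,
                   displacement = c(0.01, 0.01), ma2 = c(NA, 0.01))
  expect_equal(trigger_displacement_ma2(s2, 0.02), 140)
  # all-zero displacements trigger at the first MA2 entry
  s3 <- displacement_series(
    efforts = c(10, 20, 30, 40),
    estimates = rep(list(c(0.8, 0.9)), 4), found = 3:6
  )
  expect_equal(trigger_displacement_ma2(s3, 1e-9), 30)
  # stricter thresholds never trigger earlier
  s4 <- data.frame(effort = c(10, 20, 30, 40), found = 4:7,
                   displacement = c(0.08, 0.04, 0.02, 0.01),
                   ma2 = c(NA, 0.06, 0.03, 0.015))
  loose <- trigger_displacement_ma2(s4, 0.05)
  strict <- trigger_displacement_ma2(s4, 0.02)
  expect_lte(loose, strict)
})

test_that("MA2 needs two displacements, hence five relevant studies", {
  s <- displacement_series(efforts = c(10, 20),
                           estimates = list(c(0.8, 0.9), c(0.8, 0.9)),
                           found = 3:4)
  expect_true(all(is.na(s$ma2)))  # single displacement: no full window
  expect_true(is.na(trigger_displacement_ma2(s, 1)))
})

test_that("LOOCV displacement matches its direct definition", {
  # exchangeable group: every leave-one-out fit equals the full fit
  expect_equal(loocv_displacement(identical_group(5)), 0, tolerance = 1e-8)
  expect_true(is.na(loocv_displacement(identical_group(3))))
  # naive from-scratch oracle on a 6-study group
  g <- random_group(6, seed = 13)
  full <- fit_bivariate(g)
  d <- vapply(1:6, function(i) {
    l2_loss(fit_bivariate(ma_group("x", g$studies[-i])), full)
  }, numeric(1))
  expect_equal(loocv_displacement(g), median(d), tolerance = 1e-10)
  # even count: midpoint of the two central order statistics
  g4 <- random_group(4, seed = 14)
  full4 <- fit_bivariate(g4)
  d4 <- sort(vapply(1:4, function(i) {
    l2_loss(fit_bivariate(ma_group("x", g4$studies[-i])), full4)
  }, numeric(1)))
  expect_equal(loocv_displacement(g4), mean(d4[2:3]), tolerance = 1e-10)
})

test_that("LOOCV trigger fires on stable sets and never at threshold zero", {
  s <- data.frame(effort = c(10, 20), found = 4:5, loocv = c(0, 0))
  expect_equal(trigger_displacement_loocv(s, 1e-12), 10)
  expect_error(trigger_displacement_loocv(s, 0))  # strict inequality, > 0 cutoff
  empty <- data.frame(effort = numeric(0), found = numeric(0),
                      loocv = numeric(0))
  expect_true(is.na(trigger_displacement_loocv(empty, 0.01)))
})

test_that("knee trigger lifts knee_point to efforts", {
  curve <- cbind(c(5, 30, 200), c(1, 0.05, 0))
  expect_equal(trigger_knee(curve), 30)
  col <- cbind(c(5, 10, 15), c(0.3, 0.2, 0.1))
  expect_equal(trigger_knee(col), 5)  # collinear: first point by tie-break
  expect_true(is.na(trigger_knee(cbind(c(1, 2), c(1, 0)))))
})

test_that("OR combination takes the earliest trigger", {
  cfg <- criterion("relevant_found", n = 1)
  ev <- function(eff) {
    if (is.na(eff)) dtastop:::criterion_event(cfg, FALSE)
    else dtastop:::criterion_event(cfg, TRUE, trigger_effort = eff,
                                   recall_at_trigger = 0.5)
  }
  expect_equal(combine_or(list(ev(NA), ev(500)))$trigger_effort, 500)
  expect_equal(combine_or(list(ev(300), ev(500)))$trigger_effort, 300)
  all_no <- combine_or(list(ev(NA), ev(NA)))
  expect_false(all_no$triggered)
  expect_true(is.na(all_no$trigger_effort))
})

test_that("criterion configs validate their parameters", {
  expect_error(criterion("recall", R = 1.2), "\\(0, 1\\]")
  expect_error(criterion("loss_effort", Lambda = 0.01), "E")
  expect_error(criterion("displacement_ma2", threshold = -1), "positive")
  c1 <- criterion("found_effort", F = 1, E = 500)
  expect_equal(c1$params$min_found, 3)
})
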