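#' Euclidean loss of a sensitivity/specificity estimate
#'
#' Scalar loss of an estimated (sensitivity, specificity) pair against the
#' reference pair: `sqrt((sens - sens_hat)^2 + (spec - spec_hat)^2)`.
#'
#' @param estimate,truth Numeric length-2 vectors `(sens, spec)` with
#'   components in \[0, 1\], or `dta_summary_estimate` objects.
#' @return Non-negative number.
#' @export
l2_loss <- function(estimate, truth) {
  e <- as_sens_spec(estimate)
  t <- as_sens_spec(truth)
  if (any(e < 0 | e > 1) || any(t < 0 | t > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  sqrt(sum((t - e)^2))
}

as_sens_spec <- function(x) {
  if (inherits(x, "dta_summary_estimate")) c(x$sens, x$spec)
  else {
    stopifnot(is.numeric(x), length(x) == 2L)
    as.numeric(x)
  }
}

#' Displacement between consecutive summary estimates
#'
#' How far the (sensitivity, specificity) summary estimate moved when the
#' latest relevant study was added. Undefined (returns `NA`) until two
#' estimates exist, i.e. until at least three relevant studies have been
#' found and a fourth arrives.
#'
#' @param curr,prev Summary estimates (or length-2 sens/spec vectors);
#'   `prev = NULL` signals "no predecessor yet".
#' @return Non-negative number, or `NA_real_` if not yet defined.
#' @export
displacement <- function(curr, prev) {
  if (is.null(curr) || is.null(prev)) return(NA_real_)
  l2_loss(as_sens_spec(curr), as_sens_spec(prev))
}

#' Leave-one-out displacement of a meta-analysis
#'
#' Influence-style stability diagnostic: the median, over studies s in the
#' group, of the distance between the full-group summary estimate and the
#' estimate with s left out. Each reduced fit must itself be analyzable
#' (>= 3 studies), so the diagnostic is defined only for groups of at least
#' four studies; smaller groups yield `NA`.
#'
#' @param group A [ma_group()].
#' @param ... Passed to [fit_bivariate()].
#' @return Non-negative number, or `NA_real_` when the group is too small.
#' @export
loocv_displacement <- function(group, ...) {
  stopifnot(inherits(group, "dta_ma_group"))
  n <- length(group$studies)
  if (n < 4L) return(NA_real_)
  full <- fit_bivariate(group, ...)
  d <- vapply(seq_len(n), function(i) {
    g <- ma_group(group$ma_id, group$studies[-i], group$review_id)
    l2_loss(fit_bivariate(g, ...), full)
  }, numeric(1))
  median(d)
}

#' Monotone lower convex hull of an effort/loss curve
#'
#' The effort/loss curve is not monotone: a single added study frequently
#' shifts the estimate away from the truth. The loss/effort slope rule is
#' therefore evaluated on the lower convex envelope of the curve, restricted
#' to its non-increasing part, whose segment slopes are non-decreasing.
#'
#' @param points Two-column matrix or data.frame `(effort, loss)`, efforts
#'   strictly increasing, losses non-negative.
#' @return Matrix with columns `effort`, `loss` (a subset of the input rows).
#' @export
monotone_hull <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) > 1 && any(diff(pts[, 1]) <= 0)) {
    stop("efforts must be strictly increasing")
  }
  colnames(pts) <- c("effort", "loss")
  if (nrow(pts) < 2L) return(pts)
  # Andrew's monotone chain, lower hull: pop while the turn is clockwise or
  # straight (keeps slopes strictly increasing left to right)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  keep <- integer(0)
  for (i in seq_len(nrow(pts))) {
    while (length(keep) >= 2L &&
           cross(pts[keep[length(keep) - 1L], ],
                 pts[keep[length(keep)], ], pts[i, ]) <= 0) {
      keep <- keep[-length(keep)]
    }
    keep <- c(keep, i)
  }
  hull <- pts[keep, , drop = FALSE]
  # restrict to the non-increasing part: truncate before the first segment
  # with positive slope (flat segments are kept)
  if (nrow(hull) > 1) {
    slopes <- diff(hull[, 2]) / diff(hull[, 1])
    up <- which(slopes > 0)
    if (length(up)) hull <- hull[seq_len(up[[1]]), , drop = FALSE]
  }
  hull
}

#' Knee (elbow) point of a curve
#'
#' Returns the index of the point farthest from the chord joining the first
#' and last points after both axes are normalized to \[0, 1\] (normalization
#' makes the result invariant to axis units). Ties are broken by the smallest
#' index; for fewer than three points the knee is undefined.
#'
#' @param points Two-column matrix or data.frame `(x, y)`.
#' @return Integer index into `points`, or `NA_integer_` if undefined.
#' @export
knee_point <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 3L) return(NA_integer_)
  rng <- apply(pts, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1  # degenerate axis: all points share that coordinate
  z <- sweep(sweep(pts, 2, rng[1, ]), 2, span, "/")
  a <- z[1, ]; b <- z[n, ]
  chord <- b - a
  len <- sqrt(sum(chord^2))
  d <- if (len == 0) {
    sqrt(rowSums(sweep(z, 2, a)^2))
  } else {
    abs(chord[1] * (a[2] - z[, 2]) - chord[2] * (a[1] - z[, 1])) / len
  }
  # smallest-index tie-break, with a tolerance so exactly collinear inputs do
  # not resolve by floating-point noise
  which(d >= max(d) - 1e-12)[[1]]
}

# ---- trigger evaluation -----------------------------------------------------
# Each trigger_* returns the effort position at which the criterion fires, or
# NA_real_ when it never does. Prospective criteria are conservative: they
# simply do not trigger when their preconditions are never met.

#' Target-recall stopping position (retrospective)
#'
#' Effort at which the ceiling(R * f_total)-th relevant reference is screened.
#' Needs the complete trace (the total number of relevant references is not
#' knowable during screening).
#'
#' @param trace A [screening_trace()].
#' @param R Target recall in (0, 1].
#' @return Effort position, or `NA_real_` if the pool holds no relevant
#'   reference.
#' @export
trigger_recall <- function(trace, R) {
  stopifnot(inherits(trace, "dta_trace"), R > 0, R <= 1)
  pos <- which(trace$relevant)
  f_total <- length(pos)
  if (f_total == 0L) return(NA_real_)
  as.numeric(pos[[ceiling(R * f_total)]])
}

#' Loss/effort slope rule (retrospective)
#'
#' Stops where reducing the loss by a further `Lambda` would cost at least
#' `E` more screened references: the first consecutive pair of points on the
#' monotone hull of the effort/loss curve whose slope exceeds `-Lambda / E`;
#' the trigger effort is the left endpoint of that segment.
#'
#' @param curve Two-column `(effort, loss)` matrix/data.frame (the raw curve;
#'   the hull is taken internally), or the `curve` element of
#'   [effort_loss_trace()].
#' @param Lambda,E Loss and effort deltas, both positive.
#' @return Effort position or `NA_real_`.
#' @export
trigger_loss_effort <- function(curve, Lambda, E) {
  stopifnot(Lambda > 0, E > 0)
  curve <- as_curve_matrix(curve)
  hull <- monotone_hull(curve)
  if (nrow(hull) < 2L) return(NA_real_)
  slopes <- diff(hull[, 2]) / diff(hull[, 1])
  hit <- which(slopes > -Lambda / E)
  if (!length(hit)) return(NA_real_)
  as.numeric(hull[hit[[1]], 1])
}

as_curve_matrix <- function(curve) {
  if (is.list(curve) && !is.data.frame(curve) && !is.null(curve$curve)) {
    curve <- curve$curve
  }
  m <- as.matrix(curve[, 1:2])
  storage.mode(m) <- "double"
  m
}

#' Relevant-found stopping rule (prospective)
#'
#' Stops as soon as `n` relevant references have been identified; does not
#' trigger when fewer than `n` exist in the pool.
#'
#' @param trace A [screening_trace()].
#' @param n Positive integer.
#' @return Effort position or `NA_real_`.
#' @export
trigger_relevant_found <- function(trace, n) {
  stopifnot(inherits(trace, "dta_trace"), n >= 1)
  hit <- which(trace$found_curve >= n)
  if (!length(hit)) return(NA_real_)
  as.numeric(hit[[1]])
}

#' Found/effort gap rule (prospective)
#'
#' Stops when finding `F` further relevant references would require screening
#' at least `E` more candidates. Evaluated at every screened reference, this
#' is equivalent to stopping as soon as no new relevant reference has
#' appeared among the last `E / F` screened — so the rule always pays a
#' constant effort penalty of `E / F` after the last relevant found. To guard
#' against firing in pools with very few relevant references, the rule is
#' suppressed until `min_found` relevant references have been identified.
#'
#' @param trace A [screening_trace()].
#' @param F,E Found and effort deltas, both positive.
#' @param min_found Minimum relevant count before the rule may fire
#'   (default 3).
#' @return Effort position or `NA_real_` (pool exhausted first).
#' @export
trigger_found_effort <- function(trace, F, E, min_found = 3) {
  stopifnot(inherits(trace, "dta_trace"), F > 0, E > 0, min_found >= 0)
  gap <- E / F
  pos <- which(trace$relevant)
  if (length(pos) < min_found) return(NA_real_)
  t_min <- if (min_found >= 1) pos[[min_found]] else 1
  # last relevant position at or before each effort t (0 when none yet)
  last_rel <- cummax(ifelse(trace$relevant, seq_len(trace$n_total), 0L))
  t <- seq_len(trace$n_total)
  # gap since the last relevant found (measured from position 0 when none yet)
  ok <- t >= t_min & (t - last_rel) >= gap
  hit <- which(ok)
  if (!length(hit)) return(NA_real_)
  as.numeric(hit[[1]])
}

#' Displacement series of an incrementally updated meta-analysis
#'
#' Builds the per-update displacement record from a sequence of summary
#' estimates (one per newly identified relevant study from the third
#' onward): displacement entries exist from the fourth study, and the
#' two-update moving average (MA2) from the fifth.
#'
#' @param efforts Efforts at which the estimates were computed.
#' @param estimates List of `dta_summary_estimate` (or sens/spec pairs),
#'   parallel to `efforts`.
#' @param found Relevant-found counts at those efforts (optional).
#' @return data.frame of class `dta_displacement_series` with columns
#'   `effort`, `found`, `displacement`, `ma2` (MA2 is `NA` at the first
#'   displacement: no partial windows).
#' @export
displacement_series <- function(efforts, estimates, found = NULL) {
  stopifnot(length(efforts) == length(estimates))
  n <- length(efforts)
  if (is.null(found)) found <- rep(NA_real_, n)
  if (n < 2L) {
    out <- data.frame(effort = numeric(0), found = numeric(0),
                      displacement = numeric(0), ma2 = numeric(0))
    class(out) <- c("dta_displacement_series", "data.frame")
    return(out)
  }
  d <- vapply(2:n, function(i) {
    displacement(estimates[[i]], estimates[[i - 1]])
  }, numeric(1))
  ma2 <- c(NA_real_, (d[-1] + d[-length(d)]) / 2)
  out <- data.frame(effort = efforts[-1], found = found[-1],
                    displacement = d, ma2 = ma2)
  class(out) <- c("dta_displacement_series", "data.frame")
  out
}

#' Displacement MA2 stopping rule (prospective)
#'
#' Triggers at the first update whose two-window moving average of the
#' displacement falls strictly below `threshold`. Needs at least two
#' displacements (hence at least five identified relevant studies); shorter
#' series never trigger.
#'
#' @param series A [displacement_series()] (or data.frame with columns
#'   `effort`, `ma2`).
#' @param threshold Positive cutoff.
#' @return Effort position or `NA_real_`.
#' @export
trigger_displacement_ma2 <- function(series, threshold) {
  stopifnot(threshold > 0)
  if (is.null(series) || nrow(series) == 0L) return(NA_real_)
  hit <- which(!is.na(series$ma2) & series$ma2 < threshold)
  if (!length(hit)) return(NA_real_)
  as.numeric(series$effort[[hit[[1]]]])
}

#' Displacement LOOCV stopping rule (prospective)
#'
#' At each newly identified relevant study with at least four found, computes
#' the leave-one-out displacement of the found set and triggers when it falls
#' strictly below `threshold`.
#'
#' @param series data.frame with columns `effort` and `loocv` (one row per
#'   update where the diagnostic is defined), e.g. the `loocv_series` element
#'   of [effort_loss_trace()].
#' @param threshold Positive cutoff.
#' @return Effort position or `NA_real_`.
#' @export
trigger_displacement_loocv <- function(series, threshold) {
  stopifnot(threshold > 0)
  if (is.null(series) || nrow(series) == 0L) return(NA_real_)
  hit <- which(!is.na(series$loocv) & series$loocv < threshold)
  if (!length(hit)) return(NA_real_)
  as.numeric(series$effort[[hit[[1]]]])
}

#' Knee stopping rule (retrospective)
#'
#' Stops at the knee of the (raw) effort/loss curve, located with
#' [knee_point()].
#'
#' @param curve Two-column `(effort, loss)` matrix/data.frame.
#' @return Effort position or `NA_real_` (fewer than three points).
#' @export
trigger_knee <- function(curve) {
  curve <- as_curve_matrix(curve)
  k <- knee_point(curve)
  if (is.na(k)) return(NA_real_)
  as.numeric(curve[k, 1])
}

#' Combine criterion events with OR logic
#'
#' Several stopping criteria monitored in parallel, stopping at the first
#' that fires: the combined event triggers iff any member triggered, at the
#' minimum trigger effort; recall, estimate and losses are those recorded at
#' that effort (taken from the earliest-triggering member).
#'
#' @param events List of `dta_criterion_event`s (all for the same trace and
#'   meta-analysis).
#' @param label Label for the combined configuration.
#' @return A `dta_criterion_event`.
#' @export
combine_or <- function(events, label = "combined_or") {
  stopifnot(length(events) >= 1L)
  trig <- vapply(events, function(e) isTRUE(e$triggered), logical(1))
  cfg <- structure(list(name = "combined_or", params = list(), label = label),
                   class = "dta_criterion")
  if (!any(trig)) return(criterion_event(cfg, triggered = FALSE))
  efforts <- vapply(events, function(e) {
    if (isTRUE(e$triggered)) e$trigger_effort else Inf
  }, numeric(1))
  win <- events[[which.min(efforts)]]
  criterion_event(cfg, triggered = TRUE, trigger_effort = win$trigger_effort,
                  recall_at_trigger = win$recall_at_trigger,
                  estimate = win$estimate_at_trigger, losses = win$losses)
}
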