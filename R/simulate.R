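#' Effort/loss curve and displacement series for one meta-analysis
#'
#' Replays a screening trace for one meta-analysis group: every time a group
#' study is newly screened and at least three have been found, the bivariate
#' model is refit on the found studies and the point (effort, L2 loss versus
#' the final-estimate truth) is recorded, together with the displacement from
#' the previous estimate and (optionally) the leave-one-out displacement of
#' the found set. Updates whose fit does not converge are skipped and tallied.
#'
#' @param trace A `dta_trace` covering the group's pool.
#' @param group An analyzable [ma_group()] whose `study_ref`s occur in the
#'   trace.
#' @param compute_loocv Also compute the leave-one-out displacement at each
#'   update with >= 4 found (refits the model once per found study; costs
#'   grow quadratically in group size).
#' @param ... Passed to [fit_bivariate()].
#' @return List with elements `curve` (data.frame `effort`, `found`, `loss`,
#'   `sens`, `spec`, `sens_lb`, `sens_ub`, `spec_lb`, `spec_ub`), `series`
#'   (a [displacement_series()]), `loocv_series` (data.frame `effort`,
#'   `found`, `loocv`, or `NULL`), `truth` (the final estimate),
#'   `estimates` (list, parallel to curve rows), `n_skipped`.
#' @export
effort_loss_trace <- function(trace, group, compute_loocv = TRUE, ...) {
  stopifnot(inherits(trace, "dta_trace"), inherits(group, "dta_ma_group"))
  if (!is_analyzable(group)) {
    stop("meta-analysis '", group$ma_id, "' is not analyzable (< 3 studies)")
  }
  srefs <- vapply(group$studies, `[[`, character(1), "study_ref")
  pos <- match(srefs, trace$order)
  if (anyNA(pos)) {
    stop("meta-analysis '", group$ma_id,
         "' contains studies absent from the trace")
  }
  truth <- truth_estimate(group, ...)
  ord <- order(pos)  # studies in the order the trace discovers them
  efforts_all <- pos[ord]
  studies_ord <- group$studies[ord]

  n <- length(studies_ord)
  rows <- vector("list", n)
  estimates <- list()
  efforts <- numeric(0)
  founds <- integer(0)
  loocv_rows <- list()
  n_skipped <- 0L
  for (kk in 3:n) {
    g <- ma_group(group$ma_id, studies_ord[seq_len(kk)], group$review_id)
    est <- fit_bivariate(g, ...)
    if (!est$converged) {
      n_skipped <- n_skipped + 1L
      next
    }
    estimates[[length(estimates) + 1L]] <- est
    efforts <- c(efforts, efforts_all[[kk]])
    founds <- c(founds, kk)
    rows[[kk]] <- data.frame(
      effort = efforts_all[[kk]], found = kk, loss = l2_loss(est, truth),
      sens = est$sens, spec = est$spec,
      sens_lb = est$sens_ci[1], sens_ub = est$sens_ci[2],
      spec_lb = est$spec_ci[1], spec_ub = est$spec_ci[2]
    )
    if (compute_loocv && kk >= 4L) {
      loocv_rows[[length(loocv_rows) + 1L]] <- data.frame(
        effort = efforts_all[[kk]], found = kk,
        loocv = loocv_displacement(g, ...)
      )
    }
  }
  curve <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  series <- displacement_series(efforts, estimates, found = founds)
  loocv_series <- if (compute_loocv && length(loocv_rows)) {
    do.call(rbind, loocv_rows)
  } else if (compute_loocv) {
    data.frame(effort = numeric(0), found = numeric(0), loocv = numeric(0))
  } else NULL
  list(curve = curve, series = series, loocv_series = loocv_series,
       truth = truth, estimates = estimates, efforts = efforts,
       n_skipped = n_skipped)
}

# losses of the last estimate at or before `effort` against the truth
losses_at_effort <- function(elt, effort) {
  if (is.na(effort)) return(NULL)
  i <- findInterval(effort, elt$efforts)
  if (i < 1L) return(NULL)
  est <- elt$estimates[[i]]
  truth <- elt$truth
  list(estimate = est, losses = c(
    l2 = l2_loss(est, truth),
    sens = abs(est$sens - truth$sens),
    spec = abs(est$spec - truth$spec),
    sens_lb = abs(est$sens_ci[1] - truth$sens_ci[1]),
    sens_ub = abs(est$sens_ci[2] - truth$sens_ci[2]),
    spec_lb = abs(est$spec_ci[1] - truth$spec_ci[1]),
    spec_ub = abs(est$spec_ci[2] - truth$spec_ci[2])
  ))
}

# evaluate one criterion config on one (trace, group, effort-loss-trace)
evaluate_criterion <- function(config, trace, elt) {
  effort <- switch(config$name,
    recall = trigger_recall(trace, config$params$R),
    knee = trigger_knee(elt$curve[, c("effort", "loss")]),
    loss_effort = trigger_loss_effort(elt$curve[, c("effort", "loss")],
                                      config$params$Lambda, config$params$E),
    relevant_found = trigger_relevant_found(trace, config$params$n),
    found_effort = trigger_found_effort(trace, config$params$F,
                                        config$params$E,
                                        config$params$min_found),
    displacement_ma2 = trigger_displacement_ma2(elt$series,
                                                config$params$threshold),
    displacement_loocv = trigger_displacement_loocv(elt$loocv_series,
                                                    config$params$threshold),
    stop("unknown criterion: ", config$name)
  )
  if (is.na(effort)) return(criterion_event(config, triggered = FALSE))
  at <- losses_at_effort(elt, effort)
  criterion_event(
    config, triggered = TRUE, trigger_effort = effort,
    recall_at_trigger = recall_at(trace, effort),
    estimate = at$estimate, losses = at$losses
  )
}

event_row <- function(ev, method, ma_id, rep, n_total) {
  data.frame(
    method = method, criterion = ev$config$label, ma_id = ma_id, rep = rep,
    triggered = ev$triggered, trigger_effort = ev$trigger_effort,
    effort_frac = ev$trigger_effort / n_total,
    recall = ev$recall_at_trigger,
    l2 = ev$losses[["l2"]], sens = ev$losses[["sens"]],
    spec = ev$losses[["spec"]],
    sens_lb = ev$losses[["sens_lb"]], sens_ub = ev$losses[["sens_ub"]],
    spec_lb = ev$losses[["spec_lb"]], spec_ub = ev$losses[["spec_ub"]],
    stringsAsFactors = FALSE
  )
}

#' Run a screening-and-stopping simulation
#'
#' For each replicate and ordering method, builds a screening trace (active
#' learner or randomized control) with a seed derived deterministically from
#' `base_seed`, replays every analyzable meta-analysis of the review along
#' the trace, evaluates every stopping criterion, and aggregates per
#' (method, criterion): how many meta-analyses triggered, whether all of them
#' did ("review triggered"), and mean effort, recall and losses over
#' triggered events only.
#'
#' @param dataset A [review_dataset()].
#' @param criteria List of [criterion()] configurations.
#' @param methods Character subset of `c("ranked", "random")`.
#' @param reps Named integer vector or single number: replicates per method.
#' @param base_seed Integer master seed; all per-replicate seeds derive from
#'   it.
#' @param al_config [active_learner_config()] for the ranked method.
#' @param compute_loocv Passed to [effort_loss_trace()]; set `FALSE` to skip
#'   the quadratic-cost leave-one-out series when no LOOCV criterion is used.
#' @param combine Optional character vector of criterion labels to monitor
#'   jointly with OR logic (an extra `combined_or` event per trace and
#'   meta-analysis).
#' @param ... Passed to [fit_bivariate()].
#' @return Object of class `dta_simulation_report`: list with `events`
#'   (data.frame, one row per method x rep x meta-analysis x criterion),
#'   `aggregates` (data.frame per method x criterion), `curves` (nested list
#'   of [effort_loss_trace()] results), `traces`, `review_id`, `meta`.
#' @export
run_simulation <- function(dataset, criteria, methods = c("ranked", "random"),
                           reps = c(ranked = 20L, random = 50L),
                           base_seed = 1L,
                           al_config = active_learner_config(),
                           compute_loocv = NULL, combine = NULL, ...) {
  stopifnot(inherits(dataset, "dta_review_dataset"), length(criteria) >= 1L)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(names(reps))) {
    reps <- setNames(rep(as.integer(reps[[1]]), length(methods)), methods)
  }
  if (is.null(compute_loocv)) {
    compute_loocv <- any(vapply(criteria, function(cf) {
      cf$name == "displacement_loocv"
    }, logical(1)))
  }
  groups <- Filter(is_analyzable, dataset$groups)
  excluded <- length(groups) == 0L
  n_total <- length(dataset$pool)

  rows <- list()
  curves <- list()
  traces <- list()
  for (method in methods) {
    for (r in seq_len(reps[[method]])) {
      seed_r <- derive_seed(base_seed, method, r)
      trace <- if (method == "ranked") {
        rank_active(dataset, al_config, seed = seed_r)
      } else {
        rank_random(dataset, seed = seed_r)
      }
      traces[[method]][[r]] <- trace
      if (excluded) next
      for (g in groups) {
        elt <- effort_loss_trace(trace, g, compute_loocv = compute_loocv, ...)
        curves[[method]][[as.character(r)]][[g$ma_id]] <- elt
        evs <- lapply(criteria, evaluate_criterion, trace = trace, elt = elt)
        names(evs) <- vapply(criteria, `[[`, character(1), "label")
        for (ev in evs) {
          rows[[length(rows) + 1L]] <- event_row(ev, method, g$ma_id, r, n_total)
        }
        if (!is.null(combine)) {
          ev <- combine_or(evs[combine])
          rows[[length(rows) + 1L]] <- event_row(ev, method, g$ma_id, r, n_total)
        }
      }
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else data.frame()
  aggregates <- aggregate_events(events, n_groups = length(groups))
  structure(
    list(events = events, aggregates = aggregates, curves = curves,
         traces = traces, review_id = dataset$review_id,
         meta = list(base_seed = base_seed, reps = as.list(reps),
                     n_total = n_total, n_analyzable = length(groups),
                     excluded = excluded)),
    class = "dta_simulation_report"
  )
}

# deterministic per-replicate seed below 2^31
derive_seed <- function(base_seed, method, rep) {
  off <- if (method == "ranked") 0L else 500000L
  as.integer((as.numeric(base_seed) * 10007 + off + rep * 131) %% 2147483629)
}

# per (method, criterion) aggregates; means over triggered events only
aggregate_events <- function(events, n_groups) {
  if (!nrow(events)) {
    return(data.frame(method = character(0), criterion = character(0)))
  }
  key <- interaction(events$method, events$criterion, drop = TRUE, sep = "\r")
  out <- lapply(split(events, key), function(e) {
    trig <- e[e$triggered, , drop = FALSE]
    # a review "triggers" in a replicate when all its meta-analyses trigger
    by_rep <- split(e, e$rep)
    sr <- mean(vapply(by_rep, function(er) {
      all(er$triggered) && nrow(er) == n_groups
    }, logical(1)))
    data.frame(
      method = e$method[[1]], criterion = e$criterion[[1]],
      n_events = nrow(e), triggered_ma = sum(e$triggered),
      triggered_frac = mean(e$triggered), triggered_sr_frac = sr,
      effort_abs = mean(trig$trigger_effort),
      effort_frac = mean(trig$effort_frac),
      recall = mean(trig$recall),
      l2_mean = mean(trig$l2, na.rm = TRUE),
      sens_loss_mean = mean(trig$sens, na.rm = TRUE),
      sens_lb = mean(trig$sens_lb, na.rm = TRUE),
      sens_ub = mean(trig$sens_ub, na.rm = TRUE),
      spec_loss_mean = mean(trig$spec, na.rm = TRUE),
      spec_lb = mean(trig$spec_lb, na.rm = TRUE),
      spec_ub = mean(trig$spec_ub, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$method, res$criterion), , drop = FALSE]
}

#' @export
print.dta_simulation_report <- function(x, ...) {
  cat("<dta_simulation_report> review '", x$review_id, "': ",
      nrow(x$events), " events over ", x$meta$n_analyzable,
      " analyzable meta-analyses\n", sep = "")
  if (nrow(x$aggregates)) {
    print(x$aggregates[, c("method", "criterion", "triggered_frac",
                           "effort_frac", "recall", "l2_mean")], ...)
  }
  invisible(x)
}

#' Percentile bands of replicate estimate curves
#'
#' Aligns the per-replicate evolution of the summary sensitivity and
#' specificity on a common effort grid (step interpolation: the estimate is
#' carried forward between updates) and returns pointwise percentile
#' envelopes, e.g. the 25/50/75% bands of the estimate evolution across
#' simulated screenings.
#'
#' @param elts List of [effort_loss_trace()] results (one per replicate, same
#'   meta-analysis).
#' @param percentiles Probabilities of the envelopes.
#' @param grid Optional effort grid; defaults to the union of update efforts.
#' @return data.frame with columns `effort`, `axis` (`"sens"`/`"spec"`), one
#'   column per percentile (`p25`, ...). Efforts before a replicate's first
#'   estimate are dropped from the grid.
#' @export
percentile_bands <- function(elts, percentiles = c(0.25, 0.5, 0.75),
                             grid = NULL) {
  stopifnot(length(elts) >= 2L)
  if (is.null(grid)) {
    grid <- sort(unique(unlist(lapply(elts, function(e) e$curve$effort))))
  }
  first <- max(vapply(elts, function(e) min(e$curve$effort), numeric(1)))
  grid <- grid[grid >= first]
  step_at <- function(e, axis) {
    idx <- findInterval(grid, e$curve$effort)
    e$curve[[axis]][pmax(idx, 1L)]
  }
  out <- lapply(c("sens", "spec"), function(axis) {
    vals <- vapply(elts, step_at, numeric(length(grid)), axis = axis)
    vals <- matrix(vals, nrow = length(grid))
    q <- t(apply(vals, 1, quantile, probs = percentiles, names = FALSE))
    df <- data.frame(effort = grid, axis = axis)
    for (j in seq_along(percentiles)) {
      df[[sprintf("p%02d", round(100 * percentiles[j]))]] <- q[, j]
    }
    df
  })
  do.call(rbind, out)
}

#' Correlation between displacement and concurrent loss
#'
#' Pools (displacement, L2 loss) pairs across all update points of a
#' simulation report (or a list of [effort_loss_trace()] results) and
#' returns their Pearson correlation; the displacement may be smoothed with
#' a moving average first. Returns `NA` with a message when either variable
#' has zero variance.
#'
#' @param x A `dta_simulation_report` or list of `effort_loss_trace` results.
#' @param window Moving-average window on the displacement (1 = raw).
#' @return Pearson correlation coefficient or `NA_real_`.
#' @export
displacement_loss_correlation <- function(x, window = 1L) {
  elts <- if (inherits(x, "dta_simulation_report")) {
    unlist(unlist(x$curves, recursive = FALSE), recursive = FALSE)
  } else x
  pairs <- do.call(rbind, lapply(elts, function(e) {
    s <- e$series
    if (is.null(s) || !nrow(s)) return(NULL)
    d <- s$displacement
    if (window > 1L) {
      d <- as.numeric(stats::filter(d, rep(1 / window, window), sides = 1))
    }
    loss <- e$curve$loss[match(s$effort, e$curve$effort)]
    cbind(d, loss)
  }))
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (is.null(pairs) || nrow(pairs) < 3L) {
    message("too few displacement/loss pairs; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(pairs[, 1]) == 0 || stats::sd(pairs[, 2]) == 0) {
    message("zero variance in displacement or loss; correlation undefined")
    return(NA_real_)
  }
  cor(pairs[, 1], pairs[, 2])
}
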