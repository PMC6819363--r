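#' @importFrom stats qlogis plogis qnorm quantile median cor optim rnorm runif
#'   rbinom setNames predict
#' @importFrom utils read.csv write.csv head tail
NULL

#' Candidate reference
#'
#' One candidate citation in the screening pool. The relevance label plays the
#' role of the (simulated) human screener's judgment: the ranker never looks at
#' it until the reference has been "screened".
#'
#' @param ref_id Unique identifier within the pool.
#' @param title Title text. May be empty only if `abstract` is not.
#' @param abstract Abstract text; may be empty (many PubMed records lack one).
#' @param is_relevant Logical screener judgment.
#' @param source_id Optional external identifier (e.g. a PubMed ID), or `NA`.
#' @return An object of class `dta_reference`.
#' @export
reference <- function(ref_id, title, abstract = "", is_relevant = FALSE,
                      source_id = NA_character_) {
  stopifnot(is.character(ref_id), length(ref_id) == 1L, nzchar(ref_id))
  title <- as.character(title)
  abstract <- as.character(abstract)
  if (is.na(abstract)) abstract <- ""
  if (!nzchar(title) && !nzchar(abstract)) {
    stop("reference '", ref_id, "': title and abstract cannot both be empty")
  }
  structure(
    list(ref_id = ref_id, title = title, abstract = abstract,
         is_relevant = isTRUE(is_relevant), source_id = source_id),
    class = "dta_reference"
  )
}

#' Diagnostic accuracy 2x2 table
#'
#' True/false positive and negative counts of one diagnostic accuracy study,
#' attached to the pool reference that reports it.
#'
#' @param tp,fp,fn,tn Non-negative integer counts. At least one diseased
#'   (`tp + fn >= 1`) and one non-diseased (`fp + tn >= 1`) subject required.
#' @param study_ref `ref_id` of the contributing reference.
#' @return An object of class `dta_two_by_two`.
#' @export
two_by_two <- function(tp, fp, fn, tn, study_ref) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("2x2 counts must be non-negative integers (study '", study_ref, "')")
  }
  if (tp + fn < 1) stop("study '", study_ref, "': tp + fn must be >= 1")
  if (fp + tn < 1) stop("study '", study_ref, "': fp + tn must be >= 1")
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         tn = as.integer(tn), study_ref = as.character(study_ref)),
    class = "dta_two_by_two"
  )
}

#' Meta-analysis group
#'
#' The set of studies (2x2 tables) feeding one summary estimate. A group is
#' analyzable only when it contains at least three studies; summary estimates
#' from fewer studies are refused throughout the package.
#'
#' @param ma_id Identifier of the meta-analysis.
#' @param studies List of [two_by_two()] objects with distinct `study_ref`s.
#' @param review_id Identifier of the owning review.
#' @return An object of class `dta_ma_group`.
#' @export
ma_group <- function(ma_id, studies, review_id = NA_character_) {
  stopifnot(is.list(studies))
  ok <- vapply(studies, inherits, logical(1), "dta_two_by_two")
  if (length(studies) && !all(ok)) stop("all studies must be two_by_two objects")
  refs <- vapply(studies, `[[`, character(1), "study_ref")
  if (anyDuplicated(refs)) {
    stop("duplicate study_ref in meta-analysis '", ma_id, "': ",
         paste(unique(refs[duplicated(refs)]), collapse = ", "))
  }
  structure(
    list(ma_id = as.character(ma_id), studies = studies,
         review_id = as.character(review_id)),
    class = "dta_ma_group"
  )
}

#' @rdname ma_group
#' @param group A `dta_ma_group`.
#' @export
is_analyzable <- function(group) {
  stopifnot(inherits(group, "dta_ma_group"))
  length(group$studies) >= 3L
}

#' @export
length.dta_ma_group <- function(x) length(x$studies)

#' Review dataset
#'
#' A candidate pool, the protocol text used as the active learner's seed
#' document, and the meta-analysis groups of the review. Construction checks
#' that every study in every group resolves to a relevant pool reference.
#'
#' @param review_id Review identifier.
#' @param pool List of [reference()] objects with unique `ref_id`s.
#' @param protocol_text Seed document text.
#' @param groups List of [ma_group()] objects.
#' @return An object of class `dta_review_dataset`.
#' @export
review_dataset <- function(review_id, pool, protocol_text = "", groups = list()) {
  stopifnot(is.list(pool), length(pool) >= 1L, is.list(groups))
  ids <- vapply(pool, `[[`, character(1), "ref_id")
  if (anyDuplicated(ids)) stop("duplicate ref_id in pool")
  rel <- vapply(pool, `[[`, logical(1), "is_relevant")
  relevant_ids <- ids[rel]
  for (g in groups) {
    stopifnot(inherits(g, "dta_ma_group"))
    srefs <- vapply(g$studies, `[[`, character(1), "study_ref")
    missing <- setdiff(srefs, relevant_ids)
    if (length(missing)) {
      stop("meta-analysis '", g$ma_id, "': study_ref(s) not found among ",
           "relevant pool references: ", paste(missing, collapse = ", "))
    }
  }
  structure(
    list(review_id = as.character(review_id), pool = pool,
         protocol_text = as.character(protocol_text), groups = groups),
    class = "dta_review_dataset"
  )
}

#' @export
print.dta_review_dataset <- function(x, ...) {
  rel <- sum(vapply(x$pool, `[[`, logical(1), "is_relevant"))
  cat("<dta_review_dataset> review '", x$review_id, "': ",
      length(x$pool), " candidates (", rel, " relevant), ",
      length(x$groups), " meta-analysis group(s)\n", sep = "")
  invisible(x)
}

#' Screening trace
#'
#' A complete ordering of the pool: position t is the effort at which that
#' reference is screened. The found curve `f_t` counts relevant references
#' among the first t screened.
#'
#' @param order Character vector: permutation of the pool's `ref_id`s.
#' @param relevant Logical vector aligned with `order` (revealed labels).
#' @param seed Integer seed the trace was generated with.
#' @param method_tag `"ranked"` or `"random"`.
#' @return An object of class `dta_trace` with fields `order`, `relevant`,
#'   `found_curve`, `n_total`, `seed`, `method_tag`.
#' @export
screening_trace <- function(order, relevant, seed = NA_integer_,
                            method_tag = c("ranked", "random")) {
  method_tag <- match.arg(method_tag)
  stopifnot(length(order) == length(relevant), !anyDuplicated(order))
  structure(
    list(order = as.character(order), relevant = as.logical(relevant),
         found_curve = cumsum(as.logical(relevant)),
         n_total = length(order), seed = seed, method_tag = method_tag),
    class = "dta_trace"
  )
}

#' @export
print.dta_trace <- function(x, ...) {
  cat("<dta_trace> ", x$method_tag, " order of ", x$n_total, " references, ",
      x$found_curve[x$n_total], " relevant (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Stopping-criterion configuration
#'
#' @param type One of `"recall"`, `"knee"`, `"loss_effort"`,
#'   `"relevant_found"`, `"found_effort"`, `"displacement_ma2"`,
#'   `"displacement_loocv"`.
#' @param ... Named numeric parameters the criterion needs: `R` (target recall
#'   in (0, 1]), `Lambda` and `E` (loss/effort deltas), `F` and `E`
#'   (found/effort deltas) plus `min_found`, `n` (relevant-found count), or
#'   `threshold` (displacement cutoffs).
#' @param label Optional display label; defaults to the type plus parameters.
#' @return An object of class `dta_criterion`.
#' @export
criterion <- function(type = c("recall", "knee", "loss_effort", "relevant_found",
                               "found_effort", "displacement_ma2",
                               "displacement_loocv"),
                      ..., label = NULL) {
  name <- match.arg(type)
  params <- list(...)
  required <- switch(name,
    recall = "R",
    knee = character(0),
    loss_effort = c("Lambda", "E"),
    relevant_found = "n",
    found_effort = c("F", "E"),
    displacement_ma2 = "threshold",
    displacement_loocv = "threshold"
  )
  if (name == "found_effort" && is.null(params$min_found)) params$min_found <- 3
  miss <- setdiff(required, names(params))
  if (length(miss)) {
    stop("criterion '", name, "' requires parameter(s): ",
         paste(miss, collapse = ", "))
  }
  for (p in required) {
    v <- params[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("criterion '", name, "': parameter '", p,
           "' must be a single positive number")
    }
  }
  if (name == "recall" && params$R > 1) stop("target recall R must be in (0, 1]")
  if (name == "found_effort" &&
      (params$min_found < 0 || params$min_found != round(params$min_found))) {
    stop("min_found must be a non-negative integer")
  }
  if (is.null(label)) {
    pp <- params[setdiff(names(params), "min_found")]
    label <- if (length(pp)) {
      paste0(name, "(", paste(names(pp), unlist(pp), sep = "=", collapse = ","), ")")
    } else name
  }
  structure(list(name = name, params = params, label = label),
            class = "dta_criterion")
}

#' Criterion event
#'
#' The outcome of evaluating one stopping criterion on one screening trace for
#' one meta-analysis: whether it triggered, at what effort, and the losses of
#' the estimate frozen at that point relative to the final ("truth") estimate.
#'
#' @keywords internal
criterion_event <- function(config, triggered, trigger_effort = NA_real_,
                            recall_at_trigger = NA_real_, estimate = NULL,
                            losses = NULL) {
  if (!triggered) trigger_effort <- NA_real_
  if (is.null(losses)) {
    losses <- c(l2 = NA_real_, sens = NA_real_, spec = NA_real_,
                sens_lb = NA_real_, sens_ub = NA_real_,
                spec_lb = NA_real_, spec_ub = NA_real_)
  }
  structure(
    list(config = config, triggered = isTRUE(triggered),
         trigger_effort = trigger_effort,
         recall_at_trigger = recall_at_trigger,
         estimate_at_trigger = estimate, losses = losses),
    class = "dta_criterion_event"
  )
}

# internal: relevance flags of a dataset pool, in pool order
pool_relevance <- function(dataset) {
  vapply(dataset$pool, `[[`, logical(1), "is_relevant")
}

pool_ids <- function(dataset) {
  vapply(dataset$pool, `[[`, character(1), "ref_id")
}
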