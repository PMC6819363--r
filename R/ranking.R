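#' Active-learner configuration
#'
#' Settings of the relevance-feedback ranker: size of the pseudo-negative
#' sample drawn from the unscreened pool each iteration, initial batch size,
#' ridge penalty of the logistic classifier, and the minimum document
#' frequency a bigram needs to enter the vocabulary (unigrams are always
#' kept; rare bigrams are overwhelmingly noise and inflate the feature
#' space).
#'
#' @param n_pseudo_negatives Pseudo-negative top-up target (default 100).
#' @param batch_start Initial batch size (default 1).
#' @param lambda Ridge (L2) regularization strength (default 1e-4).
#' @param bigram_min_df Minimum document frequency for bigram features
#'   (default 2).
#' @param seed Integer seed.
#' @return Object of class `dta_al_config`.
#' @export
active_learner_config <- function(n_pseudo_negatives = 100L, batch_start = 1L,
                                  lambda = 1e-4, bigram_min_df = 2L,
                                  seed = 1L) {
  stopifnot(n_pseudo_negatives >= 1, batch_start >= 1, lambda > 0)
  structure(
    list(n_pseudo_negatives = as.integer(n_pseudo_negatives),
         batch_start = as.integer(batch_start), lambda = lambda,
         bigram_min_df = as.integer(bigram_min_df),
         feature_mode = "uni+bi", seed = as.integer(seed)),
    class = "dta_al_config"
  )
}

#' Batch-size schedule
#'
#' Number of references shown to the screener in iteration k: starts at 1
#' and grows by `ceiling(B / 10)` each iteration (so 1, 2, ..., 10, 11, 13,
#' 15, ...), giving roughly geometric growth once batches exceed ten.
#'
#' @param k Iteration index (vectorized), `k >= 1`.
#' @param batch_start Initial batch size.
#' @return Integer batch size(s) `B_k`.
#' @export
batch_schedule <- function(k, batch_start = 1L) {
  if (any(k < 1) || any(k != round(k))) stop("iteration index k must be >= 1")
  kmax <- max(k)
  B <- integer(kmax)
  B[1] <- as.integer(batch_start)
  if (kmax > 1) {
    for (i in 2:kmax) B[i] <- B[i - 1] + as.integer(ceiling(B[i - 1] / 10))
  }
  B[k]
}

#' Unigram + bigram term counts
#'
#' Case-folds and tokenizes the concatenation of title and abstract (tokens
#' are maximal runs of letters, digits, hyphens or apostrophes) and counts
#' unigrams plus adjacent bigrams (joined with `"_"`).
#'
#' @param title,abstract Text fields; at least one must be non-empty.
#' @return Named integer vector of term counts.
#' @export
extract_features <- function(title, abstract = "") {
  if (is.na(abstract)) abstract <- ""
  text <- trimws(paste(title, abstract))
  if (!nzchar(text)) stop("cannot extract features: title and abstract both empty")
  toks <- tokenize(text)
  if (!length(toks)) stop("cannot extract features: no tokens in input")
  terms <- c(toks, if (length(toks) > 1)
    paste(toks[-length(toks)], toks[-1], sep = "_"))
  tab <- table(terms)
  setNames(as.integer(tab), names(tab))
}

tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9'-]+")[[1]]
  toks[nzchar(toks)]
}

# Build the sparse tf-idf document-term matrix for a pool plus the protocol
# document (last row). Vocabulary = all unigrams + bigrams with document
# frequency >= bigram_min_df (computed over pool documents only). Rows are
# L2-normalized term counts scaled by smoothed idf.
build_dtm <- function(dataset, bigram_min_df = 2L) {
  docs <- c(
    lapply(dataset$pool, function(r) paste(r$title, r$abstract)),
    list(dataset$protocol_text)
  )
  tok <- lapply(docs, function(d) {
    t <- tokenize(d)
    c(t, if (length(t) > 1) paste(t[-length(t)], t[-1], sep = "_"))
  })
  n_pool <- length(dataset$pool)
  # document frequency over pool docs
  df_terms <- table(unlist(lapply(tok[seq_len(n_pool)], unique)))
  keep <- names(df_terms)[!grepl("_", names(df_terms), fixed = TRUE) |
                            df_terms >= bigram_min_df]
  vocab <- sort(keep)
  vidx <- seq_along(vocab)
  names(vidx) <- vocab
  triplets <- lapply(seq_along(tok), function(i) {
    tt <- table(tok[[i]])
    j <- vidx[names(tt)]
    ok <- !is.na(j)
    if (!any(ok)) return(NULL)
    cbind(i = i, j = j[ok], x = as.numeric(tt)[ok])
  })
  tr <- do.call(rbind, triplets)
  m <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                            dims = c(length(tok), length(vocab)),
                            dimnames = list(NULL, vocab))
  dfv <- numeric(length(vocab))
  dfv[vidx[names(df_terms)][!is.na(vidx[names(df_terms)])]] <-
    as.numeric(df_terms)[!is.na(vidx[names(df_terms)])]
  idf <- log((n_pool + 1) / (dfv + 1)) + 1
  m <- m %*% Matrix::Diagonal(x = idf)
  rs <- sqrt(Matrix::rowSums(m^2))
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% m
}

#' Active-learning screening trace
#'
#' Simulates prioritized screening with relevance feedback. The review
#' protocol serves as a single artificial positive example until the first
#' real relevant reference has been screened, after which it is discarded.
#' Each iteration, pseudo-negatives are drawn uniformly from the unscreened
#' pool (fresh every iteration, labeled negative regardless of their true
#' label) topping the negative class up to at least `n_pseudo_negatives`; a
#' ridge-penalized logistic classifier is refit on tf-idf unigram/bigram
#' features; the unscreened references are scored and the top `B_k` (see
#' [batch_schedule()]) are screened, revealing their labels. The loop runs
#' until the pool is exhausted — stopping criteria are applied afterwards,
#' never inside the ranker. Deterministic given the seed.
#'
#' If a classifier fit is impossible (degenerate training set), scoring falls
#' back to cosine similarity against the protocol seed document.
#'
#' @param dataset A [review_dataset()] with non-empty protocol text.
#' @param config An [active_learner_config()].
#' @param seed Seed overriding `config$seed`.
#' @return A `dta_trace` with `method_tag = "ranked"`.
#' @export
rank_active <- function(dataset, config = active_learner_config(),
                        seed = config$seed) {
  stopifnot(inherits(dataset, "dta_review_dataset"),
            inherits(config, "dta_al_config"))
  if (!nzchar(trimws(dataset$protocol_text))) {
    stop("rank_active needs a non-empty protocol_text as seed document")
  }
  n <- length(dataset$pool)
  labels <- pool_relevance(dataset)
  ids <- pool_ids(dataset)
  dtm <- build_dtm(dataset, bigram_min_df = config$bigram_min_df)
  seed_vec <- dtm[n + 1L, , drop = FALSE]
  X <- dtm[seq_len(n), , drop = FALSE]

  order_idx <- integer(0)
  screened <- logical(n)
  k <- 0L
  withr::with_seed(seed, {
    while (any(!screened)) {
      k <- k + 1L
      B <- batch_schedule(k, config$batch_start)
      unscreened <- which(!screened)
      pos_scr <- order_idx[labels[order_idx]]
      neg_scr <- order_idx[!labels[order_idx]]
      n_pseudo <- max(0L, config$n_pseudo_negatives - length(neg_scr))
      pseudo <- if (n_pseudo > 0L && length(unscreened) > 0L) {
        unscreened[sample.int(length(unscreened),
                              min(n_pseudo, length(unscreened)))]
      } else integer(0)
      use_seed_doc <- length(pos_scr) == 0L

      scores <- al_scores(X, seed_vec, pos_scr, c(neg_scr, pseudo),
                          use_seed_doc, config$lambda)
      cand <- unscreened[order(-scores[unscreened], unscreened)]
      take <- cand[seq_len(min(B, length(cand)))]
      order_idx <- c(order_idx, take)
      screened[take] <- TRUE
    }
  })
  screening_trace(ids[order_idx], labels[order_idx], seed = seed,
                  method_tag = "ranked")
}

# fit the classifier and return scores for all pool rows; fall back to
# seed-document cosine similarity when a fit is impossible
al_scores <- function(X, seed_vec, pos_idx, neg_idx, use_seed_doc, lambda) {
  rows <- list()
  yy <- numeric(0)
  if (use_seed_doc) {
    rows <- c(rows, list(seed_vec))
    yy <- c(yy, 1)
  }
  if (length(pos_idx)) {
    rows <- c(rows, list(X[pos_idx, , drop = FALSE]))
    yy <- c(yy, rep(1, length(pos_idx)))
  }
  if (length(neg_idx)) {
    rows <- c(rows, list(X[neg_idx, , drop = FALSE]))
    yy <- c(yy, rep(0, length(neg_idx)))
  }
  Xtr <- do.call(rbind, rows)
  # a short decreasing lambda path warm-starts coordinate descent; scores are
  # taken at the configured penalty. Tiny positive classes are expected here
  # (a single seed document early on), so class-size warnings are silenced.
  path <- sort(unique(c(0.1, 0.02, 0.005, lambda)), decreasing = TRUE)
  fit <- tryCatch(
    suppressWarnings(
      glmnet::glmnet(Xtr, yy, family = "binomial", alpha = 0, lambda = path,
                     standardize = FALSE, thresh = 1e-6)
    ),
    error = function(e) NULL
  )
  scores <- if (!is.null(fit)) {
    tryCatch(as.numeric(predict(fit, X, s = lambda)), error = function(e) NULL)
  }
  if (is.null(scores)) {
    return(as.numeric(X %*% Matrix::t(seed_vec)))
  }
  scores
}

#' Randomized-order control trace
#'
#' Uniformly random permutation of the pool; the control the prioritized
#' order is compared against.
#'
#' @param dataset A [review_dataset()].
#' @param seed Integer seed.
#' @return A `dta_trace` with `method_tag = "random"`.
#' @export
rank_random <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "dta_review_dataset"))
  n <- length(dataset$pool)
  labels <- pool_relevance(dataset)
  ids <- pool_ids(dataset)
  perm <- withr::with_seed(seed, sample.int(n))
  screening_trace(ids[perm], labels[perm], seed = seed, method_tag = "random")
}

#' Recall at a given effort
#'
#' Fraction of all relevant references identified after screening the first
#' `effort` references of a trace.
#'
#' @param trace A `dta_trace`.
#' @param effort Number of references screened (may be fractional of
#'   `n_total` via `frac = TRUE`).
#' @param frac Interpret `effort` as a fraction of the pool.
#' @return Recall in \[0, 1\] (`NaN` when the pool has no relevant).
#' @export
recall_at <- function(trace, effort, frac = FALSE) {
  stopifnot(inherits(trace, "dta_trace"))
  t <- if (frac) max(1L, floor(effort * trace$n_total)) else effort
  t <- min(max(1L, as.integer(t)), trace$n_total)
  total <- trace$found_curve[trace$n_total]
  trace$found_curve[t] / total
}
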