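#' Specification of a synthetic review dataset
#'
#' Describes a synthetic candidate pool with the statistical and textual
#' structure the simulator assumes: a pool of `n_candidates` references of
#' which `n_relevant` are relevant; relevant references carrying diagnostic
#' 2x2 tables drawn from a bivariate logit-normal model (logit-scale means,
#' between-study SDs `tau_*`, correlation `rho`, binomial within-study
#' sampling with `n_diseased` / `n_healthy` subjects per study); and
#' title/abstract token streams in which relevant references are enriched for
#' a signal vocabulary shared with the protocol text.
#'
#' Defaults describe a mid-sized, clearly separable review: 2000 candidates
#' with 60 relevant, summary sensitivity 0.85 and specificity 0.92 on the
#' probability scale, between-study SDs 0.4 with correlation -0.3 (diagnostic
#' accuracy typically trades sensitivity against specificity), and 50
#' diseased / 50 healthy subjects per study so binomial noise stays visible.
#'
#' @param n_candidates Pool size.
#' @param n_relevant Number of relevant references (`<= n_candidates`).
#' @param group_sizes Integer vector of meta-analysis sizes; the groups are
#'   mapped onto distinct relevant references, so `sum(group_sizes) <=
#'   n_relevant`.
#' @param logit_sens_mean,logit_spec_mean True logit-scale means.
#' @param tau_sens,tau_spec Between-study SDs on the logit scale (>= 0).
#' @param rho Between-study correlation in \[-1, 1\].
#' @param n_diseased,n_healthy Subjects per study arm.
#' @param vocab_size Background vocabulary size.
#' @param signal_vocab_size Signal vocabulary size (disjoint from background).
#' @param signal_weight Probability a relevant-document token is drawn from
#'   the signal vocabulary (0 = relevant and irrelevant documents are
#'   textually exchangeable).
#' @param doc_length Tokens per abstract (titles use `title_length` tokens).
#' @param title_length Tokens per title.
#' @param seed Integer RNG seed.
#' @return Object of class `dta_synthetic_spec`.
#' @export
synthetic_spec <- function(n_candidates = 2000, n_relevant = 60,
                           group_sizes = c(20, 12, 6),
                           logit_sens_mean = qlogis(0.85),
                           logit_spec_mean = qlogis(0.92),
                           tau_sens = 0.4, tau_spec = 0.4, rho = -0.3,
                           n_diseased = 50, n_healthy = 50,
                           vocab_size = 1000, signal_vocab_size = 50,
                           signal_weight = 0.6, doc_length = 60,
                           title_length = 5, seed = 1L) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (tau_sens < 0 || tau_spec < 0) stop("between-study SDs must be >= 0")
  if (n_relevant > n_candidates) stop("n_relevant must not exceed n_candidates")
  if (sum(group_sizes) > n_relevant) {
    stop("sum(group_sizes) must not exceed n_relevant")
  }
  if (signal_weight < 0 || signal_weight > 1) {
    stop("signal_weight must lie in [0, 1]")
  }
  structure(
    list(n_candidates = as.integer(n_candidates),
         n_relevant = as.integer(n_relevant),
         group_sizes = as.integer(group_sizes),
         logit_sens_mean = logit_sens_mean, logit_spec_mean = logit_spec_mean,
         tau_sens = tau_sens, tau_spec = tau_spec, rho = rho,
         n_diseased = as.integer(n_diseased), n_healthy = as.integer(n_healthy),
         vocab_size = as.integer(vocab_size),
         signal_vocab_size = as.integer(signal_vocab_size),
         signal_weight = signal_weight, doc_length = as.integer(doc_length),
         title_length = as.integer(title_length), seed = as.integer(seed)),
    class = "dta_synthetic_spec"
  )
}

# draw n (logit sens, logit spec) pairs from the bivariate normal
draw_logit_pairs <- function(n, spec) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  lse <- spec$logit_sens_mean + spec$tau_sens * z1
  lsp <- spec$logit_spec_mean +
    spec$tau_spec * (spec$rho * z1 + sqrt(1 - spec$rho^2) * z2)
  cbind(lse, lsp)
}

#' Generate synthetic 2x2 tables
#'
#' For each study, per-study true (logit sens, logit spec) are drawn from the
#' bivariate normal of [synthetic_spec()]; `tp` is binomial with `n_diseased`
#' trials and success probability `expit(logit sens)`, `tn` binomial with
#' `n_healthy` and `expit(logit spec)`; `fn` and `fp` are the complements, so
#' `tp + fn = n_diseased` and `fp + tn = n_healthy` for every study.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed overriding `spec$seed`.
#' @param study_refs Optional character vector of `study_ref`s (one per study
#'   across all groups); defaults to `"S0001"`-style identifiers.
#' @return List of `dta_ma_group` objects (one per entry of
#'   `spec$group_sizes`), plus attribute `"logit_pairs"` with the latent
#'   per-study values.
#' @export
gen_2x2 <- function(spec, seed = spec$seed, study_refs = NULL) {
  stopifnot(inherits(spec, "dta_synthetic_spec"))
  n_tot <- sum(spec$group_sizes)
  if (is.null(study_refs)) study_refs <- sprintf("S%04d", seq_len(n_tot))
  stopifnot(length(study_refs) == n_tot)
  withr::with_seed(seed, {
    lp <- draw_logit_pairs(n_tot, spec)
    tp <- rbinom(n_tot, spec$n_diseased, plogis(lp[, 1]))
    tn <- rbinom(n_tot, spec$n_healthy, plogis(lp[, 2]))
  })
  fn <- spec$n_diseased - tp
  fp <- spec$n_healthy - tn
  idx <- 0L
  groups <- lapply(seq_along(spec$group_sizes), function(g) {
    k <- spec$group_sizes[[g]]
    studies <- lapply(seq_len(k), function(j) {
      i <- idx + j
      two_by_two(tp[i], fp[i], fn[i], tn[i], study_refs[[i]])
    })
    idx <<- idx + k
    ma_group(sprintf("MA%02d", g), studies, review_id = "SYNTH")
  })
  attr(groups, "logit_pairs") <- lp
  groups
}

# sample one document as a token string; relevant docs mix in signal words
sample_doc <- function(n_tokens, spec, relevant) {
  from_signal <- if (relevant && spec$signal_vocab_size > 0L) {
    runif(n_tokens) < spec$signal_weight
  } else rep(FALSE, n_tokens)
  toks <- character(n_tokens)
  n_sig <- sum(from_signal)
  if (n_sig) {
    toks[from_signal] <- sprintf("s%04d", sample.int(spec$signal_vocab_size,
                                                     n_sig, replace = TRUE))
  }
  if (n_tokens - n_sig) {
    toks[!from_signal] <- sprintf("w%06d", sample.int(spec$vocab_size,
                                                      n_tokens - n_sig,
                                                      replace = TRUE))
  }
  paste(toks, collapse = " ")
}

#' Generate a complete synthetic review dataset
#'
#' Builds a pool of pseudo-word references (relevant documents enriched for
#' the signal vocabulary the protocol text is composed from), attaches the
#' 2x2 groups from [gen_2x2()] to distinct relevant references, and returns a
#' ready-to-simulate [review_dataset()]. Fixed seed gives a byte-identical
#' dataset on repeated calls.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed overriding `spec$seed`.
#' @return A `dta_review_dataset`.
#' @export
gen_pool <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "dta_synthetic_spec"))
  n <- spec$n_candidates
  withr::with_seed(seed, {
    rel_idx <- if (spec$n_relevant > 0L) {
      sort(sample.int(n, spec$n_relevant))
    } else integer(0)
    is_rel <- seq_len(n) %in% rel_idx
    titles <- vapply(seq_len(n), function(i) {
      sample_doc(spec$title_length, spec, is_rel[i])
    }, character(1))
    abstracts <- vapply(seq_len(n), function(i) {
      sample_doc(spec$doc_length, spec, is_rel[i])
    }, character(1))
    protocol <- if (spec$signal_vocab_size > 0L) {
      paste(sprintf("s%04d", sample.int(spec$signal_vocab_size,
                                        max(spec$doc_length, 2L * spec$signal_vocab_size),
                                        replace = TRUE)), collapse = " ")
    } else {
      paste(sprintf("w%06d", sample.int(spec$vocab_size, spec$doc_length,
                                        replace = TRUE)), collapse = " ")
    }
  })
  pool <- lapply(seq_len(n), function(i) {
    reference(sprintf("R%06d", i), titles[[i]], abstracts[[i]],
              is_relevant = is_rel[[i]])
  })
  groups <- list()
  if (sum(spec$group_sizes) > 0L) {
    study_refs <- sprintf("R%06d", rel_idx[seq_len(sum(spec$group_sizes))])
    groups <- gen_2x2(spec, seed = seed + 1L, study_refs = study_refs)
    attr(groups, "logit_pairs") <- NULL
  }
  review_dataset(review_id = "SYNTH", pool = pool,
                 protocol_text = protocol, groups = groups)
}
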