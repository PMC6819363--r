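# Small in-code fixtures shared across the suite.

pool_ids_of <- function(ds) vapply(ds$pool, `[[`, character(1), "ref_id")

# a trace with relevant references at given positions
toy_trace <- function(relevant_at, n_total, method_tag = "ranked") {
  stopifnot(length(relevant_at) == 0 || max(relevant_at) <= n_total)
  rel <- seq_len(n_total) %in% relevant_at
  screening_trace(sprintf("R%04d", seq_len(n_total)), rel,
                  method_tag = method_tag)
}

# k copies of the same 2x2 study (distinct refs)
identical_group <- function(k, tp = 8, fp = 1, fn = 2, tn = 9, ma_id = "M") {
  ma_group(ma_id, lapply(seq_len(k), function(i) {
    two_by_two(tp, fp, fn, tn, sprintf("s%02d", i))
  }))
}

# random analyzable group drawn from the bivariate logit-normal generator
random_group <- function(k, seed, tau = 0.4, rho = -0.3,
                         sens = 0.85, spec = 0.92, n_arm = 50) {
  sp <- synthetic_spec(n_candidates = max(2L * k, 10L), n_relevant = k,
                       group_sizes = k,
                       logit_sens_mean = qlogis(sens),
                       logit_spec_mean = qlogis(spec),
                       tau_sens = tau, tau_spec = tau, rho = rho,
                       n_diseased = n_arm, n_healthy = n_arm, seed = seed)
  gen_2x2(sp, seed = seed)[[1]]
}

# small separable synthetic review for ranking / simulation tests
small_review <- function(seed = 1, n_candidates = 300, n_relevant = 25,
                         group_sizes = c(10, 6), signal_weight = 0.8) {
  sp <- synthetic_spec(n_candidates = n_candidates, n_relevant = n_relevant,
                       group_sizes = group_sizes, vocab_size = 300,
                       signal_vocab_size = 30, doc_length = 30,
                       signal_weight = signal_weight, seed = seed)
  gen_pool(sp)
}

# independent brute-force knee oracle: explicit point-to-line distance after
# min-max normalization, linear scan
knee_oracle <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  z <- apply(pts, 2, function(col) {
    r <- range(col)
    if (diff(r) == 0) rep(0, length(col)) else (col - r[1]) / diff(r)
  })
  p1 <- z[1, ]; p2 <- z[n, ]
  v <- p2 - p1
  best <- 1L; bestd <- -1
  for (i in seq_len(n)) {
    w <- z[i, ] - p1
    d <- if (sum(v^2) == 0) sqrt(sum(w^2)) else {
      proj <- sum(w * v) / sum(v^2)
      sqrt(sum((w - proj * v)^2))
    }
    if (d > bestd + 1e-12) { bestd <- d; best <- i }
  }
  best
}

# independent lower-envelope oracle: gift-wrapping by minimal slope, then cut
# at the minimum loss
hull_oracle <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2L) return(pts)
  idx <- 1L
  keep <- 1L
  while (idx < n) {
    rest <- (idx + 1L):n
    slopes <- (pts[rest, 2] - pts[idx, 2]) / (pts[rest, 1] - pts[idx, 1])
    nxt <- rest[which(slopes == min(slopes))]
    nxt <- nxt[length(nxt)]  # farthest point on ties: drops collinear interior
    keep <- c(keep, nxt)
    idx <- nxt
  }
  hull <- pts[keep, , drop = FALSE]
  if (nrow(hull) > 1) {
    slopes <- diff(hull[, 2]) / diff(hull[, 1])
    up <- which(slopes > 0)
    if (length(up)) hull <- hull[seq_len(up[[1]]), , drop = FALSE]
  }
  hull
}

# slope-formulation oracle for the found/effort rule: walk the consecutive
# relevant-found events of the found/effort curve; after an eligible event k
# the rule fires at t = events[k] + ceiling(E/F) provided screening reaches t
# before the next relevant appears
found_effort_oracle <- function(trace, F, E, min_found = 3) {
  gap <- ceiling(E / F)
  pos <- which(trace$relevant)
  if (length(pos) < min_found) return(NA_real_)
  events <- if (min_found >= 1) pos else c(0L, pos)
  first_k <- max(min_found, 1L)
  for (k in first_k:length(events)) {
    t_fire <- events[k] + gap
    nxt <- if (k < length(events)) events[k + 1] else Inf
    if (t_fire <= trace$n_total && nxt > t_fire) return(as.numeric(t_fire))
  }
  NA_real_
}
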