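#' Logit transform of a 2x2 table
#'
#' Prepares one study for the bivariate random-effects model: observed
#' logit-sensitivity and logit-specificity with their within-study sampling
#' variances from the delta method. With continuity correction c,
#' `y = (logit((tp+c)/(tp+fn+2c)), logit((tn+c)/(tn+fp+2c)))` and the
#' within-study covariance is diagonal with `1/(tp+c)+1/(fn+c)` and
#' `1/(tn+c)+1/(fp+c)`.
#'
#' @param study A [two_by_two()] object.
#' @param correction Continuity correction value (default 0.5).
#' @param correction_policy When to apply it: `"only0"` adds `correction` to
#'   all four cells of a study containing a zero cell and leaves other studies
#'   untouched (default); `"all"` corrects every study; `"none"` never (zero
#'   cells then yield infinite logits).
#' @return List with `y` (length-2 numeric) and `V` (2x2 diagonal matrix).
#' @export
logit_transform <- function(study, correction = 0.5,
                            correction_policy = c("only0", "all", "none")) {
  correction_policy <- match.arg(correction_policy)
  stopifnot(inherits(study, "dta_two_by_two"), correction >= 0)
  cells <- c(study$tp, study$fp, study$fn, study$tn)
  c0 <- switch(correction_policy,
    none = 0,
    all = correction,
    only0 = if (any(cells == 0L)) correction else 0
  )
  tp <- study$tp + c0; fn <- study$fn + c0
  tn <- study$tn + c0; fp <- study$fp + c0
  y <- c(qlogis(tp / (tp + fn)), qlogis(tn / (tn + fp)))
  V <- diag(c(1 / tp + 1 / fn, 1 / tn + 1 / fp))
  list(y = y, V = V)
}

# Profile negative log-likelihood machinery for the marginal model
#   y_i ~ N2(mu, Psi + V_i),  V_i diagonal.
# Psi is parameterized through its Cholesky factor L = [[exp(a), 0], [b, exp(c)]]
# so every proposal is positive semidefinite by construction; mu is profiled
# out by generalized least squares.
psi_from_theta <- function(theta) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  L %*% t(L)
}

# vectorized over studies: y is n x 2, v1/v2 within-study variances
bivar_profile <- function(theta, y, v1, v2) {
  Psi <- psi_from_theta(theta)
  s11 <- Psi[1, 1] + v1
  s22 <- Psi[2, 2] + v2
  s12 <- Psi[1, 2]
  det <- s11 * s22 - s12 * s12
  if (any(det <= 0) || any(!is.finite(det))) return(list(nll = Inf))
  # elements of (Psi + V_i)^{-1}
  w11 <- s22 / det; w22 <- s11 / det; w12 <- -s12 / det
  A11 <- sum(w11); A22 <- sum(w22); A12 <- sum(w12)
  b1 <- sum(w11 * y[, 1] + w12 * y[, 2])
  b2 <- sum(w12 * y[, 1] + w22 * y[, 2])
  detA <- A11 * A22 - A12 * A12
  mu <- c(A22 * b1 - A12 * b2, A11 * b2 - A12 * b1) / detA
  r1 <- y[, 1] - mu[1]; r2 <- y[, 2] - mu[2]
  quad <- sum(w11 * r1 * r1 + 2 * w12 * r1 * r2 + w22 * r2 * r2)
  nll <- 0.5 * (sum(log(det)) + quad) + nrow(y) * log(2 * pi)
  # covariance of mu from the GLS information matrix
  Vmu <- matrix(c(A22, -A12, -A12, A11), 2, 2) / detA
  list(nll = nll, mu = mu, Vmu = Vmu, Psi = Psi)
}

#' Fit the bivariate random-effects model
#'
#' Maximum-likelihood fit of the joint normal model of per-study
#' logit-sensitivity and logit-specificity: `y_i ~ N2(mu, Psi + V_i)` with
#' `V_i` the within-study (delta-method) covariance and `Psi` the
#' between-study covariance. `mu` is profiled out by generalized least
#' squares and `Psi` is optimized in a log-Cholesky parameterization, so
#' proposals are positive semidefinite by construction. Summary sensitivity
#' and specificity are the inverse-logits of `mu`; 95% confidence intervals
#' are Wald intervals on the logit scale, back-transformed.
#'
#' @param group A [ma_group()] with at least three studies.
#' @param correction,correction_policy Passed to [logit_transform()].
#' @param control List: `reltol` for the optimizer (default 1e-8), `maxit`
#'   (default 500).
#' @return Object of class `dta_summary_estimate` with fields `sens`, `spec`,
#'   `sens_ci`, `spec_ci`, `logit_means`, `between_cov`, `se_mu`, `loglik`,
#'   `n_studies`, `converged`.
#' @export
fit_bivariate <- function(group, correction = 0.5,
                          correction_policy = c("only0", "all", "none"),
                          control = list()) {
  correction_policy <- match.arg(correction_policy)
  stopifnot(inherits(group, "dta_ma_group"))
  n <- length(group$studies)
  if (n < 3L) {
    stop("meta-analysis '", group$ma_id, "' has ", n,
         " studies; summary estimates require at least 3")
  }
  reltol <- if (is.null(control$reltol)) 1e-8 else control$reltol
  maxit <- if (is.null(control$maxit)) 500L else control$maxit

  tr <- lapply(group$studies, logit_transform, correction = correction,
               correction_policy = correction_policy)
  y <- t(vapply(tr, `[[`, numeric(2), "y"))
  v1 <- vapply(tr, function(z) z$V[1, 1], numeric(1))
  v2 <- vapply(tr, function(z) z$V[2, 2], numeric(1))

  # start: moment estimate of Psi (observed cov minus mean within-study var)
  S <- stats::cov(y) * (n - 1) / n
  d1 <- max(S[1, 1] - mean(v1), 1e-4)
  d2 <- max(S[2, 2] - mean(v2), 1e-4)
  r0 <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  if (!is.finite(r0)) r0 <- 0
  r0 <- max(min(r0, 0.95), -0.95)
  l11 <- sqrt(d1); l21 <- r0 * sqrt(d2); l22 <- sqrt(max(d2 - l21^2, 1e-6))
  theta0 <- c(log(l11), l21, log(l22))

  obj <- function(th) bivar_profile(th, y, v1, v2)$nll
  opt <- stats::optim(theta0, obj, method = "BFGS",
                      control = list(reltol = reltol, maxit = maxit))
  # fall back to Nelder-Mead if BFGS stalled on a non-finite region
  if (!is.finite(opt$value)) {
    opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
  }
  fit <- bivar_profile(opt$par, y, v1, v2)
  converged <- opt$convergence == 0L && is.finite(fit$nll)

  mu <- fit$mu
  se <- sqrt(diag(fit$Vmu))
  z <- qnorm(0.975)
  est <- structure(
    list(sens = plogis(mu[1]), spec = plogis(mu[2]),
         sens_ci = plogis(c(mu[1] - z * se[1], mu[1] + z * se[1])),
         spec_ci = plogis(c(mu[2] - z * se[2], mu[2] + z * se[2])),
         logit_means = mu, between_cov = fit$Psi, se_mu = se,
         loglik = -fit$nll, n_studies = n, converged = converged,
         ma_id = group$ma_id),
    class = "dta_summary_estimate"
  )
  est
}

#' @export
print.dta_summary_estimate <- function(x, ...) {
  cat(sprintf(
    "<dta_summary_estimate> %d studies: sens %.3f [%.3f, %.3f], spec %.3f [%.3f, %.3f]%s\n",
    x$n_studies, x$sens, x$sens_ci[1], x$sens_ci[2],
    x$spec, x$spec_ci[1], x$spec_ci[2],
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Reference ("truth") estimate of a meta-analysis
#'
#' The summary estimate over the complete study set. All losses and
#' displacements in the simulator are measured against this final estimate,
#' under the assumption that the complete set is large enough for the summary
#' estimate to have converged.
#'
#' @inheritParams fit_bivariate
#' @return A `dta_summary_estimate` with attribute `role = "truth"`.
#' @export
truth_estimate <- function(group, correction = 0.5,
                           correction_policy = c("only0", "all", "none"),
                           control = list()) {
  est <- fit_bivariate(group, correction = correction,
                       correction_policy = correction_policy, control = control)
  attr(est, "role") <- "truth"
  est
}
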