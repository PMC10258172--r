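# Beyond the Huber-White sandwich: the plug-in asymptotic variance
# M^{-1} Var{h0 + h1} M^{-T}, whose h1 term involves the second-order
# influence function of the Aalen-Johansen functional, and the
# non-parametric subject bootstrap.

# Weighted functional value / gradient for a cumulative incidence or the
# survival complement.
weighted_target <- function(tab, status, t, cause, w, gradient = FALSE) {
  survival <- identical(cause, "survival")
  causes <- if (survival) seq_len(tab$d) else as.integer(cause)
  if (!gradient) {
    v <- sum(vapply(causes, function(j)
      weighted_cuminc(tab, status, t, j, w), numeric(1)))
    return(if (survival) 1 - v else v)
  }
  val <- 0
  grad <- numeric(tab$n)
  for (j in causes) {
    g <- weighted_cuminc_gradient(tab, status, t, j, w)
    val <- val + g$value
    grad <- grad + g$grad
  }
  if (survival) list(value = 1 - val, grad = -grad)
  else list(value = val, grad = grad)
}

#' Second-order influence function by numerical differentiation
#'
#' The mixed second directional derivative of the Aalen--Johansen functional
#' at the empirical distribution, in the directions of two subjects' point
#' masses: `phi''(delta_{x_{i1}} - F_n, delta_{x_{i2}} - F_n)`.  Computed by
#' central differences on a two-parameter perturbation of the subject weight
#' vector of the weighted product-limit estimator.  The result is symmetric
#' in `(i1, i2)` up to the finite-difference tolerance, and its average over
#' `i1` is approximately zero (the defining mean-zero property of the
#' second-order influence function at the empirical distribution).
#'
#' @inheritParams pseudo_obs
#' @param i1,i2 subject indices.
#' @param step finite-difference step on the perturbation scale (the weight
#'   vector moves by `step * (delta_i - 1/n)`).
#' @return A scalar.
#' @export
second_order_influence <- function(sample, time, cause = 1, i1, i2,
                                   step = 1e-4) {
  stopifnot(inherits(sample, "event_sample"))
  if (sample$truncated)
    stop("second-order influence is implemented for untruncated samples")
  n <- sample$n
  t <- as.numeric(time)
  tab <- risk_tables(sample, truncation_adjusted = FALSE)
  w0 <- rep(1 / n, n)
  v1 <- -w0; v1[i1] <- v1[i1] + 1
  v2 <- -w0; v2[i2] <- v2[i2] + 1
  f <- function(s1, s2) {
    w <- w0 + s1 * v1 + s2 * v2
    if (any(w <= 0)) stop("weight perturbation produced non-positive weights")
    weighted_target(tab, sample$status, t, cause, w)
  }
  h <- step
  (f(h, h) - f(h, -h) - f(-h, h) + f(-h, -h)) / (4 * h^2)
}

#' Plug-in asymptotic variance including the second-order correction
#'
#' Estimates `M^{-1} Var{h0(X,Z) + h1(X)} M^{-T}`, where
#' `h0 = A(beta; Z) {theta_IJ - mu(beta; Z)}` is the first-order
#' (Huber--White) part and `h1(x) = E{A(beta; Z) phidd(X, x)}` carries the
#' correlation between pseudo-observations induced by the second-order
#' influence function `phidd` of the base functional.  `h1` is computed
#' without forming all `n^2` pairs: for each regression coordinate the
#' required contraction is a single directional derivative of the analytic
#' weight-gradient of the weighted product-limit estimator, obtained by
#' central differences.  The Huber--White estimate ignores `h1` and is
#' conservative for these functionals; this estimate removes that bias.
#'
#' @param fit a [pseudoglm()] fit based on an untruncated sample.
#' @param step finite-difference step for the directional derivative.
#' @return A symmetric variance matrix for the coefficient vector.
#' @export
asymptotic_vcov <- function(fit, step = 1e-4) {
  stopifnot(inherits(fit, "pseudoglm"))
  smp <- fit$sample
  if (smp$truncated)
    stop("the asymptotic-variance plug-in is implemented for untruncated cohorts")
  X <- smp$covariates
  n <- smp$n
  lk <- stats::make.link(fit$link)
  eta <- fit$linear.predictors
  me <- lk$mu.eta(eta)
  A <- X * me                                   # n x p quasi-score rows
  h0 <- A * (fit$pseudo$values - fit$fitted.values)
  tab <- risk_tables(smp, truncation_adjusted = FALSE)
  w0 <- rep(1 / n, n)
  h1 <- matrix(0, n, ncol(A))
  for (cc in seq_len(ncol(A))) {
    u <- (A[, cc] - mean(A[, cc])) / n          # direction (1/n) sum A (d_k - F_n)
    gp <- weighted_target(tab, smp$status, fit$time, fit$cause,
                          w0 + step * u, gradient = TRUE)$grad
    gm <- weighted_target(tab, smp$status, fit$time, fit$cause,
                          w0 - step * u, gradient = TRUE)$grad
    h1[, cc] <- ((gp - mean(gp)) - (gm - mean(gm))) / (2 * step)
  }
  M <- crossprod(X * sqrt(fit$pseudo$weights) * me)
  Minv <- solve(M)
  Sig <- crossprod(h0 + h1)
  v <- Minv %*% Sig %*% t(Minv)
  v <- (v + t(v)) / 2
  dimnames(v) <- list(names(fit$coefficients), names(fit$coefficients))
  v
}

#' Non-parametric bootstrap variance for pseudo-observation regression
#'
#' Resamples subjects with replacement, recomputes the pseudo-observations
#' (and, for the truncation-modified method, the sampling weights) within
#' each replicate, refits the estimating equation and returns the empirical
#' covariance of the replicate coefficient vectors.  Replicate-level
#' failures (e.g. inestimable curves in a degenerate resample) are skipped
#' and counted; more than 10 percent failures is an error.
#'
#' @param sample an [event_sample()] carrying the design matrix as its
#'   covariates, or pass `X` explicitly.
#' @inheritParams pseudoglm
#' @param X design matrix (defaults to the sample's covariates).
#' @param B number of bootstrap replicates (`>= 2`).
#' @return Covariance matrix with attributes `B` (effective replicates) and
#'   `failures`.
#' @export
bootstrap_vcov <- function(sample, time, cause = 1, method = "ij",
                           link = "identity", X = NULL, B = 200L,
                           seed = NULL) {
  stopifnot(inherits(sample, "event_sample"))
  if (B < 2L) stop("'B' must be at least 2")
  if (is.null(X)) X <- sample$covariates
  if (is.null(X)) stop("no design matrix available")
  if (!is.null(seed)) set.seed(seed)
  n <- sample$n
  res <- vector("list", B)
  fails <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    res[[b]] <- tryCatch({
      sub <- event_sample(sample$time[idx], sample$status[idx],
                          entry = sample$entry[idx], n_causes = sample$d)
      ps <- pseudo_obs(sub, time = time, cause = cause, method = method)
      ee_solve(ps$values, X[idx, , drop = FALSE], ps$weights, link)$beta
    }, error = function(e) NULL)
    if (is.null(res[[b]])) fails <- fails + 1L
  }
  if (fails > 0.1 * B)
    stop("bootstrap failed in ", fails, " of ", B, " replicates")
  bmat <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  v <- stats::cov(bmat)
  dimnames(v) <- list(colnames(X), colnames(X))
  attr(v, "B") <- nrow(bmat)
  attr(v, "failures") <- fails
  v
}
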