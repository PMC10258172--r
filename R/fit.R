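# Weighted generalized-linear estimating equation for pseudo-observations:
#   sum_i A(beta; Z_i) w_i { theta_i - mu(beta^T Z_i) } = 0,
# with A the quasi-score mu'(eta) Z (GEE convention), solved by Fisher
# scoring; the identity link reduces to weighted least squares in closed
# form.  Huber-White sandwich variance by default.

pseudo_links <- c("identity", "log", "logit", "cloglog")

# Solve the estimating equation.  Returns beta, iterations, convergence flag,
# the model-based matrix M = sum w mu'^2 Z Z^T at the solution and the
# per-subject estimating functions U_i = w mu' Z (y - mu).
ee_solve <- function(y, X, w, link, tol_ee = 1e-10, tol_beta = 1e-12,
                     maxit = 100L, closed_form = TRUE) {
  lk <- stats::make.link(link)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is not of full rank")
  if (link == "identity" && closed_form) {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    eta <- drop(X %*% beta)
    mu <- eta
    me <- rep(1, length(y))
    M <- crossprod(X * (w * me * me), X)
    U <- X * (w * me * (y - mu))
    return(list(beta = beta, iterations = 0L, converged = TRUE,
                M = M, U = U, mu = mu, eta = eta, link = link))
  }
  # initialisation: intercept at link(clipped mean), slopes at 0; identity
  # link (iterative path) starts at the WLS solution
  if (link == "identity") {
    beta <- stats::lm.wfit(X, y, w)$coefficients
  } else {
    beta <- numeric(p)
    mbar <- min(max(sum(w * y) / sum(w), 0.001), 0.999)
    beta[1L] <- lk$linkfun(mbar)
  }
  names(beta) <- colnames(X)
  conv <- FALSE
  it <- 0L
  ee_norm_at <- function(b) {
    eta <- drop(X %*% b)
    mu <- lk$linkinv(eta)
    me <- lk$mu.eta(eta)
    if (any(!is.finite(mu)) || any(!is.finite(me))) return(Inf)
    sqrt(sum(colSums(X * (w * me * (y - mu)))^2))
  }
  repeat {
    eta <- drop(X %*% beta)
    mu <- lk$linkinv(eta)
    me <- lk$mu.eta(eta)
    Uvec <- colSums(X * (w * me * (y - mu)))
    M <- crossprod(X * sqrt(w) * me)
    if (sqrt(sum(Uvec^2)) < tol_ee) { conv <- TRUE; break }
    if (it >= maxit) break
    step <- tryCatch(solve(M, Uvec), error = function(e)
      stop("singular estimating-equation Jacobian"))
    # step-halving on link-domain violations / non-finite estimating function
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (is.finite(ee_norm_at(cand))) break
      lam <- lam / 2
      if (lam < 1e-10)
        stop("step-halving failed: mean function left its domain")
    }
    delta <- lam * step
    beta <- beta + delta
    it <- it + 1L
    if (sqrt(sum(delta^2)) < tol_beta * max(1, sqrt(sum(beta^2)))) {
      conv <- ee_norm_at(beta) < 1e-6
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- lk$linkinv(eta)
  me <- lk$mu.eta(eta)
  M <- crossprod(X * sqrt(w) * me)
  U <- X * (w * me * (y - mu))
  list(beta = beta, iterations = it, converged = conv, M = M, U = U,
       mu = mu, eta = eta, link = link)
}

# Huber-White sandwich from a solved estimating equation.
ee_sandwich <- function(sol) {
  Minv <- solve(sol$M)
  meat <- crossprod(sol$U)
  v <- Minv %*% meat %*% t(Minv)
  (v + t(v)) / 2
}

#' Pseudo-observation regression for cumulative incidence and survival
#'
#' Fits a generalized-linear mean model `E(V | Z) = mu(beta^T Z)` to
#' pseudo-observations of the cumulative incidence `P(T <= t, cause = j | Z)`
#' (or survival `P(T > t | Z)`), by solving the weighted estimating equation
#' with quasi-score weights.  Pseudo-observations are computed internally by
#' [pseudo_obs()]; for delayed-entry cohorts use `method = "ij-truncated"`,
#' which combines truncation-adjusted curves with inverse probability of
#' sampling weights.
#'
#' @param formula model formula; the left-hand side is built with [Event()]
#'   (or `survival::Surv()`), e.g. `Event(time, status) ~ trt + age`.
#' @param data data frame containing the formula variables.
#' @param time target analysis time `t`.
#' @param cause event type of interest, or `"survival"`.
#' @param method pseudo-observation method passed to [pseudo_obs()].
#' @param link one of `"identity"`, `"log"`, `"logit"`, `"cloglog"`.
#' @param vcov character vector of variance estimators to compute:
#'   `"hw"` (Huber--White, always computed and used for Wald inference),
#'   `"sigma"` (plug-in asymptotic variance including the second-order
#'   influence correction; untruncated methods only) and `"boot"`
#'   (non-parametric subject bootstrap).
#' @param boot number of bootstrap replicates when `"boot"` is requested.
#' @param seed seed for the bootstrap resampling.
#' @param algorithm jack-knife algorithm, see [pseudo_obs()].
#' @param ... further arguments passed to the internal solver (e.g.
#'   `maxit`).
#'
#' @return An object of class `"pseudoglm"`: coefficients, convergence
#'   information, the pseudo-observation set, and the requested variance
#'   matrices (`vcov_hw`, `vcov_sigma`, `vcov_boot`).
#' @examples
#' cfg <- scenario_config(n = 400, p_oc = 0.2)
#' dat <- as.data.frame(simulate_cohort(cfg, seed = 7))
#' fit <- pseudoglm(Event(time, status) ~ z1, dat, time = 1, cause = 1)
#' summary(fit)
#' @export
pseudoglm <- function(formula, data, time, cause = 1,
                      method = c("ij", "jackknife", "ij-truncated", "ipcw"),
                      link = c("identity", "log", "logit", "cloglog"),
                      vcov = "hw", boot = 200L, seed = NULL,
                      algorithm = c("efficient", "naive"), ...) {
  cl <- match.call()
  method <- match.arg(method)
  link <- match.arg(link)
  algorithm <- match.arg(algorithm)
  vcov <- match.arg(vcov, c("hw", "sigma", "boot"), several.ok = TRUE)
  mf <- stats::model.frame(formula, data)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  ets <- response_to_ets(y)
  X <- stats::model.matrix(mt, mf)
  smp <- event_sample(ets$time, ets$status, entry = ets$entry,
                      covariates = X)
  ps <- pseudo_obs(smp, time = time, cause = cause, method = method,
                   algorithm = algorithm)
  sol <- ee_solve(ps$values, X, ps$weights, link, ...)
  out <- list(coefficients = sol$beta, iterations = sol$iterations,
              converged = sol$converged,
              vcov_hw = ee_sandwich(sol),
              vcov_sigma = NULL, vcov_boot = NULL,
              fitted.values = sol$mu, linear.predictors = sol$eta,
              pseudo = ps, sample = smp, link = link, method = method,
              time = time, cause = ps$cause, n = smp$n,
              terms = mt, xlevels = stats::.getXlevels(mt, mf),
              call = cl)
  dimnames(out$vcov_hw) <- list(names(sol$beta), names(sol$beta))
  class(out) <- "pseudoglm"
  if ("sigma" %in% vcov)
    out$vcov_sigma <- asymptotic_vcov(out)
  if ("boot" %in% vcov)
    out$vcov_boot <- bootstrap_vcov(smp, time = time, cause = cause,
                                    method = method, link = link, X = X,
                                    B = boot, seed = seed)
  out
}

#' @export
print.pseudoglm <- function(x, digits = 4, ...) {
  cat("Pseudo-observation regression (", x$method, " pseudo-observations)\n",
      sep = "")
  cat("  target: ",
      if (identical(x$cause, "survival")) "P(T > t)" else
        paste0("P(T <= t, cause = ", x$cause, ")"),
      " at t = ", format(x$time), ";  link = ", x$link,
      ";  n = ", x$n, "\n", sep = "")
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  if (!x$converged) cat("\nWARNING: estimating equation did not converge\n")
  invisible(x)
}

#' @export
coef.pseudoglm <- function(object, ...) object$coefficients

#' @export
vcov.pseudoglm <- function(object, type = c("hw", "sigma", "boot"), ...) {
  type <- match.arg(type)
  v <- object[[paste0("vcov_", type)]]
  if (is.null(v))
    stop("variance '", type, "' was not computed; refit with vcov = \"",
         type, "\"")
  v
}

#' @export
nobs.pseudoglm <- function(object, ...) object$n

#' @export
summary.pseudoglm <- function(object, type = "hw", level = 0.95, ...) {
  v <- vcov(object, type = type)
  est <- object$coefficients
  se <- sqrt(diag(v))
  z <- est / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  tab <- cbind(Estimate = est, `Std. Error` = se,
               Lower = est - q * se, Upper = est + q * se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, vcov_type = type, level = level,
                 object = object),
            class = "summary.pseudoglm")
}

#' @export
print.summary.pseudoglm <- function(x, digits = 4, ...) {
  o <- x$object
  print(o)
  cat("\nInference (", x$vcov_type, " variance, ",
      format(100 * x$level), "% CI):\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
confint.pseudoglm <- function(object, parm, level = 0.95,
                              type = "hw", ...) {
  v <- vcov(object, type = type)
  est <- object$coefficients
  se <- sqrt(diag(v))
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - q * se, est + q * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2,
                                       1 - (1 - level) / 2)), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.pseudoglm <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "link") eta else stats::make.link(object$link)$linkinv(eta)
}

#' @export
residuals.pseudoglm <- function(object, ...) {
  object$pseudo$values - object$fitted.values
}
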