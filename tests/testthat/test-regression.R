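# Estimating-equation layer: closed forms, links, sandwich and the
# second-order variance machinery.

test_that("identity-link fits reduce to the classical closed forms", {
  s <- scenario1_sample(n = 300, seed = 2)
  dat <- as.data.frame(s)
  f0 <- pseudoglm(Event(time, status) ~ 1, dat, time = 1)
  expect_equal(unname(coef(f0)), f0$pseudo$base_estimate, tolerance = 1e-12)

  f1 <- pseudoglm(Event(time, status) ~ z1, dat, time = 1)
  pv <- f1$pseudo$values
  expect_equal(unname(coef(f1)[2]),
               mean(pv[dat$z1 == 1]) - mean(pv[dat$z1 == 0]),
               tolerance = 1e-12)

  # closed form equals the iterative solution
  X <- cbind(1, dat$z1)
  it <- ijpseudo:::ee_solve(pv, X, rep(1, s$n), "identity",
                            closed_form = FALSE)
  expect_equal(unname(coef(f1)), unname(it$beta), tolerance = 1e-10)
})

test_that("all links solve the estimating equation to tolerance", {
  s <- scenario1_sample(n = 400, seed = 3)
  dat <- as.data.frame(s)
  for (lk in c("identity", "log", "logit", "cloglog")) {
    f <- pseudoglm(Event(time, status) ~ z1, dat, time = 1, link = lk)
    expect_true(f$converged)
    lkf <- stats::make.link(lk)
    me <- lkf$mu.eta(f$linear.predictors)
    X <- cbind(1, dat$z1)
    U <- colSums(X * (me * (f$pseudo$values - f$fitted.values)))
    expect_lt(sqrt(sum(U^2)), 1e-8)
    # predictions on new data follow the inverse link
    nd <- data.frame(z1 = c(0, 1))
    expect_equal(unname(predict(f, nd, type = "response")),
                 lkf$linkinv(cumsum(unname(coef(f)))), tolerance = 1e-10)
  }
  expect_error(pseudoglm(Event(time, status) ~ z1 + I(z1 * 1), dat,
                         time = 1), "full rank")
})

test_that("sandwich variance matches the textbook OLS sandwich and scales", {
  s <- scenario1_sample(n = 250, seed = 5)
  dat <- as.data.frame(s)
  f <- pseudoglm(Event(time, status) ~ z1, dat, time = 1)
  X <- cbind(1, dat$z1)
  pv <- f$pseudo$values
  r <- pv - X %*% solve(crossprod(X), crossprod(X, pv))
  Vtext <- solve(crossprod(X)) %*% crossprod(X * as.numeric(r)) %*%
    solve(crossprod(X))
  expect_equal(unname(vcov(f)), unname(Vtext), tolerance = 1e-12)

  # scaling all pseudo-observations by c scales the variance by c^2
  sol <- ijpseudo:::ee_solve(3 * pv, X, rep(1, s$n), "identity")
  expect_equal(ijpseudo:::ee_sandwich(sol), 9 * Vtext, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("second-order influence is symmetric, centred, and vanishes
          without censoring", {
  s <- random_sample(n = 60, seed = 8, p_cens = 0.35)
  a <- second_order_influence(s, 1, 1, 5, 17)
  b <- second_order_influence(s, 1, 1, 17, 5)
  expect_equal(a, b, tolerance = 1e-7)

  s0 <- random_sample(n = 50, seed = 9, p_cens = 0)
  vals <- vapply(1:50, function(k) second_order_influence(s0, 1, 1, k, 7),
                 numeric(1))
  expect_lt(max(abs(vals)), 1e-6)

  # empirical analogue of E(phidd(X, x)) = 0 at the empirical distribution
  m <- mean(vapply(1:60, function(k) second_order_influence(s, 1, 1, k, 11),
                   numeric(1)))
  expect_lt(abs(m), 1e-6)
})

test_that("asymptotic variance equals the sandwich without censoring and is
          dominated by it under heavy censoring", {
  s0 <- simulate_cohort(scenario_config(n = 200, p_oc = 0), seed = 12)
  d0 <- as.data.frame(s0)
  f0 <- pseudoglm(Event(time, status) ~ z1, d0, time = 1,
                  vcov = c("hw", "sigma"))
  expect_equal(f0$vcov_sigma, f0$vcov_hw, tolerance = 1e-5)

  # strong effect + heavy censoring: HW exceeds the corrected variance as a
  # quadratic form (the documented upward bias of the sandwich)
  s1 <- simulate_cohort(scenario_config(n = 2000, p_oc = 0.5, beta1 = 0.55),
                        seed = 13)
  d1 <- as.data.frame(s1)
  f1 <- pseudoglm(Event(time, status) ~ z1, d1, time = 1,
                  vcov = c("hw", "sigma"))
  ev <- eigen(f1$vcov_hw - f1$vcov_sigma, symmetric = TRUE,
              only.values = TRUE)$values
  # positive semi-definite up to finite-difference noise in the h1 term
  expect_gt(min(ev), -1e-4 * max(diag(f1$vcov_hw)))
  expect_gt(f1$vcov_hw[2, 2], f1$vcov_sigma[2, 2])
})

test_that("bootstrap variance is deterministic given a seed and vanishes for
          a degenerate sample", {
  s <- scenario1_sample(n = 120, seed = 14)
  X <- cbind(1, s$covariates[, 1])
  b1 <- bootstrap_vcov(s, 1, 1, X = X, B = 25, seed = 99)
  b2 <- bootstrap_vcov(s, 1, 1, X = X, B = 25, seed = 99)
  expect_identical(b1[, ], b2[, ])

  sd0 <- event_sample(rep(2, 30), rep(1, 30), n_causes = 1)
  bd <- bootstrap_vcov(sd0, 1, 1, X = matrix(1, 30, 1), B = 10, seed = 1)
  expect_equal(max(abs(bd[, ])), 0)
  expect_error(bootstrap_vcov(s, 1, 1, X = X, B = 1), "at least 2")
})

test_that("bootstrap and asymptotic variances agree within Monte-Carlo
          error on moderate samples", {
  s <- simulate_cohort(scenario_config(n = 500, p_oc = 0.3, beta1 = 0.3),
                       seed = 15)
  dat <- as.data.frame(s)
  f <- pseudoglm(Event(time, status) ~ z1, dat, time = 1,
                 vcov = c("hw", "sigma", "boot"), boot = 150, seed = 7)
  se_sig <- sqrt(f$vcov_sigma[2, 2])
  se_boot <- sqrt(f$vcov_boot[2, 2])
  expect_lt(abs(se_boot - se_sig) / se_sig, 0.2)
})
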