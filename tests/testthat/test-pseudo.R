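# Pseudo-observation properties: exact mean identity, no-censoring collapse,
# jack-knife algorithms, martingale construction, weight-derivative form,
# truncation modification and sampling weights.

test_that("IJ pseudo-observations average exactly to the base estimate", {
  for (seed in 1:8) {
    s <- random_sample(n = 50, seed = seed, ties = seed %% 2 == 0)
    p <- pseudo_obs(s, time = 1, cause = 1, method = "ij")
    expect_equal(mean(p$values), p$base_estimate, tolerance = 1e-12)
    ps <- pseudo_obs(s, time = 1, cause = "survival", method = "ij")
    expect_equal(mean(ps$values), ps$base_estimate, tolerance = 1e-12)
  }
})

test_that("without censoring every method returns the plain indicator", {
  s <- simulate_cohort(scenario_config(n = 150, p_oc = 0), seed = 9)
  ind <- as.numeric(s$time <= 1 & s$status == 1)
  for (m in c("ij", "jackknife", "ipcw")) {
    p <- pseudo_obs(s, time = 1, cause = 1, method = m)
    expect_equal(p$values, ind, tolerance = 1e-12)
  }
  psurv <- pseudo_obs(s, time = 1, cause = "survival", method = "ij")
  expect_equal(psurv$values, as.numeric(s$time > 1), tolerance = 1e-12)
})

test_that("survival pseudo-observations complement the single-cause CIF", {
  tt <- c(0.2, 0.5, 0.9, 1.4, 2.2, 0.7, 1.1)
  st <- c(1, 0, 1, 0, 1, 1, 0)
  s <- event_sample(tt, st, n_causes = 1)
  pc <- pseudo_obs(s, time = 1, cause = 1, method = "ij")
  psv <- pseudo_obs(s, time = 1, cause = "survival", method = "ij")
  expect_equal(psv$values, 1 - pc$values, tolerance = 1e-12)
})

test_that("efficient and naive jack-knife agree on random tied samples", {
  for (seed in 1:12) {
    s <- random_sample(n = 50, seed = seed, ties = TRUE,
                       truncated = seed > 6)
    pe <- pseudo_obs(s, time = 1, cause = 1, method = "jackknife",
                     algorithm = "efficient")
    pn <- pseudo_obs(s, time = 1, cause = 1, method = "jackknife",
                     algorithm = "naive")
    expect_equal(pe$values, pn$values, tolerance = 1e-12)
  }
  expect_error(pseudo_obs(event_sample(1, 1), 1, 1, method = "jackknife"),
               "at least 2")
})

test_that("per-subject censoring martingales sum to zero at every time", {
  s <- random_sample(n = 60, seed = 4, ties = TRUE)
  tab <- ijpseudo:::risk_tables(s, FALSE)
  ct <- ijpseudo:::curve_tables(tab)
  # sum_i M0i(s) = n [H0(s) - int Hc dLambda0] = 0 at every jump time
  M0sum <- cumsum(tab$c0) - cumsum(tab$Yc * ct$dL0)
  expect_equal(M0sum, rep(0, tab$m), tolerance = 1e-10)
})

test_that("jack-knife and IJ pseudo-observations converge to each other", {
  # sup_i |jk - ij| should shrink at rate faster than 1/sqrt(n):
  # sqrt(n) * max_i |difference| must not grow with n
  gap <- function(n, seed) {
    s <- scenario1_sample(n = n, seed = seed)
    jk <- pseudo_obs(s, 1, 1, method = "jackknife")
    ij <- pseudo_obs(s, 1, 1, method = "ij")
    sqrt(n) * max(abs(jk$values - ij$values))
  }
  g_small <- stats::median(vapply(1:5, function(sd) gap(100, sd), numeric(1)))
  g_large <- stats::median(vapply(1:5, function(sd) gap(1600, sd), numeric(1)))
  expect_lt(g_large, g_small)
})

test_that("the weight-derivative form reproduces the influence form", {
  s <- scenario1_sample(n = 400, seed = 21)
  ij <- pseudo_obs(s, 1, 1, method = "ij")
  wd <- ij_weight_derivative(s, 1, 1)
  expect_lt(max(abs(ij$values - wd$values)), 1e-14)
  expect_equal(wd$base_estimate, ij$base_estimate, tolerance = 1e-14)

  # and agrees with a central finite difference in each subject's weight
  s2 <- random_sample(n = 50, seed = 13)
  tab <- ijpseudo:::risk_tables(s2, FALSE)
  w0 <- rep(1 / s2$n, s2$n)
  g <- ijpseudo:::weighted_cuminc_gradient(tab, s2$status, 1, 1, w0)
  h <- 1e-6
  for (i in c(1, 10, 25)) {
    wp <- w0; wp[i] <- wp[i] + h
    wm <- w0; wm[i] <- wm[i] - h
    fd <- (ijpseudo:::weighted_cuminc(tab, s2$status, 1, 1, wp) -
             ijpseudo:::weighted_cuminc(tab, s2$status, 1, 1, wm)) / (2 * h)
    expect_equal(g$grad[i], fd, tolerance = 1e-5)
  }
})

test_that("truncation-modified IJ reduces to plain IJ at zero entries", {
  s <- random_sample(n = 60, seed = 6)
  sz <- event_sample(s$time, s$status, entry = rep(0, s$n), n_causes = s$d)
  a <- pseudo_obs(s, 1, 1, method = "ij")
  b <- pseudo_obs(sz, 1, 1, method = "ij-truncated")
  expect_equal(b$values, a$values, tolerance = 1e-12)
  expect_equal(b$weights, rep(1, s$n))
})

test_that("sampling weights invert the estimated entry distribution", {
  s <- random_sample(n = 40, seed = 11)
  expect_equal(sampling_weights(s), rep(1, 40))

  # FL puts mass 1/2 below tau = 0.5: the subject observed below tau gets
  # weight 2, subjects with follow-up beyond tau the tau-conditional weight 1
  st <- event_sample(c(0.3, 2, 3), c(1, 1, 1), entry = c(0, 0, 0.5))
  w <- sampling_weights(st)
  expect_equal(w, c(2, 1, 1))

  w2 <- sampling_weights(simulate_truncated_cohort(
    scenario_config(n = 300, p_oc = 0.2, truncation = "mass-uniform"),
    seed = 3))
  expect_true(all(is.finite(w2)) && all(w2 >= 1))
})

test_that("weighted pseudo residuals centre at the truth under truncation", {
  # Monte-Carlo mean of w * (pseudo - F1(t|Z)) over replications is ~ 0
  cfg <- scenario_config(n = 800, p_oc = 0.2, beta1 = 0.4, beta0 = 0.1,
                         p_Z = 0.3, truncation = "mass-uniform")
  set.seed(31)
  ms <- replicate(40, {
    st <- simulate_truncated_cohort(cfg)
    p <- pseudo_obs(st, 1, 1, method = "ij-truncated")
    truth <- cfg$beta0 + cfg$beta1 * st$covariates[, 1]
    mean(p$weights * (p$values - truth))
  })
  expect_lt(abs(mean(ms)), 3 * stats::sd(ms) / sqrt(length(ms)))
})

test_that("unmodified pseudo-observations are biased under truncation in the
          documented direction", {
  # conditional-mean distortion by P(T >= L) / P(T >= L | Z): with a rare
  # exposure (p_Z = 0.2) the risk difference is overestimated, with a common
  # exposure (p_Z = 0.8) underestimated
  run_bias <- function(p_Z) {
    cfg <- scenario_config(n = 4000, p_oc = 0.2, beta0 = 0.1, beta1 = 0.4,
                           p_Z = p_Z, truncation = "mass-uniform")
    set.seed(57)
    b1 <- replicate(12, {
      st <- simulate_truncated_cohort(cfg)
      jk <- pseudo_obs(st, 1, 1, method = "jackknife")
      X <- cbind(1, st$covariates[, 1])
      ijpseudo:::ee_solve(jk$values, X, rep(1, st$n), "identity")$beta[2]
    })
    mean(b1) - cfg$beta1
  }
  expect_gt(run_bias(0.2), 0.02)
  expect_lt(run_bias(0.8), -0.02)
})
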