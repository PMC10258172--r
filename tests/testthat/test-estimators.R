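# Product-limit / IPCW functionals: hazards, Kaplan-Meier, Aalen-Johansen,
# the entry-time distribution and the rho reconstruction.

test_that("cumulative hazard matches hand counting-process computations", {
  # one censoring at 2 among n = 2 (other subject has an event at 3)
  s <- event_sample(c(2, 3), c(0, 1))
  cs <- counting_summary(s)
  L0 <- cumulative_hazard(cs$counts[["0"]],
                          at_risk_at(cs, cs$table$u, "censoring"))
  expect_equal(step_eval(L0, 2), 0.5)

  # no censorings at all
  s2 <- event_sample(c(1, 2), c(1, 1))
  cs2 <- counting_summary(s2)
  L0b <- cumulative_hazard(cs2$counts[["0"]],
                           at_risk_at(cs2, cs2$table$u, "censoring"))
  expect_equal(step_eval(L0b, 5), 0)

  # single subject, event at 1: full risk set, hazard increment 1
  s3 <- event_sample(1, 1)
  cs3 <- counting_summary(s3)
  L1 <- cumulative_hazard(cs3$counts[["1"]],
                          at_risk_at(cs3, cs3$table$u, "events"))
  expect_equal(step_eval(L1, 1), 1)

  # zero risk set where the numerator jumps is an error naming the time
  expect_error(cumulative_hazard(step_function(c(1, 2), c(0.5, 1)),
                                 c(1, 0)), "time 2")
})

test_that("product limit transforms hazard increments multiplicatively", {
  L <- step_function(c(1, 2), c(1/3, 1/3 + 1/2), initial_value = 0)
  S <- product_limit(L)
  expect_equal(S$y, c(2/3, 1/3))
  expect_equal(step_eval(S, 0.5), 1)

  Labs <- step_function(1, 1, initial_value = 0)
  expect_equal(product_limit(Labs)$y, 0)
  expect_error(product_limit(step_function(1, 1.5, initial_value = 0)),
               "\\[0, 1\\]")

  # KM with no censoring is the empirical survivor function
  s <- event_sample(c(1, 2, 3), c(1, 1, 1))
  cs <- counting_summary(s)
  Lam <- cumulative_hazard(cs$counts[["1"]],
                           at_risk_at(cs, cs$table$u, "events"))
  S2 <- product_limit(Lam)
  expect_equal(step_eval(S2, c(1, 2, 3)), 1 - (1:3) / 3)
  expect_equal(step_eval(S2, 2, side = "left"), 2/3)
})

test_that("fit_curves reproduces hand and oracle Aalen-Johansen values", {
  # hand IPCW computation on times (1,2,3), statuses (1,0,1)
  s <- event_sample(c(1, 2, 3), c(1, 0, 1), n_causes = 1)
  cv <- fit_curves(counting_summary(s))
  expect_equal(step_eval(cv$F[[1]], 1), 1/3)
  expect_equal(step_eval(cv$F[[1]], 3), 1/3 + 1 / (3 * 0.5))
  expect_equal(step_eval(cv$G, 2), 0.5)

  # without censoring F1 is the empirical subdistribution
  s0 <- random_sample(n = 40, seed = 2, p_cens = 0)
  cv0 <- fit_curves(counting_summary(s0))
  tq <- c(0.5, 1, 2)
  expect_equal(step_eval(cv0$F[[1]], tq),
               vapply(tq, function(v) mean(s0$time <= v & s0$status == 1),
                      numeric(1)))
})

test_that("IPCW-form and hazard-form Aalen-Johansen agree exactly", {
  for (seed in 1:10) {
    for (ties in c(FALSE, TRUE)) {
      s <- random_sample(n = 50, seed = seed, ties = ties)
      cv <- fit_curves(counting_summary(s))
      for (t0 in c(0.4, 1, 2.5)) {
        expect_equal(step_eval(cv$F[[1]], t0), aj_oracle(s, t0, 1),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("cumulative incidences agree with cmprsk on tied data", {
  skip_if_not_installed("cmprsk")
  s <- random_sample(n = 80, seed = 7, ties = TRUE)
  cv <- fit_curves(counting_summary(s))
  ci <- cmprsk::cuminc(s$time, s$status, cencode = 0)
  tp <- cmprsk::timepoints(ci, 1.5)$est
  expect_equal(step_eval(cv$F[[1]], 1.5), unname(tp["1 1", 1]),
               tolerance = 1e-10)
  expect_equal(step_eval(cv$F[[2]], 1.5), unname(tp["1 2", 1]),
               tolerance = 1e-10)
})

test_that("H(s+) = S(s) G(s) and the rho map inverts the curve fit", {
  for (seed in c(1, 4)) {
    for (ties in c(FALSE, TRUE)) {
      s <- random_sample(n = 40, seed = seed, ties = ties)
      cs <- counting_summary(s)
      cv <- fit_curves(cs)
      u <- cs$table$u
      Hplus <- step_eval(cs$at_risk, u)     # right-continuous: H(s+)
      expect_equal(Hplus, step_eval(cv$S, u) * step_eval(cv$G, u),
                   tolerance = 1e-10)
      rm <- rho_map(cv)
      expect_equal(step_eval(rm$at_risk, u), at_risk_at(cs, u),
                   tolerance = 1e-10)
      expect_equal(step_eval(rm$at_risk_cens, u),
                   at_risk_at(cs, u, "censoring"), tolerance = 1e-10)
      for (j in 0:2)
        expect_equal(step_eval(rm$counts[[as.character(j)]], u),
                     step_eval(cs$counts[[as.character(j)]], u),
                     tolerance = 1e-10)
    }
  }
})

test_that("rho map conserves total mass when both survivors reach zero", {
  G <- step_function(c(1, 2), c(0.5, 0))
  F1 <- step_function(c(0.5, 1.5), c(0.4, 1), initial_value = 0)
  rm <- rho_map(G, list(F1))
  total <- step_eval(rm$counts[["0"]], 10) + step_eval(rm$counts[["1"]], 10)
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("reversed-time product limit estimates the entry distribution", {
  # hand value: entries (0, 0.5), both follow-ups beyond tau
  s <- event_sample(c(2, 3), c(1, 1), entry = c(0, 0.5))
  tc <- truncation_cdf(s)
  expect_equal(tc$tau, 0.5)
  expect_equal(step_eval(tc$FL, 0.4), 0.5)
  expect_equal(step_eval(tc$FL, 0.5), 1)

  # degenerate entry law
  s0 <- random_sample(n = 30, seed = 1)
  tc0 <- truncation_cdf(s0)
  expect_equal(step_eval(tc0$FL, c(0, 1, 5)), rep(1, 3))

  # consistency against the true conditional entry law (mass 0.2 at 0,
  # else uniform) on a large truncated cohort
  cfg <- scenario_config(n = 10000, p_oc = 0.2, truncation = "mass-uniform")
  st <- simulate_truncated_cohort(cfg, seed = 42)
  tcl <- truncation_cdf(st)
  tau <- tcl$tau
  sq <- seq(0, tau, length.out = 200)
  truth <- (0.2 + 0.8 * sq) / (0.2 + 0.8 * tau)
  expect_lt(max(abs(step_eval(tcl$FL, sq) - truth)), 0.02)
})

test_that("truncation-adjusted curves match survival::survfit", {
  skip_if_not_installed("survival")
  cfg <- scenario_config(n = 400, p_oc = 0.2, truncation = "mass-uniform")
  st <- simulate_truncated_cohort(cfg, seed = 5)
  cv <- fit_curves(counting_summary(st))
  sf <- survival::survfit(survival::Surv(st$entry, st$time,
                                         factor(st$status, 0:2)) ~ 1)
  ss <- summary(sf, times = 1, extend = TRUE)
  expect_equal(step_eval(cv$F[[1]], 1), ss$pstate[2], tolerance = 1e-10)
  expect_equal(step_eval(cv$F[[2]], 1), ss$pstate[3], tolerance = 1e-10)
})
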