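# Competing-risks cohort generator with linear subdistributions
#   F_1(s | Z) = (beta0 + beta1 Z) s,   F_2(s | Z) = eta s,   s in [0, 1],
# uniform censoring calibrated to a target observed-censoring fraction, and
# optional left truncation (entry-time mass at zero plus a uniform
# component), together with a replication engine for method evaluation.

#' Scenario configuration for the simulation engine
#'
#' A binary exposure `Z ~ Bernoulli(p_Z)`; cause-1 events follow the linear
#' subdistribution `F_1(s|Z) = (beta0 + beta1 Z) s` on `[0, 1]`, the
#' competing event follows `F_2(s|Z) = eta s`; censoring is uniform on
#' `[0, 1/p_c]`, with `p_c` calibrated by [solve_censoring_rate()] so that
#' the observed fraction censored before time 1 equals `p_oc`.  Left
#' truncation (when enabled) draws entry times with probability mass
#' `trunc_mass0` at zero and otherwise uniform on `(0, 1)`, independently of
#' everything else; subjects are retained only when `entry <= time`, and
#' sampling continues until `n` subjects are retained.
#'
#' @param p_Z exposure prevalence `P(Z = 1)`.
#' @param beta0 baseline cause-1 risk at `t = 1` (unexposed).
#' @param beta1 cause-1 risk difference (exposed minus unexposed) at `t = 1`.
#' @param eta competing-event risk at `t = 1`.
#' @param p_oc target observed fraction censored before time 1, in `[0, 1)`.
#' @param n retained sample size.
#' @param truncation `"none"`, or `"mass-uniform"` for the delayed-entry law.
#' @param trunc_mass0 entry-time point mass at zero.
#' @param t analysis time.
#' @return A validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(p_Z = 0.5, beta0 = 0.2, beta1 = 0.2, eta = 0.2,
                            p_oc = 0.2, n = 1000L,
                            truncation = c("none", "mass-uniform"),
                            trunc_mass0 = 0.2, t = 1) {
  truncation <- match.arg(truncation)
  stopifnot(p_Z >= 0, p_Z <= 1, beta0 >= 0, beta1 >= -beta0, eta >= 0,
            p_oc >= 0, p_oc < 1, n >= 1, trunc_mass0 >= 0, trunc_mass0 <= 1)
  if (beta0 + max(beta1, 0) + eta > 1)
    stop("beta0 + beta1 + eta must not exceed 1 (subdistribution masses)")
  structure(list(p_Z = p_Z, beta0 = beta0, beta1 = beta1, eta = eta,
                 p_oc = p_oc, n = as.integer(n), truncation = truncation,
                 trunc_mass0 = trunc_mass0, t = t),
            class = "scenario_config")
}

#' Calibrate the censoring rate to a target observed-censoring fraction
#'
#' Uses the relation `p_oc = P(C < 1) {P(T <= 1)/2 + P(T > 1)}`, which holds
#' because censoring is uniform on `[0, 1/p_c]` and event times are uniform
#' given an event by 1 (so a censoring time before 1 precedes an event with
#' probability 1/2).
#'
#' @param config a [scenario_config()].
#' @return The censoring parameter `p_c = P(C < 1)`.
#' @export
solve_censoring_rate <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  pT1 <- config$p_Z * (config$beta0 + config$beta1 + config$eta) +
    (1 - config$p_Z) * (config$beta0 + config$eta)
  p_c <- config$p_oc / (pT1 / 2 + 1 - pT1)
  if (p_c > 1)
    stop("target observed-censoring fraction ", config$p_oc,
         " is unattainable (implied P(C < 1) = ", format(p_c), " > 1)")
  p_c
}

# raw draws (Z, T, Delta, C, observed time/status) for nn subjects
draw_cohort <- function(config, nn, p_c, admin_time = 1.01) {
  z <- stats::rbinom(nn, 1L, config$p_Z)
  p1 <- config$beta0 + config$beta1 * z
  uu <- stats::runif(nn)
  cause <- ifelse(uu < p1, 1L, ifelse(uu < p1 + config$eta, 2L, 0L))
  tev <- stats::runif(nn)                # event time given an event by 1
  tev[cause == 0L] <- Inf                # event-free by time 1
  cc <- if (p_c > 0) stats::runif(nn, 0, 1 / p_c) else rep(Inf, nn)
  tt <- pmin(tev, cc)
  dd <- ifelse(tev <= cc, cause, 0L)
  # without censoring, event-free subjects carry an administrative censoring
  # time just beyond the analysis horizon (only t <= 1 is ever analyzed)
  inf_obs <- !is.finite(tt)
  tt[inf_obs] <- admin_time
  dd[inf_obs] <- 0L
  list(z = z, time = tt, status = as.integer(dd))
}

#' Simulate an untruncated cohort
#'
#' @param config a [scenario_config()] (its `truncation` field is ignored).
#' @param seed optional integer seed.
#' @return An [event_sample()] with the exposure as covariate column `z1`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  p_c <- solve_censoring_rate(config)
  d <- draw_cohort(config, config$n, p_c)
  event_sample(d$time, d$status,
               covariates = matrix(d$z, ncol = 1,
                                   dimnames = list(NULL, "z1")),
               n_causes = 2L)
}

#' Simulate a left-truncated cohort
#'
#' Draws `(Z, T, Delta, C)` as in [simulate_cohort()] and an independent
#' entry time `L` (point mass `trunc_mass0` at zero, otherwise uniform on
#' `(0, 1)`); retains a subject when `L <= min(T, C)` and repeats until `n`
#' subjects are retained.
#'
#' @inheritParams simulate_cohort
#' @return An [event_sample()] with positive entry times.
#' @export
simulate_truncated_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  if (config$truncation == "none")
    return(simulate_cohort(config))
  p_c <- solve_censoring_rate(config)
  n <- config$n
  acc <- list(z = integer(0), time = numeric(0), status = integer(0),
              entry = numeric(0))
  tried <- 0L
  while (length(acc$time) < n) {
    nn <- max(n, ceiling(1.5 * (n - length(acc$time))))
    d <- draw_cohort(config, nn, p_c)
    at0 <- stats::runif(nn) < config$trunc_mass0
    L <- ifelse(at0, 0, stats::runif(nn))
    keep <- L <= d$time
    tried <- tried + nn
    acc$z <- c(acc$z, d$z[keep])
    acc$time <- c(acc$time, d$time[keep])
    acc$status <- c(acc$status, d$status[keep])
    acc$entry <- c(acc$entry, L[keep])
    if (tried >= 100L * n && length(acc$time) < 0.01 * tried)
      stop("retention probability below 1%; pathological configuration")
  }
  idx <- seq_len(n)
  event_sample(acc$time[idx], acc$status[idx], entry = acc$entry[idx],
               covariates = matrix(acc$z[idx], ncol = 1,
                                   dimnames = list(NULL, "z1")),
               n_causes = 2L)
}

#' @export
as.data.frame.event_sample <- function(x, ...) {
  out <- data.frame(id = if (is.null(x$id)) seq_len(x$n) else x$id,
                    entry = x$entry, time = x$time, status = x$status)
  if (!is.null(x$covariates)) {
    cv <- as.data.frame(x$covariates)
    if (is.null(colnames(x$covariates)))
      names(cv) <- paste0("z", seq_len(ncol(cv)))
    out <- cbind(out, cv)
  }
  out
}

#' Default parameter grids for the five simulation scenarios
#'
#' Scenario 1: a single computational-speed setting; Scenario 2: medium and
#' large sample properties without truncation; Scenario 3: efficiency versus
#' pure inverse-probability-of-censoring weighting at `n = 10000`;
#' Scenario 4: the truncation-modified method under delayed entry;
#' Scenario 5: bias of the unmodified jack-knife versus the modified method
#' under delayed entry at `n = 10000`.
#'
#' @param scenario integer 1 to 5.
#' @return A data frame with one row per cell (columns `p_Z`, `beta0`,
#'   `beta1`, `eta`, `p_oc`, `n`, `truncation`).
#' @export
scenario_cells <- function(scenario) {
  scenario <- as.integer(scenario)
  base <- list(p_Z = 0.5, beta0 = 0.2, eta = 0.2)
  grid <- switch(as.character(scenario),
    "1" = data.frame(p_Z = 0.5, beta0 = 0.2, beta1 = 0.2, eta = 0.2,
                     p_oc = 0.2, n = 1000L, truncation = "none"),
    "2" = {
      g1 <- expand.grid(p_oc = c(0.2, 0.5), beta1 = 0.10,
                        n = c(100L, 200L, 500L, 1000L))
      g2 <- expand.grid(p_oc = c(0.2, 0.5), beta1 = 0.55,
                        n = c(200L, 400L, 1000L, 2000L))
      g <- rbind(g1, g2)
      data.frame(p_Z = base$p_Z, beta0 = base$beta0, beta1 = g$beta1,
                 eta = base$eta, p_oc = g$p_oc, n = g$n,
                 truncation = "none")
    },
    "3" = {
      g <- expand.grid(p_oc = c(0.1, 0.3, 0.6), beta1 = c(0.05, 0.2, 0.5),
                       beta0 = c(0.1, 0.2))
      data.frame(p_Z = 0.5, beta0 = g$beta0, beta1 = g$beta1, eta = 0.2,
                 p_oc = g$p_oc, n = 10000L, truncation = "none")
    },
    "4" = {
      g1 <- expand.grid(p_oc = c(0.2, 0.5), beta1 = 0.10,
                        n = c(100L, 200L, 500L, 1000L))
      g2 <- expand.grid(p_oc = c(0.2, 0.5), beta1 = 0.55,
                        n = c(200L, 400L, 1000L, 2000L))
      g <- rbind(g1, g2)
      data.frame(p_Z = 0.5, beta0 = 0.2, beta1 = g$beta1, eta = 0.2,
                 p_oc = g$p_oc, n = g$n, truncation = "mass-uniform")
    },
    "5" = {
      g <- expand.grid(p_Z = c(0.2, 0.5, 0.8), beta1 = c(0.2, 0.4, 0.6),
                       beta0 = c(0.1, 0.2))
      data.frame(p_Z = g$p_Z, beta0 = g$beta0, beta1 = g$beta1, eta = 0.2,
                 p_oc = 0.2, n = 10000L, truncation = "mass-uniform")
    },
    stop("'scenario' must be 1..5"))
  grid
}

#' Run a simulation experiment over a grid of scenario cells
#'
#' For each cell, simulates `reps` cohorts, computes pseudo-observations by
#' each requested method, fits the identity-link model with the binary
#' exposure, and aggregates: average estimate, bias, `sqrt(n)` times the
#' Monte-Carlo standard deviation of the risk-difference estimate, `sqrt(n)`
#' times the average Huber--White standard error, and (when both `"ij"` and
#' `"ipcw"` are run) the relative efficiency `SD_ij / SD_ipcw`.  Monte-Carlo
#' standard errors accompany every summary.
#'
#' @param cells data frame as produced by [scenario_cells()], or a
#'   [scenario_config()] for a single cell.
#' @param methods character vector from `"ij"`, `"jackknife"`,
#'   `"ij-truncated"`, `"ipcw"`.
#' @param reps replications per cell.
#' @param seed integer seed; each cell uses `seed + cell index` so cells are
#'   reproducible independently.
#' @param t analysis time.
#' @param progress print one line per completed cell.
#' @return A data frame of class `"scenario_result"` with one row per
#'   (cell, method).
#' @export
run_scenario <- function(cells, methods = "ij", reps = 100L, seed = 1L,
                         t = 1, progress = FALSE) {
  if (inherits(cells, "scenario_config"))
    cells <- data.frame(p_Z = cells$p_Z, beta0 = cells$beta0,
                        beta1 = cells$beta1, eta = cells$eta,
                        p_oc = cells$p_oc, n = cells$n,
                        truncation = cells$truncation)
  methods <- match.arg(methods, c("ij", "jackknife", "ij-truncated", "ipcw"),
                       several.ok = TRUE)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    cfg <- scenario_config(p_Z = cell$p_Z, beta0 = cell$beta0,
                           beta1 = cell$beta1, eta = cell$eta,
                           p_oc = cell$p_oc, n = cell$n,
                           truncation = as.character(cell$truncation),
                           t = t)
    set.seed(seed + ci)
    est <- matrix(NA_real_, reps, length(methods),
                  dimnames = list(NULL, methods))
    sehw <- est
    fails <- 0L
    for (r in seq_len(reps)) {
      smp <- tryCatch({
        if (cfg$truncation == "none") simulate_cohort(cfg)
        else simulate_truncated_cohort(cfg)
      }, error = function(e) NULL)
      if (is.null(smp)) { fails <- fails + 1L; next }
      X <- cbind(`(Intercept)` = 1, z1 = smp$covariates[, 1L])
      for (mth in methods) {
        res <- tryCatch({
          ps <- pseudo_obs(smp, time = t, cause = 1, method = mth)
          sol <- ee_solve(ps$values, X, ps$weights, "identity")
          c(sol$beta[2L], sqrt(diag(ee_sandwich(sol)))[2L])
        }, error = function(e) c(NA_real_, NA_real_))
        est[r, mth] <- res[1L]
        sehw[r, mth] <- res[2L]
      }
    }
    if (fails > 0.1 * reps)
      stop("more than 10% replicate failures in cell ", ci)
    for (mth in methods) {
      b <- est[, mth]
      se <- sehw[, mth]
      ok <- sum(!is.na(b))
      sdb <- stats::sd(b, na.rm = TRUE)
      row <- data.frame(cell = ci, method = mth, p_Z = cfg$p_Z,
                        beta0 = cfg$beta0, beta1 = cfg$beta1,
                        eta = cfg$eta, p_oc = cfg$p_oc, n = cfg$n,
                        truncation = cfg$truncation, reps = ok,
                        ave_beta1 = mean(b, na.rm = TRUE),
                        bias = mean(b, na.rm = TRUE) - cfg$beta1,
                        sd_rd = sdb,
                        sqrt_n_sd = sqrt(cfg$n) * sdb,
                        sqrt_n_se_hw = sqrt(cfg$n) * mean(se, na.rm = TRUE),
                        mcse_ave = sdb / sqrt(ok),
                        mcse_sd = sdb / sqrt(2 * (ok - 1)),
                        mcse_se_hw = stats::sd(se, na.rm = TRUE) / sqrt(ok),
                        efficiency = NA_real_)
      out[[length(out) + 1L]] <- row
    }
    if (all(c("ij", "ipcw") %in% methods)) {
      k <- length(out)
      iij <- which(vapply(out, function(r)
        r$cell == ci && r$method == "ij", logical(1)))
      iip <- which(vapply(out, function(r)
        r$cell == ci && r$method == "ipcw", logical(1)))
      eff <- stats::sd(est[, "ij"], na.rm = TRUE) /
        stats::sd(est[, "ipcw"], na.rm = TRUE)
      out[[iij]]$efficiency <- eff
      out[[iip]]$efficiency <- eff
    }
    if (progress)
      message(sprintf("cell %d/%d done (n = %d, p_oc = %.2f, beta1 = %.2f)",
                      ci, nrow(cells), cfg$n, cfg$p_oc, cfg$beta1))
  }
  res <- do.call(rbind, out)
  class(res) <- c("scenario_result", class(res))
  attr(res, "seed") <- seed
  res
}
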