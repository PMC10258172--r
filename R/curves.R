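# Product-limit and IPCW-form functionals of the counting-process summary:
# censoring survival G, event survival S, Aalen-Johansen cumulative
# incidences F_j, cumulative hazards, and the reversed-time product-limit
# estimator of the entry-time distribution.

#' Nelson--Aalen cumulative hazard from counting curves
#'
#' Integrates `d(numerator) / at_risk` over the jumps of the numerator:
#' the censoring hazard uses the censoring at-risk curve evaluated at each
#' jump, event hazards use the event at-risk curve.
#'
#' @param numerator a non-decreasing [step_function()] of cumulative counts
#'   (e.g. the censoring count proportion `H0`).
#' @param at_risk a [step_function()] of at-risk proportions evaluated at the
#'   jump times of `numerator` (use [counting_summary()] components, whose
#'   stored values at jump times follow the events-before-censoring tie
#'   convention via [at_risk_at()]); alternatively a numeric vector of at-risk
#'   values, one per jump of `numerator`.
#'
#' @return A [step_function()]: the cumulative hazard, 0 before the first jump.
#' @export
cumulative_hazard <- function(numerator, at_risk) {
  inc <- step_increments(numerator)
  risk <- if (is.numeric(at_risk)) {
    if (length(at_risk) != length(numerator$x))
      stop("'at_risk' must supply one value per jump of 'numerator'")
    at_risk
  } else {
    step_eval(at_risk, numerator$x)
  }
  need <- inc > 0
  if (any(need & risk <= 0)) {
    bad <- numerator$x[which(need & risk <= 0)[1L]]
    stop("zero at-risk set at time ", format(bad),
         " where the numerator jumps; cumulative hazard undefined")
  }
  dL <- ifelse(need, inc / risk, 0)
  step_function(numerator$x, cumsum(dL), initial_value = 0)
}

#' Product-limit (product-integral) transform of a cumulative hazard
#'
#' @param Lambda a non-decreasing [step_function()] with increments in
#'   `[0, 1]`.
#' @return A [step_function()]: `S(s) = prod_{u <= s} (1 - dLambda(u))`,
#'   equal to 1 before the first jump.
#' @export
product_limit <- function(Lambda) {
  dL <- step_increments(Lambda)
  if (any(dL < -1e-12) || any(dL > 1 + 1e-12))
    stop("cumulative-hazard increments must lie in [0, 1]")
  dL <- pmin(pmax(dL, 0), 1)
  step_function(Lambda$x, cumprod(1 - dL), initial_value = 1)
}

# Core curve computation on a risk table.  Untruncated samples use the IPCW
# form F_j(s) = int dH_j(u) / G(u-); truncation-adjusted samples use the
# hazard-based Aalen-Johansen form (the IPCW form is not consistent under
# delayed entry).  Under the events-before-censoring tie convention the two
# forms coincide exactly without truncation.  S = 1 - sum_j F_j throughout.
curve_tables <- function(tab, check_to = NULL) {
  m <- tab$m
  n <- tab$n
  dL0 <- ifelse(tab$c0 > 0, tab$c0 / tab$Yc, 0)  # c0 <= Yc always
  G <- cumprod(1 - dL0)
  Glag <- c(1, G[-m])
  Fj <- matrix(0, m, tab$d)
  if (tab$truncated) {
    dLj <- tab$nd / tab$Y            # Y >= D + c0 >= 1 at every jump time
    Spl <- cumprod(1 - tab$D / tab$Y)
    Splag <- c(1, Spl[-m])
    for (j in seq_len(tab$d)) Fj[, j] <- cumsum(Splag * dLj[, j])
  } else {
    if (!is.null(check_to)) {
      bad <- Glag <= 0 & tab$D > 0 & tab$u <= check_to
      if (any(bad))
        stop("censoring survival reached zero before event time ",
             format(tab$u[which(bad)[1L]]),
             "; cumulative incidence not estimable there")
    }
    w <- ifelse(Glag > 0, 1 / (n * Glag), 0)
    for (j in seq_len(tab$d)) Fj[, j] <- cumsum(tab$nd[, j] * w)
  }
  S <- 1 - .rowSums(Fj, m, tab$d)
  list(u = tab$u, dL0 = dL0, G = G, Glag = Glag, Fj = Fj, S = S)
}

#' Estimated curves from a counting summary
#'
#' Computes the censoring Kaplan--Meier `G`, the Aalen--Johansen cumulative
#' incidences `F_j` (IPCW form without truncation, hazard-based product-limit
#' form with truncation-adjusted risk sets), the event survival
#' `S = 1 - sum_j F_j`, and the cumulative censoring and event hazards.
#'
#' @param summary a [counting_summary()].
#' @return An object of class `"curve_set"` with step functions `G`, `S`,
#'   `F` (list over causes), `Lambda0` and `LambdaJ` (list over causes).
#' @examples
#' s <- event_sample(c(1, 2, 3), c(1, 0, 1))
#' cv <- fit_curves(counting_summary(s))
#' step_eval(cv$F[[1]], 3)   # Aalen-Johansen estimate at t = 3
#' @export
fit_curves <- function(summary) {
  stopifnot(inherits(summary, "counting_summary"))
  tab <- summary$table
  ct <- curve_tables(tab, check_to = max(tab$u))
  Fl <- lapply(seq_len(tab$d), function(j)
    step_function(tab$u, ct$Fj[, j], initial_value = 0))
  LamJ <- lapply(seq_len(tab$d), function(j)
    step_function(tab$u, cumsum(tab$nd[, j] / tab$Y), initial_value = 0))
  structure(list(G = step_function(tab$u, ct$G, initial_value = 1),
                 S = step_function(tab$u, ct$S, initial_value = 1),
                 F = Fl,
                 Lambda0 = step_function(tab$u, cumsum(ct$dL0),
                                         initial_value = 0),
                 LambdaJ = LamJ,
                 truncation_adjusted = tab$truncated,
                 table = tab),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat("Estimated curves (G, S, F_1..F_", length(x$F), ") on ",
      x$table$m, " unique times",
      if (x$truncation_adjusted) ", truncation-adjusted" else "", "\n",
      sep = "")
  invisible(x)
}

#' Reversed-time product-limit estimator of the entry-time distribution
#'
#' Estimates `F_L(s) = P(L <= s | L <= tau)` for `tau` the largest observed
#' entry time, by the product-limit estimator on the reversed time scale:
#' `F_L(s) = prod_{v > s} (1 - dN_L(v) / H(v))`, where `N_L` counts entries
#' and `H(v)` is the truncation-adjusted at-risk proportion.  The estimate is
#' right-continuous, non-decreasing and satisfies `F_L(tau) = 1`.
#'
#' @param sample an [event_sample()]; entry times may be all zero, in which
#'   case `F_L` is identically 1.
#' @return An object of class `"truncation_cdf"` with elements `FL` (a
#'   [step_function()]) and `tau`.
#' @export
truncation_cdf <- function(sample) {
  stopifnot(inherits(sample, "event_sample"))
  v <- sort(unique(sample$entry))
  K <- length(v)
  dL <- tabulate(match(sample$entry, v), K)
  # risk set on the reversed scale: #{L <= v <= T}
  R <- findInterval(v, sort(sample$entry)) -
    findInterval(v, sort(sample$time), left.open = TRUE)
  if (any(R <= 0))
    stop("empty risk set at entry time ", format(v[which(R <= 0)[1L]]))
  fac <- 1 - dL / R
  # F_L at v_k is the product of factors at entry times strictly above v_k
  rp <- rev(cumprod(rev(fac)))          # rp[k] = prod_{j >= k} fac_j
  vals <- c(rp[-1L], 1)
  structure(list(FL = step_function(v, vals, initial_value = rp[1L]),
                 tau = v[K]),
            class = "truncation_cdf")
}

#' @export
print.truncation_cdf <- function(x, ...) {
  cat("Reversed-time product-limit estimate of the entry distribution,",
      "tau =", format(x$tau), "\n")
  invisible(x)
}

#' Reconstruct counting curves from (G, F) --- the rho mapping
#'
#' Maps the estimated censoring survival and cumulative incidences back to
#' the counting-process scale:
#' `H(s) = S(s-) G(s-)`, `Hc(s) = S(s) G(s-)`,
#' `H0(s) = int_0^s S(u) d(1 - G(u))` and
#' `Hj(s) = int_0^s G(u-) dF_j(u)`, with `S = 1 - sum_j F_j`.
#' Applied to truncation-adjusted curves this produces the estimate of the
#' *untruncated* counting-process expectation that the modified
#' pseudo-observations are evaluated at.
#'
#' @param G censoring survival [step_function()], or a `"curve_set"` from
#'   [fit_curves()] (in which case `F` is taken from it).
#' @param F list of cumulative-incidence step functions (one per cause).
#' @return A list of step functions `at_risk` (`H`), `at_risk_cens` (`Hc`) and
#'   `counts` (`H_0..H_d`), all on the pooled jump-time grid.  `at_risk` and
#'   `at_risk_cens` store the value *at* each grid time (they are not
#'   right-continuous).
#' @export
rho_map <- function(G, F = NULL) {
  if (inherits(G, "curve_set")) {
    F <- G$F
    G <- G$G
  }
  if (!length(F)) stop("'F' must contain at least one cumulative incidence")
  grid <- sort(unique(c(G$x, unlist(lapply(F, `[[`, "x")))))
  Gv <- step_eval(G, grid)
  Gl <- step_eval(G, grid, side = "left")
  Fv <- sapply(F, step_eval, s = grid)
  Fv <- matrix(Fv, nrow = length(grid))
  Fl <- sapply(F, step_eval, s = grid, side = "left")
  Fl <- matrix(Fl, nrow = length(grid))
  Sv <- 1 - rowSums(Fv)
  Sl <- 1 - rowSums(Fl)
  H <- Sl * Gl
  Hc <- Sv * Gl
  dH0 <- Sv * (Gl - Gv)
  counts <- vector("list", ncol(Fv) + 1L)
  names(counts) <- as.character(0:ncol(Fv))
  counts[["0"]] <- step_function(grid, cumsum(dH0), initial_value = 0)
  for (j in seq_len(ncol(Fv)))
    counts[[as.character(j)]] <-
      step_function(grid, cumsum(Gl * (Fv[, j] - Fl[, j])), initial_value = 0)
  list(at_risk = step_function(grid, H, initial_value = 1),
       at_risk_cens = step_function(grid, Hc, initial_value = 1),
       counts = counts)
}

#' Export estimated curves as delimited text
#'
#' Writes `(time, value)` pairs for each curve of a [fit_curves()] result
#' (and optionally the entry-time distribution) to a comma-delimited file for
#' external plotting.
#'
#' @param curves a `"curve_set"`, or a named list of [step_function()]s.
#' @param path output file path.
#' @return Invisibly, the exported data frame.
#' @export
export_curves <- function(curves, path) {
  fl <- if (inherits(curves, "curve_set")) {
    c(list(G = curves$G, S = curves$S),
      stats::setNames(curves$F, paste0("F", seq_along(curves$F))))
  } else curves
  rows <- lapply(names(fl), function(nm) {
    f <- fl[[nm]]
    data.frame(curve = nm, time = c(0, f$x), value = c(f$y0, f$y))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
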