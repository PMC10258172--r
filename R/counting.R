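# Internal per-unique-time tables underlying every estimator.
#
# For a sample of n subjects, the pooled sorted unique follow-up times u_1 <
# ... < u_m carry, per time l:
#   nd[l, j]  number of type-j events at u_l (j = 1..d)
#   c0[l]     number of censorings at u_l
#   D[l]      total events at u_l (rowSums of nd)
#   Y[l]      at-risk count for events:  #{T >= u_l}            (plain)
#                                        #{L <= u_l <= T}       (adjusted)
#   Yc[l]     at-risk count for censoring: Y[l] - D[l]  (events precede
#             censorings at tied times, so subjects with an event at u_l are
#             not at risk of censoring there)
#   idx[i]    index of subject i's follow-up time in u
#   kL[i]     first index l with u_l >= entry_i (1 when no delayed entry)
risk_tables <- function(sample, truncation_adjusted = sample$truncated) {
  n <- sample$n
  d <- sample$d
  u <- sort(unique(sample$time))
  m <- length(u)
  idx <- match(sample$time, u)
  tot <- tabulate(idx, m)
  nd <- matrix(0, m, d)
  for (j in seq_len(d))
    nd[, j] <- tabulate(idx[sample$status == j], m)
  c0 <- tabulate(idx[sample$status == 0L], m)
  D <- .rowSums(nd, m, d)
  before <- c(0, cumsum(tot))[seq_len(m)]   # #{T < u_l}
  if (truncation_adjusted) {
    sL <- sort(sample$entry)
    cntL <- findInterval(u, sL)             # #{L <= u_l}
    Y <- cntL - before
    kL <- findInterval(sample$entry, u, left.open = TRUE) + 1L
  } else {
    Y <- n - before
    kL <- rep(1L, n)
  }
  Yc <- Y - D
  list(u = u, m = m, n = n, d = d, nd = nd, c0 = c0, D = D, Y = Y, Yc = Yc,
       tot = tot, idx = idx, kL = kL, truncated = truncation_adjusted)
}

#' Empirical counting-process summary
#'
#' Averages of the counting-process representation of the sample: the at-risk
#' proportion `H(s)`, the censoring at-risk proportion `Hc(s)` (which keeps a
#' subject censored at `s` at risk of censoring at `s`, so that tied event and
#' censoring times are handled with events first) and the cumulative event /
#' censoring count proportions `Hj(s)`, `j = 0..d`.  With
#' `truncation_adjusted = TRUE` the risk sets start at each subject's entry
#' time.
#'
#' @param sample an [event_sample()].
#' @param truncation_adjusted logical; adjust risk sets for delayed entry.
#'   Defaults to `TRUE` when the sample has positive entry times.
#'
#' @return An object of class `"counting_summary"`: step functions `at_risk`,
#'   `at_risk_cens` and `counts` (a list indexed `"0"`..`"d"`), the flag
#'   `truncation_adjusted`, and the underlying integer tables.
#' @examples
#' s <- event_sample(c(1, 2, 3), c(1, 1, 1))
#' cs <- counting_summary(s)
#' step_eval(cs$at_risk, 2)        # 2/3
#' @export
counting_summary <- function(sample, truncation_adjusted = sample$truncated) {
  stopifnot(inherits(sample, "event_sample"))
  tab <- risk_tables(sample, truncation_adjusted)
  n <- tab$n
  # H and Hc drop just *after* each follow-up time (and, with truncation, rise
  # at entry times); the stored step functions are the right-continuous
  # versions, and at_risk_at() returns the exact at-risk proportion at s.
  if (truncation_adjusted) {
    g <- sort(unique(c(sample$entry, sample$time)))
    hv <- (findInterval(g, sort(sample$entry)) -
             findInterval(g, sort(sample$time))) / n
    at_risk <- step_function(g, hv, initial_value = 0)
  } else {
    at_risk <- step_function(tab$u, (tab$Y - tab$tot) / n,
                             initial_value = 1)
  }
  counts <- vector("list", tab$d + 1L)
  names(counts) <- as.character(0:tab$d)
  counts[["0"]] <- step_function(tab$u, cumsum(tab$c0) / n, initial_value = 0)
  for (j in seq_len(tab$d))
    counts[[as.character(j)]] <-
      step_function(tab$u, cumsum(tab$nd[, j]) / n, initial_value = 0)
  # the right-continuous versions of H and Hc coincide (both equal the
  # proportion with s < T and L <= s just after s); they differ only *at*
  # follow-up times, which at_risk_at() resolves exactly
  at_risk_cens <- if (truncation_adjusted) at_risk else
    step_function(tab$u, (tab$Yc - tab$c0) / n, initial_value = 1)
  structure(list(at_risk = at_risk, at_risk_cens = at_risk_cens,
                 counts = counts,
                 truncation_adjusted = truncation_adjusted,
                 table = tab, sample = sample),
            class = "counting_summary")
}

#' Evaluate the at-risk proportions of a counting summary
#'
#' `H(s)` and `Hc(s)` are not right-continuous (they drop just after each
#' follow-up time), so the stored step functions hold the values just after
#' each time and these helpers return the exact at-risk proportion *at* `s`.
#'
#' @param summary a [counting_summary()].
#' @param s evaluation times.
#' @param which `"events"` for `H(s)`, `"censoring"` for `Hc(s)`.
#' @return Numeric vector of at-risk proportions.
#' @export
at_risk_at <- function(summary, s, which = c("events", "censoring")) {
  which <- match.arg(which)
  tab <- summary$table
  if (which == "events") {
    if (tab$truncated) {
      sL <- sort(summary$sample$entry)
      (findInterval(s, sL) -
         findInterval(s, sort(summary$sample$time), left.open = TRUE)) / tab$n
    } else {
      (tab$n - findInterval(s, sort(summary$sample$time),
                            left.open = TRUE)) / tab$n
    }
  } else {
    # Hc(s) = #{s < T} + #{s = T, censored}, entry-adjusted when truncated
    H <- at_risk_at(summary, s, "events")
    k <- findInterval(s, tab$u)
    hit <- k >= 1L & tab$u[pmax(k, 1L)] == s
    ev <- ifelse(hit, tab$D[pmax(k, 1L)], 0)
    H - ev / tab$n
  }
}

#' @export
print.counting_summary <- function(x, ...) {
  cat("Counting-process summary on", x$table$m, "unique times",
      if (x$truncation_adjusted) "(truncation-adjusted risk sets)" else "",
      "\n")
  invisible(x)
}
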