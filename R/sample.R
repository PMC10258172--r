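#' Construct a validated time-to-event sample
#'
#' The unit of all computation in the package: subject-level observed data
#' consisting of a follow-up time, an event status code (0 = censored,
#' 1..d = event types), an optional delayed-entry (left-truncation) time and an
#' optional numeric covariate matrix.  Subjects are only observed when their
#' entry time does not exceed their follow-up time, so `entry <= time` is
#' enforced row by row.
#'
#' @param time positive follow-up times.
#' @param status integer event codes in `{0, 1, ..., d}`; 0 means censored.
#' @param entry entry (left-truncation) times, `>= 0`; `NULL` means no
#'   delayed entry (all zero).
#' @param covariates numeric matrix (or data.frame coercible to one) with one
#'   row per subject; may be `NULL`.
#' @param id optional subject identifiers (used in messages and output files).
#' @param n_causes number of competing event types `d`; by default the largest
#'   observed status code (at least 1).
#'
#' @return An object of class `"event_sample"` with elements `time`, `status`,
#'   `entry`, `covariates`, `id`, `n`, `d` and the flag `truncated`.
#' @examples
#' s <- event_sample(time = c(1, 2, 3), status = c(1, 0, 2))
#' s$n; s$d
#' @export
event_sample <- function(time, status, entry = NULL, covariates = NULL,
                         id = NULL, n_causes = NULL) {
  n <- length(time)
  if (n < 1L) stop("empty sample")
  time <- as.numeric(time)
  status <- as.integer(status)
  if (length(status) != n)
    stop("'time' and 'status' must have the same length")
  if (is.null(entry)) entry <- numeric(n)
  entry <- as.numeric(entry)
  if (length(entry) != n)
    stop("'entry' must have length ", n)
  if (anyNA(time) || anyNA(status) || anyNA(entry))
    stop("missing values are not allowed in time, status or entry")
  if (any(time <= 0)) {
    i <- which(time <= 0)[1L]
    stop("follow-up time must be positive; offending row ", i)
  }
  if (any(entry < 0)) {
    i <- which(entry < 0)[1L]
    stop("entry time must be non-negative; offending row ", i)
  }
  bad <- which(entry > time)
  if (length(bad))
    stop("entry time exceeds follow-up time in row ", bad[1L],
         " (entry = ", format(entry[bad[1L]]), ", time = ",
         format(time[bad[1L]]), "); left-truncated sampling requires entry <= time")
  d <- if (is.null(n_causes)) max(1L, max(status)) else as.integer(n_causes)
  if (d < 1L) stop("'n_causes' must be at least 1")
  if (any(status < 0L | status > d)) {
    i <- which(status < 0L | status > d)[1L]
    stop("status must lie in {0, ..., ", d, "}; offending row ", i,
         " has status ", status[i])
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n)
      stop("'covariates' must have one row per subject (", n, " rows)")
    if (anyNA(covariates))
      stop("missing values are not allowed in covariates")
  }
  if (!is.null(id) && length(id) != n)
    stop("'id' must have length ", n)
  structure(list(time = time, status = status, entry = entry,
                 covariates = covariates, id = id,
                 n = n, d = d, truncated = any(entry > 0)),
            class = "event_sample")
}

#' @export
print.event_sample <- function(x, ...) {
  cat("Time-to-event sample: n =", x$n, ", event types d =", x$d, "\n")
  cat("  events:", sum(x$status > 0L), " censored:", sum(x$status == 0L),
      if (x$truncated) " (left-truncated)" else "", "\n")
  if (!is.null(x$covariates))
    cat("  covariates:", ncol(x$covariates), "column(s)\n")
  invisible(x)
}

#' Time-to-event response for model formulas
#'
#' Builds the left-hand side of a [pseudoglm()] formula, analogous to
#' `survival::Surv()` but with explicit competing-risks status codes and an
#' optional entry time for delayed-entry cohorts.
#'
#' @inheritParams event_sample
#' @return A numeric matrix of class `"Event"` with columns `entry`, `time`
#'   and `status`.
#' @examples
#' Event(time = c(1, 2), status = c(1, 0))
#' @export
Event <- function(time, status, entry = 0) {
  n <- length(time)
  entry <- rep_len(entry, n)
  m <- cbind(entry = as.numeric(entry), time = as.numeric(time),
             status = as.numeric(status))
  class(m) <- c("Event", "matrix")
  m
}

# Convert a formula response (Event or survival::Surv) to entry/time/status.
response_to_ets <- function(y) {
  if (inherits(y, "Event")) {
    m <- unclass(y)
    return(list(entry = m[, "entry"], time = m[, "time"],
                status = as.integer(m[, "status"])))
  }
  if (inherits(y, "Surv")) {
    type <- attr(y, "type")
    m <- unclass(y)
    if (type %in% c("right", "mstate")) {
      return(list(entry = NULL, time = m[, 1L],
                  status = as.integer(m[, ncol(m)])))
    }
    if (type %in% c("counting", "mcounting")) {
      return(list(entry = m[, 1L], time = m[, 2L],
                  status = as.integer(m[, ncol(m)])))
    }
    stop("unsupported Surv type '", type, "'")
  }
  stop("model response must be built with Event() or survival::Surv()")
}
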