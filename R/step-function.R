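#' Right-continuous step functions
#'
#' Lightweight container for right-continuous piecewise-constant curves with
#' left-limit queries.  Every estimated curve in the package (censoring
#' survival, event survival, cumulative incidences, cumulative hazards, the
#' entry-time distribution) is stored in this form.
#'
#' @param jump_times strictly increasing numeric vector of jump locations.
#' @param values value taken at and immediately after each jump.
#' @param initial_value value on `[0, jump_times[1])`.
#'
#' @return An object of class `"step_function"`.
#' @seealso [step_eval()]
#' @examples
#' f <- step_function(c(1, 2), c(0.5, 0.25), initial_value = 1)
#' step_eval(f, c(0.2, 1, 2))          # right-continuous values
#' step_eval(f, 1, side = "left")      # left limit
#' @export
step_function <- function(jump_times, values, initial_value = 1) {
  jump_times <- as.numeric(jump_times)
  values <- as.numeric(values)
  if (length(jump_times) != length(values))
    stop("'jump_times' and 'values' must have the same length")
  if (length(jump_times) > 1L && is.unsorted(jump_times, strictly = TRUE))
    stop("'jump_times' must be strictly increasing")
  structure(list(x = jump_times, y = values, y0 = as.numeric(initial_value)),
            class = "step_function")
}

#' Evaluate a step function
#'
#' @param f a [step_function()].
#' @param s numeric vector of evaluation times (non-negative).
#' @param side `"right"` for the right-continuous value `f(s)`, `"left"` for
#'   the left limit `f(s-)`.
#'
#' @return Numeric vector of the same length as `s`.
#' @export
step_eval <- function(f, s, side = c("right", "left")) {
  side <- match.arg(side)
  if (!inherits(f, "step_function")) stop("'f' must be a step_function")
  k <- findInterval(s, f$x, left.open = identical(side, "left"))
  c(f$y0, f$y)[k + 1L]
}

#' @export
print.step_function <- function(x, ...) {
  cat("Step function with", length(x$x), "jumps",
      if (length(x$x)) sprintf("on [%g, %g]", x$x[1], x$x[length(x$x)]),
      "\n")
  cat("  initial value:", format(x$y0), "\n")
  invisible(x)
}

# increments of a step function (same length as x)
step_increments <- function(f) {
  diff(c(f$y0, f$y))
}
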