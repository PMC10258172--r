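# Delimited-text interfaces: subject records in, fits / tables / curves out.
# Comma-delimited throughout, '#'-prefixed metadata lines, decimal points
# independent of locale (C numeric formatting via write.csv / read.csv).

#' Read subject records from delimited text
#'
#' Expects a comma-delimited file with a header naming at least `id`, `time`
#' and `status`; an optional `entry` column (all zero when absent) and any
#' number of covariate columns `z1, z2, ...`.  Column order is free; lines
#' starting with `#` are ignored.
#'
#' @param path input file path.
#' @return An [event_sample()].
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = TRUE)
  need <- c("id", "time", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  known <- c("id", "entry", "time", "status")
  zcols <- setdiff(names(df), known)
  if (length(zcols) && !all(grepl("^z[0-9]+$", zcols)))
    stop("unknown column(s): ",
         paste(zcols[!grepl("^z[0-9]+$", zcols)], collapse = ", "),
         " (covariates must be named z1, z2, ...)")
  numcols <- c("time", "status", intersect("entry", names(df)), zcols)
  for (cc in numcols) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1L]
      stop("column '", cc, "' is not numeric (first offending row ",
           if (is.na(bad)) 1L else bad, ")")
    }
  }
  if (anyDuplicated(df$id))
    stop("duplicate id in row ", which(duplicated(df$id))[1L])
  entry <- if ("entry" %in% names(df)) df$entry else NULL
  cov <- if (length(zcols))
    as.matrix(df[, zcols[order(as.integer(sub("^z", "", zcols)))],
                 drop = FALSE]) else NULL
  event_sample(df$time, df$status, entry = entry, covariates = cov,
               id = df$id)
}

#' Write subject records (optionally with pseudo-observations) to text
#'
#' Inverse of [read_records()]; when a [pseudo_obs()] result is supplied its
#' values and sampling weights are appended as columns `pseudo` and
#' `weight`.
#'
#' @param sample an [event_sample()].
#' @param path output file path.
#' @param pseudo optional `"pseudo_set"` aligned with the sample.
#' @return Invisibly, the written data frame.
#' @export
write_records <- function(sample, path, pseudo = NULL) {
  df <- as.data.frame(sample)
  if (!is.null(pseudo)) {
    stopifnot(inherits(pseudo, "pseudo_set"), pseudo$n == sample$n)
    df$pseudo <- pseudo$values
    df$weight <- pseudo$weights
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write a fit or scenario table with a reproducibility header
#'
#' Writes delimited text preceded by `#`-prefixed metadata lines recording
#' the package version, the seed and the generating call, so that outputs
#' are reproducible from their own header.
#'
#' @param x a [pseudoglm()] fit, a `"scenario_result"` table, or any data
#'   frame.
#' @param path output file path.
#' @param seed seed to record (if any).
#' @param command command line / call to record.
#' @return Invisibly, the written data frame.
#' @export
write_results <- function(x, path, seed = NULL, command = NULL) {
  if (inherits(x, "pseudoglm")) {
    s <- summary(x)
    tab <- data.frame(term = rownames(s$coefficients), s$coefficients,
                      check.names = FALSE, row.names = NULL)
  } else {
    tab <- as.data.frame(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ijpseudo ",
           as.character(utils::packageVersion("ijpseudo"))),
    paste0("# date: ", format(Sys.time(), "%Y-%m-%d")),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(command)) paste0("# command: ", command)), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
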