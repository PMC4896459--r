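#' Clip values to the unit interval
#'
#' @param x numeric vector.
#' @return `x` with every element forced into \[0, 1\].
#' @keywords internal
clip01 <- function(x) pmin(1, pmax(0, x))

#' Round half away from zero
#'
#' Report tables use conventional half-up rounding (so 0.35825 prints as
#' 35.8 and 0.4495 as 45.0), not the IEEE banker's rounding of [round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a one-decimal percentage string
#'
#' @param p proportion(s) in \[0, 1\].
#' @param digits decimal places (default 1, matching report tables).
#' @return character vector like `"35.8%"`.
#' @export
format_percent <- function(p, digits = 1) {
  paste0(formatC(round_half_up(100 * p, digits), format = "f", digits = digits), "%")
}

#' Weighted quantile of a discrete score
#'
#' Returns, for each probability, the smallest observed value whose weighted
#' cumulative distribution reaches that probability. With ties this assigns
#' the boundary value itself (so ties later fall in the lower group).
#'
#' @param x numeric values.
#' @param w positive weights, same length as `x`.
#' @param probs probabilities in (0, 1).
#' @return numeric vector of quantiles, one per element of `probs`.
#' @keywords internal
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0))
  ord <- order(x)
  x <- x[ord]
  cdf <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cdf >= p - 1e-12)[1]], numeric(1))
}

#' Parse flexible binary codings
#'
#' Accepts logicals, 0/1 numerics, and the strings yes/no/true/false/1/0
#' (case-insensitive). Empty strings and NA parse to NA.
#'
#' @param x vector to parse.
#' @param what label used in error messages.
#' @return logical vector.
#' @keywords internal
parse_binary <- function(x, what = "value") {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad)) stop(sprintf("%s has non-binary numeric codes: %s",
                               what, paste(unique(x[bad]), collapse = ", ")))
    return(as.logical(x))
  }
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("yes", "true", "1")] <- TRUE
  out[s %in% c("no", "false", "0")] <- FALSE
  bad <- !is.na(s) & s != "" & is.na(out)
  if (any(bad)) stop(sprintf("%s has unrecognized codes: %s",
                             what, paste(unique(s[bad]), collapse = ", ")))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
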