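#' Trial-style cumulative curve
#'
#' Container for the two kinds of published curves the transition
#' probabilities are derived from: a cumulative incidence curve (e.g.
#' ipsilateral breast tumour recurrence), starting at 0 and
#' non-decreasing, or an overall survival curve, starting at 1 and
#' non-increasing.  Values are indexed by whole years 0..T.
#'
#' @param values Numeric vector of length T + 1 (year 0 first).
#' @param kind `"incidence"` or `"survival"`.
#' @return An object of class `cumulative_curve`.
#' @export
cumulative_curve <- function(values, kind = c("incidence", "survival")) {
  kind <- match.arg(kind)
  check_prob(values, "values")
  if (length(values) < 2L)
    stopf("a curve needs at least years 0 and 1")
  eps <- 1e-12
  if (kind == "incidence") {
    if (abs(values[1]) > eps)
      stopf("an incidence curve must start at 0 (year 0)")
    if (any(diff(values) < -eps))
      stopf("an incidence curve must be non-decreasing")
  } else {
    if (abs(values[1] - 1) > eps)
      stopf("a survival curve must start at 1 (year 0)")
    if (any(diff(values) > eps))
      stopf("a survival curve must be non-increasing")
  }
  structure(list(kind = kind, values = as.numeric(values)),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("Cumulative %s curve over %d years:\n", x$kind,
              length(x$values) - 1L))
  print(stats::setNames(x$values, seq_along(x$values) - 1L))
  invisible(x)
}

#' Annual transition probabilities from a cumulative curve
#'
#' Converts a cumulative curve into the per-year conditional event
#' probabilities a discrete-time cohort model consumes.  For a cumulative
#' incidence curve C the year-t probability conditions on the at-risk set
#' remaining at t - 1: `p[t] = (C[t] - C[t-1]) / (1 - C[t-1])`.  For a
#' survival curve S it is the discrete hazard `p[t] = 1 - S[t]/S[t-1]`.
#' No competing-risk correction is applied: the curve is read
#' cause-specifically, as published.
#'
#' @param curve A [cumulative_curve()].
#' @return Numeric vector of T annual probabilities (years 1..T).
#' @export
annual_probs <- function(curve) {
  stopifnot(inherits(curve, "cumulative_curve"))
  if (curve$kind == "incidence")
    annual_probs_from_cumulative_incidence(curve)
  else annual_probs_from_survival(curve)
}

#' @rdname annual_probs
#' @export
annual_probs_from_cumulative_incidence <- function(curve) {
  stopifnot(inherits(curve, "cumulative_curve"), curve$kind == "incidence")
  C <- curve$values
  Tn <- length(C) - 1L
  prev <- C[seq_len(Tn)]
  if (any(prev >= 1 & C[-1] > prev))
    stopf("impossible curve: cumulative incidence rises after reaching 1")
  p <- (C[-1] - prev) / (1 - prev)
  p[prev >= 1] <- 0
  pmin(pmax(p, 0), 1)
}

#' @rdname annual_probs
#' @export
annual_probs_from_survival <- function(curve) {
  stopifnot(inherits(curve, "cumulative_curve"), curve$kind == "survival")
  S <- curve$values
  Tn <- length(S) - 1L
  prev <- S[seq_len(Tn)]
  if (any(prev <= 0 & S[-1] > 0))
    stopf("impossible curve: survival positive after reaching 0")
  p <- ifelse(prev > 0, 1 - S[-1] / prev, 0)
  pmin(pmax(p, 0), 1)
}

#' Cumulative curve from annual probabilities
#'
#' Exact algebraic inverse of [annual_probs()]: survival
#' `S[t] = prod(1 - p[1..t])`, incidence `C[t] = 1 - prod(1 - p[1..t])`.
#'
#' @param p Vector of annual probabilities in `[0, 1]`.
#' @param kind `"incidence"` or `"survival"`.
#' @return A [cumulative_curve()] over years 0..length(p).
#' @export
cumulative_from_annual <- function(p, kind = c("incidence", "survival")) {
  kind <- match.arg(kind)
  check_prob(p, "p")
  surv <- cumprod(1 - p)
  values <- if (kind == "survival") c(1, surv) else c(0, 1 - surv)
  cumulative_curve(values, kind)
}

#' Read or write a cumulative curve as CSV (columns `year`, `value`)
#'
#' @param path CSV file path.
#' @param kind Curve kind, for [read_curve_csv()].
#' @return The curve (read) or `path` invisibly (write).
#' @export
read_curve_csv <- function(path, kind = c("incidence", "survival")) {
  d <- utils::read.csv(path)
  if (!all(c("year", "value") %in% names(d)))
    stopf("curve CSV must have columns year, value")
  cumulative_curve(d$value[order(d$year)], match.arg(kind))
}

#' @rdname read_curve_csv
#' @param curve A [cumulative_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "cumulative_curve"))
  utils::write.csv(data.frame(year = seq_along(curve$values) - 1L,
                              value = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}
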