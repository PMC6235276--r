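#' Four-class opinion counts
#'
#' The joint state of a finite population is summarised by the counts of the
#' four (public, private) opinion combinations. The first index is the
#' public level, the second the private one; `p` stands for +1 and `m`
#' for -1.
#'
#' @param n_pp,n_pm,n_mp,n_mm nonnegative integer counts.
#' @return an object of class `"qv_counts"` (a named integer vector).
#' @export
class_counts <- function(n_pp, n_pm, n_mp, n_mm) {
  n <- c(n_pp = n_pp, n_pm = n_pm, n_mp = n_mp, n_mm = n_mm)
  if (!is.numeric(n) || anyNA(n) || any(n < 0) || any(n != round(n))) {
    stop("class counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(n) < 1) stop("population must contain at least one agent", call. = FALSE)
  structure(as.integer(n), names = names(n), class = "qv_counts")
}

#' Macroscopic observables from class counts
#'
#' Computes the fraction of positive public opinions `c_S`, the fraction of
#' positive private opinions `c_sigma`, the dissonance `d` (fraction of
#' agents whose public and private opinions differ), and the Pearson
#' correlation `rho` between the two opinion levels. `rho` is `NA` when
#' either marginal is degenerate (all agents share the same opinion on that
#' level), since the correlation is then undefined.
#'
#' @param counts a [class_counts()] object or a nonnegative integer vector
#'   `(n_pp, n_pm, n_mp, n_mm)`.
#' @return named list with `c_S`, `c_sigma`, `d`, `rho`.
#' @export
observables_from_counts <- function(counts) {
  n <- as.numeric(counts)
  if (length(n) != 4L || anyNA(n) || any(n < 0)) {
    stop("counts must be four nonnegative numbers", call. = FALSE)
  }
  N <- sum(n)
  c_S <- (n[1] + n[2]) / N
  c_sigma <- (n[1] + n[3]) / N
  d <- (n[2] + n[3]) / N
  var_prod <- c_S * (1 - c_S) * c_sigma * (1 - c_sigma)
  rho <- if (var_prod <= 0) {
    NA_real_
  } else {
    (n[1] / N - c_S * c_sigma) / sqrt(var_prod)
  }
  list(c_S = c_S, c_sigma = c_sigma, d = d, rho = rho)
}

#' Dissonance under the assumption of independent opinion levels
#'
#' If the public and private opinion states were statistically independent,
#' the dissonance would factorise as
#' `d = c_S (1 - c_sigma) + c_sigma (1 - c_S)`. Deviations of the measured
#' dissonance from this value signal correlations between the two levels.
#'
#' @param c_S,c_sigma concentrations in `[0, 1]`.
#' @return the factorised dissonance level.
#' @export
dissonance_independent <- function(c_S, c_sigma) {
  stopifnot(all(c_S >= 0 & c_S <= 1), all(c_sigma >= 0 & c_sigma <= 1))
  c_S * (1 - c_sigma) + c_sigma * (1 - c_S)
}

#' Pearson correlation between public and private opinions
#'
#' For binary +/-1 opinions the population Pearson correlation between the
#' two levels can be written in terms of the two marginal concentrations
#' and the dissonance:
#' \deqn{\rho = \frac{c_S(1-c_\sigma) + c_\sigma(1-c_S) - d}
#'                 {2\sqrt{c_S c_\sigma (1-c_S)(1-c_\sigma)}}.}
#' The numerator vanishes exactly when the dissonance takes its
#' independent-levels value, so independent levels imply `rho = 0`.
#'
#' @param c_S,c_sigma concentrations in `[0, 1]`.
#' @param d dissonance level in `[0, 1]`.
#' @return the correlation, or `NA` when a marginal is degenerate
#'   (`c_S` or `c_sigma` equal to 0 or 1).
#' @export
pearson_correlation <- function(c_S, c_sigma, d) {
  stopifnot(all(c_S >= 0 & c_S <= 1), all(c_sigma >= 0 & c_sigma <= 1),
            all(d >= 0 & d <= 1))
  denom <- 2 * sqrt(c_S * c_sigma * (1 - c_S) * (1 - c_sigma))
  num <- c_S * (1 - c_sigma) + c_sigma * (1 - c_S) - d
  out <- ifelse(denom <= 0, NA_real_, num / denom)
  out
}
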