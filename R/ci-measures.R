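#' Aggregate a CI coefficient vector into reference and excitation weights
#'
#' Normalizes a configuration-interaction coefficient vector internally and
#' aggregates it into the reference-determinant coefficient `c0` and the
#' total singles and doubles weights \eqn{c_S^2 = \sum (c_i^a)^2},
#' \eqn{c_D^2 = \sum (c_{ij}^{ab})^2}.  The sign of `c0` is preserved; every
#' formula downstream only uses `c0^2`.  A warning is raised when the
#' reference is not dominant (`c0^2 < 0.5`).
#'
#' @param coefficients numeric vector of CI coefficients.
#' @param ranks integer excitation rank per coefficient: 0 for the reference
#'   determinant (exactly one entry), 1 for singles, 2 for doubles.  Higher
#'   ranks are accepted (relevant when ingesting beyond-CISD vectors) and
#'   accumulated into `higher_weight`.
#' @param n_electrons electron count the expansion refers to.
#' @return An object of class `"ci_expansion"`: `c0`, `singles_weight`,
#'   `doubles_weight`, `higher_weight`, `n_electrons`, `normalized`.
#' @examples
#' ci_expansion(c(2, 0, 0), ranks = c(0, 1, 2), n_electrons = 2)  # c0^2 = 1
#' ci_expansion(c(1, 1) / sqrt(2), ranks = c(0, 2), n_electrons = 2)
#' @export
ci_expansion <- function(coefficients, ranks, n_electrons) {
  coefficients <- as.numeric(coefficients)
  ranks <- as.integer(ranks)
  stopifnot(length(coefficients) == length(ranks), all(ranks >= 0L))
  if (sum(ranks == 0L) != 1L)
    nd_stop("noodiag_degenerate_input",
            "exactly one coefficient must be tagged rank 0 (reference), got %d",
            sum(ranks == 0L))
  nrm <- sqrt(sum(coefficients^2))
  if (nrm == 0)
    nd_stop("noodiag_degenerate_input", "all-zero CI coefficient vector")
  c_ <- coefficients / nrm
  c0 <- c_[ranks == 0L]
  if (c0^2 < 0.5)
    warning(sprintf("reference determinant is not dominant: c0^2 = %.4g < 0.5",
                    c0^2), call. = FALSE)
  structure(
    list(c0 = c0,
         singles_weight = sum(c_[ranks == 1L]^2),
         doubles_weight = sum(c_[ranks == 2L]^2),
         higher_weight = sum(c_[ranks >= 3L]^2),
         n_electrons = as.integer(n_electrons),
         normalized = TRUE),
    class = "ci_expansion")
}

#' @export
print.ci_expansion <- function(x, ...) {
  cat(sprintf(
    "<ci_expansion> N = %d: c0^2 = %.6g, singles %.6g, doubles %.6g%s\n",
    x$n_electrons, x$c0^2, x$singles_weight, x$doubles_weight,
    if (x$higher_weight > 0) sprintf(", higher %.6g", x$higher_weight) else ""))
  invisible(x)
}

#' Size-intensive version of the CI leading coefficient
#'
#' \deqn{1 - (c_0^2)^{1/N},}
#' which behaves as \eqn{(1 - c_0^2)/N} to first order as \eqn{c_0^2 \to 1}
#' and thereby makes the leading CI weight comparable across system sizes.
#'
#' @param c0 reference coefficient, \eqn{0 < c_0^2 \le 1}.
#' @param n_electrons electron count \eqn{N \ge 1}.
#' @return Scalar in \eqn{[0, 1)}.
#' @examples
#' size_intensive_c0(sqrt(0.9), 2)   # 1 - sqrt(0.9)
#' @export
size_intensive_c0 <- function(c0, n_electrons) {
  stopifnot(n_electrons >= 1)
  if (any(c0 == 0))
    nd_stop("noodiag_degenerate_input",
            "size-intensive c0 undefined at c0 = 0 (log branch)")
  if (any(c0^2 > 1 + 1e-12))
    nd_stop("noodiag_range_error", "c0^2 = %g exceeds 1", max(c0^2))
  1 - pmin(c0^2, 1)^(1 / n_electrons)
}

#' Trace decomposition of the CISD one-particle density
#'
#' Splits the trace of the one-particle density matrix into the blocks of
#' orbitals that are occupied and empty in the mean-field picture.  Each
#' single excitation promotes one electron and each double two, so
#' \deqn{\mathrm{Tr}\,{}^1D^{vir} = c_S^2 + 2 c_D^2, \qquad
#'       \mathrm{Tr}\,{}^1D^{occ} = N - c_S^2 - 2 c_D^2.}
#'
#' @param x a [ci_expansion()].
#' @return A list with `trace_occ` and `trace_vir`; they sum to `N`.
#' @examples
#' cisd_trace_decomposition(ci_expansion(c(sqrt(0.95), sqrt(0.05)),
#'                                       ranks = c(0, 2), n_electrons = 10))
#' @export
cisd_trace_decomposition <- function(x) {
  stopifnot(inherits(x, "ci_expansion"))
  tv <- x$singles_weight + 2 * x$doubles_weight
  list(trace_occ = x$n_electrons - tv, trace_vir = tv)
}

#' Predict the size-intensive nondynamic index from c0
#'
#' Analytic bridge between the leading CI weight and the occupancy-based
#' measure: for a dominant block-diagonal one-particle density,
#' \deqn{\hat{I}_{ND} \approx 4 (1 - c_0^2) / N.}
#' The estimate is quantitative in the weakly correlated regime
#' (\eqn{c_0^2 \gtrsim 0.9}) and degrades as correlation grows.
#'
#' @inheritParams size_intensive_c0
#' @return Nonnegative scalar estimate of \eqn{\hat{I}_{ND}}.
#' @examples
#' predict_ind_hat_from_c0(sqrt(0.95), 10)  # 0.02
#' @export
predict_ind_hat_from_c0 <- function(c0, n_electrons) {
  if (n_electrons < 1)
    nd_stop("noodiag_zero_electrons",
            "normalization undefined for N = %d electrons", n_electrons)
  if (any(c0^2 > 1 + 1e-12))
    nd_stop("noodiag_range_error", "c0^2 = %g exceeds 1", max(c0^2))
  4 * (1 - pmin(c0^2, 1)) / n_electrons
}
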