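#' Normalization constants for the correlation indices
#'
#' Every prefactor entering the occupancy-based indices lives here, in one
#' place, so that an alternative normalization convention is a one-argument
#' change rather than an edit scattered through the code.
#'
#' The defaults encode the conventions used throughout the package:
#' \describe{
#'   \item{spin_prefactor}{\eqn{I_{ND} = c \sum_{i\sigma} n_{i\sigma}(1-n_{i\sigma})}
#'     with \eqn{c = 1/2}, which fixes the range \eqn{[0, N/2]}.}
#'   \item{intensive_scale}{\eqn{\hat{I} = s\, I / N} with \eqn{s = 2}, so the
#'     size-intensive nondynamic index lies in \eqn{[0, 1]}.}
#'   \item{max_prefactor}{\eqn{I_{ND}^{max} = c \max_{i\sigma} n_{i\sigma}(1-n_{i\sigma})}
#'     with \eqn{c = 1/2}, giving the maximum \eqn{1/8} at a half-filled
#'     spin orbital.}
#'   \item{d2_bridge}{Proportionality constant linking the approximate
#'     (exchange-free) extreme virtual occupancy to the D2 diagnostic,
#'     \eqn{\tilde{n}_L = k\, D_2^2} with \eqn{k = 4}; see
#'     [predict_indmax_from_d2()].}
#' }
#'
#' Numerical policy knobs:
#' \describe{
#'   \item{tol_neg}{occupancies in \eqn{[-tol_neg, 1+tol_neg]} (spin) are
#'     clipped into range with a warning; anything further out is an error.}
#'   \item{trace_tol}{tolerated mismatch between the occupancy sum and the
#'     declared electron count before a warning is raised.}
#'   \item{tie_tol}{degeneracy window at the pseudo-occupied/pseudo-virtual
#'     boundary that triggers a tie warning.}
#'   \item{hermit_tol}{maximum asymmetry accepted in a density matrix.}
#'   \item{svd_dense_max}{largest matrix dimension for which spectral norms
#'     use a dense SVD; above it a power iteration is used.}
#' }
#'
#' @param spin_prefactor,intensive_scale,max_prefactor,d2_bridge index
#'   normalization constants (see Details).
#' @param tol_neg,trace_tol,tie_tol,hermit_tol tolerances (see Details).
#' @param svd_dense_max dense-SVD dimension cutoff.
#' @return A named list of constants, class `"noodiag_constants"`.
#' @examples
#' const <- index_constants()
#' const$spin_prefactor
#' @export
index_constants <- function(spin_prefactor = 0.5,
                            intensive_scale = 2,
                            max_prefactor = 0.5,
                            d2_bridge = 4,
                            tol_neg = 1e-6,
                            trace_tol = 1e-4,
                            tie_tol = 1e-10,
                            hermit_tol = 1e-8,
                            svd_dense_max = 500L) {
  stopifnot(spin_prefactor > 0, intensive_scale > 0, max_prefactor > 0,
            d2_bridge > 0, tol_neg >= 0, trace_tol > 0)
  structure(
    list(spin_prefactor = spin_prefactor,
         intensive_scale = intensive_scale,
         max_prefactor = max_prefactor,
         d2_bridge = d2_bridge,
         tol_neg = tol_neg,
         trace_tol = trace_tol,
         tie_tol = tie_tol,
         hermit_tol = hermit_tol,
         svd_dense_max = svd_dense_max),
    class = "noodiag_constants")
}

# internal: raise a classed error
nd_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "noodiag_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
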