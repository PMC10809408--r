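#' Nondynamic correlation index I_ND
#'
#' Deviation from idempotency of the one-particle reduced density matrix,
#' \deqn{I_{ND} = \tfrac12 \sum_{i\sigma} n_{i\sigma}(1 - n_{i\sigma}),}
#' equivalently \eqn{\frac14 \sum_i n_i(2 - n_i)} for a closed-shell set of
#' spatial occupancies.  Vanishes exactly at the mean-field (0/1) limit and
#' is bounded by \eqn{N/2}.
#'
#' @param x a [spin_occupancy_set()] or [closed_shell_occupancies()] object.
#' @param const normalization constants, see [index_constants()].
#' @return Nonnegative scalar \eqn{I_{ND} \in [0, N/2]}.
#' @examples
#' nondynamic_index(spin_occupancy_set(c(1, 1, 0, 0)))   # 0 at the HF limit
#' nondynamic_index(closed_shell_occupancies(c(1, 1)))   # 0.5, fully entangled pair
#' @export
nondynamic_index <- function(x, const = index_constants()) {
  UseMethod("nondynamic_index")
}

#' @export
nondynamic_index.spin_occupancy_set <- function(x, const = index_constants()) {
  n <- c(x$occ_alpha, x$occ_beta)
  const$spin_prefactor * sum(n * (1 - n))
}

#' @export
nondynamic_index.closed_shell_occupancy_set <- function(x, const = index_constants()) {
  # spatial specialization: n_sigma = n/2 in both channels
  (const$spin_prefactor / 2) * sum(x$occ * (2 - x$occ))
}

#' Dynamic and total correlation indices I_D, I_T
#'
#' Total index \eqn{I_T = \tfrac12 \sum_{i\sigma} \sqrt{n_{i\sigma}(1 - n_{i\sigma})}}
#' and its dynamic part \eqn{I_D = I_T - I_{ND}}.  Unlike \eqn{I_{ND}},
#' \eqn{I_D} is not bounded above: it grows without bound as the occupation
#' spreads over ever more orbitals at fixed electron number.
#'
#' @inheritParams nondynamic_index
#' @return A list with components `i_d` and `i_t` (both nonnegative,
#'   `i_t >= i_nd` by construction).
#' @examples
#' dynamic_total_indices(spin_occupancy_set(c(0.5, 1, 0), n_alpha = 1,
#'                                          occ_beta = c(1, 0, 0), n_beta = 1))
#' @export
dynamic_total_indices <- function(x, const = index_constants()) {
  s <- as_spin_occupancy_set(x)
  n <- c(s$occ_alpha, s$occ_beta)
  i_t <- const$spin_prefactor * sum(sqrt(pmax(n * (1 - n), 0)))
  list(i_d = i_t - nondynamic_index(s, const), i_t = i_t)
}

#' Size-intensive correlation indices
#'
#' Per-electron scaling \eqn{\hat{I}_{ND} = 2 I_{ND}/N \in [0, 1]} and, by
#' the same normalization, \eqn{\hat{I}_D = 2 I_D/N}.  The latter shares the
#' \eqn{2/N} scale for practical comparability even though \eqn{I_D} itself
#' is unbounded; the raw \eqn{I_D} is available from
#' [dynamic_total_indices()].
#'
#' @inheritParams nondynamic_index
#' @return A list with components `i_nd_hat` and `i_d_hat`.
#' @examples
#' size_intensive_indices(closed_shell_occupancies(c(1, 1)))  # i_nd_hat = 0.5
#' @export
size_intensive_indices <- function(x, const = index_constants()) {
  n_el <- n_electrons(x)
  if (n_el < 1)
    nd_stop("noodiag_zero_electrons",
            "size-intensive normalization undefined for N = %d electrons", n_el)
  dt <- dynamic_total_indices(x, const)
  list(i_nd_hat = const$intensive_scale * nondynamic_index(x, const) / n_el,
       i_d_hat = const$intensive_scale * dt$i_d / n_el)
}

#' Pseudo-occupied / pseudo-virtual split of the nondynamic index
#'
#' Splits \eqn{\hat{I}_{ND}} into the contribution of the \eqn{N^\alpha}
#' (resp. \eqn{N^\beta}) highest-occupied spin natural orbitals
#' (pseudo-occupied) and the rest (pseudo-virtual).  Their sum reproduces
#' \eqn{\hat{I}_{ND}} exactly; their near-equality reflects the particle-hole
#' symmetry typical of molecular one-particle density matrices.  Orbitals are
#' selected in stored descending order; degenerate occupations at the
#' boundary keep their original input order and trigger a warning.
#'
#' @inheritParams nondynamic_index
#' @return A list with components `i_nd_hat_occ` and `i_nd_hat_vir`.
#' @examples
#' split_occ_vir(closed_shell_occupancies(c(1.9, 0.1)))  # 0.0475 each
#' @export
split_occ_vir <- function(x, const = index_constants()) {
  s <- as_spin_occupancy_set(x)
  n_el <- n_electrons(s)
  if (n_el < 1)
    nd_stop("noodiag_zero_electrons",
            "size-intensive normalization undefined for N = %d electrons", n_el)
  part <- function(occ, n, channel) {
    if (length(occ) < n)
      nd_stop("noodiag_dimension_error",
              "%s channel has %d orbitals but %d electrons", channel,
              length(occ), n)
    if (n > 0 && n < length(occ) && abs(occ[n] - occ[n + 1]) < const$tie_tol)
      warning(sprintf(
        "degenerate occupation %.12g at the pseudo-occupied boundary of the %s channel; split uses input order",
        occ[n], channel), call. = FALSE)
    g <- occ * (1 - occ)
    occ_sum <- sum(g[seq_len(n)])
    c(occ = occ_sum, vir = sum(g) - occ_sum)
  }
  pa <- part(s$occ_alpha, s$n_alpha, "alpha")
  pb <- part(s$occ_beta, s$n_beta, "beta")
  scale <- const$intensive_scale * const$spin_prefactor / n_el
  list(i_nd_hat_occ = scale * (pa[["occ"]] + pb[["occ"]]),
       i_nd_hat_vir = scale * (pa[["vir"]] + pb[["vir"]]))
}

#' Maximal single-orbital nondynamic contribution I_ND^max
#'
#' \deqn{I_{ND}^{max} = \tfrac12 \max_{i\sigma} n_{i\sigma}(1 - n_{i\sigma})
#'   = \tfrac18 \max_i n_i(2 - n_i)\ \mathrm{(closed\ shell)},}
#' the recommended multireference diagnostic: it reaches its maximum
#' \eqn{1/8} as soon as a single natural orbital sits midway between
#' occupied and empty, regardless of system size.
#'
#' @inheritParams nondynamic_index
#' @return Scalar in \eqn{[0, 1/8]}.
#' @examples
#' nd_max(closed_shell_occupancies(c(1.98, 0.02)))  # 0.00495
#' nd_max(closed_shell_occupancies(c(1, 1)))        # 0.125
#' @export
nd_max <- function(x, const = index_constants()) {
  s <- as_spin_occupancy_set(x)
  n <- c(s$occ_alpha, s$occ_beta)
  if (!length(n)) return(0)
  const$max_prefactor * max(n * (1 - n))
}

#' Full correlation report for an occupancy set
#'
#' Aggregates every occupancy-based index into one object and, when a method
#' is named, classifies the system against that method's multireference
#' thresholds (see [classify_mr()]).
#'
#' @inheritParams nondynamic_index
#' @param method `"mp2"`, `"ccsd"`, a user-defined method present in
#'   `table`, or `NULL` for no classification.
#' @param table a [threshold_table()]; defaults to the built-in Table of
#'   MP2/CCSD fits.
#' @return An object of class `"correlation_report"`: fields `i_nd`, `i_d`,
#'   `i_t`, `i_nd_hat`, `i_d_hat`, `i_nd_hat_occ`, `i_nd_hat_vir`,
#'   `i_nd_max`, `ph_asymmetry`, `method`, `classification`, `label`.
#' @examples
#' correlation_report(closed_shell_occupancies(c(1.95, 0.05)), method = "mp2")
#' @export
correlation_report <- function(x, method = NULL, table = default_thresholds(),
                               const = index_constants()) {
  s <- as_spin_occupancy_set(x)
  i_nd <- nondynamic_index(s, const)
  dt <- dynamic_total_indices(s, const)
  si <- size_intensive_indices(s, const)
  sp <- split_occ_vir(s, const)
  im <- nd_max(s, const)
  eps <- .Machine$double.eps
  cls <- if (is.null(method) || identical(tolower(method), "none"))
    "not-classified" else classify_mr(im, method, table)
  structure(
    list(i_nd = i_nd, i_d = dt$i_d, i_t = dt$i_t,
         i_nd_hat = si$i_nd_hat, i_d_hat = si$i_d_hat,
         i_nd_hat_occ = sp$i_nd_hat_occ, i_nd_hat_vir = sp$i_nd_hat_vir,
         i_nd_max = im,
         ph_asymmetry = abs(sp$i_nd_hat_occ - sp$i_nd_hat_vir) /
           max(si$i_nd_hat, eps),
         method = if (is.null(method)) "none" else tolower(method),
         classification = cls,
         label = s$label),
    class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>", if (nzchar(x$label)) x$label else "", "\n")
  cat(sprintf("  I_ND  = %.6g   I_D  = %.6g   I_T = %.6g\n", x$i_nd, x$i_d, x$i_t))
  cat(sprintf("  ^I_ND = %.6g  (occ %.6g + vir %.6g)   ^I_D = %.6g\n",
              x$i_nd_hat, x$i_nd_hat_occ, x$i_nd_hat_vir, x$i_d_hat))
  cat(sprintf("  I_ND^max = %.6g   particle-hole asymmetry = %.3g\n",
              x$i_nd_max, x$ph_asymmetry))
  cat(sprintf("  classification [%s]: %s\n", x$method, x$classification))
  invisible(x)
}
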