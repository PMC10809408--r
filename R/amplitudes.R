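#' Closed-shell doubles-amplitude tensor
#'
#' Container for spin-adapted doubles amplitudes \eqn{t_{ij}^{ab}} stored as
#' a rank-4 array indexed `(i, j, a, b)` with `i, j` over doubly occupied
#' and `a, b` over virtual spatial orbitals.  The permutational symmetry
#' \eqn{t_{ij}^{ab} = t_{ji}^{ba}} is checked; mild violations are
#' symmetrized with a warning.
#'
#' @param t2 numeric 4-d array, dimensions `(n_occ, n_occ, n_vir, n_vir)`.
#' @param sym_tol symmetry tolerance before symmetrization warns.
#' @return An object of class `"amplitude_set"` with fields `t2`, `n_occ`,
#'   `n_vir`.
#' @examples
#' t2 <- array(0, c(2, 2, 3, 3)); t2[1, 1, 1, 1] <- 0.1
#' amplitude_set(t2)
#' @export
amplitude_set <- function(t2, sym_tol = 1e-10) {
  if (!is.array(t2) || length(dim(t2)) != 4)
    nd_stop("noodiag_dimension_error",
            "t2 must be a 4-d array (i, j, a, b)")
  d <- dim(t2)
  if (d[1] != d[2] || d[3] != d[4])
    nd_stop("noodiag_dimension_error",
            "t2 dimensions (%d,%d,%d,%d) must satisfy dim1==dim2, dim3==dim4",
            d[1], d[2], d[3], d[4])
  if (any(d == 0))
    nd_stop("noodiag_dimension_error", "empty amplitude tensor")
  if (any(!is.finite(t2)))
    nd_stop("noodiag_invalid_amplitudes", "non-finite amplitude entries")
  tsym <- aperm(t2, c(2, 1, 4, 3))
  if (max(abs(t2 - tsym)) > sym_tol) {
    warning(sprintf(
      "amplitudes violate t_ij^ab = t_ji^ba by %.3e; symmetrizing",
      max(abs(t2 - tsym))), call. = FALSE)
    t2 <- (t2 + tsym) / 2
  }
  structure(list(t2 = t2, n_occ = d[1], n_vir = d[3]),
            class = "amplitude_set")
}

#' @export
print.amplitude_set <- function(x, ...) {
  cat(sprintf("<amplitude_set> %d occupied x %d virtual, max|t| = %.4g\n",
              x$n_occ, x$n_vir, max(abs(x$t2))))
  invisible(x)
}

#' D2 diagnostic of a doubles-amplitude tensor
#'
#' Spectral (2-)norm diagnostic of Nielsen and Janssen.  Under the
#' `"per-occupied-max"` convention (default), for each occupied orbital `i`
#' the slab \eqn{t_{ij}^{ab}} is arranged as a matrix with row `j` and
#' compound column `(a, b)` and D2 is the largest of their spectral norms.
#' `"compound"` instead takes the spectral norm of the single
#' \eqn{(ij) \times (ab)} matricization.  Both coincide for a single
#' dominant amplitude, are invariant under simultaneous `(i<->j, a<->b)`
#' relabeling, and scale linearly with the amplitudes.
#'
#' @param t an [amplitude_set()].
#' @param matricization `"per-occupied-max"` (Nielsen-Janssen convention) or
#'   `"compound"`.
#' @param keep_spectrum retain the full singular spectrum of the (last)
#'   matricization inspected.
#' @param const constants; `const$svd_dense_max` selects dense SVD vs power
#'   iteration.
#' @return An object of class `"d2_result"` with fields `value`,
#'   `matricization` and optionally `singular_values`.
#' @examples
#' t2 <- array(0, c(2, 2, 3, 3)); t2[1, 1, 1, 1] <- 0.1
#' d2_diagnostic(amplitude_set(t2))$value  # 0.1
#' @export
d2_diagnostic <- function(t, matricization = c("per-occupied-max", "compound"),
                          keep_spectrum = FALSE, const = index_constants()) {
  stopifnot(inherits(t, "amplitude_set"))
  matricization <- match.arg(matricization)
  no <- t$n_occ; nv <- t$n_vir
  spectrum <- NULL
  if (matricization == "compound") {
    m <- matrix(aperm(t$t2, c(1, 2, 3, 4)), nrow = no * no)  # rows (i,j), cols (a,b)
    sv <- spectral_values(m, keep_spectrum, const)
    value <- sv$top; spectrum <- sv$spectrum
  } else {
    value <- 0
    for (i in seq_len(no)) {
      m <- matrix(t$t2[i, , , , drop = TRUE], nrow = no)  # rows j, cols (a,b)
      sv <- spectral_values(m, keep_spectrum, const)
      if (sv$top >= value) { value <- sv$top; spectrum <- sv$spectrum }
    }
  }
  structure(list(value = value, matricization = matricization,
                 singular_values = spectrum),
            class = "d2_result")
}

#' @export
print.d2_result <- function(x, ...) {
  cat(sprintf("<d2_result> D2 = %.6g  [%s]\n", x$value, x$matricization))
  invisible(x)
}

#' Unrelaxed second-order density-matrix blocks
#'
#' Occupied-occupied and virtual-virtual blocks of the closed-shell
#' unrelaxed MP2 one-particle density built from spin-adapted doubles
#' amplitudes.  Writing \eqn{u_{ij}^{ab} = 2 t_{ij}^{ab} - t_{ij}^{ba}},
#' \deqn{{}^1D^{occ}_{ij} = 2\delta_{ij}
#'   - 2 \sum_{kab} t_{ik}^{ab}\, u_{jk}^{ab}, \qquad
#'   {}^1D^{vir}_{ab} = 2 \sum_{ijc} t_{ij}^{ac}\, u_{ij}^{bc}.}
#' The corrections carry opposite traces, so particle number is conserved
#' exactly: \eqn{\mathrm{Tr}\,{}^1D^{occ} + \mathrm{Tr}\,{}^1D^{vir} =
#' 2 n_{occ}}.  The occupied-virtual coupling vanishes at this order without
#' orbital relaxation, so the two blocks carry the whole density.
#'
#' @param t an [amplitude_set()].
#' @return An object of class `"density_blocks"`: symmetric matrices
#'   `occ_block` (`n_occ x n_occ`), `vir_block` (`n_vir x n_vir`), and
#'   `approximate = FALSE`.
#' @examples
#' t2 <- array(0, c(1, 1, 1, 1)); t2[1, 1, 1, 1] <- 0.1
#' b <- mp2_density_blocks(amplitude_set(t2))
#' b$occ_block  # 2 - 2 * 0.1^2
#' @seealso [approx_density_blocks()], [extreme_occupations()]
#' @export
mp2_density_blocks <- function(t) {
  stopifnot(inherits(t, "amplitude_set"))
  density_blocks_impl(t, approximate = FALSE)
}

#' Exchange-free approximate density blocks
#'
#' Same second-order construction as [mp2_density_blocks()] with the
#' exchange-like contraction (the \eqn{t\cdot t^{swap}} term hidden in
#' \eqn{u = 2t - t^{swap}}) discarded, i.e. \eqn{u \to 2t}.  For physically
#' structured amplitudes the discarded term is positive semidefinite, so the
#' approximate blocks overestimate electron correlation: their extreme
#' eigenvalues satisfy \eqn{\tilde{n}_H \le n_H} and
#' \eqn{\tilde{n}_L \ge n_L}, with a gap that grows with the amplitude
#' magnitude.
#'
#' @inheritParams mp2_density_blocks
#' @return A `"density_blocks"` object with `approximate = TRUE`.
#' @export
approx_density_blocks <- function(t) {
  stopifnot(inherits(t, "amplitude_set"))
  density_blocks_impl(t, approximate = TRUE)
}

# single home of the second-order contraction; tested against a loop oracle
density_blocks_impl <- function(t, approximate) {
  t2 <- t$t2; no <- t$n_occ; nv <- t$n_vir
  u <- if (approximate) 2 * t2 else 2 * t2 - aperm(t2, c(1, 2, 4, 3))
  ti <- matrix(t2, nrow = no)                      # rows i, cols (k,a,b)
  ui <- matrix(u, nrow = no)
  occ <- diag(2, no) - 2 * ti %*% t(ui)
  ta <- matrix(aperm(t2, c(3, 1, 2, 4)), nrow = nv)  # rows a, cols (i,j,c)
  ua <- matrix(aperm(u, c(3, 1, 2, 4)), nrow = nv)
  vir <- 2 * ta %*% t(ua)
  structure(list(occ_block = (occ + t(occ)) / 2,
                 vir_block = (vir + t(vir)) / 2,
                 approximate = approximate),
            class = "density_blocks")
}

#' @export
print.density_blocks <- function(x, ...) {
  cat(sprintf("<density_blocks>%s %dx%d occupied, %dx%d virtual, trace %.8g\n",
              if (x$approximate) " (exchange-free approximation)" else "",
              nrow(x$occ_block), ncol(x$occ_block),
              nrow(x$vir_block), ncol(x$vir_block),
              sum(diag(x$occ_block)) + sum(diag(x$vir_block))))
  invisible(x)
}

#' Extreme natural occupancies of the density blocks
#'
#' Identifies \eqn{n_H}, the lowest eigenvalue of the occupied block, and
#' \eqn{n_L}, the highest eigenvalue of the virtual block - the natural
#' occupancies closest to the occupied/virtual divide, which carry the
#' multireference signal.
#'
#' @param blocks a `"density_blocks"` object (full or approximate).
#' @param const constants; `const$hermit_tol` bounds the accepted asymmetry.
#' @return An object of class `"extreme_occupations"` with fields `n_h`,
#'   `n_l`, `approximate`.  A warning is raised when the pair falls outside
#'   the physically sensible ordering \eqn{0 \le n_L \le n_H \le 2}.
#' @export
extreme_occupations <- function(blocks, const = index_constants()) {
  stopifnot(inherits(blocks, "density_blocks"))
  for (nm in c("occ_block", "vir_block")) {
    m <- blocks[[nm]]
    if (max(abs(m - t(m))) > const$hermit_tol)
      nd_stop("noodiag_symmetry_error",
              "%s asymmetric by %.3e (tolerance %.1e)", nm,
              max(abs(m - t(m))), const$hermit_tol)
  }
  n_h <- min(eigen(blocks$occ_block, symmetric = TRUE, only.values = TRUE)$values)
  n_l <- max(eigen(blocks$vir_block, symmetric = TRUE, only.values = TRUE)$values)
  if (n_l < -1e-10 || n_h > 2 + 1e-10 || n_l > n_h + 1e-10)
    warning(sprintf(
      "extreme occupancies (n_H = %.6g, n_L = %.6g) outside the physical ordering 0 <= n_L <= n_H <= 2; amplitudes may be too large for second order",
      n_h, n_l), call. = FALSE)
  structure(list(n_h = n_h, n_l = n_l, approximate = blocks$approximate),
            class = "extreme_occupations")
}

#' @export
print.extreme_occupations <- function(x, ...) {
  cat(sprintf("<extreme_occupations>%s n_H = %.6g, n_L = %.6g\n",
              if (x$approximate) " (approximate)" else "", x$n_h, x$n_l))
  invisible(x)
}

#' I_ND^max from the extreme occupancy pair
#'
#' Evaluates the maximal single-orbital nondynamic contribution from the
#' frontier occupancies alone:
#' \deqn{I_{ND}^{max} = \tfrac18 \max\{ n_H (2 - n_H),\; n_L (2 - n_L) \}.}
#' Equals [nd_max()] over the full eigen-spectrum whenever one of the two
#' extreme eigenvalues dominates the deviation from idempotency, which holds
#' for second-order densities.
#'
#' @param x an `"extreme_occupations"` object, or a list with numeric `n_h`,
#'   `n_l` in \eqn{[0, 2]}.
#' @param const normalization constants.
#' @return Scalar in \eqn{[0, 1/8]}.
#' @examples
#' indmax_from_blocks(list(n_h = 1.98, n_l = 0.02))  # 0.00495
#' @export
indmax_from_blocks <- function(x, const = index_constants()) {
  n_h <- x$n_h; n_l <- x$n_l
  if (!is.finite(n_h) || !is.finite(n_l) ||
      n_h < -1e-10 || n_h > 2 + 1e-10 || n_l < -1e-10 || n_l > 2 + 1e-10)
    nd_stop("noodiag_range_error",
            "extreme occupancies (n_H = %g, n_L = %g) outside [0, 2]", n_h, n_l)
  n_h <- min(max(n_h, 0), 2); n_l <- min(max(n_l, 0), 2)
  # spatial n in [0,2]: per-spin n/2, so 1/2 * (n/2)(1 - n/2) = n(2-n)/8
  (const$max_prefactor / 4) * max(n_h * (2 - n_h), n_l * (2 - n_l))
}

#' Analytic I_ND^max estimate from the D2 diagnostic
#'
#' Propagates the exchange-free second-order relation
#' \eqn{\tilde{n}_L = k D_2^2} (with `k = const$d2_bridge`, fixed by the
#' single-dominant-amplitude limit) through the frontier-occupancy formula
#' of [indmax_from_blocks()]:
#' \deqn{I_{ND}^{max} \approx \tfrac18\, m (2 - m), \qquad
#'       m = \min(k D_2^2,\, 1).}
#' The cap at the midway occupancy \eqn{m = 1} keeps the map monotone; it is
#' strictly increasing for \eqn{D_2 < 1/2}, which covers the whole
#' diagnostic regime (thresholds sit at \eqn{D_2 = 0.15} to \eqn{0.18}).
#' The constant is exact in the single-dominant-amplitude limit; for
#' general amplitude tensors the estimate is a frontier-occupancy
#' approximation that rank-correlates strongly with the value computed from
#' the full blocks rather than bounding it.
#'
#' @param d2 nonnegative D2 value(s).
#' @param const constants; `const$d2_bridge` is the proportionality constant.
#' @return Estimate(s) of \eqn{I_{ND}^{max}} in \eqn{[0, 1/8]}.
#' @examples
#' predict_indmax_from_d2(c(0, 0.15, 0.18))
#' @export
predict_indmax_from_d2 <- function(d2, const = index_constants()) {
  stopifnot(all(is.finite(d2)), all(d2 >= 0))
  m <- pmin(const$d2_bridge * d2^2, 1)
  (const$max_prefactor / 4) * m * (2 - m)
}

#' Closed-shell occupancies collected from density blocks
#'
#' Diagonalizes both blocks and returns their eigenvalues as one
#' closed-shell occupancy set (the occupied-virtual coupling vanishes for
#' unrelaxed second-order densities, so the block eigenvalues are the
#' natural occupancies).
#'
#' @inheritParams extreme_occupations
#' @return A [closed_shell_occupancies()] set with \eqn{N = 2 n_{occ}}.
#' @export
occupancies_from_blocks <- function(blocks, const = index_constants()) {
  stopifnot(inherits(blocks, "density_blocks"))
  ev <- c(eigen(blocks$occ_block, symmetric = TRUE, only.values = TRUE)$values,
          eigen(blocks$vir_block, symmetric = TRUE, only.values = TRUE)$values)
  # second-order densities can mildly overshoot [0, 2]; clip to the physical range
  ev <- pmin(pmax(ev, 0), 2)
  closed_shell_occupancies(ev, n_electrons = 2L * nrow(blocks$occ_block),
                           label = if (blocks$approximate)
                             "approximate second-order density" else
                             "unrelaxed second-order density",
                           const = const)
}

# internal: top singular value (and optionally the spectrum) of a matrix
spectral_values <- function(m, keep_spectrum, const) {
  if (length(m) == 0) return(list(top = 0, spectrum = numeric(0)))
  if (min(dim(m)) <= const$svd_dense_max || keep_spectrum) {
    d <- svd(m, nu = 0, nv = 0)$d
    list(top = d[1], spectrum = if (keep_spectrum) d else NULL)
  } else {
    list(top = power_top_singular(m), spectrum = NULL)
  }
}

# power iteration on m'm for the largest singular value; tol 1e-10
power_top_singular <- function(m, tol = 1e-10, maxit = 10000L) {
  v <- rep(1 / sqrt(ncol(m)), ncol(m))
  s_old <- 0
  for (k in seq_len(maxit)) {
    w <- as.numeric(crossprod(m, m %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    s <- sqrt(nw)
    if (abs(s - s_old) <= tol * max(1, s)) return(s)
    s_old <- s
  }
  s_old
}
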