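#' Spin-resolved natural orbital occupancies
#'
#' Container for per-spin-orbital natural occupation numbers, the domain of
#' every correlation index in the package.  Occupations are validated against
#' the physical range \eqn{[0, 1]}: values within `tol_neg` outside the range
#' (typical of relaxed-density artifacts) are clipped with a warning, values
#' further out are an error naming the offending entry.  Entries are stored
#' in descending order within each spin channel; ties keep their original
#' input order so downstream boundary selections are reproducible.
#'
#' @param occ_alpha,occ_beta numeric vectors of spin-orbital occupations in
#'   \eqn{[0, 1]}.  `occ_beta` defaults to `occ_alpha` (closed shell).
#' @param n_alpha,n_beta integer electron counts per spin channel; default is
#'   the rounded occupation sum.  A mismatch between the sum and the declared
#'   count beyond `const$trace_tol` raises a warning, not an error.
#' @param label free-text provenance.
#' @param const numerical policy constants, see [index_constants()].
#' @return An object of class `"spin_occupancy_set"` with fields
#'   `occ_alpha`, `occ_beta`, `n_alpha`, `n_beta`, `label`.
#' @examples
#' spin_occupancy_set(c(1, 1, 0, 0))           # idempotent, 2 alpha electrons
#' spin_occupancy_set(c(0.95, 0.05), n_alpha = 1)
#' @seealso [closed_shell_occupancies()], [nondynamic_index()]
#' @export
spin_occupancy_set <- function(occ_alpha, occ_beta = occ_alpha,
                               n_alpha = NULL, n_beta = NULL,
                               label = "", const = index_constants()) {
  occ_alpha <- validate_channel(as.numeric(occ_alpha), "alpha", 1, const)
  occ_beta <- validate_channel(as.numeric(occ_beta), "beta", 1, const)
  if (is.null(n_alpha)) n_alpha <- as.integer(round(sum(occ_alpha)))
  if (is.null(n_beta)) n_beta <- as.integer(round(sum(occ_beta)))
  n_alpha <- as.integer(n_alpha); n_beta <- as.integer(n_beta)
  check_trace(occ_alpha, n_alpha, "alpha", const)
  check_trace(occ_beta, n_beta, "beta", const)
  structure(
    list(occ_alpha = sort_desc_stable(occ_alpha),
         occ_beta = sort_desc_stable(occ_beta),
         n_alpha = n_alpha, n_beta = n_beta, label = label),
    class = "spin_occupancy_set")
}

#' Closed-shell (spatial) natural orbital occupancies
#'
#' Spatial-orbital occupancies in \eqn{[0, 2]} for an even number of
#' electrons.  Convertible to a [spin_occupancy_set()] by halving each entry
#' into both spin channels; the round trip is exact.
#'
#' @param occ numeric vector of spatial occupations in \eqn{[0, 2]}.
#' @param n_electrons even integer electron count; default rounded sum.
#' @inheritParams spin_occupancy_set
#' @return An object of class `"closed_shell_occupancy_set"` with fields
#'   `occ`, `n_electrons`, `label`.
#' @examples
#' closed_shell_occupancies(c(2, 0))       # Hartree-Fock limit, N = 2
#' closed_shell_occupancies(c(1.9, 0.1))   # correlated two-electron pair
#' @export
closed_shell_occupancies <- function(occ, n_electrons = NULL, label = "",
                                     const = index_constants()) {
  occ <- validate_channel(as.numeric(occ), "spatial", 2, const)
  if (is.null(n_electrons)) n_electrons <- as.integer(round(sum(occ)))
  n_electrons <- as.integer(n_electrons)
  if (n_electrons %% 2L != 0L)
    nd_stop("noodiag_invalid_occupancy",
            "closed-shell electron count must be even, got %d", n_electrons)
  if (abs(sum(occ) - n_electrons) > const$trace_tol)
    warning(sprintf(
      "spatial occupancies sum to %.8g but n_electrons = %d (trace_tol %.1e)",
      sum(occ), n_electrons, const$trace_tol), call. = FALSE)
  structure(
    list(occ = sort_desc_stable(occ), n_electrons = n_electrons, label = label),
    class = "closed_shell_occupancy_set")
}

#' Convert occupancy containers to spin-resolved form
#'
#' @param x an occupancy set.
#' @param ... passed on to methods.
#' @return A [spin_occupancy_set()].
#' @export
as_spin_occupancy_set <- function(x, ...) UseMethod("as_spin_occupancy_set")

#' @export
as_spin_occupancy_set.spin_occupancy_set <- function(x, ...) x

#' @export
as_spin_occupancy_set.closed_shell_occupancy_set <- function(x, ...) {
  spin_occupancy_set(x$occ / 2, x$occ / 2,
                     n_alpha = x$n_electrons %/% 2L,
                     n_beta = x$n_electrons %/% 2L,
                     label = x$label)
}

#' Total electron count of an occupancy set
#' @param x an occupancy set.
#' @return integer \eqn{N}.
#' @export
n_electrons <- function(x) UseMethod("n_electrons")

#' @export
n_electrons.spin_occupancy_set <- function(x) x$n_alpha + x$n_beta

#' @export
n_electrons.closed_shell_occupancy_set <- function(x) x$n_electrons

#' @export
print.spin_occupancy_set <- function(x, ...) {
  cat(sprintf("<spin_occupancy_set> %d alpha + %d beta electrons, %d + %d spin orbitals\n",
              x$n_alpha, x$n_beta, length(x$occ_alpha), length(x$occ_beta)))
  cat("  alpha:", format(utils::head(x$occ_alpha, 8), digits = 4),
      if (length(x$occ_alpha) > 8) "..." else "", "\n")
  cat("  beta: ", format(utils::head(x$occ_beta, 8), digits = 4),
      if (length(x$occ_beta) > 8) "..." else "", "\n")
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' @export
print.closed_shell_occupancy_set <- function(x, ...) {
  cat(sprintf("<closed_shell_occupancy_set> N = %d, %d spatial orbitals\n",
              x$n_electrons, length(x$occ)))
  cat("  occ:", format(utils::head(x$occ, 8), digits = 4),
      if (length(x$occ) > 8) "..." else "", "\n")
  invisible(x)
}

# internal ------------------------------------------------------------------

# descending sort; ties keep original input order (order() is stable)
sort_desc_stable <- function(x) x[order(-x)]

# validate one occupancy channel against [0, top], clipping tol_neg overshoot
validate_channel <- function(occ, channel, top, const) {
  if (length(occ) && any(!is.finite(occ)))
    nd_stop("noodiag_invalid_occupancy",
            "non-finite occupation in %s channel at index %d",
            channel, which(!is.finite(occ))[1])
  tol <- const$tol_neg * top
  bad <- which(occ < -tol | occ > top + tol)
  if (length(bad))
    nd_stop("noodiag_invalid_occupancy",
            "occupation %.10g at index %d of %s channel outside [%g, %g] (tol %.1e)",
            occ[bad[1]], bad[1], channel, 0, top, tol)
  if (any(occ < 0 | occ > top)) {
    warning(sprintf("clipping %d %s occupation(s) within %.1e of [0, %g] into range",
                    sum(occ < 0 | occ > top), channel, tol, top), call. = FALSE)
    occ <- pmin(pmax(occ, 0), top)
  }
  occ
}

check_trace <- function(occ, n, channel, const) {
  if (abs(sum(occ) - n) > const$trace_tol)
    warning(sprintf("%s occupancies sum to %.8g but n_%s = %d (trace_tol %.1e)",
                    channel, sum(occ), channel, n, const$trace_tol),
            call. = FALSE)
  invisible(NULL)
}
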