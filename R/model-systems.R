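#' Specify a small model Hamiltonian
#'
#' Desk-scale model systems used as in-package oracles: exact
#' diagonalization of these Hamiltonians supplies CI vectors, one-particle
#' density matrices and natural occupancies with a tunable correlation
#' strength `U/t`.
#'
#' @param kind `"hubbard-dimer"`, `"hubbard-chain"` (open boundary),
#'   `"two-level-pairing"` or `"custom"`.
#' @param sites number of sites/levels (at most 6).
#' @param t hopping amplitude (level spacing is `2 t` for the pairing
#'   model); must be positive.
#' @param U on-site interaction (pairing strength for the pairing model);
#'   nonnegative.
#' @param n_alpha,n_beta electrons per spin; default half filling.
#' @param h_site,u_site for `kind = "custom"`: one-body site matrix and
#'   per-site interaction vector.
#' @return An object of class `"model_spec"`.
#' @examples
#' model_spec("hubbard-chain", sites = 4, t = 1, U = 2)
#' @export
model_spec <- function(kind = c("hubbard-dimer", "hubbard-chain",
                                "two-level-pairing", "custom"),
                       sites = 2L, t = 1, U = 0,
                       n_alpha = NULL, n_beta = NULL,
                       h_site = NULL, u_site = NULL) {
  kind <- match.arg(kind)
  if (kind == "hubbard-dimer") sites <- 2L
  if (kind == "custom") {
    stopifnot(is.matrix(h_site), nrow(h_site) == ncol(h_site))
    sites <- nrow(h_site)
    if (is.null(u_site)) u_site <- rep(0, sites)
    stopifnot(length(u_site) == sites)
  }
  sites <- as.integer(sites)
  if (sites < 2L || sites > 6L)
    nd_stop("noodiag_parameter_error", "sites must be in 2..6, got %d", sites)
  if (t <= 0)
    nd_stop("noodiag_parameter_error", "hopping t must be positive, got %g", t)
  if (U < 0)
    nd_stop("noodiag_parameter_error", "interaction U must be nonnegative, got %g", U)
  if (is.null(n_alpha)) n_alpha <- sites %/% 2L
  if (is.null(n_beta)) n_beta <- n_alpha
  n_alpha <- as.integer(n_alpha); n_beta <- as.integer(n_beta)
  if (n_alpha < 0L || n_beta < 0L || n_alpha > sites || n_beta > sites)
    nd_stop("noodiag_parameter_error",
            "electron counts (%d, %d) incompatible with %d sites",
            n_alpha, n_beta, sites)
  hdim <- choose(sites, n_alpha) * choose(sites, n_beta)
  if (hdim > 1e4)
    nd_stop("noodiag_guard_error",
            "Hilbert-space dimension %g exceeds the desk-scale guard of 1e4", hdim)
  structure(list(kind = kind, sites = sites, t = t, U = U,
                 n_alpha = n_alpha, n_beta = n_beta,
                 h_site = h_site, u_site = u_site),
            class = "model_spec")
}

#' Analytic Hubbard dimer ground state
#'
#' Half-filled two-site Hubbard singlet: in the mean-field (bonding g /
#' antibonding u) orbital basis the singlet problem has three
#' configurations, of which the closed-shell pair `g^2` and `u^2` couple
#' through `U/2` while the open-shell singlet decouples by symmetry.  The
#' ground state is
#' \deqn{E_0 = U/2 - \sqrt{U^2/4 + 4 t^2},}
#' with natural spin occupancies \eqn{(c_0^2, 1 - c_0^2)} interpolating from
#' the idempotent mean-field limit at `U = 0` to the fully entangled
#' \eqn{(1/2, 1/2)} as \eqn{U/t \to \infty}.
#'
#' @param U on-site repulsion (nonnegative).
#' @param t hopping (positive).
#' @return A `"model_solution"`: `energy`, `ci` (data frame of determinant
#'   bitmasks with ranks and coefficients, reference flagged), `one_rdm`
#'   (per-spin matrices in the mean-field orbital basis), `occupancies`
#'   ([spin_occupancy_set()]), `c0`, `e_reference`, `metadata`.
#' @examples
#' sol <- hubbard_dimer(U = 4, t = 1)
#' sol$occupancies
#' nd_max(sol$occupancies)
#' @export
hubbard_dimer <- function(U, t = 1) {
  if (t <= 0)
    nd_stop("noodiag_parameter_error", "hopping t must be positive, got %g", t)
  if (U < 0)
    nd_stop("noodiag_parameter_error", "interaction U must be nonnegative, got %g", U)
  two_config_solution(e_gap = 4 * t, coupling = U / 2, e_shift = -2 * t + U / 2,
                      kind = "hubbard-dimer", params = list(U = U, t = t))
}

# shared analytic 2x2 closed-shell CI: H = [[e_shift, coupling],
#                                           [coupling, e_shift + e_gap]]
# in the {reference pair, doubly excited pair} basis
two_config_solution <- function(e_gap, coupling, e_shift, kind, params) {
  disc <- sqrt((e_gap / 2)^2 + coupling^2)
  energy <- e_shift + e_gap / 2 - disc
  # eigenvector from the second row: robust at coupling -> 0
  r <- coupling / (e_gap / 2 + disc)
  c0 <- 1 / sqrt(1 + r^2)
  c2 <- -r * c0
  ci <- data.frame(det_alpha = c(1L, 1L, 2L, 2L),
                   det_beta = c(1L, 2L, 1L, 2L),
                   rank = c(0L, 1L, 1L, 2L),
                   coefficient = c(c0, 0, 0, c2),
                   is_reference = c(TRUE, FALSE, FALSE, FALSE))
  rdm <- diag(c(c0^2, c2^2))
  occ <- spin_occupancy_set(c(c0^2, c2^2), n_alpha = 1L, n_beta = 1L,
                            label = sprintf("%s analytic ground state", kind))
  structure(
    list(energy = energy,
         ci = ci,
         one_rdm = list(alpha = rdm, beta = rdm),
         occupancies = occ,
         c0 = c0,
         e_reference = e_shift,
         metadata = c(params,
                      list(kind = kind, degenerate = FALSE,
                           reference = "aufbau mean-field determinant (alpha-major bitstrings, lowest orbital first)"))),
    class = "model_solution")
}

#' Exact diagonalization of a model specification
#'
#' Full CI over bitstring determinants.  For Hubbard-type specifications the
#' many-body Hamiltonian is assembled in the site basis (where the
#' interaction is diagonal); the ground-state vector is then projected onto
#' determinants of the mean-field (`U = 0`) orbitals through per-spin
#' determinant overlap matrices, and the one-particle density matrix in
#' that basis is accumulated by the one-substitution Slater-Condon sum.
#' The global phase is fixed so the reference coefficient is nonnegative;
#' a ground-state degeneracy (possible at special parameter points) selects
#' the lowest-index eigenvector and is flagged in the metadata.
#'
#' @param spec a [model_spec()].
#' @return A `"model_solution"` (see [hubbard_dimer()]); `ci` holds one row
#'   per determinant pair with alpha/beta bitmasks, excitation rank relative
#'   to the aufbau reference, and coefficient.
#' @examples
#' sol <- exact_diagonalize(model_spec("hubbard-chain", sites = 4, U = 2))
#' sol$energy <= sol$e_reference
#' @export
exact_diagonalize <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$kind == "two-level-pairing") {
    if (spec$n_alpha != 1L || spec$n_beta != 1L || spec$sites != 2L)
      nd_stop("noodiag_parameter_error",
              "two-level-pairing oracle is defined for 2 electrons in 2 levels")
    return(two_config_solution(e_gap = 4 * spec$t, coupling = -spec$U,
                               e_shift = -spec$U,
                               kind = "two-level-pairing",
                               params = list(U = spec$U, t = spec$t)))
  }
  M <- spec$sites
  h <- spec$h_site
  u_site <- spec$u_site
  if (spec$kind != "custom") {
    h <- matrix(0, M, M)
    for (s in seq_len(M - 1L)) h[s, s + 1L] <- h[s + 1L, s] <- -spec$t
    u_site <- rep(spec$U, M)
  }
  # mean-field orbitals: one-particle eigenvectors, ascending energy,
  # sign-fixed (largest-magnitude component positive) for reproducibility
  ev <- eigen(h, symmetric = TRUE)
  ord <- order(ev$values)
  C <- ev$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(C))) {
    j <- which.max(abs(C[, k]))
    if (C[j, k] < 0) C[, k] <- -C[, k]
  }
  e_orb <- ev$values[ord]

  dets_a <- sc_dets(M, spec$n_alpha)
  dets_b <- sc_dets(M, spec$n_beta)
  Nb <- length(dets_b)
  H <- sc_hubbard_hamiltonian(h, u_site, dets_a, dets_b, M)
  es <- eigen(H, symmetric = TRUE)
  dim <- nrow(H)
  energy <- es$values[dim]
  degenerate <- dim > 1 && abs(es$values[dim - 1L] - energy) < 1e-8
  c_site <- es$vectors[, dim]

  # project onto mean-field-orbital determinants (alpha-major Kronecker)
  Sa <- sc_overlap(C, dets_a, dets_a, M)
  Sb <- sc_overlap(C, dets_b, dets_b, M)
  c_mo <- as.numeric(kronecker(Sa, Sb) %*% c_site)
  ref_idx <- 1L  # aufbau mask 2^n - 1 is the first lexicographic determinant
  if (c_mo[ref_idx] < 0 || (c_mo[ref_idx] == 0 && c_mo[which(c_mo != 0)[1]] < 0)) {
    c_mo <- -c_mo; c_site <- -c_site
  }

  ranks <- integer(dim)
  ia_of <- rep(seq_along(dets_a), each = Nb)
  ib_of <- rep(seq_along(dets_b), times = length(dets_a))
  ref_a <- dets_a[1L]; ref_b <- dets_b[1L]
  for (k in seq_len(dim))
    ranks[k] <- (sc_popcount(bitwXor(dets_a[ia_of[k]], ref_a)) +
                   sc_popcount(bitwXor(dets_b[ib_of[k]], ref_b))) %/% 2L

  rdm <- sc_one_rdm(c_mo, dets_a, dets_b, M)
  occ <- natural_occupations(rdm,
                             label = sprintf("%s U=%g t=%g exact ground state",
                                             spec$kind, spec$U, spec$t))

  # mean-field determinant energy in the interacting Hamiltonian
  e_vec <- as.numeric(kronecker(Sa[ref_idx, , drop = FALSE],
                                Sb[ref_idx, , drop = FALSE]))
  e_reference <- as.numeric(e_vec %*% H %*% e_vec)

  structure(
    list(energy = energy,
         ci = data.frame(det_alpha = dets_a[ia_of], det_beta = dets_b[ib_of],
                         rank = ranks, coefficient = c_mo,
                         is_reference = seq_len(dim) == ref_idx),
         one_rdm = rdm,
         occupancies = occ,
         c0 = c_mo[ref_idx],
         e_reference = e_reference,
         orbital_energies = e_orb,
         mo_coefficients = C,
         metadata = list(kind = spec$kind, U = spec$U, t = spec$t,
                         sites = M, n_alpha = spec$n_alpha,
                         n_beta = spec$n_beta, degenerate = degenerate,
                         reference = "aufbau mean-field determinant (alpha-major bitstrings, lowest orbital first)")),
    class = "model_solution")
}

#' @export
print.model_solution <- function(x, ...) {
  cat(sprintf("<model_solution> %s: E0 = %.8g (reference %.8g), c0^2 = %.6g%s\n",
              x$metadata$kind, x$energy, x$e_reference, x$c0^2,
              if (isTRUE(x$metadata$degenerate)) " [degenerate ground state]" else ""))
  print(x$occupancies)
  invisible(x)
}

#' Natural occupancies from a one-particle density matrix
#'
#' Diagonalizes per-spin Hermitian density blocks and returns the sorted
#' eigenvalues as a [spin_occupancy_set()], clipped by the standard
#' occupancy policy.
#'
#' @param one_rdm a Hermitian matrix (used for both spin channels) or a
#'   list with elements `alpha` and `beta`.
#' @param label provenance text.
#' @param const numerical policy constants.
#' @return A [spin_occupancy_set()].
#' @examples
#' natural_occupations(diag(c(0.98, 0.02)))
#' @export
natural_occupations <- function(one_rdm, label = "", const = index_constants()) {
  as_channel <- function(m, nm) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
      nd_stop("noodiag_dimension_error", "%s density matrix must be square", nm)
    if (max(abs(m - t(Conj(m)))) > const$hermit_tol)
      nd_stop("noodiag_symmetry_error",
              "%s density matrix non-Hermitian by %.3e (tolerance %.1e)",
              nm, max(abs(m - t(Conj(m)))), const$hermit_tol)
    sort(Re(eigen((m + t(Conj(m))) / 2, symmetric = TRUE,
                  only.values = TRUE)$values), decreasing = TRUE)
  }
  if (is.matrix(one_rdm)) one_rdm <- list(alpha = one_rdm, beta = one_rdm)
  occ_a <- as_channel(one_rdm$alpha, "alpha")
  occ_b <- as_channel(one_rdm$beta, "beta")
  spin_occupancy_set(pmin(pmax(occ_a, 0), 1), pmin(pmax(occ_b, 0), 1),
                     n_alpha = round(sum(occ_a)), n_beta = round(sum(occ_b)),
                     label = label, const = const)
}

#' Seeded sampler of doubles-amplitude tensors
#'
#' Reproducible random [amplitude_set()] generators for ensemble
#' experiments.  The default `"mp2"` structure mimics genuine second-order
#' amplitudes, \eqn{t_{ij}^{ab} = -G_{ia,jb} / (\epsilon_a + \epsilon_b -
#' \epsilon_i - \epsilon_j)} with a random positive-semidefinite integral
#' kernel `G` and positive energy denominators - the structure under which
#' the exchange-free approximation provably overestimates correlation.
#' `"gaussian"` gives a plain symmetrized Gaussian tensor with entries of
#' magnitude about `scale`.  Both are exactly linear in `scale` at fixed
#' seed, so the D2 diagnostic is scale-equivariant, and the caller's RNG
#' state is left untouched.
#'
#' @param n_occ,n_vir positive orbital-space dimensions.
#' @param scale nonnegative amplitude magnitude (`max |t| = scale` for
#'   `"mp2"`; Gaussian standard deviation for `"gaussian"`).
#' @param seed integer seed; identical seeds give identical tensors.
#' @param structure `"mp2"` (default) or `"gaussian"`.
#' @return An [amplitude_set()].
#' @examples
#' t <- sample_amplitudes(3, 4, scale = 0.05, seed = 42)
#' d2_diagnostic(t)$value
#' @export
sample_amplitudes <- function(n_occ, n_vir, scale, seed,
                              structure = c("mp2", "gaussian")) {
  structure <- match.arg(structure)
  n_occ <- as.integer(n_occ); n_vir <- as.integer(n_vir)
  if (n_occ < 1L || n_vir < 1L)
    nd_stop("noodiag_parameter_error",
            "orbital-space dimensions must be positive, got (%d, %d)",
            n_occ, n_vir)
  if (!is.finite(scale) || scale < 0)
    nd_stop("noodiag_parameter_error", "scale must be nonnegative, got %g", scale)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  if (structure == "gaussian") {
    t2 <- array(stats::rnorm(n_occ^2 * n_vir^2), c(n_occ, n_occ, n_vir, n_vir))
    t2 <- scale * (t2 + aperm(t2, c(2, 1, 4, 3))) / 2
  } else {
    nia <- n_occ * n_vir
    L <- matrix(stats::rnorm(nia * (nia + 2L)), nia)
    G <- L %*% t(L)
    e_occ <- sort(stats::runif(n_occ, -2, -0.5))
    e_vir <- sort(stats::runif(n_vir, 0.3, 2))
    t2 <- array(0, c(n_occ, n_occ, n_vir, n_vir))
    for (i in seq_len(n_occ)) for (j in seq_len(n_occ))
      for (a in seq_len(n_vir)) for (b in seq_len(n_vir))
        t2[i, j, a, b] <- -G[(i - 1L) * n_vir + a, (j - 1L) * n_vir + b] /
          (e_vir[a] + e_vir[b] - e_occ[i] - e_occ[j])
    mx <- max(abs(t2))
    if (mx > 0) t2 <- t2 / mx * scale
  }
  amplitude_set(t2)
}

#' Correlation-regime sweep over a model family
#'
#' Solves the model at each interaction strength and tabulates every
#' occupancy index together with the CI leading weight and its
#' [predict_ind_hat_from_c0()] estimate - the model-system analogue of the
#' correlation-regime scans used to validate the analytic bridges.
#'
#' @param u_over_t numeric grid of interaction-to-hopping ratios.
#' @param t hopping (sets the absolute scale).
#' @param kind `"hubbard-dimer"` (analytic path), `"hubbard-chain"` or
#'   `"two-level-pairing"`.
#' @param sites chain length for `"hubbard-chain"`.
#' @param method optional method name for MR classification of each row.
#' @return A data frame, one row per grid point: `u_over_t`, `energy`,
#'   `c0sq`, all [correlation_report()] indices, `ind_hat_from_c0`,
#'   `bridge_residual` (absolute Eq-20 deviation), `d2` (`NA`: no doubles
#'   amplitudes are defined for these Hamiltonians), `classification`.
#' @examples
#' model_sweep(c(0, 1, 2, 4, 8))
#' @export
model_sweep <- function(u_over_t, t = 1, kind = c("hubbard-dimer",
                                                  "hubbard-chain",
                                                  "two-level-pairing"),
                        sites = 4L, method = NULL) {
  kind <- match.arg(kind)
  rows <- lapply(u_over_t, function(r) {
    sol <- if (kind == "hubbard-dimer") hubbard_dimer(U = r * t, t = t)
    else exact_diagonalize(model_spec(kind, sites = sites, t = t, U = r * t))
    rep <- correlation_report(sol$occupancies, method = method)
    n_el <- n_electrons(sol$occupancies)
    est <- predict_ind_hat_from_c0(sol$c0, n_el)
    data.frame(u_over_t = r, energy = sol$energy, c0sq = sol$c0^2,
               i_nd = rep$i_nd, i_d = rep$i_d, i_t = rep$i_t,
               i_nd_hat = rep$i_nd_hat, i_d_hat = rep$i_d_hat,
               i_nd_hat_occ = rep$i_nd_hat_occ,
               i_nd_hat_vir = rep$i_nd_hat_vir,
               i_nd_max = rep$i_nd_max, ph_asymmetry = rep$ph_asymmetry,
               ind_hat_from_c0 = est,
               bridge_residual = abs(rep$i_nd_hat - est),
               d2 = NA_real_,
               classification = rep$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
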