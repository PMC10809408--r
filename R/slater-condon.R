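# Bitstring determinant machinery for the exact-diagonalization oracles.
#
# Conventions (fixed so CI vectors are portable):
#   * orbitals/sites are numbered 1..M; bit (p-1) of an integer mask marks
#     orbital p occupied;
#   * determinant lists are lexicographic over ascending orbital indices
#     (lowest-orbital-first), so the aufbau mask 2^n - 1 is always entry 1;
#   * the full many-body basis is alpha-major: k = (i_alpha - 1) * Nb + i_beta;
#   * operator strings act alpha-before-beta, so per-spin overlap matrices
#     combine as a plain Kronecker product without extra signs.

sc_bits <- function(mask, M) which(bitwAnd(mask, bitwShiftL(1L, 0:(M - 1L))) != 0L)

sc_popcount <- function(mask) {
  n <- 0L
  while (mask > 0L) { n <- n + bitwAnd(mask, 1L); mask <- bitwShiftR(mask, 1L) }
  n
}

# all n-electron determinants over M orbitals, lexicographic masks
sc_dets <- function(M, n) {
  if (n == 0L) return(0L)
  if (n > M) nd_stop("noodiag_dimension_error",
                     "cannot place %d electrons in %d orbitals", n, M)
  combs <- utils::combn(M, n)
  as.integer(colSums(matrix(bitwShiftL(1L, combs - 1L), nrow = n)))
}

# phase of a_q acting first then a^dagger_p on mask I (q occupied, p empty)
sc_exc_phase <- function(I, p, q) {
  below <- function(mask, orb) sc_popcount(bitwAnd(mask, bitwShiftL(1L, orb - 1L) - 1L))
  ph <- (-1L)^below(I, q)
  I2 <- bitwAnd(I, bitwNot(bitwShiftL(1L, q - 1L)))
  ph * (-1L)^below(I2, p)
}

# table of all single substitutions within a determinant list:
# a^dagger_p a_q |dets[from]> = phase |dets[to]>, p != q
sc_singles_table <- function(dets, M) {
  lookup <- structure(seq_along(dets), names = as.character(dets))
  from <- integer(0); to <- integer(0); cr <- integer(0); an <- integer(0)
  ph <- integer(0)
  for (i in seq_along(dets)) {
    I <- dets[i]
    occ <- sc_bits(I, M)
    emp <- setdiff(seq_len(M), occ)
    for (q in occ) for (p in emp) {
      J <- bitwOr(bitwAnd(I, bitwNot(bitwShiftL(1L, q - 1L))),
                  bitwShiftL(1L, p - 1L))
      j <- lookup[[as.character(J)]]
      from <- c(from, i); to <- c(to, j); cr <- c(cr, p); an <- c(an, q)
      ph <- c(ph, sc_exc_phase(I, p, q))
    }
  }
  list(from = from, to = to, create = cr, annihilate = an, phase = ph)
}

# dense many-body Hamiltonian for H = sum_sigma h_pq a+a + sum_m U_m n_m,up n_m,dn
# (one-body general, two-body diagonal in this basis - the Hubbard structure)
sc_hubbard_hamiltonian <- function(h, u_site, dets_a, dets_b, M) {
  Na <- length(dets_a); Nb <- length(dets_b)
  dim <- Na * Nb
  H <- matrix(0, dim, dim)
  diag_1b <- function(dets) vapply(dets, function(I) sum(diag(h)[sc_bits(I, M)]),
                                   numeric(1))
  ea <- diag_1b(dets_a); eb <- diag_1b(dets_b)
  for (ia in seq_len(Na)) for (ib in seq_len(Nb)) {
    k <- (ia - 1L) * Nb + ib
    dbl <- sc_bits(bitwAnd(dets_a[ia], dets_b[ib]), M)
    H[k, k] <- ea[ia] + eb[ib] + sum(u_site[dbl])
  }
  ta <- sc_singles_table(dets_a, M)
  for (r in seq_along(ta$from)) {
    hval <- h[ta$create[r], ta$annihilate[r]]
    if (hval == 0) next
    for (ib in seq_len(Nb)) {
      k <- (ta$to[r] - 1L) * Nb + ib
      l <- (ta$from[r] - 1L) * Nb + ib
      H[k, l] <- H[k, l] + ta$phase[r] * hval
    }
  }
  tb <- sc_singles_table(dets_b, M)
  for (r in seq_along(tb$from)) {
    hval <- h[tb$create[r], tb$annihilate[r]]
    if (hval == 0) next
    for (ia in seq_len(Na)) {
      k <- (ia - 1L) * Nb + tb$to[r]
      l <- (ia - 1L) * Nb + tb$from[r]
      H[k, l] <- H[k, l] + tb$phase[r] * hval
    }
  }
  H
}

# per-spin determinant overlap matrix between a target orbital basis (columns
# of C, orthonormal) and the site basis: S[K, I] = det(C[sites(I), orbs(K)])
sc_overlap <- function(C, dets_target, dets_site, M) {
  S <- matrix(0, length(dets_target), length(dets_site))
  orbs <- lapply(dets_target, sc_bits, M = M)
  sites <- lapply(dets_site, sc_bits, M = M)
  for (K in seq_along(dets_target)) for (I in seq_along(dets_site)) {
    sub <- C[sites[[I]], orbs[[K]], drop = FALSE]
    S[K, I] <- if (nrow(sub) == 0) 1 else det(sub)
  }
  S
}

# spin-resolved 1-RDM <a+_p a_q> from a CI vector by the one-substitution
# Slater-Condon sum (diagonal occupations plus the singles table)
sc_one_rdm <- function(coef, dets_a, dets_b, M) {
  Na <- length(dets_a); Nb <- length(dets_b)
  ga <- matrix(0, M, M); gb <- matrix(0, M, M)
  for (ia in seq_len(Na)) for (ib in seq_len(Nb)) {
    w <- coef[(ia - 1L) * Nb + ib]^2
    if (w == 0) next
    occa <- sc_bits(dets_a[ia], M); occb <- sc_bits(dets_b[ib], M)
    ga[cbind(occa, occa)] <- ga[cbind(occa, occa)] + w
    gb[cbind(occb, occb)] <- gb[cbind(occb, occb)] + w
  }
  ta <- sc_singles_table(dets_a, M)
  for (r in seq_along(ta$from)) {
    p <- ta$create[r]; q <- ta$annihilate[r]
    for (ib in seq_len(Nb)) {
      ga[p, q] <- ga[p, q] +
        ta$phase[r] * coef[(ta$to[r] - 1L) * Nb + ib] *
          coef[(ta$from[r] - 1L) * Nb + ib]
    }
  }
  tb <- sc_singles_table(dets_b, M)
  for (r in seq_along(tb$from)) {
    p <- tb$create[r]; q <- tb$annihilate[r]
    for (ia in seq_len(Na)) {
      gb[p, q] <- gb[p, q] +
        tb$phase[r] * coef[(ia - 1L) * Nb + tb$to[r]] *
          coef[(ia - 1L) * Nb + tb$from[r]]
    }
  }
  list(alpha = ga, beta = gb)
}
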