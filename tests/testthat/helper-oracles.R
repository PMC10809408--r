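# Independent brute-force oracles used across the suite.  These deliberately
# use plain elementwise loops/sums, not the package's vectorized paths.

# direct-sum index oracles over a spin occupancy vector
oracle_ind <- function(n) {
  s <- 0
  for (x in n) s <- s + x * (1 - x)
  s / 2
}
oracle_it <- function(n) {
  s <- 0
  for (x in n) s <- s + sqrt(max(x * (1 - x), 0))
  s / 2
}

# one random occupancy channel with sum(x) == n_el and all entries in [0, 1]
rand_channel <- function(n_el, n_orb) {
  stopifnot(n_orb >= n_el)
  repeat {
    x <- stats::runif(n_orb)
    x <- x * n_el / sum(x)
    if (all(x <= 1)) return(x)
  }
}

rand_spin_set <- function() {
  na <- sample(1:3, 1)
  nb <- sample(1:3, 1)
  spin_occupancy_set(rand_channel(na, na * 2 + sample(0:4, 1)),
                     rand_channel(nb, nb * 2 + sample(0:4, 1)),
                     n_alpha = na, n_beta = nb)
}

# index-loop oracle for the second-order density blocks
oracle_blocks <- function(t2, approximate = FALSE) {
  no <- dim(t2)[1]; nv <- dim(t2)[3]
  occ <- diag(2, no)
  for (i in seq_len(no)) for (j in seq_len(no)) {
    s <- 0
    for (k in seq_len(no)) for (a in seq_len(nv)) for (b in seq_len(nv)) {
      u <- if (approximate) 2 * t2[j, k, a, b]
      else 2 * t2[j, k, a, b] - t2[j, k, b, a]
      s <- s + t2[i, k, a, b] * u
    }
    occ[i, j] <- occ[i, j] - 2 * s
  }
  vir <- matrix(0, nv, nv)
  for (a in seq_len(nv)) for (b in seq_len(nv)) {
    s <- 0
    for (i in seq_len(no)) for (j in seq_len(no)) for (cc in seq_len(nv)) {
      u <- if (approximate) 2 * t2[i, j, b, cc]
      else 2 * t2[i, j, b, cc] - t2[i, j, cc, b]
      s <- s + t2[i, j, a, cc] * u
    }
    vir[a, b] <- 2 * s
  }
  list(occ = occ, vir = vir)
}

# dense-SVD oracles for the D2 matricizations
oracle_d2_compound <- function(t2) {
  no <- dim(t2)[1]; nv <- dim(t2)[3]
  m <- matrix(0, no * no, nv * nv)
  for (i in seq_len(no)) for (j in seq_len(no))
    for (a in seq_len(nv)) for (b in seq_len(nv))
      m[(i - 1) * no + j, (a - 1) * nv + b] <- t2[i, j, a, b]
  max(svd(m)$d)
}
oracle_d2_per_occ <- function(t2) {
  no <- dim(t2)[1]; nv <- dim(t2)[3]
  best <- 0
  for (i in seq_len(no)) {
    m <- matrix(0, no, nv * nv)
    for (j in seq_len(no)) for (a in seq_len(nv)) for (b in seq_len(nv))
      m[j, (a - 1) * nv + b] <- t2[i, j, a, b]
    best <- max(best, svd(m)$d[1])
  }
  best
}

rand_amplitudes <- function(seed, scale = 0.08) {
  sample_amplitudes(sample(2:4, 1), sample(2:5, 1), scale, seed)
}

# path to the installed CLI wrapper script
cli_script <- function() system.file("cli", "noodiag.R", package = "noodiag")

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cli_script(), args),
                                  stdout = TRUE, stderr = TRUE))
  list(status = if (is.null(attr(out, "status"))) 0L else attr(out, "status"),
       output = out)
}
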