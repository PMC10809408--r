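---
title: "Occupancy-based correlation measures and multireference diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy-based correlation measures and multireference diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noodiag)
```

## The model

A mean-field (Hartree--Fock) state has an idempotent one-particle reduced
density matrix (1-RDM): every natural spin orbital is occupied by exactly
one electron or empty.  Electron correlation spreads occupation across
orbitals, so the eigenvalues $n_{i\sigma}$ of the correlated 1-RDM become
fractional.  `noodiag` quantifies that deviation with a family of indices
computed from the natural orbital occupation numbers (NOOs) alone:

* **Nondynamic correlation** $I_{ND} = \tfrac12 \sum_{i\sigma}
  n_{i\sigma}(1-n_{i\sigma})$, the deviation from idempotency, bounded by
  $N/2$ for $N$ electrons.  For closed shells with spatial occupancies
  $n_i \in [0,2]$ this is $\tfrac14\sum_i n_i(2-n_i)$.
* **Total and dynamic correlation** $I_T = \tfrac12 \sum_{i\sigma}
  \sqrt{n_{i\sigma}(1-n_{i\sigma})}$ and $I_D = I_T - I_{ND}$.  The square
  root weights many small deviations much more strongly than one large
  one, which is the signature of dynamic correlation; $I_D$ is unbounded
  as occupation spreads over ever more orbitals.
* **Size-intensive forms** $\hat I_{ND} = 2 I_{ND}/N \in [0,1]$, and by
  the same $2/N$ scale $\hat I_D$.  $I_D$ has no natural upper bound, so
  no normalization can confine $\hat I_D$ to $[0,1]$; we expose both the
  raw $I_D$ and the $2/N$-scaled value and leave the choice to the user.
* **Pseudo-occupied/pseudo-virtual split**: the $N^\alpha$ (and $N^\beta$)
  highest-occupied spin natural orbitals define the pseudo-occupied space;
  $\hat I_{ND} = \hat I_{ND}^{o} + \hat I_{ND}^{v}$ exactly, and the
  near-equality of the two halves (particle--hole symmetry) is reported as
  `ph_asymmetry`.
* **The diagnostic** $I_{ND}^{max} = \tfrac12 \max_{i\sigma}
  n_{i\sigma}(1-n_{i\sigma}) \in [0, \tfrac18]$: the single worst orbital.
  A molecule deserves a multireference (MR) treatment as soon as *one*
  orbital pair sits far from integer occupation, no matter how large the
  molecule is, which is why the maximum, not the sum, is the recommended
  MR diagnostic.

Classification against `I_ND^max` uses method-specific thresholds
(`default_thresholds()`): below the lower value the system is non-MR, at
or above the upper value it is MR, in between it deserves caution.  The
shipped values translate the Nielsen--Janssen $D_2$ boundaries (0.15 safe;
0.17 for MP2 / 0.18 for CCSD) through large fitted equivalences: MP2
0.030/0.037 (5090-molecule fit; the 34-molecule fit 0.029/0.037 ships as
`"mp2-setc"`), CCSD 0.024/0.034.  The tables are plain data frames, so a
user calibrating another method supplies a `threshold_table()` (or a JSON
file on the command line) without touching code.

### Prefactor conventions

All normalization constants live in `index_constants()`.  The conventions
are pinned by three internal-consistency requirements: the $\tfrac12$ spin
prefactor fixes the $[0, N/2]$ range of $I_{ND}$; the $2/N$ intensive
scale makes the weak-correlation estimate of $\hat I_{ND}$ come out as
$4(1-c_0^2)/N$ (below); and the $\tfrac12$ maximum prefactor puts the
fitted MR thresholds well below the $\tfrac18$ ceiling.  An alternative
convention is a one-argument change, not an edit across files.

## Analytic bridges

**To the CI leading coefficient.**  For a normalized CISD-type expansion
with reference weight $c_0^2$, singles weight $c_S^2$ and doubles weight
$c_D^2$, each single promotes one electron and each double two, so the
trace of the 1-RDM over the mean-field virtual block is
$c_S^2 + 2 c_D^2$ (`cisd_trace_decomposition()`).  When the 1-RDM is
dominantly block diagonal -- the weakly correlated regime -- this trace
leak is carried by occupancies close to 0 and 2, and propagating it
through the intensive normalization gives
$\hat I_{ND} \approx 4(1-c_0^2)/N$ (`predict_ind_hat_from_c0()`).  The
package also provides the size-intensive reference weight
$1 - (c_0^2)^{1/N}$, whose Taylor expansion around $c_0^2 \to 1$ begins
with $(1-c_0^2)/N$ -- the same leading behaviour, which is what makes
$c_0$ usable as a correlation measure once properly normalized.

**To the $D_2$ diagnostic.**  For closed-shell doubles amplitudes
$t_{ij}^{ab}$ the unrelaxed second-order density has occupied and virtual
blocks (with $u = 2t - t^{\mathrm{swap}}$ the spin-adapted combination)

$$ {}^1D^{occ}_{ij} = 2\delta_{ij} - 2\sum_{kab} t_{ik}^{ab} u_{jk}^{ab},
   \qquad
   {}^1D^{vir}_{ab} = 2\sum_{ijc} t_{ij}^{ac} u_{ij}^{bc}, $$

whose corrections carry opposite traces, so particle number is conserved
exactly.  The frontier eigenvalues $n_H$ (lowest occupied) and $n_L$
(highest virtual) determine $I_{ND}^{max} = \tfrac18\max\{n_H(2-n_H),
n_L(2-n_L)\}$ (`indmax_from_blocks()`).  Dropping the exchange-like term
($u \to 2t$, `approx_density_blocks()`) yields blocks whose frontier
eigenvalues $\tilde n_H \le n_H$ and $\tilde n_L \ge n_L$ overestimate
correlation; in the single-dominant-amplitude limit $\tilde n_L = 4 D_2^2$
exactly, which fixes the bridge constant of `predict_indmax_from_d2()`.
The estimate is capped at the midway occupancy $\tilde n_L = 1$ so the map
stays monotone; it is strictly increasing for $D_2 < 0.5$, far beyond the
diagnostic thresholds.  For generic tensors the bridge is an
approximation validated by rank correlation with the full-block value,
not a bound.

$D_2$ itself (`d2_diagnostic()`) is a spectral norm of the amplitude
tensor.  Two matricizations ship behind a switch because the literature
convention arranges the amplitudes per occupied orbital: the default
`"per-occupied-max"` takes, for each $i$, the matrix $(T^{(i)})_{j,(ab)}$
and reports the largest of the spectral norms; `"compound"` takes the
single $(ij)\times(ab)$ matrix.  Both coincide for one dominant
amplitude, scale linearly with the amplitudes, and are invariant under
the simultaneous $(i\leftrightarrow j, a\leftrightarrow b)$ relabeling
that the tensor symmetry $t_{ij}^{ab} = t_{ji}^{ba}$ permits.  Spectral
norms use a dense SVD up to dimension 500 (`svd_dense_max`) and a power
iteration with tolerance $10^{-10}$ above it.

## Model systems: the in-package oracles

Real multireference benchmarking needs external geometries and electronic
structure engines; the package instead carries exactly solvable models
whose correlation strength is a dial.

* `hubbard_dimer(U, t)`: the half-filled two-site Hubbard singlet.  In
  the mean-field orbital basis the closed-shell configurations $g^2$ and
  $u^2$ couple through $U/2$; the ground state is known in closed form,
  the natural spin occupancies are $(c_0^2, 1-c_0^2)$, and $U/t$ sweeps
  continuously from the idempotent limit ($U=0$) to maximal entanglement
  ($\hat I_{ND} \to 0.5$, $I_{ND}^{max} \to 0.125$ as $U/t \to \infty$).
* `exact_diagonalize(model_spec(...))`: full CI over bitstring
  determinants for Hubbard chains up to 6 sites (Hilbert dimension
  guarded at $10^4$), a custom one-body-plus-on-site-interaction
  Hamiltonian, and an analytic two-level pairing model.  The many-body
  Hamiltonian is assembled in the site basis, where the interaction is
  diagonal; the ground state is then projected onto mean-field-orbital
  determinants through per-spin determinant overlap matrices (a Kronecker
  product in the alpha-major determinant ordering), and the 1-RDM in that
  basis is accumulated by the one-substitution Slater--Condon sum.
  Determinants are bitmasks, alpha-major, lowest orbital first; the
  reference for $c_0$ is the aufbau determinant of the $U=0$ orbitals;
  the global sign is fixed by $c_0 \ge 0$; degenerate ground states pick
  the lowest-index eigenvector and are flagged in the metadata.
* `sample_amplitudes(n_occ, n_vir, scale, seed)`: reproducible amplitude
  tensors.  The default `"mp2"` structure draws a random
  positive-semidefinite integral kernel and positive energy denominators,
  $t = -G/\Delta$, because the overestimation direction
  $\tilde n_H \le n_H$, $\tilde n_L \ge n_L$ rests on the
  semidefiniteness of the discarded exchange term, which that structure
  guarantees; plain symmetrized Gaussian tensors (available as
  `structure = "gaussian"`) violate the direction occasionally and are
  kept only for stress testing.  Tensors are exactly linear in `scale` at
  fixed seed, so $D_2$ scale equivariance is exact, and the caller's RNG
  stream is never disturbed.

What the models do *not* emulate: real molecules have singles
contributions, orbital relaxation, basis-set dependence and
symmetry-induced degeneracies far richer than a chain's.  Passing the
model-based suite therefore certifies the *algebra* of the indices and
bridges -- bounds, exact limits, conservation laws, oracle agreement --
not the empirical threshold fits, which are taken from the published
large-set calibrations and shipped as constants with provenance notes.

```{r sweep}
model_sweep(c(0, 1, 2, 4, 8))[, c("u_over_t", "c0sq", "i_nd_hat",
                                  "i_nd_max", "ind_hat_from_c0")]
```

## Numerical policy

* **Occupancy validation**: entries within `tol_neg` ($10^{-6}$) outside
  the physical range are clipped with a warning -- unrelaxed and relaxed
  densities routinely produce tiny negative occupancies -- while anything
  further out is an error naming the offending index.  Occupancy sums are
  checked against the declared electron counts to `trace_tol`
  ($10^{-4}$); a mismatch warns but does not stop, since truncated
  printed occupancies are common in the wild.
* **Sorting and ties**: occupancies are stored in descending order; the
  pseudo-occupied boundary breaks exact ties by original input order
  (R's stable ordering) and warns when the boundary is degenerate within
  $10^{-10}$, as in the fully entangled pair.
* **Degenerate inputs**: all-zero CI vectors, $c_0 = 0$ (the
  size-intensive logarithm branch), zero-electron normalizations, empty
  amplitude tensors and non-Hermitian density matrices are classed
  errors, each with its own condition class so callers and the CLI can
  map them to exit codes (0 success, 2 usage, 3 parse, 4 computation).
* **Problem sizes**: the shipped test-suite and acceptance ensembles use
  $10^4$ random occupancy sets, a few hundred amplitude tensors with 2--4
  occupied and 2--5 virtual orbitals, and chains up to 6 sites.  These
  sizes resolve every asserted property with large margins while keeping
  the whole suite in the ten-second range; nothing in the algebra limits
  larger inputs, and the dense-SVD/power-iteration switch covers
  amplitude spaces of realistic dimension.

## Known limitations

* Threshold calibration for new methods is a workflow hook, not a
  shipped computation: the published fits require molecule sets and
  electronic-structure runs outside the package's scope.
* Amplitude handling is closed-shell and spin-adapted; open-shell $D_2$
  variants are not implemented (occupancy indices, by contrast, are
  natively spin-resolved).
* The amplitude exchange format is a plain-text JSON container with the
  tensor dimensions and a column-major flattening; it is simple and
  exact, but not a binary scientific container format.
* The unrelaxed second-order density omits orbital response by
  construction; comparisons against relaxed densities will differ
  precisely by those terms.
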