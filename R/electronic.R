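# Electronic amplitude propagation: overlap matrices, phase correction,
# substep propagator, energy-based decoherence.  These are reference
# implementations for general N; the compiled engine carries an equivalent
# two-state fast path that is cross-checked against them in the tests.

#' Overlap matrix between two adiabatic bases
#'
#' \eqn{S(t, t+\Delta t) = U^\dagger(t)\,U(t+\Delta t)} from the
#' transformation matrices obtained by diagonalizing the diabatic
#' Hamiltonian at the two times.
#'
#' @param U_start,U_end Column-orthonormal transformation matrices.
#' @return The overlap matrix.
#' @export
overlap_matrix <- function(U_start, U_end) {
  stopifnot(is.matrix(U_start), is.matrix(U_end),
            all(dim(U_start) == dim(U_end)))
  for (U in list(U_start, U_end)) {
    dev <- max(abs(crossprod(U) - diag(ncol(U))))
    if (dev > 1e-8)
      abort("transformation matrices must be column-orthonormal")
  }
  crossprod(U_start, U_end)
}

#' Phase-correct an overlap matrix (and Hamiltonian)
#'
#' The eigenvectors returned by a diagonalization carry arbitrary per-state
#' phases (signs, in the real case); left uncorrected they flip the apparent
#' direction of population transfer at random.  Each state's phase is chosen
#' so the corresponding diagonal element of S becomes real and non-negative,
#' and the same phases are applied to the Hamiltonian so both stay in a
#' consistent gauge.  A diagonal element below 1e-12 (trivial crossing)
#' leaves that state's phase untouched, with a warning.
#'
#' @param S Near-orthogonal overlap matrix.
#' @param H Optional Hamiltonian to transform with the same phases.
#' @return List with `S`, `H`, and the `phases` applied.
#' @export
phase_correct <- function(S, H = NULL) {
  d <- diag(S)
  phases <- rep(1 + 0i, length(d))
  small <- Mod(d) < 1e-12
  if (any(small))
    warn("near-zero overlap diagonal (trivial crossing); phase carried over")
  ok <- !small
  phases[ok] <- Conj(d[ok]) / Mod(d[ok])
  Sc <- sweep(S, 2, phases, `*`)
  Hc <- if (!is.null(H)) diag(Conj(phases)) %*% H %*% diag(phases) else NULL
  if (all(Im(Sc) == 0)) Sc <- Re(Sc)
  if (!is.null(Hc) && all(Im(Hc) == 0)) Hc <- Re(Hc)
  list(S = Sc, H = Hc, phases = phases)
}

# real matrix logarithm of a near-identity orthogonal matrix, antisymmetrized
orthogonal_log <- function(S) {
  n <- nrow(S)
  if (n == 2L) {
    theta <- atan2(S[2, 1] - S[1, 2], S[1, 1] + S[2, 2])
    return(matrix(c(0, theta, -theta, 0), 2, 2))
  }
  es <- eigen(S)
  L <- es$vectors %*% diag(log(es$values + 0i), n) %*% solve(es$vectors)
  L <- Re(L)
  (L - t(L)) / 2
}

# expm of a (small) anti-Hermitian matrix via its eigendecomposition
anti_hermitian_expm <- function(A) {
  es <- eigen(A)
  es$vectors %*% diag(exp(es$values), nrow(A)) %*% Conj(t(es$vectors))
}

#' Propagate electronic amplitudes across one nuclear time step
#'
#' Builds the step propagator \eqn{R} from `substeps` sub-intervals, each
#' combining the phase evolution of the linearly interpolated adiabatic
#' energies with the overlap-derived nonadiabatic coupling
#' \eqn{K = \log(S)/\Delta t}:
#' \deqn{R = \prod_j \exp\{(-i\,\mathrm{diag}(H_j) - K)\,\Delta\tau\},
#'       \qquad \Delta\tau = \Delta t / s.}
#' The propagator is exactly unitary, so the amplitude norm is conserved.
#'
#' @param coefficients Complex amplitude vector (unit norm within 1e-6).
#' @param energies_start,energies_end Adiabatic energies at t and t + dt.
#' @param overlap Phase-corrected overlap matrix S(t, t + dt).
#' @param dt Nuclear time step.
#' @param substeps Number of substeps s (>= 1).
#' @return List with the propagated `coefficients` and the `propagator` R.
#' @export
propagate_amplitudes <- function(coefficients, energies_start, energies_end,
                                 overlap, dt, substeps = 25L) {
  n <- length(coefficients)
  stopifnot(substeps >= 1, length(energies_start) == n,
            length(energies_end) == n, all(dim(overlap) == c(n, n)))
  nrm <- sum(Mod(coefficients)^2)
  if (abs(nrm - 1) > 1e-6)
    abort("amplitude vector is not normalized (|sum - 1| > 1e-6)")
  K <- orthogonal_log(Re(overlap)) / dt
  dtau <- dt / substeps
  R <- diag(1 + 0i, n)
  for (j in seq_len(substeps)) {
    frac <- (j - 0.5) / substeps
    h <- energies_start + frac * (energies_end - energies_start)
    A <- (-1i * diag(h, n) - K) * dtau
    R <- anti_hermitian_expm(A) %*% R
  }
  list(coefficients = drop(R %*% coefficients), propagator = R)
}

#' Energy-based decoherence correction
#'
#' After the hop decision of each step, the amplitudes of the non-active
#' states \eqn{\alpha \ne \beta} are damped on the decoherence time scale
#' \eqn{\tau_\alpha = \frac{\hbar}{|E_\alpha - E_\beta|}
#'   \left(1 + \frac{C}{E_{kin}}\right)},
#' i.e. \eqn{c_\alpha \to c_\alpha e^{-\Delta t/\tau_\alpha}}, and the
#' active amplitude is rescaled so the total population is exactly 1.  A
#' vanishing energy gap gives an infinite decoherence time and leaves the
#' amplitudes untouched.  If the active amplitude is exactly zero the
#' renormalization is impossible; the amplitudes are left undamped for that
#' step and `applied` is FALSE.
#'
#' @param coefficients Complex amplitude vector.
#' @param active Active-state index (1-based).
#' @param energies Adiabatic energies.
#' @param e_kin Total kinetic energy (all Cartesian components).
#' @param C Decoherence parameter (0.1 in reduced energy units by default
#'   elsewhere in the package).
#' @param dt Nuclear time step.
#' @return List with `coefficients` and logical `applied`.
#' @export
decoherence_correct <- function(coefficients, active, energies, e_kin, C, dt) {
  stopifnot(e_kin >= 0, C > 0, active >= 1, active <= length(coefficients))
  cb2 <- Mod(coefficients[active])^2
  if (cb2 < 1e-15)
    return(list(coefficients = coefficients, applied = FALSE))
  out <- coefficients
  others <- setdiff(seq_along(coefficients), active)
  damp <- exp(-dt * abs(energies[others] - energies[active]) *
                e_kin / (e_kin + C))
  out[others] <- out[others] * damp
  p_other <- sum(Mod(out[others])^2)
  out[active] <- out[active] * sqrt((1 - p_other) / cb2)
  list(coefficients = out, applied = TRUE)
}
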