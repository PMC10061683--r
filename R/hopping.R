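# Fewest-switches hop probabilities, stochastic selection, and the
# energy-conservation check with parallel velocity rescaling.

#' Fewest-switches hop probabilities for one step
#'
#' Probability of hopping out of the active state \eqn{\beta} into each
#' other state \eqn{\alpha}, evaluated from the amplitudes before and after
#' the step and the step propagator R:
#' \deqn{P_{\beta\to\alpha} =
#'   \left(1 - \frac{|c_\beta(t+\Delta t)|^2}{|c_\beta(t)|^2}\right)
#'   \frac{\mathrm{Re}\,[c_\alpha(t+\Delta t)\, R_{\alpha\beta}^*\, c_\beta^*(t)]}
#'        {|c_\beta(t)|^2 - \mathrm{Re}\,[c_\beta(t+\Delta t)\, R_{\beta\beta}^*\, c_\beta^*(t)]}.}
#' Negative fluxes are clipped to zero (in particular, if the active-state
#' population grew during the step all probabilities vanish), each entry is
#' clipped to \[0, 1\], and the vector is rescaled if the clipped sum exceeds 1.
#'
#' @param c_new,c_old Complex amplitude vectors after/before the step.
#' @param propagator The step propagator R returned by
#'   [propagate_amplitudes()].
#' @param active Active state index (1-based).
#' @return Numeric probability vector with a zero at the active state.
#' @export
hop_probabilities <- function(c_new, c_old, propagator, active) {
  n <- length(c_old)
  stopifnot(length(c_new) == n, all(dim(propagator) == c(n, n)),
            active >= 1, active <= n)
  P <- numeric(n)
  pb_old <- Mod(c_old[active])^2
  if (pb_old < 1e-15) {
    warn("active-state population below 1e-15; hop probabilities set to 0")
    return(P)
  }
  fac1 <- 1 - Mod(c_new[active])^2 / pb_old
  if (fac1 <= 0) return(P)
  den <- pb_old -
    Re(c_new[active] * Conj(propagator[active, active]) * Conj(c_old[active]))
  if (den <= 0) return(P)
  for (a in seq_len(n)) {
    if (a == active) next
    num <- Re(c_new[a] * Conj(propagator[a, active]) * Conj(c_old[active]))
    P[a] <- fac1 * num / den
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  tot <- sum(P)
  if (tot > 1) P <- P / tot
  P
}

#' Select a hop target from the cumulative probability intervals
#'
#' Partitions \[0, 1) into consecutive intervals of the given probabilities
#' (in state-index order) and returns the state whose interval contains the
#' uniform random number r, or `NA` if r falls beyond the occupied
#' intervals so no hop is attempted.
#'
#' @param probabilities Output of [hop_probabilities()].
#' @param r Uniform random draw in \[0, 1).
#' @return Integer state index, or `NA_integer_`.
#' @export
select_hop <- function(probabilities, r) {
  stopifnot(r >= 0, r < 1, all(probabilities >= 0))
  cum <- cumsum(probabilities)
  i <- which(r < cum)
  if (length(i) == 0L) NA_integer_ else i[[1L]]
}

#' Attempt a surface hop with energy check and parallel velocity rescaling
#'
#' If the total energy is smaller than the potential energy of the target
#' state the hop is frustrated and nothing changes (no velocity reversal is
#' applied).  Otherwise the hop is accepted: the active state switches and
#' the velocity vector is rescaled parallel to itself,
#' \eqn{\mathbf{v}' = \mathbf{v}\sqrt{1 - \Delta E / E_{kin}}}, so total
#' energy is conserved exactly.
#'
#' @param velocity Numeric velocity vector.
#' @param active Current active state (1-based).
#' @param target Envisaged new state (1-based, different from `active`).
#' @param energies Adiabatic potential energies at the current geometry.
#' @param mass Particle mass (1 in reduced units).
#' @return List: `accepted`, `frustrated`, `active`, `velocity`, `scale`.
#' @export
attempt_hop <- function(velocity, active, target, energies, mass = 1) {
  stopifnot(target != active, target >= 1, target <= length(energies))
  e_kin <- 0.5 * mass * sum(velocity^2)
  dE <- energies[target] - energies[active]
  if (e_kin < dE) {
    return(list(accepted = FALSE, frustrated = TRUE, active = active,
                velocity = velocity, scale = 1))
  }
  scale <- if (e_kin > 0) sqrt((e_kin - dE) / e_kin) else 1
  list(accepted = TRUE, frustrated = FALSE, active = target,
       velocity = velocity * scale, scale = scale)
}
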