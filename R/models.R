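# Analytic diabatic model landscapes and their static analysis.

#' Avoided-crossing model landscape
#'
#' Two diabatic harmonic potentials in reduced units, with minima at
#' \eqn{\pm x_0} and a diabatic crossing of height \eqn{\varepsilon} at
#' \eqn{x = 0}, coupled by a constant off-diagonal element \eqn{V_c}:
#' \deqn{V_{11} = \varepsilon\,((x + x_0)/x_0)^2, \quad
#'       V_{22} = \varepsilon\,((x - x_0)/x_0)^2, \quad V_{12} = V_c,}
#' plus tight transverse harmonic potentials \eqn{\kappa_\perp (y^2+z^2)/2}
#' on both diagonal elements.  Diagonalization yields a bistable lower
#' adiabatic surface whose wells avoid each other with a minimum gap
#' \eqn{g = 2 V_c}; with the default parameters the lower-state barrier is
#' \eqn{E_a = 0.64} and the gap is 0.8.
#'
#' All quantities are dimensionless: energies in units of the diabatic
#' crossing height, lengths in units of the well offset, particle mass 1,
#' and \eqn{k_B = \hbar = 1}.
#'
#' @param coupling Constant diabatic coupling \eqn{V_c} (reduced energy).
#' @param well_offset Position \eqn{x_0} of the diabatic minima (reduced
#'   length); 1 in self-consistent reduced units.
#' @param barrier_scale Diabatic crossing height \eqn{\varepsilon}; 1 in
#'   reduced units.
#' @param transverse_stiffness Curvature \eqn{\kappa_\perp} of the tight
#'   transverse wells acting on y and z.  The transverse terms are invariant
#'   under diagonalization, so they only couple to the x dynamics through
#'   velocity rescaling and decoherence.
#' @return A `fh_model` object.
#' @seealso [model_conical_intersection()], [adiabatize()], [barrier_analysis()]
#' @export
#' @examples
#' m <- model_avoided_crossing(coupling = 0.4)
#' minimum_gap(m)$gap   # 2 * 0.4
model_avoided_crossing <- function(coupling = 0.4, well_offset = 1,
                                   barrier_scale = 1,
                                   transverse_stiffness = 12.8) {
  stopifnot(is.numeric(coupling), length(coupling) == 1L,
            well_offset > 0, barrier_scale > 0, transverse_stiffness >= 0)
  new_fh_model(
    type = 0L,
    name = "avoided_crossing",
    params = list(coupling = coupling, well_offset = well_offset,
                  barrier_scale = barrier_scale,
                  transverse_stiffness = transverse_stiffness),
    cpp_params = c(coupling, well_offset, barrier_scale, transverse_stiffness))
}

#' Conical-intersection model landscape
#'
#' Two coupled diabatic surfaces over the Cartesian coordinates (x, y, z),
#' expressed through the sum and difference coordinates \eqn{u = x - y}
#' (the reaction coordinate) and \eqn{v = x + y}:
#' \deqn{V_{11} = a\,((u-d)/d)^2 + b\,((v-d)/d)^2 + c\,e\,z^2,}
#' \deqn{V_{22} = a\,((u+d)/d)^2 + b\,((v+d)/d)^2 + c\,e\,z^2,}
#' \deqn{V_{12} = k\,(x+y)\,\exp(f\,(1 - (x-y)^2)).}
#' The diabatic minima sit at (x, y) = (d, 0) and (-d, 0); the crossing seam
#' passes through the origin, where the coupling vanishes, producing a
#' conical intersection at energy \eqn{a + b} above the wells (ground-state
#' barrier 0.64 with the default parameters).  Because the coupling is small
#' near the intersection, the system is diabatically trapped: passages
#' between the two diabatic states are rare even though the barrier is only
#' about one \eqn{k_B T} at the standard temperature.
#'
#' @param a,b Stiffness-scale energies of the u- and v-parabolas.
#' @param c Prefactor of the narrow z-confinement (times `e`).
#' @param d Diabatic well offset along the reaction coordinate.
#' @param e Curvature scale of the narrow harmonic z-potential.
#' @param k Coupling prefactor (reduced energy per length).
#' @param f Gaussian decay rate of the coupling away from the seam.
#' @return A `fh_model` object.
#' @export
#' @examples
#' m <- model_conical_intersection()
#' adiabatize(m, c(0, 0, 0))$gap < 1e-8   # exact degeneracy at the origin
model_conical_intersection <- function(a = 0.512, b = 0.128, c = 0.5,
                                       d = 3.0, e = 12.8, k = 0.0128,
                                       f = 2.3) {
  stopifnot(a > 0, b > 0, c >= 0, d > 0, e >= 0)
  new_fh_model(
    type = 1L,
    name = "conical_intersection",
    params = list(a = a, b = b, c = c, d = d, e = e, k = k, f = f),
    cpp_params = c(a, b, c, d, e, k, f))
}

new_fh_model <- function(type, name, params, cpp_params) {
  structure(list(type = type, name = name, n_states = 2L,
                 params = params, cpp_params = cpp_params),
            class = "fh_model")
}

#' @export
print.fh_model <- function(x, ...) {
  cat("<fh_model> ", x$name, " (", x$n_states, " states)\n", sep = "")
  cat("  ", paste(names(x$params), unlist(x$params), sep = " = ",
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_cpp_model <- function(model) {
  list(type = model$type, params = model$cpp_params)
}

#' Evaluate the diabatic Hamiltonian and its Cartesian gradients
#'
#' @param model A `fh_model`.
#' @param position Numeric 3-vector (x, y, z).
#' @return List with `hamiltonian` (symmetric n x n matrix) and `gradients`
#'   (array `[i, j, coord]` holding \eqn{\partial H_{ij}/\partial r_c}).
#' @export
eval_diabatic <- function(model, position) {
  stopifnot(inherits(model, "fh_model"))
  if (length(position) != 3L || !all(is.finite(position)))
    abort("`position` must be a finite numeric 3-vector")
  x <- position[1]; y <- position[2]; z <- position[3]
  G <- array(0, dim = c(2, 2, 3))
  if (model$type == 0L) {
    p <- model$params
    inv2 <- 1 / p$well_offset^2
    perp <- 0.5 * p$transverse_stiffness * (y^2 + z^2)
    V11 <- p$barrier_scale * (x + p$well_offset)^2 * inv2 + perp
    V22 <- p$barrier_scale * (x - p$well_offset)^2 * inv2 + perp
    H <- matrix(c(V11, p$coupling, p$coupling, V22), 2, 2)
    G[1, 1, ] <- c(2 * p$barrier_scale * (x + p$well_offset) * inv2,
                   p$transverse_stiffness * y, p$transverse_stiffness * z)
    G[2, 2, ] <- c(2 * p$barrier_scale * (x - p$well_offset) * inv2,
                   p$transverse_stiffness * y, p$transverse_stiffness * z)
  } else {
    p <- model$params
    u <- x - y; v <- x + y; id2 <- 1 / p$d^2
    V11 <- p$a * (u - p$d)^2 * id2 + p$b * (v - p$d)^2 * id2 + p$c * p$e * z^2
    V22 <- p$a * (u + p$d)^2 * id2 + p$b * (v + p$d)^2 * id2 + p$c * p$e * z^2
    g <- exp(p$f * (1 - u^2))
    V12 <- p$k * v * g
    H <- matrix(c(V11, V12, V12, V22), 2, 2)
    au1 <- 2 * p$a * (u - p$d) * id2; bv1 <- 2 * p$b * (v - p$d) * id2
    au2 <- 2 * p$a * (u + p$d) * id2; bv2 <- 2 * p$b * (v + p$d) * id2
    G[1, 1, ] <- c(au1 + bv1, -au1 + bv1, 2 * p$c * p$e * z)
    G[2, 2, ] <- c(au2 + bv2, -au2 + bv2, 2 * p$c * p$e * z)
    G[1, 2, ] <- c(p$k * g * (1 - 2 * p$f * u * v),
                   p$k * g * (1 + 2 * p$f * u * v), 0)
    G[2, 1, ] <- G[1, 2, ]
  }
  list(hamiltonian = H, gradients = G)
}

#' Adiabatize the diabatic Hamiltonian at one geometry
#'
#' Diagonalizes \eqn{H^{diab}(x)} and returns the adiabatic energies
#' (ascending), the transformation matrix U (columns orthonormal, each
#' column's largest-magnitude component made positive so the decomposition
#' is deterministic), and the per-state Hellmann-Feynman gradients
#' \eqn{\nabla E_\alpha = U_{:\alpha}^\dagger (\nabla H^{diab}) U_{:\alpha}}.
#' Within gap \eqn{< 10^{-10}} of an exact degeneracy the Hellmann-Feynman
#' expression is ill-conditioned and the diabatic diagonal gradients are
#' returned instead.
#'
#' @inheritParams eval_diabatic
#' @return A `fh_estruct` list: `energies`, `transform`, `gradients`
#'   (n_states x 3), `gap`, `hamiltonian`.
#' @export
adiabatize <- function(model, position) {
  ed <- eval_diabatic(model, position)
  H <- ed$hamiltonian
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)
  E <- es$values[ord]
  U <- es$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  n <- nrow(H)
  gap <- if (n > 1L) E[2] - E[1] else Inf
  grads <- matrix(0, n, 3)
  if (gap < 1e-10) {
    for (s in seq_len(n)) grads[s, ] <- ed$gradients[s, s, ]
  } else {
    for (s in seq_len(n))
      for (i in 1:3)
        grads[s, i] <- drop(t(U[, s]) %*% ed$gradients[, , i] %*% U[, s])
  }
  structure(list(energies = E, transform = U, gradients = grads,
                 gap = gap, hamiltonian = H),
            class = "fh_estruct")
}

#' Minimum adiabatic gap of a model
#'
#' Locates the global minimum of the upper-minus-lower adiabatic energy
#' difference by a grid scan over the (x, y) plane followed by local
#' refinement (the transverse z-potential is common to both states, so the
#' gap does not depend on z).
#'
#' @param model A `fh_model`.
#' @param lower,upper Numeric length-2 bounds of the (x, y) search box.
#' @param n_grid Points per axis in the initial scan.
#' @return List with `gap` and `location` (3-vector).
#' @export
minimum_gap <- function(model, lower = c(-2, -2), upper = c(2, 2),
                        n_grid = 41) {
  stopifnot(inherits(model, "fh_model"))
  if (any(upper <= lower)) abort("empty search box: `upper` must exceed `lower`")
  xs <- seq(lower[1], upper[1], length.out = n_grid)
  ys <- seq(lower[2], upper[2], length.out = n_grid)
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  pos <- cbind(pts, z = 0)
  ad <- cpp_eval_model(as_cpp_model(model), pos)
  gaps <- ad$adiabatic[, 2] - ad$adiabatic[, 1]
  i0 <- which.min(gaps)
  gapfun <- function(p) {
    e <- adiabatize(model, c(p, 0))$energies
    e[2] - e[1]
  }
  opt <- optim(pts[i0, ], gapfun, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(factr = 10))
  list(gap = opt$value, location = c(opt$par, 0))
}

#' Barrier analysis of one adiabatic surface
#'
#' Locates the two minima of a bistable adiabatic surface, scans the
#' straight segment connecting them for the barrier top, refines both with
#' golden-section search, and reports the barrier height together with the
#' harmonic frequencies of the well and of the unstable mode at the barrier
#' (from second differences along the scan direction, mass 1).
#'
#' @param model A `fh_model`.
#' @param state Adiabatic state index (1 = lowest).
#' @param starts Optional 2 x 3 matrix of starting guesses for the two
#'   minima; sensible model-specific defaults are used when omitted.
#' @return List with `E_a`, `minima` (2 x 3), `saddle` (3-vector),
#'   `omega_barrier`, `omega_well`, and the surface energies at those points.
#' @export
barrier_analysis <- function(model, state = 1L, starts = NULL) {
  stopifnot(inherits(model, "fh_model"))
  surf <- function(p) adiabatize(model, p)$energies[state]
  if (is.null(starts)) {
    starts <- if (model$type == 0L) {
      rbind(c(-model$params$well_offset, 0, 0),
            c(model$params$well_offset, 0, 0))
    } else {
      rbind(c(model$params$d, 0, 0), c(-model$params$d, 0, 0))
    }
  }
  mins <- lapply(1:2, function(i) {
    optim(starts[i, ], surf, method = "BFGS",
          control = list(reltol = 1e-14, maxit = 500))
  })
  m1 <- mins[[1]]$par; m2 <- mins[[2]]$par
  if (sqrt(sum((m1 - m2)^2)) < 1e-4)
    abort("no bistability found: both searches converged to the same minimum")
  seg <- function(s) surf(m1 + s * (m2 - m1))
  sgrid <- seq(0.02, 0.98, length.out = 400)
  vals <- vapply(sgrid, seg, numeric(1))
  stop_i <- which.max(vals)
  win <- c(sgrid[max(1, stop_i - 2)], sgrid[min(length(sgrid), stop_i + 2)])
  topt <- optimize(seg, interval = win, maximum = TRUE, tol = 1e-12)
  e_min <- min(mins[[1]]$value, mins[[2]]$value)
  E_a <- topt$objective - e_min
  if (E_a <= 0) abort("no barrier found between the located minima")
  saddle <- m1 + topt$maximum * (m2 - m1)
  dirvec <- (m2 - m1) / sqrt(sum((m2 - m1)^2))
  d2 <- function(p0) {
    h <- 1e-4
    (surf(p0 + h * dirvec) - 2 * surf(p0) + surf(p0 - h * dirvec)) / h^2
  }
  omega_barrier <- sqrt(abs(d2(saddle)))
  well <- if (mins[[1]]$value <= mins[[2]]$value) m1 else m2
  omega_well <- sqrt(max(d2(well), 0))
  list(E_a = E_a, minima = rbind(m1, m2), saddle = saddle,
       omega_barrier = omega_barrier, omega_well = omega_well,
       E_saddle = topt$objective, E_min = e_min)
}

#' Kramers turnover friction estimate
#'
#' The transition rate through a parabolic barrier is maximal near the
#' friction at which roughly one \eqn{k_B T} of energy is dissipated per
#' barrier crossing, \eqn{\gamma_{max}/m = \omega\,k_B T / E_a} with
#' \eqn{\omega} the frequency of the unstable mode at the barrier top.
#'
#' @param E_a Barrier height (reduced energy).
#' @param omega_barrier Unstable-mode frequency at the barrier top.
#' @param temperature Temperature in reduced units (kB = 1).
#' @param mass Particle mass (1 in reduced units).
#' @return The turnover friction estimate \eqn{\gamma_{max}}.
#' @export
turnover_friction <- function(E_a, omega_barrier, temperature, mass = 1) {
  stopifnot(E_a > 0, omega_barrier > 0, temperature > 0, mass > 0)
  mass * omega_barrier * temperature / E_a
}
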