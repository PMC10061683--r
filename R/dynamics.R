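# Langevin velocity-Verlet nuclear integration coupled to the electronic and
# hopping machinery: the complete trajectory-surface-hopping engine.

#' Thermostat and propagation settings
#'
#' Langevin dynamics in the high-level form
#' \eqn{m\ddot{x} = -\nabla E - \gamma m \dot{x} + \eta(t)} with Gaussian
#' white noise obeying the fluctuation-dissipation theorem.  The integrator
#' is the Gronbech-Jensen-Farago velocity-Verlet discretization, which draws
#' one Gaussian noise vector per step with variance
#' \eqn{2\gamma k_B T \Delta t} per component and reduces exactly to
#' velocity Verlet at \eqn{\gamma = 0}.
#'
#' Two independent counter-based random-number streams are used: one for the
#' thermostat noise and one for the hop draws, so hopping statistics can be
#' varied at fixed nuclear noise and vice versa.
#'
#' @param temperature Temperature in reduced units (kB = 1); may be 0.
#' @param friction Friction constant gamma (mass/time units).
#' @param dt Nuclear time step.
#' @param substeps Electronic substeps s per nuclear step.
#' @param decoherence Energy-based decoherence parameter C (reduced energy).
#' @param seed_noise,seed_hop Integer seeds of the two streams.
#' @param hopping Set to FALSE to disable the electronic machinery entirely
#'   (plain adiabatic Langevin dynamics on the active surface), used for
#'   single-surface oracle comparisons.
#' @return A `fh_thermostat` object.
#' @export
thermostat <- function(temperature, friction, dt, substeps = 25L,
                       decoherence = 0.1, seed_noise = 1L, seed_hop = 2L,
                       hopping = TRUE) {
  stopifnot(temperature >= 0, friction >= 0, dt > 0, substeps >= 1,
            decoherence > 0)
  structure(list(temperature = temperature, friction = friction, dt = dt,
                 substeps = as.integer(substeps), decoherence = decoherence,
                 seed_noise = as.double(seed_noise),
                 seed_hop = as.double(seed_hop),
                 hopping = isTRUE(hopping)),
            class = "fh_thermostat")
}

#' @export
print.fh_thermostat <- function(x, ...) {
  cat(sprintf("<fh_thermostat> T = %g, gamma = %g, dt = %g, s = %d, C = %g\n",
              x$temperature, x$friction, x$dt, x$substeps, x$decoherence))
  invisible(x)
}

#' Phase-space + electronic snapshot
#'
#' @param position,velocity Numeric 3-vectors.
#' @param active_state Active adiabatic state (1-based).
#' @param amplitudes Complex amplitude vector; defaults to a pure population
#'   on the active state.
#' @param time Time stamp.
#' @param n_states Number of electronic states.
#' @return A `fh_snapshot` object.
#' @export
snapshot <- function(position, velocity = c(0, 0, 0), active_state = 1L,
                     amplitudes = NULL, time = 0, n_states = 2L) {
  stopifnot(length(position) == 3L, length(velocity) == 3L,
            all(is.finite(position)), all(is.finite(velocity)),
            active_state >= 1, active_state <= n_states)
  if (is.null(amplitudes)) {
    amplitudes <- rep(0 + 0i, n_states)
    amplitudes[active_state] <- 1 + 0i
  }
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity),
                 active_state = as.integer(active_state),
                 amplitudes = amplitudes, time = time),
            class = "fh_snapshot")
}

snapshot_to_state <- function(s) {
  c(s$position, s$velocity, s$active_state - 1L,
    Re(s$amplitudes[1]), Im(s$amplitudes[1]),
    Re(s$amplitudes[2]), Im(s$amplitudes[2]))
}

state_to_snapshot <- function(v, time = 0) {
  snapshot(position = v[1:3], velocity = v[4:6],
           active_state = as.integer(v[7]) + 1L,
           amplitudes = complex(real = c(v[8], v[10]),
                                imaginary = c(v[9], v[11])),
           time = time)
}

#' One Langevin velocity-Verlet step on the active adiabatic surface
#'
#' Reference (R-level) implementation of the GJF step used by the compiled
#' engine; mainly useful for tests and for inspecting the integrator in
#' isolation (no electronic propagation, no hops).
#'
#' @param snap A `fh_snapshot`.
#' @param model A `fh_model`.
#' @param thermo A `fh_thermostat`.
#' @param noise Optional pre-drawn noise 3-vector (already scaled); drawn
#'   from R's RNG when omitted.
#' @return The advanced `fh_snapshot`.
#' @export
langevin_step <- function(snap, model, thermo, noise = NULL) {
  dt <- thermo$dt; g <- thermo$friction
  b <- 1 / (1 + g * dt / 2)
  a <- (1 - g * dt / 2) * b
  if (is.null(noise))
    noise <- rnorm(3, 0, sqrt(2 * g * thermo$temperature * dt))
  F0 <- -adiabatize(model, snap$position)$gradients[snap$active_state, ]
  x1 <- snap$position + b * dt * snap$velocity + b * dt^2 / 2 * F0 +
    b * dt / 2 * noise
  F1 <- -adiabatize(model, x1)$gradients[snap$active_state, ]
  v1 <- a * snap$velocity + dt / 2 * (a * F0 + F1) + b * noise
  snapshot(x1, v1, snap$active_state, snap$amplitudes, snap$time + dt)
}

#' Derive an independent child seed from a base seed
#'
#' Counter-based mixing, so the same (base, id) pair always yields the same
#' stream regardless of execution order; results stay below 2^31.
#'
#' @param base Base seed (non-negative integer).
#' @param id Stream identifier.
#' @return A derived integer seed.
#' @export
derive_seed <- function(base, id) cpp_derive_seed(base, id) %% 2^31

traj_colnames <- c("step", "time", "x", "y", "z", "vx", "vy", "vz",
                   "active_state", "re1", "im1", "re2", "im2", "E1", "E2")

traj_tibble <- function(m) {
  colnames(m) <- traj_colnames
  out <- as_tibble(m)
  out$active_state <- as.integer(out$active_state) + 1L
  out
}

hops_tibble <- function(m) {
  colnames(m) <- c("step", "time", "from", "to", "frustrated")
  out <- as_tibble(m)
  out$from <- as.integer(out$from) + 1L
  out$to <- as.integer(out$to) + 1L
  out$frustrated <- out$frustrated > 0
  out
}

records_tibble <- function(m) {
  colnames(m) <- c("event", "step", "time", "x", "y", "z", "vx", "vy", "vz",
                   "active_state", "re1", "im1", "re2", "im2")
  out <- as_tibble(m)
  out$active_state <- as.integer(out$active_state) + 1L
  out
}

record_row_to_state <- function(row) {
  c(row$x, row$y, row$z, row$vx, row$vy, row$vz, row$active_state - 1,
    row$re1, row$im1, row$re2, row$im2)
}

# low-level engine call; state is the 11-vector layout of the C++ side
engine_run <- function(model, thermo, state, time0, n_steps, stride = 0,
                       events = NULL, max_record = 100000,
                       seed_noise = thermo$seed_noise,
                       seed_hop = thermo$seed_hop,
                       noise_counter = 0, hop_counter = 0,
                       record_hops = TRUE,
                       injected_noise = NULL, injected_uniforms = NULL) {
  if (is.null(events)) events <- matrix(numeric(0), 0, 8)
  if (is.list(events)) events <- do.call(rbind, events)
  cpp_run_tsh(state, time0, as_cpp_model(model), unclass(thermo),
              n_steps, stride, events, max_record,
              seed_noise, seed_hop, noise_counter, hop_counter,
              record_hops, injected_noise, injected_uniforms)
}

#' Run a surface-hopping trajectory
#'
#' Propagates a full TSH trajectory: each nuclear step consists of a
#' Langevin (GJF) step on the active adiabatic surface, adiabatization at
#' the new geometry with persistent phase correction of the transformation
#' matrices, substep propagation of the electronic amplitudes, a
#' fewest-switches hop decision with energy check and parallel velocity
#' rescaling, and the energy-based decoherence correction.  Fully
#' reproducible from the two seeds in `thermo`.
#'
#' @param model A `fh_model`.
#' @param init A `fh_snapshot` initial condition.
#' @param thermo A `fh_thermostat`.
#' @param n_steps Number of nuclear steps.
#' @param record_stride Store every k-th snapshot (k >= 1); the hop-event
#'   log is always complete.
#' @param stop_regions Optional list of `fh_region`s; propagation stops as
#'   soon as the system enters any of them.
#' @return A `fh_trajectory`: list with `snapshots` and `hops` tibbles, the
#'   `final` snapshot, `steps_done`, `stop_region` (index or 0), the
#'   maximum electronic norm error, and hop/frustration counts.
#' @export
#' @examples
#' m <- model_avoided_crossing()
#' th <- thermostat(0.2133, 1.4133, 0.0539, seed_noise = 7, seed_hop = 8)
#' run_tsh(m, snapshot(c(-1, 0, 0)), th, 1000)$final
run_tsh <- function(model, init, thermo, n_steps, record_stride = 1L,
                    stop_regions = NULL) {
  events <- NULL
  if (!is.null(stop_regions)) {
    if (inherits(stop_regions, "fh_region")) stop_regions <- list(stop_regions)
    events <- lapply(stop_regions, region_event, type = 2L)
  }
  res <- engine_run(model, thermo, snapshot_to_state(init), init$time,
                    n_steps, stride = record_stride, events = events)
  structure(list(snapshots = traj_tibble(res$trajectory),
                 hops = hops_tibble(res$hops),
                 final = state_to_snapshot(res$state, res$time),
                 steps_done = res$steps_done,
                 stop_region = res$stop_event,
                 max_norm_err = res$max_norm_err,
                 n_hops = res$n_hops, n_frustrated = res$n_frustrated,
                 model = model, thermo = thermo, dt = thermo$dt),
            class = "fh_trajectory")
}

#' @export
print.fh_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fh_trajectory> %d steps (dt = %g), %d stored snapshots, %d hops (%d frustrated)\n",
    as.integer(x$steps_done), x$dt, nrow(x$snapshots),
    as.integer(x$n_hops), as.integer(x$n_frustrated)))
  invisible(x)
}

#' Reference single-trajectory propagation in pure R
#'
#' Mirrors the compiled engine step for step, using injected noise and hop
#' draws so the two implementations can be compared bitwise-tightly.  Only
#' intended for validation at small step counts.
#'
#' @inheritParams run_tsh
#' @param noise Matrix (n_steps x 3) of pre-scaled noise values.
#' @param uniforms Vector (n_steps) of hop draws.
#' @return List of snapshot states (matrix) and hop log.
#' @keywords internal
#' @export
run_tsh_reference <- function(model, init, thermo, n_steps, noise, uniforms) {
  dt <- thermo$dt; g <- thermo$friction; s <- thermo$substeps
  bco <- 1 / (1 + g * dt / 2); aco <- (1 - g * dt / 2) * bco
  x <- init$position; v <- init$velocity
  act <- init$active_state; cc <- init$amplitudes
  es <- adiabatize(model, x)
  U <- es$transform; E <- es$energies; Fm <- -es$gradients
  out <- matrix(NA_real_, n_steps, 8)
  hops <- list()
  for (step in seq_len(n_steps)) {
    xi <- noise[step, ]
    F0 <- Fm[act, ]
    x <- x + bco * dt * v + bco * dt^2 / 2 * F0 + bco * dt / 2 * xi
    es2 <- adiabatize(model, x)
    U2 <- es2$transform; E2 <- es2$energies
    for (col in 1:2) {
      if (sum(U[, col] * U2[, col]) < 0) U2[, col] <- -U2[, col]
    }
    if (det(crossprod(U, U2)) < 0) U2[, 2] <- -U2[, 2]   # trivial crossing
    Fm2 <- -es2$gradients     # gradients are insensitive to column signs
    F1 <- Fm2[act, ]
    v <- aco * v + dt / 2 * (aco * F0 + F1) + bco * xi
    S <- crossprod(U, U2)
    pr <- propagate_amplitudes(cc, E, E2, S, dt, s)
    c_old <- cc
    cc <- pr$coefficients
    P <- hop_probabilities(cc, c_old, pr$propagator, act)
    tgt <- select_hop(P, uniforms[step])
    if (!is.na(tgt)) {
      hp <- attempt_hop(v, act, tgt, E2)
      v <- hp$velocity; act <- hp$active
      hops[[length(hops) + 1]] <- c(step, act, hp$frustrated)
    }
    ek <- 0.5 * sum(v^2)
    cc <- decoherence_correct(cc, act, E2, ek, thermo$decoherence,
                              dt)$coefficients
    U <- U2; E <- E2; Fm <- Fm2
    out[step, ] <- c(x, v, act, 0.5 * sum(v^2) + E2[act])
  }
  colnames(out) <- c("x", "y", "z", "vx", "vy", "vz", "active", "energy")
  list(states = out, hops = hops, amplitudes = cc)
}
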