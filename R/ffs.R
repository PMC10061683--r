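# State-aware forward flux sampling: flux estimation (with and without
# reset), interface shooting cycles, rate constant with Gaussian error
# propagation, and transition-path stitching.

#' Effective positive flux out of A, "flux with reset"
#'
#' Runs surface-hopping dynamics in and around region A, counting every
#' outward crossing of lambda_0 (the boundary of A) whose post-crossing
#' active state is allowed, and storing each crossing snapshot as a shooting
#' point.  If the trajectory reaches region B it is immediately reset to a
#' randomly chosen stored in-A snapshot and re-equilibrated for a burn-in
#' that is excluded from the counted time.  The flux is
#' \eqn{\phi_A = N_0 / T_{counted}}.
#'
#' @param model,thermo,init Model, thermostat, and an initial snapshot
#'   inside A.
#' @param A,B `fh_region` definitions of the stable regions.
#' @param n_steps Counted-step budget of the flux simulation.
#' @param interfaces Optional `fh_interfaces`; its first level/state set is
#'   used for lambda_0 (defaults to the boundary of A).
#' @param equil_steps Initial equilibration steps (not counted).
#' @param burn_in_steps Re-equilibration length after a reset; defaults to
#'   10/gamma time units.
#' @param sample_every Period (steps) of the stored in-A snapshot reservoir.
#' @param max_points Cap on stored crossing snapshots.
#' @return A `fh_flux` object: `phi`, `N0`, `time_counted`, `points`
#'   (tibble of shooting snapshots), `resets`, and the advanced RNG
#'   counters.
#' @export
flux_with_reset <- function(model, thermo, init, A, B, n_steps,
                            interfaces = NULL, equil_steps = 2000L,
                            burn_in_steps = NULL, sample_every = 250L,
                            max_points = 50000L) {
  lam0 <- if (!is.null(interfaces)) interfaces$levels[1] else A$level
  st0 <- if (!is.null(interfaces)) interfaces$states[[1]] else A$states
  w0 <- if (!is.null(interfaces)) interfaces$w else A$w
  outdir <- if (!is.null(interfaces)) interfaces$direction else -A$dir
  if (is.null(burn_in_steps))
    burn_in_steps <- max(10L, ceiling(10 / max(thermo$friction, 0.1) / thermo$dt))

  ev_cross <- c(w0, lam0, outdir, state_mask(st0), 0L, 1L)
  ev_sample <- region_event(A, 3L, every = sample_every)
  ev_B <- region_event(B, 2L)
  events <- rbind(ev_cross, ev_sample, ev_B)

  # equilibrate inside A
  st <- snapshot_to_state(init); t0 <- init$time
  cn <- 0; ch <- 0
  eq <- engine_run(model, thermo, st, t0, equil_steps, record_hops = FALSE)
  st <- eq$state; t0 <- eq$time; cn <- eq$noise_counter; ch <- eq$hop_counter

  reservoir <- list(st)
  res_i <- 1L                         # ring-buffer write position
  points <- list()
  N0 <- 0; counted <- 0; resets <- 0
  remaining <- n_steps
  while (remaining > 0) {
    res <- engine_run(model, thermo, st, t0, remaining, events = events,
                      max_record = 200000, noise_counter = cn,
                      hop_counter = ch, record_hops = FALSE)
    cn <- res$noise_counter; ch <- res$hop_counter
    counted <- counted + res$steps_done
    remaining <- remaining - res$steps_done
    rec <- res$records
    if (nrow(rec) > 0) {
      cross <- rec[rec[, 1] == 1, , drop = FALSE]
      if (nrow(cross) > 0 && length(points) < max_points) {
        points[[length(points) + 1]] <- cross
      }
      samp <- rec[rec[, 1] == 2, , drop = FALSE]
      for (i in seq_len(nrow(samp))) {
        res_i <- (res_i %% 256L) + 1L
        reservoir[[res_i]] <- samp[i, 4:14]
      }
    }
    N0 <- N0 + res$event_counts[1]
    if (res$stop_event == 3) {         # entered B: reset and re-equilibrate
      resets <- resets + 1
      pick <- reservoir[[1 + (sm_unif(thermo$seed_hop, 7e8 + resets) %% length(reservoir))]]
      bi <- engine_run(model, thermo, pick, res$time, burn_in_steps,
                       noise_counter = cn, hop_counter = ch,
                       record_hops = FALSE)
      st <- bi$state; t0 <- bi$time
      cn <- bi$noise_counter; ch <- bi$hop_counter
    } else if (res$stop_event == 0) {
      st <- res$state; t0 <- res$time
      break
    } else {
      st <- res$state; t0 <- res$time
    }
  }
  time_counted <- counted * thermo$dt
  if (N0 == 0)
    warn("no outward crossings of lambda_0: flux is zero, FFS cannot proceed")
  pts <- if (length(points)) records_tibble(do.call(rbind, points)) else
    records_tibble(matrix(numeric(0), 0, 14))
  new_fh_flux(phi = N0 / time_counted, N0 = N0, time_counted = time_counted,
              points = pts, resets = resets, method = "reset",
              counters = c(noise = cn, hop = ch))
}

sm_unif <- function(seed, id) as.integer(cpp_derive_seed(seed, id) %% 2^31)

new_fh_flux <- function(...) structure(list(...), class = "fh_flux")

#' @export
print.fh_flux <- function(x, ...) {
  cat(sprintf("<fh_flux> phi_A = %.4g  (N0 = %d over time %.4g, method: %s)\n",
              x$phi, as.integer(x$N0), x$time_counted, x$method))
  invisible(x)
}

#' Flux out of A without reset
#'
#' For equilibrium systems that visit both stable regions, the flux is
#' \eqn{\phi_A = N_0 / \tilde{T}} where \eqn{\tilde{T}} accumulates all
#' time spent in A plus time outside A while B has not yet been reached;
#' after a visit to B, counting resumes only once the trajectory re-enters
#' A.  Dispatches on the first argument: a stored `fh_trajectory` is
#' analyzed as-is, while a `fh_model` triggers a fresh simulation that
#' collects crossing snapshots as shooting points.
#'
#' @param x A `fh_trajectory` (recorded at stride 1) or a `fh_model`.
#' @param A,B Stable regions.
#' @param ... For the model method: `thermo`, `init`, `n_steps`, and
#'   optionally `interfaces`, `equil_steps`.
#' @return A `fh_flux` object.
#' @export
flux_without_reset <- function(x, A, B, ...) UseMethod("flux_without_reset")

#' @rdname flux_without_reset
#' @export
flux_without_reset.fh_trajectory <- function(x, A, B, ...) {
  sn <- x$snapshots
  dt <- x$dt
  inA <- region_contains(A, sn)
  inB <- region_contains(B, sn)
  lam0 <- A$level; outdir <- -A$dir
  cv <- cv_of(A$w, sn)
  n <- nrow(sn)
  was <- outdir * (cv[-n] - lam0) < 0
  now <- outdir * (cv[-1] - lam0) >= 0
  okst <- sn$active_state[-1] %in% A$states
  crossed <- was & now & okst
  counting <- logical(n)
  cnt <- TRUE
  for (i in seq_len(n)) {
    if (inB[i]) cnt <- FALSE else if (inA[i]) cnt <- TRUE
    counting[i] <- cnt
  }
  counted_pairs <- counting[-n]
  N0 <- sum(crossed & counted_pairs)
  Tt <- sum(counted_pairs) * dt
  idx <- which(crossed & counted_pairs) + 1L
  pts <- tibble(event = 1, step = sn$step[idx], time = sn$time[idx],
                x = sn$x[idx], y = sn$y[idx], z = sn$z[idx],
                vx = sn$vx[idx], vy = sn$vy[idx], vz = sn$vz[idx],
                active_state = sn$active_state[idx],
                re1 = sn$re1[idx], im1 = sn$im1[idx],
                re2 = sn$re2[idx], im2 = sn$im2[idx])
  if (N0 == 0) warn("no outward crossings of lambda_0 in the trajectory")
  new_fh_flux(phi = N0 / Tt, N0 = N0, time_counted = Tt, points = pts,
              resets = 0L, method = "no_reset", counters = NULL)
}

#' @rdname flux_without_reset
#' @export
flux_without_reset.fh_model <- function(x, A, B, thermo, init, n_steps,
                                        interfaces = NULL,
                                        equil_steps = 2000L, ...) {
  model <- x
  lam0 <- if (!is.null(interfaces)) interfaces$levels[1] else A$level
  st0 <- if (!is.null(interfaces)) interfaces$states[[1]] else A$states
  outdir <- -A$dir
  ev_cross <- c(A$w, lam0, outdir, state_mask(st0), 0L, 1L)
  ev_B <- region_event(B, 2L)
  ev_A <- region_event(A, 2L)

  st <- snapshot_to_state(init); t0 <- init$time
  eq <- engine_run(model, thermo, st, t0, equil_steps, record_hops = FALSE)
  st <- eq$state; t0 <- eq$time
  cn <- eq$noise_counter; ch <- eq$hop_counter

  N0 <- 0; counted <- 0; points <- list()
  remaining <- n_steps
  in_b_excursion <- FALSE
  while (remaining > 0) {
    events <- if (in_b_excursion) rbind(ev_A) else rbind(ev_cross, ev_B)
    res <- engine_run(model, thermo, st, t0, remaining, events = events,
                      max_record = 200000, noise_counter = cn,
                      hop_counter = ch, record_hops = FALSE)
    cn <- res$noise_counter; ch <- res$hop_counter
    remaining <- remaining - res$steps_done
    if (!in_b_excursion) {
      counted <- counted + res$steps_done
      N0 <- N0 + res$event_counts[1]
      if (nrow(res$records) > 0)
        points[[length(points) + 1]] <- res$records
      if (res$stop_event == 2) in_b_excursion <- TRUE
    } else {
      if (res$stop_event == 1) in_b_excursion <- FALSE
    }
    st <- res$state; t0 <- res$time
    if (res$stop_event == 0) break
  }
  time_counted <- counted * thermo$dt
  if (N0 == 0)
    warn("no outward crossings of lambda_0: flux is zero, FFS cannot proceed")
  pts <- if (length(points)) records_tibble(do.call(rbind, points)) else
    records_tibble(matrix(numeric(0), 0, 14))
  new_fh_flux(phi = N0 / time_counted, N0 = N0, time_counted = time_counted,
              points = pts, resets = 0L, method = "no_reset",
              counters = c(noise = cn, hop = ch))
}

#' One forward-flux-sampling shooting cycle
#'
#' Launches `M` trial shots from shooting points stored on interface i
#' (chosen uniformly at random with replacement); each shot runs
#' surface-hopping dynamics until it crosses interface i+1 outward
#' (accepted; its endpoint becomes a shooting point of the next cycle),
#' enters region A (rejected), or exceeds `max_steps` (rejected, counted
#' separately).  The crossing probability is \eqn{P_i = N_{i+1}/M_i}.
#' Shots are seeded per shot id from the thermostat seeds, so results do
#' not depend on execution order and an interrupted cycle can be resumed.
#'
#' @param model,thermo Model and thermostat.
#' @param points Tibble of shooting snapshots (as produced by the flux
#'   functions or a previous cycle).
#' @param interfaces A `fh_interfaces`.
#' @param cycle Index i of the cycle (shots run from lambda_{i-1} toward
#'   lambda_i in 1-based level numbering: cycle 1 shoots from `levels[1]`).
#' @param A Region A (rejection region).
#' @param M Number of trial shots.
#' @param max_steps Per-shot step cap.
#' @param shot_ids Which shot ids to run (default `1:M`); running disjoint
#'   subsets and combining them reproduces the full cycle exactly.
#' @param B Region B.  When supplied and `cycle` targets the final
#'   interface (the boundary of B), acceptance is full membership of B --
#'   collective variable and electronic state -- rather than a bare level
#'   crossing, so a shot that slides past the boundary on a state outside
#'   B's allowed set is not scored as reactive until it actually enters B.
#' @return List with `P`, `N_next`, `M`, `n_timeout`, and `accepted`
#'   (tibble with endpoint state, parent/shot ids, steps, hop count).
#' @export
ffs_cycle <- function(model, thermo, points, interfaces, cycle, A, M,
                      max_steps = 100000L, shot_ids = seq_len(M),
                      B = NULL) {
  stopifnot(nrow(points) >= 1L, cycle >= 1L,
            cycle + 1L <= length(interfaces$levels))
  final <- cycle + 1L == length(interfaces$levels)
  ev_next <- if (final && !is.null(B)) region_event(B, 2L)
             else interface_event(interfaces, cycle + 1L, type = 1L)
  ev_A <- region_event(A, 2L)
  events <- rbind(ev_next, ev_A)
  npts <- nrow(points)
  acc <- list()
  n_acc <- 0L; n_timeout <- 0L
  for (j in shot_ids) {
    parent <- 1L + (sm_unif(thermo$seed_hop, cycle * 2^22 + j) %% npts)
    row <- points[parent, ]
    st <- record_row_to_state(row)
    sn_j <- cpp_derive_seed(thermo$seed_noise, cycle * 2^21 + j)
    sh_j <- cpp_derive_seed(thermo$seed_hop, cycle * 2^21 + j)
    res <- engine_run(model, thermo, st, row$time, max_steps,
                      events = events, seed_noise = sn_j, seed_hop = sh_j)
    if (res$stop_event == 1) {
      n_acc <- n_acc + 1L
      acc[[n_acc]] <- c(shot = j, parent = parent, steps = res$steps_done,
                        n_hops = res$n_hops, time = res$time,
                        start = st, state = res$state)
    } else if (res$stop_event == 0) {
      n_timeout <- n_timeout + 1L
    }
  }
  if (n_timeout > 0)
    warn(sprintf("cycle %d: %d of %d shots exceeded max_steps = %d",
                 cycle, n_timeout, length(shot_ids), as.integer(max_steps)))
  accepted <- if (n_acc > 0) {
    am <- do.call(rbind, acc)
    colnames(am) <- c("shot", "parent", "steps", "n_hops", "time",
                      paste0("start", 1:11), paste0("s", 1:11))
    as_tibble(am)
  } else tibble()
  list(P = n_acc / length(shot_ids), N_next = n_acc, M = length(shot_ids),
       n_timeout = n_timeout, accepted = accepted)
}

accepted_to_points <- function(accepted) {
  tibble(event = 1, step = 0, time = accepted$time,
         x = accepted$s1, y = accepted$s2, z = accepted$s3,
         vx = accepted$s4, vy = accepted$s5, vz = accepted$s6,
         active_state = as.integer(accepted$s7) + 1L,
         re1 = accepted$s8, im1 = accepted$s9,
         re2 = accepted$s10, im2 = accepted$s11)
}

#' Rate constant from flux and crossing probabilities
#'
#' \eqn{k_{AB} = \phi_A \prod_i P_A(\lambda_{i+1}|\lambda_i)}.
#'
#' @param phi Flux out of A.
#' @param P Vector of per-interface crossing probabilities.
#' @return The rate constant.
#' @export
compute_rate <- function(phi, P) {
  stopifnot(phi >= 0, all(P >= 0), all(P <= 1))
  phi * prod(P)
}

#' Gaussian error propagation for the FFS rate constant
#'
#' Relative error of the rate constant from the binomial errors of the
#' crossing probabilities and the Poisson error of the flux:
#' \deqn{\left(\frac{\Delta k_{AB}}{k_{AB}}\right)^2 = \frac{1}{N_0} +
#'   \sum_i \frac{1 - P_i}{P_i M_i}.}
#'
#' @param N0 Number of lambda_0 crossings in the flux simulation.
#' @param M Vector of shot counts per interface.
#' @param N_next Vector of accepted-shot counts per interface.
#' @return List with `rel_error`, `flux_rel`, and a per-interface tibble.
#' @export
estimate_error <- function(N0, M, N_next) {
  stopifnot(length(M) == length(N_next), N0 >= 1, all(M >= 1))
  P <- N_next / M
  term <- ifelse(P > 0, (1 - P) / (P * M), Inf)
  per <- tibble(interface = seq_along(M), M = M, N_next = N_next, P = P,
                rel_error = sqrt(term))
  list(rel_error = sqrt(1 / N0 + sum(term)), flux_rel = sqrt(1 / N0),
       per_interface = per)
}

#' Full nonadiabatic forward flux sampling run
#'
#' Chains the flux simulation and the shooting cycles across all interfaces
#' and assembles the rate constant \eqn{k_{AB} = \phi_A \prod_i P_i} with
#' its propagated error, plus the stitched transition paths.
#'
#' @param model,thermo,init Model, thermostat, initial snapshot in A.
#' @param A,B Stable regions.
#' @param interfaces A `fh_interfaces` whose first and last levels are the
#'   boundaries of A and B.
#' @param flux_method `"reset"` or `"no_reset"`.
#' @param flux_steps Step budget of the flux simulation.
#' @param shots Shots per interface (scalar or one value per cycle).
#' @param max_steps Per-shot cap; by default 100x the mean accepted-shot
#'   length of the previous cycle (1e5 for the first cycle).
#' @param equil_steps Equilibration before the flux simulation.
#' @param ... Passed to the flux function.
#' @return A `fh_ffs` object: flux block, per-interface `summary` tibble,
#'   `k_AB`, `dk_AB`, `rel_error`, stitched `paths` tibble, and cycles.
#' @export
run_naffs <- function(model, thermo, init, A, B, interfaces,
                      flux_method = c("reset", "no_reset"),
                      flux_steps, shots, max_steps = NULL,
                      equil_steps = 2000L, ...) {
  flux_method <- match.arg(flux_method)
  flux <- if (flux_method == "reset") {
    flux_with_reset(model, thermo, init, A, B, flux_steps,
                    interfaces = interfaces, equil_steps = equil_steps, ...)
  } else {
    flux_without_reset(model, A, B, thermo = thermo, init = init,
                       n_steps = flux_steps, interfaces = interfaces,
                       equil_steps = equil_steps, ...)
  }
  n_cycles <- length(interfaces$levels) - 1L
  shots <- rep_len(shots, n_cycles)
  points <- flux$points
  cycles <- vector("list", n_cycles)
  P <- numeric(n_cycles)
  prev_mean_steps <- NULL
  for (i in seq_len(n_cycles)) {
    if (nrow(points) == 0L) {
      warn(sprintf("no shooting points before cycle %d; sampling terminates", i))
      P[i:n_cycles] <- 0
      break
    }
    cap <- if (!is.null(max_steps)) max_steps
           else if (is.null(prev_mean_steps)) 100000L
           else max(1000L, ceiling(100 * prev_mean_steps))
    cyc <- ffs_cycle(model, thermo, points, interfaces, i, A, shots[i],
                     max_steps = cap, B = B)
    cycles[[i]] <- cyc
    P[i] <- cyc$P
    if (cyc$N_next == 0L) {
      warn(sprintf("all shots rejected at cycle %d; sampling terminates", i))
      break
    }
    prev_mean_steps <- mean(cyc$accepted$steps)
    points <- accepted_to_points(cyc$accepted)
  }
  k <- compute_rate(flux$phi, P)
  err <- if (all(P > 0)) {
    estimate_error(flux$N0,
                   vapply(cycles, function(cc) as.numeric(cc$M), 0),
                   vapply(cycles, function(cc) as.numeric(cc$N_next), 0))
  } else list(rel_error = NA_real_, flux_rel = 1 / sqrt(max(flux$N0, 1)),
              per_interface = tibble())
  summary <- tibble(
    interface = seq_len(n_cycles),
    lambda = interfaces$levels[-1],
    M = shots,
    N_next = vapply(cycles, function(cc) if (is.null(cc)) 0L else cc$N_next, 0L),
    P = P,
    cum_product = flux$phi * cumprod(P))
  obj <- structure(list(flux = flux, cycles = cycles, summary = summary,
                        interfaces = interfaces, k_AB = k,
                        rel_error = err$rel_error,
                        dk_AB = if (is.na(err$rel_error)) NA_real_
                                else k * err$rel_error,
                        model = model, thermo = thermo, dt = thermo$dt),
                   class = "fh_ffs")
  obj$paths <- stitch_paths(obj)
  obj
}

#' @export
print.fh_ffs <- function(x, ...) {
  cat(sprintf("<fh_ffs> k_AB = %.4g +/- %.2g  (phi = %.4g, %d interfaces)\n",
              x$k_AB, x$dk_AB, x$flux$phi, nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Stitch accepted partial paths into transition paths
#'
#' Walks the provenance of every accepted shot of the final cycle back to
#' its lambda_0 shooting point and sums segment lengths and hop counts;
#' each chain is one A-to-B transition path.  Each shot was launched from
#' the bitwise-identical stored endpoint of its parent, which is verified
#' here; a mismatch raises an integrity error.
#'
#' @param ffs A `fh_ffs` object.
#' @return Tibble with one row per transition path: `path_id`, `duration`,
#'   `n_hops`, and the per-cycle shot indices (list column `chain`).
#' @export
stitch_paths <- function(ffs) {
  cycles <- ffs$cycles
  n <- length(cycles)
  if (n == 0L || is.null(cycles[[n]]) || cycles[[n]]$N_next == 0L)
    return(tibble(path_id = integer(0), duration = numeric(0),
                  n_hops = numeric(0), start_state = integer(0)))
  last <- cycles[[n]]$accepted
  out <- vector("list", nrow(last))
  for (p in seq_len(nrow(last))) {
    steps <- 0; hops <- 0; chain <- integer(n)
    row <- last[p, ]
    for (i in rev(seq_len(n))) {
      steps <- steps + row$steps; hops <- hops + row$n_hops
      chain[i] <- row$shot
      if (i > 1L) {
        parent <- cycles[[i - 1L]]$accepted[row$parent, ]
        if (nrow(parent) == 0L || any(is.na(parent)))
          abort("broken provenance chain while stitching transition paths")
        endpoint <- unlist(parent[paste0("s", 1:11)], use.names = FALSE)
        startpt <- unlist(row[paste0("start", 1:11)], use.names = FALSE)
        if (!identical(endpoint, startpt))
          abort("provenance integrity error: segment endpoints do not match")
        row <- parent
      }
    }
    out[[p]] <- list(duration = steps * ffs$dt, n_hops = hops, chain = chain,
                     start_state = as.integer(row$start7) + 1L)
  }
  tibble(path_id = seq_along(out),
         duration = vapply(out, `[[`, 0, "duration"),
         n_hops = vapply(out, `[[`, 0, "n_hops"),
         start_state = vapply(out, `[[`, 0L, "start_state"),
         chain = lapply(out, `[[`, "chain"))
}
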