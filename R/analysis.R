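# Transition-path extraction and statistics, brute-force rate estimation,
# and the temperature / gap dependence fits.

#' Extract transition paths from a stored trajectory
#'
#' Each maximal segment from the last exit of region A to the first entry
#' of region B, with no intervening A re-entry, is one transition path.
#' The path starts at the first snapshot after the last A-exit and ends at
#' the first snapshot inside B, so its duration is (snapshot count - 1)
#' times the recording interval.  Hop counts include accepted hops only.
#'
#' @param trajectory A `fh_trajectory` recorded at stride 1.
#' @param A,B Stable regions (`fh_region`).
#' @param direction `"AB"` or `"BA"`.
#' @return Tibble with one row per path: start/end indices and times,
#'   `duration`, `n_hops`.
#' @export
extract_transitions <- function(trajectory, A, B, direction = c("AB", "BA")) {
  direction <- match.arg(direction)
  if (direction == "BA") { tmp <- A; A <- B; B <- tmp }
  sn <- trajectory$snapshots
  inA <- region_contains(A, sn)
  inB <- region_contains(B, sn)
  idx <- which(inA | inB)
  reg <- ifelse(inA[idx], 1L, 2L)
  change <- which(reg[-1] == 2L & reg[-length(reg)] == 1L)
  if (length(change) == 0L)
    return(tibble(path_id = integer(0), i_start = integer(0),
                  i_end = integer(0), t_start = numeric(0),
                  t_end = numeric(0), duration = numeric(0),
                  n_hops = numeric(0)))
  iA <- idx[change]          # last snapshot in A before the transition
  iB <- idx[change + 1L]     # first snapshot in B
  t_exit <- sn$time[iA]
  t_start <- sn$time[iA + 1L]
  t_end <- sn$time[iB]
  hops <- trajectory$hops
  acc <- hops[!hops$frustrated, , drop = FALSE]
  n_hops <- vapply(seq_along(iA), function(p)
    sum(acc$time > t_exit[p] & acc$time <= t_end[p]), numeric(1))
  tibble(path_id = seq_along(iA), i_start = iA + 1L, i_end = iB,
         t_start = t_start, t_end = t_end,
         duration = t_end - t_start, n_hops = n_hops)
}

#' Summary statistics of an ensemble of transition paths
#'
#' Standard deviations are population standard deviations (a single path
#' has spread zero, not NA).
#'
#' @param paths Tibble with columns `duration` and `n_hops` (as produced by
#'   [extract_transitions()] or [stitch_paths()]).
#' @return One-row tibble: `n_paths`, `mean_time`, `std_time`, `mean_hops`,
#'   `std_hops`.
#' @export
path_statistics <- function(paths) {
  pop_sd <- function(x) if (length(x) == 0L) NA_real_
                        else sqrt(mean((x - mean(x))^2))
  tibble(n_paths = nrow(paths),
         mean_time = mean(paths$duration),
         std_time = pop_sd(paths$duration),
         mean_hops = mean(paths$n_hops),
         std_hops = pop_sd(paths$n_hops))
}

#' Brute-force rate constant from a single long trajectory
#'
#' Propagates one long surface-hopping trajectory and counts A-to-B
#' transition events.  The rate constant is the number of A-to-B
#' transitions divided by the total time whose most recently visited stable
#' region is A.  Memory stays bounded because the trajectory is advanced in
#' region-to-region segments without storing snapshots; per-path durations
#' and hop counts are taken from the recorded boundary crossings and the
#' complete hop log.
#'
#' @param model,thermo,init Model, thermostat, initial snapshot inside A.
#' @param A,B Stable regions.
#' @param n_steps Total number of steps.
#' @param equil_steps Discarded equilibration steps.
#' @return List with `k_AB`, `se` (Poisson standard error), `n_paths`,
#'   `paths` (tibble of durations and hop counts), `time_A`, `time_B`,
#'   `n_BA`.
#' @export
brute_force_rate <- function(model, thermo, init, A, B, n_steps,
                             equil_steps = 2000L) {
  ev_exitA <- c(A$w, A$level, -A$dir, state_mask(A$states), 0L, 1L)
  ev_B <- region_event(B, 2L)
  ev_A <- region_event(A, 2L)

  eq <- engine_run(model, thermo, snapshot_to_state(init), init$time,
                   equil_steps, record_hops = FALSE)
  st <- eq$state; t0 <- eq$time
  cn <- eq$noise_counter; ch <- eq$hop_counter

  time_A <- 0; time_B <- 0
  n_AB <- 0L; n_BA <- 0L
  durations <- numeric(0); hop_counts <- numeric(0)
  remaining <- n_steps
  side <- "A"
  while (remaining > 0) {
    events <- if (side == "A") rbind(ev_exitA, ev_B) else rbind(ev_A)
    res <- engine_run(model, thermo, st, t0, remaining, events = events,
                      max_record = 100000, noise_counter = cn,
                      hop_counter = ch, record_hops = (side == "A"))
    cn <- res$noise_counter; ch <- res$hop_counter
    remaining <- remaining - res$steps_done
    seg_t <- res$steps_done * thermo$dt
    if (side == "A") {
      time_A <- time_A + seg_t
      if (res$stop_event == 2) {       # reached B
        n_AB <- n_AB + 1L
        rec <- res$records
        t_exit <- if (nrow(rec) > 0) rec[nrow(rec), 3] else t0
        durations <- c(durations, res$time - t_exit)
        hops <- res$hops
        nh <- if (nrow(hops) > 0)
          sum(hops[, 5] == 0 & hops[, 2] > t_exit) else 0
        hop_counts <- c(hop_counts, nh)
        side <- "B"
      }
    } else {
      time_B <- time_B + seg_t
      if (res$stop_event == 1) { n_BA <- n_BA + 1L; side <- "A" }
    }
    st <- res$state; t0 <- res$time
    if (res$stop_event == 0) break
  }
  k <- if (time_A > 0) n_AB / time_A else 0
  list(k_AB = k, se = if (n_AB > 0) k / sqrt(n_AB) else NA_real_,
       n_paths = n_AB, n_BA = n_BA,
       paths = tibble(path_id = seq_len(n_AB), duration = durations,
                      n_hops = hop_counts),
       time_A = time_A, time_B = time_B)
}

new_fh_fit <- function(tag, params, data, residuals, fitted) {
  structure(list(tag = tag, params = params, data = data,
                 residuals = residuals, fitted = fitted),
            class = "fh_fit")
}

#' @export
print.fh_fit <- function(x, ...) {
  cat("<fh_fit> ", x$tag, "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @export
tidy.fh_fit <- function(x, ...) x$params

#' @export
glance.fh_fit <- function(x, ...) {
  tibble(tag = x$tag, n = nrow(x$data),
         sigma = sqrt(mean(x$residuals^2)))
}

#' Arrhenius fit of rate constants versus temperature
#'
#' Weighted linear fit of \eqn{\ln k = \ln\nu - E_a / (k_B T)} in log-rate
#' space, with weights \eqn{1/\sigma^2} from the rate errors propagated as
#' \eqn{\sigma_{\ln k} = \Delta k / k}.  In `mode = "fixed"` the slope is
#' pinned to a known activation energy and only the intercept (the
#' prefactor \eqn{\nu}) is fitted; `mode = "free"` also fits the effective
#' activation energy.  Confidence bounds are 2-sigma.
#'
#' @param rates Tibble/data frame with columns `temperature`, `rate`, and
#'   optionally `rate_err`.
#' @param mode `"free"` or `"fixed"`.
#' @param activation_energy Required in fixed mode.
#' @return A `fh_fit` with parameters `nu` and (free mode) `E_a_eff`.
#' @export
fit_arrhenius <- function(rates, mode = c("free", "fixed"),
                          activation_energy = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(rates) >= if (mode == "free") 3L else 2L,
            all(rates$rate > 0))
  y <- log(rates$rate)
  xinv <- 1 / rates$temperature
  sig <- if ("rate_err" %in% names(rates)) rates$rate_err / rates$rate
         else rep(1, nrow(rates))
  wts <- 1 / sig^2
  if (mode == "fixed") {
    stopifnot(!is.null(activation_energy))
    z <- y + activation_energy * xinv
    mu <- weighted.mean(z, wts)
    se <- sqrt(1 / sum(wts))
    params <- tibble(term = "nu", estimate = exp(mu),
                     std_error = exp(mu) * se,
                     conf_low = exp(mu - 2 * se),
                     conf_high = exp(mu + 2 * se))
    fitted <- mu - activation_energy * xinv
    return(new_fh_fit("arrhenius-fixed-Ea", params, rates, y - fitted,
                      exp(fitted)))
  }
  fit <- lm(y ~ xinv, weights = wts)
  cf <- coef(fit); vc <- vcov(fit)
  lnnu <- cf[[1]]; se_lnnu <- sqrt(vc[1, 1])
  Ea <- -cf[[2]]; se_Ea <- sqrt(vc[2, 2])
  params <- tibble(
    term = c("nu", "E_a_eff"),
    estimate = c(exp(lnnu), Ea),
    std_error = c(exp(lnnu) * se_lnnu, se_Ea),
    conf_low = c(exp(lnnu - 2 * se_lnnu), Ea - 2 * se_Ea),
    conf_high = c(exp(lnnu + 2 * se_lnnu), Ea + 2 * se_Ea))
  new_fh_fit("arrhenius-free", params, rates, y - fitted(fit),
             exp(fitted(fit)))
}

#' Landau-Zener-type fit of rate constants versus adiabatic gap
#'
#' Weighted nonlinear least squares of
#' \eqn{k_{AB}(g) = k_{AB}^0\,(1 - e^{-z g^2})}: at zero gap the system is
#' diabatically trapped and the rate vanishes; for large gaps the rate
#' tends to the adiabatic lower-state rate \eqn{k_{AB}^0}.
#'
#' @param rates Tibble with columns `gap`, `rate`, optionally `rate_err`.
#' @return A `fh_fit` with parameters `k0` and `z` (2-sigma bounds).
#' @export
fit_landau_zener <- function(rates) {
  stopifnot(nrow(rates) >= 3L, all(rates$gap >= 0))
  wts <- if ("rate_err" %in% names(rates)) 1 / rates$rate_err^2
         else rep(1, nrow(rates))
  k0_0 <- max(rates$rate)
  nz <- rates[rates$gap > 0 & rates$rate > 0, ]
  gmin <- nz[which.min(nz$gap), ]
  frac <- min(gmin$rate / k0_0, 0.95)
  z0 <- max(-log(1 - frac) / gmin$gap^2, 1)
  df <- data.frame(g = rates$gap, k = rates$rate, w = wts)
  fml <- k ~ k0 * (1 - exp(-z * g^2))
  fit <- if (requireNamespace("minpack.lm", quietly = TRUE)) {
    minpack.lm::nlsLM(fml, data = df, weights = w,
                      start = list(k0 = k0_0, z = z0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    nls(fml, data = df, weights = w, start = list(k0 = k0_0, z = z0),
        algorithm = "port", lower = c(0, 0))
  }
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  params <- tibble(term = c("k0", "z"), estimate = unname(cf),
                   std_error = unname(se),
                   conf_low = unname(cf - 2 * se),
                   conf_high = unname(cf + 2 * se))
  new_fh_fit("landau-zener", params, rates,
             rates$rate - predict(fit), predict(fit))
}

#' Predicted Landau-Zener-type rate
#'
#' @param fit A `fh_fit` from [fit_landau_zener()], or a named vector with
#'   `k0` and `z`.
#' @param gap Gap values.
#' @return Predicted rates (`k0 * (1 - exp(-z g^2))`; 0 at g = 0).
#' @export
landau_zener_rate <- function(fit, gap) {
  p <- if (inherits(fit, "fh_fit")) setNames(fit$params$estimate,
                                             fit$params$term) else fit
  p[["k0"]] * (1 - exp(-p[["z"]] * gap^2))
}

#' Decompose the rate constant by the number of hops per path
#'
#' Classifies transition paths by their (accepted) hop count and assigns
#' each class the fraction of the total rate constant carried by its paths:
#' \eqn{k_{class} = k_{AB}\, n_{class} / n_{total}}.  When both stable
#' regions live on the same single adiabatic state, only even hop counts
#' can occur.
#'
#' @param paths Tibble with a `n_hops` column.
#' @param k_AB Total rate constant.
#' @return Tibble with `n_hops_class`, `n_paths`, `fraction`, `rate`.
#' @export
hop_class_rates <- function(paths, k_AB) {
  stopifnot(nrow(paths) > 0)
  paths |>
    dplyr::count(n_hops_class = .data$n_hops, name = "n_paths") |>
    dplyr::arrange(.data$n_hops_class) |>
    dplyr::mutate(fraction = .data$n_paths / sum(.data$n_paths),
                  rate = k_AB * .data$fraction)
}
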