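# shared fixtures: models, thermostats, regions, interfaces

ac_model <- function(coupling = 0.4) model_avoided_crossing(coupling)
ci_model <- function() model_conical_intersection()

ac_thermo <- function(seed_n = 1, seed_h = 2, temperature = 0.64 / 3,
                      friction = 1.4133, hopping = TRUE)
  thermostat(temperature, friction, dt = 0.0539, substeps = 25,
             decoherence = 0.1, seed_noise = seed_n, seed_hop = seed_h,
             hopping = hopping)

ci_thermo <- function(seed_n = 1, seed_h = 2, temperature = 0.6370)
  thermostat(temperature, 0.7995, dt = 0.1348, substeps = 25,
             decoherence = 0.1, seed_noise = seed_n, seed_hop = seed_h)

ac_regions <- function(w = 0.5)
  list(A = region_spec("x", "<", -w, states = 1),
       B = region_spec("x", ">", w, states = 1))

ac_interfaces <- function(w = 0.5, n = 6)
  interface_set("x", seq(-w, w, length.out = n), states = c(1, 2))

ci_regions <- function()
  list(A = region_spec("x-y", ">=", 2.5, states = 1),
       B = region_spec("x-y", "<=", -2.5, states = 1))

ci_interfaces <- function()
  interface_set("x-y", c(2.5, 1.5, 0.5, -0.5, -1.5, -2.5), states = c(1, 2))

# rotation matrix, used to build smooth 2-state transformation paths
rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

# hand-built fh_trajectory from a vector of x positions at unit spacing
toy_trajectory <- function(x, dt = 1, state = 1L) {
  n <- length(x)
  structure(list(
    snapshots = tibble::tibble(
      step = seq_len(n) - 1, time = (seq_len(n) - 1) * dt,
      x = x, y = 0, z = 0, vx = 0, vy = 0, vz = 0,
      active_state = rep_len(state, n),
      re1 = 1, im1 = 0, re2 = 0, im2 = 0, E1 = 0, E2 = 1),
    hops = tibble::tibble(step = numeric(0), time = numeric(0),
                          from = integer(0), to = integer(0),
                          frustrated = logical(0)),
    dt = dt), class = "fh_trajectory")
}

# effective sample size of a stitched-path ensemble: paths sharing the same
# first-cycle shot are strongly correlated, so cluster on distinct ancestors
path_n_eff <- function(paths) {
  if (nrow(paths) == 0L || !"chain" %in% names(paths)) return(nrow(paths))
  length(unique(vapply(paths$chain, function(ch) as.integer(ch[1]), 0L)))
}
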