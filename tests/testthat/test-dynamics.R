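test_that("gamma = 0 reduces to velocity Verlet with bounded energy drift", {
  m <- ac_model(0.4)
  th <- thermostat(0.2133, 0, dt = 0.0539, seed_noise = 10, seed_hop = 20)
  # small displacement inside one well of the lower surface
  tr <- run_tsh(m, snapshot(c(-0.88, 0, 0)), th, 1e5, record_stride = 50)
  sn <- tr$snapshots
  E <- 0.5 * (sn$vx^2 + sn$vy^2 + sn$vz^2) +
    ifelse(sn$active_state == 1, sn$E1, sn$E2)
  expect_lt(max(abs(E - E[1])), 1e-4)
  expect_lt(tr$max_norm_err, 1e-9)
})

test_that("pure-friction limit decays the velocity exponentially", {
  m <- ac_model(0.4)
  g <- 50                      # friction dominates the well frequency
  th <- thermostat(0, g, dt = 2e-4, seed_noise = 1, seed_hop = 2)
  ba <- barrier_analysis(m)
  x0 <- ba$minima[1, ]         # start at the minimum: force ~ 0 during decay
  tr <- run_tsh(m, snapshot(x0, c(0.05, 0, 0)), th, 200, record_stride = 200)
  v_end <- tr$final$velocity[1]
  expect_equal(v_end / 0.05, exp(-g * 200 * 2e-4), tolerance = 0.01)
})

test_that("thermostatted single well satisfies equipartition and Boltzmann", {
  m <- ac_model(0.4)
  th <- thermostat(0.2133, 1.4133, 0.0539, seed_noise = 31, seed_hop = 32)
  tr <- run_tsh(m, snapshot(c(-0.9798, 0, 0)), th, 1e6, record_stride = 10)
  sn <- tr$snapshots[-(1:2000), ]
  ekin <- 0.5 * mean(sn$vx^2 + sn$vy^2 + sn$vz^2)
  expect_equal(ekin, 1.5 * 0.2133, tolerance = 0.02)

  # transverse marginal is exactly Gaussian on the active surface
  y <- sn$y[seq(1, nrow(sn), by = 20)]
  ks <- suppressWarnings(
    ks.test(y, "pnorm", mean = 0, sd = sqrt(0.2133 / 12.8)))
  expect_gt(ks$p.value, 0.01)
})

test_that("trajectories are reproducible and regularly spaced", {
  m <- ci_model()
  th <- ci_thermo(77, 88)
  t1 <- run_tsh(m, snapshot(c(3, 0, 0)), th, 4000)
  t2 <- run_tsh(m, snapshot(c(3, 0, 0)), th, 4000)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$hops, t2$hops)
  expect_identical(snapshot_to_state(t1$final), snapshot_to_state(t2$final))
  dts <- diff(t1$snapshots$time)
  expect_true(all(abs(dts - th$dt) < 1e-12))
  expect_true(all(dts > 0))
  # different hop seed, same noise seed: same thermostat kicks
  t3 <- run_tsh(m, snapshot(c(3, 0, 0)),
                thermostat(0.6370, 0.7995, 0.1348, seed_noise = 77,
                           seed_hop = 999), 4000)
  expect_false(identical(t1$hops, t3$hops) &&
                 !identical(nrow(t1$hops), 0L))
})

test_that("compiled engine matches the pure-R reference step for step", {
  set.seed(99)
  for (m in list(ac_model(0.4), ci_model())) {
    n <- 150
    th <- if (m$type == 0) ac_thermo(1, 2) else ci_thermo(1, 2)
    noise <- matrix(rnorm(3 * n, 0,
                          sqrt(2 * th$friction * th$temperature * th$dt)),
                    n, 3)
    unifs <- runif(n)
    init <- if (m$type == 0) snapshot(c(-0.7, 0.1, 0), c(0.6, 0, 0))
            else snapshot(c(1.2, 0.4, 0), c(-0.8, 0.5, 0))
    ref <- run_tsh_reference(m, init, th, n, noise, unifs)
    res <- engine_run(m, th, snapshot_to_state(init), 0, n, stride = 1,
                      injected_noise = noise, injected_uniforms = unifs)
    tr <- traj_tibble(res$trajectory)[-1, ]   # drop the initial snapshot
    expect_equal(tr$x, ref$states[, "x"], tolerance = 1e-9)
    expect_equal(tr$vx, ref$states[, "vx"], tolerance = 1e-9)
    expect_equal(tr$y, ref$states[, "y"], tolerance = 1e-9)
    expect_equal(tr$active_state, unname(ref$states[, "active"]))
  }
})

test_that("uncoupled diabats trap the system: no transitions at V_c = 0", {
  m <- ac_model(0)
  th <- ac_thermo(55, 66)
  rg <- ac_regions(0.5)
  bf <- brute_force_rate(m, th, snapshot(c(-0.98, 0, 0)), rg$A, rg$B, 2e5)
  expect_identical(bf$n_paths, 0L)
  expect_equal(bf$k_AB, 0)
})

test_that("rate through the barrier shows the Kramers turnover", {
  # first-passage rates (equilibrated A-well start to first B entry), so
  # correlated ballistic recrossings at low friction are not double-counted
  m <- ac_model(0.4)
  B <- region_spec("x", ">", 1, states = 1)
  fp_rate <- function(g, trips = 80) {
    base <- round(1e4 * g)
    ts <- vapply(seq_len(trips), function(i) {
      th <- thermostat(0.64 / 3, g, 0.0539, seed_noise = base + i,
                       seed_hop = base + 5000 + i)
      run_tsh(m, snapshot(c(-0.98, 0, 0)), th, 3e5, record_stride = 0,
              stop_regions = B)$final$time
    }, numeric(1))
    1 / mean(ts)
  }
  rates <- vapply(c(0.094, 0.943, 9.43), fp_rate, numeric(1))
  expect_gt(rates[2], rates[1])
  expect_gt(rates[2], rates[3])
})

test_that("propagation stops when a stop region is entered", {
  m <- ac_model(0.4)
  th <- ac_thermo(5, 6)
  B <- region_spec("x", ">", 0.5, states = 1)
  tr <- run_tsh(m, snapshot(c(-0.98, 0, 0)), th, 3e5, record_stride = 0,
                stop_regions = B)
  expect_identical(tr$stop_region, 1L)
  expect_gt(tr$final$position[1], 0.5)
  expect_lt(tr$steps_done, 3e5)
})
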