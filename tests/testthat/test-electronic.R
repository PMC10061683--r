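test_that("overlap matrix: self-overlap, sign flips, continuity", {
  U <- rot2(0.3)
  expect_equal(overlap_matrix(U, U), diag(2), tolerance = 1e-14)
  Uf <- U; Uf[, 2] <- -Uf[, 2]
  S <- overlap_matrix(U, Uf)
  expect_equal(diag(S), c(1, -1), tolerance = 1e-14)
  # ||S - I|| is O(dt): halving the step halves the deviation
  d1 <- max(abs(overlap_matrix(rot2(0), rot2(0.02)) - diag(2)))
  d2 <- max(abs(overlap_matrix(rot2(0), rot2(0.01)) - diag(2)))
  expect_equal(d1 / d2, 2, tolerance = 0.02)
  expect_error(overlap_matrix(matrix(1:4, 2), diag(2)), "orthonormal")
})

test_that("phase correction repairs signs and is idempotent", {
  expect_equal(phase_correct(diag(2))$S, diag(2))
  pc <- phase_correct(diag(c(1, -1)), H = diag(c(0.1, 0.5)))
  expect_equal(pc$S, diag(2))
  expect_equal(pc$H, diag(c(0.1, 0.5)))
  S <- overlap_matrix(rot2(0.1), rot2(0.13))
  once <- phase_correct(S)$S
  twice <- phase_correct(once)$S
  expect_equal(once, twice, tolerance = 1e-14)
  expect_warning(phase_correct(matrix(c(0, 1, 1, 0), 2)), "trivial crossing")
})

test_that("uncoupled propagation is a pure phase rotation", {
  e <- c(0.25, 0.8)
  pr <- propagate_amplitudes(c(1 + 0i, 0i), e, e, diag(2), dt = 0.1,
                             substeps = 25)
  expect_equal(Mod(pr$coefficients[1])^2, 1, tolerance = 1e-12)
  expect_equal(pr$coefficients[1], exp(-1i * e[1] * 0.1), tolerance = 1e-12)
  expect_error(propagate_amplitudes(c(2 + 0i, 0i), e, e, diag(2), 0.1),
               "normalized")
})

test_that("propagator is unitary and conserves the norm", {
  set.seed(5)
  for (rep in 1:100) {
    e1 <- runif(2, 0, 2); e2 <- e1 + runif(2, -0.2, 0.2)
    S <- rot2(runif(1, -0.4, 0.4))
    c0 <- complex(real = rnorm(2), imaginary = rnorm(2))
    c0 <- c0 / sqrt(sum(Mod(c0)^2))
    pr <- propagate_amplitudes(c0, e1, e2, S, dt = 0.05, substeps = 5)
    R <- pr$propagator
    expect_lt(max(Mod(R %*% Conj(t(R)) - diag(2))), 1e-9)
    expect_equal(sum(Mod(pr$coefficients)^2), 1, tolerance = 1e-9)
  }
})

test_that("substep count is converged at the default setting", {
  # strong-coupling passage assembled from a sequence of rotation overlaps
  nstep <- 40
  c25 <- c500 <- c(1 + 0i, 0i)
  e_of <- function(i) c(-0.1, 0.1) * (i - nstep / 2) / 5
  for (i in seq_len(nstep)) {
    S <- rot2(0.12 * exp(-((i - nstep / 2) / 6)^2))
    c25 <- propagate_amplitudes(c25, e_of(i), e_of(i + 1), S, 0.0539, 25)$coefficients
    c500 <- propagate_amplitudes(c500, e_of(i), e_of(i + 1), S, 0.0539, 500)$coefficients
  }
  expect_gt(Mod(c25[2])^2, 0.05)   # real population transfer happened
  expect_equal(Mod(c25[1])^2, Mod(c500[1])^2, tolerance = 1e-4)
  expect_equal(Mod(c25[2])^2, Mod(c500[2])^2, tolerance = 1e-4)
})

test_that("random sign injection is healed by phase correction", {
  set.seed(9)
  thetas <- cumsum(rnorm(60, 0, 0.05))
  e1 <- c(0, 0.5)
  run <- function(flip) {
    cc <- c(1 + 0i, 0i)
    U_prev <- rot2(0)
    for (i in seq_along(thetas)) {
      U <- rot2(thetas[i])
      if (flip && runif(1) < 0.5) { j <- sample(2, 1); U[, j] <- -U[, j] }
      S <- phase_correct(overlap_matrix(U_prev, U))$S
      cc <- propagate_amplitudes(cc, e1, e1, S, 0.05, 10)$coefficients
      U_prev <- U * rep(sign(diag(overlap_matrix(U_prev, U))), each = 2)
    }
    Mod(cc)^2
  }
  expect_equal(run(FALSE), run(TRUE), tolerance = 1e-8)
})

test_that("energy-based decoherence matches the closed formula", {
  cc <- complex(real = c(0.8, 0.6), imaginary = c(0, 0))
  e <- c(0, 0.8); ekin <- 0.3; C <- 0.1; dt <- 0.0539
  out <- decoherence_correct(cc, active = 1, e, ekin, C, dt)
  # tau = (1/|dE|)(1 + C/Ekin); non-active damped by exp(-dt/tau)
  damp <- exp(-dt * 0.8 / (1 + C / ekin))
  c2 <- 0.6 * damp
  expect_equal(Mod(out$coefficients[2]), c2, tolerance = 1e-12)
  expect_equal(sum(Mod(out$coefficients)^2), 1, tolerance = 1e-12)
  expect_equal(Mod(out$coefficients[1]), sqrt(1 - c2^2), tolerance = 1e-12)

  # nothing to damp
  pure <- decoherence_correct(c(1 + 0i, 0i), 1, e, ekin, C, dt)
  expect_equal(pure$coefficients, c(1 + 0i, 0i))

  # degenerate energies: infinite decoherence time
  deg <- decoherence_correct(cc, 1, c(0.5, 0.5), ekin, C, dt)
  expect_equal(deg$coefficients, cc, tolerance = 1e-12)

  # active amplitude exactly zero: renormalization impossible, flagged
  z <- decoherence_correct(c(0i, 1 + 0i), 1, e, ekin, C, dt)
  expect_false(z$applied)
  expect_equal(z$coefficients, c(0i, 1 + 0i))
})
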