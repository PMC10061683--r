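test_that("avoided-crossing diabats: constant coupling and mirror symmetry", {
  m <- ac_model(0.4)
  for (x in c(-1.7, -0.3, 0, 0.8, 2.1)) {
    H <- eval_diabatic(m, c(x, 0.2, -0.1))$hamiltonian
    expect_identical(H[1, 2], 0.4)
    expect_identical(H[2, 1], 0.4)
    H2 <- eval_diabatic(m, c(-x, 0, 0))$hamiltonian
    expect_equal(eval_diabatic(m, c(x, 0, 0))$hamiltonian[1, 1],
                 H2[2, 2], tolerance = 1e-12)
  }
  expect_error(eval_diabatic(m, c(NaN, 0, 0)), "finite")
})

test_that("all diabatic gradients match central finite differences", {
  set.seed(42)
  for (m in list(ac_model(0.4), ci_model())) {
    for (rep in 1:15) {
      p <- runif(3, -2.5, 2.5)
      ed <- eval_diabatic(m, p)
      h <- 1e-6
      for (ic in 1:3) {
        dp <- c(0, 0, 0); dp[ic] <- h
        Hp <- eval_diabatic(m, p + dp)$hamiltonian
        Hm <- eval_diabatic(m, p - dp)$hamiltonian
        expect_equal(ed$gradients[, , ic], (Hp - Hm) / (2 * h),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("adiabatization: energies, orthonormality, reconstruction", {
  m <- ac_model(0.4)
  # degenerate-diagonal point: V11 = V22 = 1, V12 = 0.4 at x = 0
  es <- adiabatize(m, c(0, 0, 0))
  expect_equal(es$energies, c(0.6, 1.4), tolerance = 1e-12)
  expect_equal(es$gap, 0.8, tolerance = 1e-12)

  set.seed(7)
  for (mm in list(ac_model(0.4), ci_model())) {
    for (rep in 1:100) {
      p <- runif(3, -3, 3)
      es <- adiabatize(mm, p)
      U <- es$transform
      expect_lt(max(abs(crossprod(U) - diag(2))), 1e-10)
      expect_true(es$energies[1] <= es$energies[2])
      H_rec <- U %*% diag(es$energies) %*% t(U)
      expect_lt(max(abs(H_rec - es$hamiltonian)), 1e-10)
      # deterministic sign convention
      for (j in 1:2) expect_gte(U[which.max(abs(U[, j])), j], 0)
    }
  }
})

test_that("adiabatic gradients match finite differences away from degeneracy", {
  set.seed(11)
  for (mm in list(ac_model(0.4), ci_model())) {
    n_ok <- 0
    for (rep in 1:25) {
      p <- runif(3, -2, 2)
      es <- adiabatize(mm, p)
      if (es$gap < 1e-3) next
      n_ok <- n_ok + 1
      h <- 1e-6
      for (ic in 1:3) {
        dp <- c(0, 0, 0); dp[ic] <- h
        ep <- adiabatize(mm, p + dp)$energies
        em <- adiabatize(mm, p - dp)$energies
        expect_equal(es$gradients[, ic], (ep - em) / (2 * h),
                     tolerance = 1e-5)
      }
    }
    expect_gt(n_ok, 10)
  }
})

test_that("transverse terms are invariant under diagonalization", {
  m <- ac_model(0.4)
  kp <- m$params$transverse_stiffness
  set.seed(3)
  for (rep in 1:20) {
    x <- runif(1, -2, 2); y <- runif(1, -1, 1); z <- runif(1, -1, 1)
    e_xyz <- adiabatize(m, c(x, y, z))$energies
    e_x00 <- adiabatize(m, c(x, 0, 0))$energies
    expect_equal(e_xyz - e_x00, rep(0.5 * kp * (y^2 + z^2), 2),
                 tolerance = 1e-10)
  }
})

test_that("minimum gap equals twice the diabatic coupling", {
  for (vc in c(0.02, 0.05, 0.1, 0.2, 0.4)) {
    g <- minimum_gap(ac_model(vc))
    expect_equal(g$gap, 2 * vc, tolerance = 1e-8)
  }
  expect_equal(minimum_gap(ac_model(0))$gap, 0, tolerance = 1e-12)
  expect_error(minimum_gap(ac_model(0.4), lower = c(1, 1), upper = c(0, 0)),
               "empty")
})

test_that("conical-intersection model is exactly degenerate at the marked point", {
  m <- ci_model()
  expect_lt(adiabatize(m, c(0, 0, 0))$gap, 1e-8)
  g <- minimum_gap(m)
  expect_lt(g$gap, 1e-8)
  # degeneracy fallback: gradients revert to the diabatic diagonal
  es <- adiabatize(m, c(0, 0, 0))
  ed <- eval_diabatic(m, c(0, 0, 0))
  expect_equal(es$gradients[1, ], ed$gradients[1, 1, ])
  expect_equal(es$gradients[2, ], ed$gradients[2, 2, ])
})

test_that("barrier analysis reproduces the lower-state barriers", {
  ba <- barrier_analysis(ac_model(0.4))
  expect_equal(ba$E_a, 0.64, tolerance = 0.005 / 0.64)
  expect_equal(ba$omega_barrier, sqrt(8), tolerance = 1e-3)
  expect_equal(ba$omega_well, sqrt(1.92), tolerance = 1e-3)
  expect_equal(unname(abs(ba$minima[, 1])), c(0.98, 0.98), tolerance = 1e-2)

  # uncoupled limit: barrier equals the diabatic crossing height
  ba0 <- barrier_analysis(ac_model(0))
  expect_equal(ba0$E_a, 1.0, tolerance = 5e-3)

  bci <- barrier_analysis(ci_model())
  expect_equal(bci$E_a, 0.64, tolerance = 0.005 / 0.64)
})

test_that("turnover friction estimate", {
  ba <- barrier_analysis(ac_model(0.4))
  g1 <- turnover_friction(ba$E_a, ba$omega_barrier, 0.64 / 3)
  expect_equal(g1, 0.94, tolerance = 0.01)
  # linear in temperature
  expect_equal(turnover_friction(ba$E_a, ba$omega_barrier, 2 * 0.64 / 3),
               2 * g1, tolerance = 1e-12)
  # the alternative high-friction estimate omega exceeds it when E_a > kB T
  expect_gt(ba$omega_barrier, g1)
})
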