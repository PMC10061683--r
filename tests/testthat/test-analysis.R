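test_that("transition extraction recovers a telegraph signal exactly", {
  # deterministic two-level telegraph with known switch times
  x <- c(rep(-1, 20), seq(-0.9, 0.9, by = 0.2), rep(1, 15),
         seq(0.9, -0.9, by = -0.2), rep(-1, 10),
         seq(-0.9, 0.9, by = 0.2), rep(1, 5))
  A <- region_spec("x", "<", -0.95, states = 1)
  B <- region_spec("x", ">", 0.95, states = 1)
  tr <- toy_trajectory(x)
  paths <- extract_transitions(tr, A, B)
  expect_identical(nrow(paths), 2L)
  # 10 intermediate snapshots + the first snapshot in B: duration 10 each
  expect_equal(paths$duration, c(10, 10))
  expect_equal(paths$n_hops, c(0, 0))
  # reverse direction: exactly one B -> A transition
  expect_identical(nrow(extract_transitions(tr, A, B, "BA")), 1L)
  # confined trajectory: no paths
  expect_identical(nrow(extract_transitions(toy_trajectory(rep(-1, 50)),
                                            A, B)), 0L)
})

test_that("path statistics use population spread and count accepted hops", {
  p1 <- tibble::tibble(duration = 2, n_hops = 0)
  s1 <- path_statistics(p1)
  expect_equal(s1$mean_time, 2)
  expect_equal(s1$std_time, 0)

  # frustrated hop events never enter the path hop counts
  x <- c(rep(-1, 5), 0, rep(1, 5))
  tr <- toy_trajectory(x)
  tr$hops <- tibble::tibble(step = c(5, 6), time = c(5, 6),
                            from = c(1L, 1L), to = c(2L, 2L),
                            frustrated = c(FALSE, TRUE))
  A <- region_spec("x", "<", -0.5, states = 1)
  B <- region_spec("x", ">", 0.5, states = 1)
  paths <- extract_transitions(tr, A, B)
  expect_equal(paths$n_hops, 1)   # only the accepted hop
})

test_that("arrhenius fits recover known parameters exactly on clean data", {
  Ts <- seq(0.1, 0.35, length.out = 6)
  d <- tibble::tibble(temperature = Ts, rate = 0.5 * exp(-0.7 / Ts),
                      rate_err = 0.01 * 0.5 * exp(-0.7 / Ts))
  f <- suppressWarnings(fit_arrhenius(d, "free"))  # noiseless: lm warns
  est <- setNames(f$params$estimate, f$params$term)
  expect_equal(est[["nu"]], 0.5, tolerance = 1e-6)
  expect_equal(est[["E_a_eff"]], 0.7, tolerance = 1e-6)

  ffix <- fit_arrhenius(d, "fixed", activation_energy = 0.7)
  expect_equal(ffix$params$estimate, 0.5, tolerance = 1e-6)
  expect_identical(ffix$tag, "arrhenius-fixed-Ea")
})

test_that("landau-zener fit recovers parameters and obeys the g = 0 limit", {
  g <- c(0.04, 0.1, 0.2, 0.4, 0.8)
  k0 <- 3.01e-3; z <- 135.72
  d <- tibble::tibble(gap = g, rate = k0 * (1 - exp(-z * g^2)),
                      rate_err = 0.02 * k0 * (1 - exp(-z * g^2)))
  f <- fit_landau_zener(d)
  est <- setNames(f$params$estimate, f$params$term)
  expect_equal(est[["k0"]], k0, tolerance = 1e-6)
  expect_equal(est[["z"]], z, tolerance = 1e-6)
  expect_equal(landau_zener_rate(f, 0), 0)
  expect_equal(landau_zener_rate(f, 1e3), est[["k0"]], tolerance = 1e-6)
})

test_that("fits are scale-equivariant", {
  Ts <- c(0.1, 0.15, 0.2, 0.3)
  d <- tibble::tibble(temperature = Ts,
                      rate = 0.21 * exp(-0.5 / Ts) * exp(rnorm(4, 0, 0.02)),
                      rate_err = 0.05 * 0.21 * exp(-0.5 / Ts))
  d10 <- d; d10$rate <- 10 * d$rate; d10$rate_err <- 10 * d$rate_err
  f1 <- fit_arrhenius(d, "free"); f2 <- fit_arrhenius(d10, "free")
  e1 <- setNames(f1$params$estimate, f1$params$term)
  e2 <- setNames(f2$params$estimate, f2$params$term)
  expect_equal(e2[["nu"]], 10 * e1[["nu"]], tolerance = 1e-10)
  expect_equal(e2[["E_a_eff"]], e1[["E_a_eff"]], tolerance = 1e-10)

  g <- c(0.05, 0.1, 0.2, 0.4)
  dl <- tibble::tibble(gap = g, rate = 2e-3 * (1 - exp(-100 * g^2)),
                       rate_err = 1e-4)
  dl10 <- dl; dl10$rate <- 10 * dl$rate; dl10$rate_err <- 10 * dl$rate_err
  l1 <- fit_landau_zener(dl); l2 <- fit_landau_zener(dl10)
  expect_equal(l2$params$estimate[2], l1$params$estimate[2],
               tolerance = 1e-8)
  expect_equal(l2$params$estimate[1], 10 * l1$params$estimate[1],
               tolerance = 1e-8)
})

test_that("tidy and glance expose the fit in broom style", {
  d <- tibble::tibble(temperature = c(0.1, 0.2, 0.3),
                      rate = 0.5 * exp(-0.7 / c(0.1, 0.2, 0.3)))
  f <- suppressWarnings(fit_arrhenius(d, "free"))
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std_error", "conf_low",
                    "conf_high") %in% names(td)))
  gl <- glance(f)
  expect_identical(gl$tag, "arrhenius-free")
  expect_identical(gl$n, 3L)
})

test_that("hop-class decomposition partitions the rate", {
  paths <- tibble::tibble(duration = rep(1, 10),
                          n_hops = c(0, 0, 0, 0, 2, 2, 2, 4, 4, 6))
  hc <- hop_class_rates(paths, k_AB = 5e-3)
  expect_equal(sum(hc$rate), 5e-3, tolerance = 1e-15)
  expect_equal(hc$rate[hc$n_hops_class == 0], 5e-3 * 0.4)

  hopless <- hop_class_rates(tibble::tibble(duration = 1:4,
                                            n_hops = rep(0, 4)), 2e-3)
  expect_identical(nrow(hopless), 1L)
  expect_equal(hopless$rate, 2e-3)
})

test_that("re-extracting an extracted path is the identity", {
  m <- ac_model(0.4)
  th <- ac_thermo(61, 62)
  rg <- ac_regions(0.5)
  tr <- run_tsh(m, snapshot(c(-0.98, 0, 0)), th, 3e5)
  paths <- extract_transitions(tr, rg$A, rg$B)
  expect_gt(nrow(paths), 0)
  p <- paths[1, ]
  # sub-trajectory spanning the path plus its bracketing region snapshots
  sub <- tr
  keep <- (p$i_start - 1):p$i_end
  sub$snapshots <- tr$snapshots[keep, ]
  again <- extract_transitions(sub, rg$A, rg$B)
  expect_identical(nrow(again), 1L)
  expect_equal(again$duration, p$duration)
  expect_equal(again$n_hops, p$n_hops)
})
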