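test_that("shell resistance matches the quadrature oracle and its scalings", {
  expect_equal(shell_resistance(1, 2, 1), quadrature_resistance(1, 2, 1),
               tolerance = 1e-10)

  set.seed(11)
  for (i in 1:25) {
    r_in <- runif(1, 0.01, 5)
    r_out <- r_in + runif(1, 0, 5)
    D <- 10^runif(1, -6, 2)
    expect_equal(shell_resistance(r_in, r_out, D),
                 quadrature_resistance(r_in, r_out, D),
                 tolerance = 1e-8)
  }

  # zero-thickness shell carries no resistance
  expect_identical(shell_resistance(5, 5, 1), 0)
  # linear in 1/D
  expect_equal(shell_resistance(1, 2, 2), shell_resistance(1, 2, 1) / 2)
})

test_that("shell resistance rejects bad inputs by name", {
  expect_error(shell_resistance(-1, 2, 1), "r_in")
  expect_error(shell_resistance(1, 0.5, 1), "r_out")
  expect_error(shell_resistance(1, 2, 0), "D")
})

test_that("composite sphere enforces its geometric invariants", {
  sp <- composite_sphere(r2 = 2, t = 0.5, D1 = 1, D2 = 1)
  expect_identical(sp$r3, sp$r2 + sp$t)
  expect_identical(sp$r1, 1)  # default r2/2
  expect_error(composite_sphere(r2 = 2, t = 0.5, D1 = 1, D2 = 1, r1 = 2.5),
               "r1")
  expect_error(composite_sphere(r2 = 2, t = -0.1, D1 = 1, D2 = 1), "t")
  expect_error(composite_sphere(r2 = 2, t = 0.1, D1 = -1, D2 = 1), "D1")
  expect_error(composite_sphere(r2 = 2, t = 0.1, D1 = 1, D2 = 1, K = 0), "K")
})

test_that("total resistance splits into independently verified parts", {
  sp <- composite_sphere(r2 = 2, t = 1, D1 = 0.5, D2 = 0.25, K = 1, r1 = 1)
  rb <- total_resistance(sp)
  expect_equal(rb$R_a, quadrature_resistance(1, 2, 0.5), tolerance = 1e-8)
  expect_equal(rb$R_b, quadrature_resistance(2, 3, 0.25), tolerance = 1e-8)
  expect_equal(rb$R_T, rb$R_a + rb$R_b)
  expect_false(rb$core_blocked)

  # partition coefficient scales the shell term as an effective diffusivity
  spK <- composite_sphere(r2 = 2, t = 1, D1 = 0.5, D2 = 0.25, K = 0.1,
                          r1 = 1)
  expect_equal(total_resistance(spK)$R_b,
               quadrature_resistance(2, 3, 0.1 * 0.25), tolerance = 1e-8)

  # no shell, no shell resistance
  rb0 <- total_resistance(composite_sphere(r2 = 2, t = 0, D1 = 1, D2 = 1))
  expect_identical(rb0$R_b, 0)
  expect_identical(rb0$R_T, rb0$R_a)

  # blocked core is flagged, not an error
  rbb <- total_resistance(composite_sphere(r2 = 2, t = 1, D1 = 0, D2 = 1))
  expect_true(rbb$core_blocked)
  expect_identical(rbb$R_a, Inf)
})

test_that("mass-transfer rate follows the driving force over the resistance", {
  sp <- composite_sphere(r2 = 2, t = 1, D1 = 0.5, D2 = 0.25, K = 1, r1 = 1)
  rb <- total_resistance(sp)

  expect_identical(mass_transfer_rate(driving_force(3, 3), rb), 0)
  expect_equal(mass_transfer_rate(driving_force(5, 2), rb), 3 / rb$R_T)
  # cross-check the composed value against quadrature oracles
  R_oracle <- quadrature_resistance(1, 2, 0.5) +
    quadrature_resistance(2, 3, 0.25)
  expect_equal(mass_transfer_rate(driving_force(5, 2), rb), 3 / R_oracle,
               tolerance = 1e-8)
  # sign follows the concentration difference
  expect_lt(mass_transfer_rate(driving_force(1, 2), rb), 0)

  # blocked transport
  rb_inf <- total_resistance(composite_sphere(r2 = 2, t = 1, D1 = 0, D2 = 1))
  expect_identical(mass_transfer_rate(driving_force(5, 0), rb_inf), 0)

  # degenerate zero-resistance geometry
  rb0 <- structure(list(R_a = 0, R_b = 0, R_T = 0, core_blocked = FALSE),
                   class = "resistance_breakdown")
  expect_error(mass_transfer_rate(driving_force(1, 0), rb0), "degenerate")
})

test_that("retardation ratio hits its exact limits and the quadrature value", {
  # no coating: exactly 1, not within floating point of 1
  expect_identical(retardation_ratio(
    composite_sphere(r2 = 7, t = 0, D1 = 3, D2 = 2, K = 0.5)), 1)
  # capsule limit: all resistance on the core side, exactly 1
  expect_identical(retardation_ratio(
    composite_sphere(r2 = 7, t = 2, D1 = 0, D2 = 2, K = 0.5)), 1)

  # nanoparticle-scale geometry against quadrature-composed resistances
  sp <- composite_sphere(r2 = 0.2, t = 0.02, D1 = 1, D2 = 1, K = 1,
                         r1 = 0.1)
  Ra <- quadrature_resistance(0.1, 0.2, 1)
  Rb <- quadrature_resistance(0.2, 0.22, 1)
  expect_equal(retardation_ratio(sp), Ra / (Ra + Rb), tolerance = 1e-8)
})

test_that("retardation ratio lies in (0,1] and is monotone in t, D2, K", {
  set.seed(23)
  for (i in 1:30) {
    r2 <- runif(1, 0.1, 10)
    sp <- composite_sphere(r2 = r2, t = runif(1, 1e-4, r2),
                           D1 = 10^runif(1, -3, 1), D2 = 10^runif(1, -3, 1),
                           K = 10^runif(1, -2, 1), r1 = runif(1, 0.1, 0.9) * r2)
    rr <- retardation_ratio(sp)
    expect_gt(rr, 0)
    expect_lt(rr, 1)  # t > 0 and D1 > 0 here, so strictly below 1

    thicker <- composite_sphere(r2 = sp$r2, t = sp$t * 2, D1 = sp$D1,
                                D2 = sp$D2, K = sp$K, r1 = sp$r1)
    expect_lt(retardation_ratio(thicker), rr)
    faster_shell <- composite_sphere(r2 = sp$r2, t = sp$t, D1 = sp$D1,
                                     D2 = sp$D2 * 3, K = sp$K, r1 = sp$r1)
    expect_gt(retardation_ratio(faster_shell), rr)
    more_partition <- composite_sphere(r2 = sp$r2, t = sp$t, D1 = sp$D1,
                                       D2 = sp$D2, K = sp$K * 3, r1 = sp$r1)
    expect_gt(retardation_ratio(more_partition), rr)
  }
})

test_that("size sweep is monotone, approaches 1, and handles edge cases", {
  base <- nano_sphere()
  sw <- size_sweep(base, r2_values = c(5, 0.33, 1, 60, 160, 0.165))
  expect_equal(sw$r2, sort(sw$r2))
  expect_true(all(diff(sw$ratio) >= 0))
  expect_true(all(sw$ratio > 0 & sw$ratio <= 1))

  # large-size limit of the pure-diffusivity form (K*D2 = D1): within
  # 1e-3 of 1 once r2/t reaches 1e4
  pure <- composite_sphere(r2 = 1, t = 0.02, D1 = 1, D2 = 1, K = 1)
  big <- size_sweep(pure, r2_values = 1e4 * pure$t)
  expect_lt(1 - big$ratio, 1e-3)

  # no coating anywhere: identically 1
  bare <- composite_sphere(r2 = 1, t = 0, D1 = 1, D2 = 1)
  expect_true(all(size_sweep(bare, c(1, 2, 3))$ratio == 1))

  empty <- size_sweep(base, numeric(0))
  expect_identical(nrow(empty), 0L)
  expect_named(attr(empty, "params"),
               c("r1_fraction", "t", "D1", "D2", "K"))

  expect_error(size_sweep(base, c(1, 2), r1_fraction = 1.2), "r1_fraction")
})

test_that("size sweep round-trips through CSV with its JSON sidecar", {
  sw <- size_sweep(nano_sphere(), c(0.33, 2, 60))
  csv <- tempfile(fileext = ".csv")
  sidecar <- write_size_sweep(sw, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$ratio, sw$ratio)
  params <- jsonlite::read_json(sidecar)
  expect_equal(params$t, sw |> attr("params") |> getElement("t"))
  expect_named(params, c("r1_fraction", "t", "D1", "D2", "K"))
  unlink(c(csv, sidecar))
})
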