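test_that("cumulative release equals the brute-force sampling ledger", {
  # single point: just what the vessel holds
  pr1 <- sampling_protocol(1, 0.1, times = 5)
  expect_equal(cumulative_mass_released(3, pr1), 3)

  pr <- sampling_protocol(1, 0.2, times = c(1, 2, 3))
  expect_equal(cumulative_mass_released(c(0, 0, 0), pr), c(0, 0, 0))

  conc <- c(4, 3.5, 5)
  expect_equal(cumulative_mass_released(conc, pr),
               simulate_sampling_ledger(conc, 1, 0.2))

  # property: agreement for random schedules, volumes and concentrations
  set.seed(97)
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    V <- runif(1, 0.5, 10)
    a <- runif(1, 0.01, 1) * V
    conc_i <- runif(n, 0, 50)
    pr_i <- sampling_protocol(V, a, times = seq_len(n))
    expect_equal(cumulative_mass_released(conc_i, pr_i),
                 simulate_sampling_ledger(conc_i, V, a))
  }

  expect_error(cumulative_mass_released(c(1, -2, 3), pr), "egative")
  expect_error(cumulative_mass_released(c(1, 2), pr), "per scheduled time")
  # disabling the correction drops the aliquot make-up term
  expect_equal(cumulative_mass_released(conc, pr, correct = FALSE),
               1 * conc)
})

test_that("sampling protocol validates volumes and schedule", {
  expect_error(sampling_protocol(1, 1.5, 1), "V_aliquot")
  expect_error(sampling_protocol(1, 0.5, c(2, 1)), "increasing")
})

test_that("percent release reproduces the printed worked example", {
  expect_equal(percent_release(20, 100), 20)
  expect_equal(render_percent(percent_release(5, 85)), 5.9)
  expect_equal(percent_release(0, 42), 0)
  expect_error(percent_release(1, 0), "zero")
})

test_that("loading and encapsulation efficiency are plain mass ratios", {
  ct <- drug_content(mass_drug = 7.6, mass_particles = 100,
                     theoretical_mass = 11.2)
  expect_equal(drug_loading(ct), 100 * 7.6 / 100)
  expect_equal(encapsulation_efficiency(ct), 100 * 7.6 / 11.2)

  expect_equal(drug_loading(drug_content(0, 50, 10)), 0)
  expect_equal(drug_loading(drug_content(5, 5, 10)), 100)
  expect_equal(encapsulation_efficiency(drug_content(10, 50, 10)), 100)

  expect_error(drug_loading(drug_content(1, 0, 2)), "zero")
  expect_error(encapsulation_efficiency(drug_content(0, 1, 0)), "zero")
  expect_warning(drug_content(12, 100, 10), "exceeds")
})

test_that("percent arithmetic is invariant to the mass unit", {
  set.seed(5)
  for (i in 1:50) {
    m <- runif(2, 0.1, 100)  # released, content
    s <- 10^runif(1, -3, 3)
    expect_equal(percent_release(m[1], m[2]),
                 percent_release(s * m[1], s * m[2]))
    ct1 <- drug_content(m[1], m[2], m[1] + m[2])
    ct2 <- drug_content(s * m[1], s * m[2], s * (m[1] + m[2]))
    expect_equal(drug_loading(ct1), drug_loading(ct2))
    expect_equal(encapsulation_efficiency(ct1),
                 encapsulation_efficiency(ct2))
  }
})

test_that("loss summary reports per-step percents and the pH signature", {
  # at pH 9 the first wash loses far less than the first adsorption
  run9 <- coating_run("PAH/PSS @ pH 9",
                      data.frame(layer = c(1, 1),
                                 step = c("adsorption", "wash"),
                                 loss_mass = c(2.4, 0.2)),
                      content_basis = 100)
  s9 <- loss_summary(run9)
  expect_equal(s9$per_step$percent, c(2.4, 0.2))
  expect_false(s9$wash_exceeds_adsorption)
  expect_equal(s9$total_percent, 2.6)
  expect_equal(render_percent(s9$per_step$percent), c(2.4, 0.2))

  # at pH 4 the wash loss exceeds the adsorption loss
  run4 <- coating_run("PAH/PSS @ pH 4",
                      data.frame(layer = c(1, 1),
                                 step = c("adsorption", "wash"),
                                 loss_mass = c(1.4, 1.9)),
                      content_basis = 100)
  s4 <- loss_summary(run4)
  expect_true(s4$wash_exceeds_adsorption)
  expect_equal(render_percent(s4$per_step$percent), c(1.4, 1.9))

  # single zero-loss step
  run0 <- coating_run("control",
                      data.frame(layer = 1, step = "wash", loss_mass = 0),
                      content_basis = 50)
  expect_equal(loss_summary(run0)$total_percent, 0)
  expect_true(is.na(loss_summary(run0)$wash_exceeds_adsorption))

  # empty runs summarise to empty, not an error
  rune <- coating_run("empty",
                      data.frame(layer = integer(0), step = character(0),
                                 loss_mass = numeric(0)),
                      content_basis = 100)
  se <- loss_summary(rune)
  expect_identical(nrow(se$per_step), 0L)
  expect_length(se$total_percent, 0)

  # per-layer totals aggregate the steps
  run2 <- coating_run("x", data.frame(layer = c(1, 1, 2, 2),
                                      step = rep(c("adsorption", "wash"), 2),
                                      loss_mass = c(2, 1, 1, 0.5)),
                      content_basis = 200)
  expect_equal(loss_summary(run2)$per_layer$percent, c(1.5, 0.75))

  expect_error(coating_run("bad", data.frame(layer = 1, step = "rinse",
                                             loss_mass = 1), 100), "step")
  expect_error(coating_run("bad", data.frame(layer = c(2, 1),
                                             step = c("wash", "wash"),
                                             loss_mass = c(1, 1)), 100),
               "non-decreasing")
})

test_that("mean total loss reproduces the six-condition average", {
  expect_equal(render_percent(mean_total_loss(c(8.0, 5.4, 6.8, 3.7, 5.0,
                                                3.7))), 5.4)
  expect_equal(mean_total_loss(4.2), 4.2)
  expect_equal(mean_total_loss(rep(7.3, 5)), 7.3)
  expect_error(mean_total_loss(numeric(0)), "no totals")
})

test_that("loss adjustment turns 5 of 100 into 5.9% of the 85 that remain", {
  # the cautionary arithmetic end-to-end: 20 ug of 100 ug registers 20%;
  # after losing 15 ug, releasing 5 ug registers 5.9% of the 85 ug left
  expect_equal(percent_release(20, 100), 20)
  adjusted <- loss_adjusted_release(percent_release(5, 100), 15)
  expect_equal(render_percent(adjusted), 5.9)
  expect_equal(adjusted, percent_release(5, 85))

  # zero loss changes nothing
  expect_equal(loss_adjusted_release(12.5, 0), 12.5)

  # property: always agrees with the explicit mass ledger
  set.seed(31)
  for (i in 1:100) {
    content <- runif(1, 10, 500)
    loss <- runif(1, 0, 0.9) * 100
    released <- runif(1, 0, content * (1 - loss / 100))
    ledger <- 100 * released / (content - content * loss / 100)
    expect_equal(
      loss_adjusted_release(percent_release(released, content), loss),
      ledger
    )
  }

  expect_error(loss_adjusted_release(5, 100), "100%")
})
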