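test_that("integration matches the closed-form exponential decay", {
  net <- toy_model("decay1")
  grid <- time_grid(600, 50)
  traj <- simulate(net, grid)
  expect_equal(series(traj, "A"), 100 * exp(-0.01 * grid),
               tolerance = 1e-6)
})

test_that("conservation holds along trajectories and integration is deterministic", {
  net <- toy_model("chain2")
  grid <- time_grid(1000, 100)
  t1 <- simulate(net, grid)
  expect_equal(colSums(t1$values), rep(100, length(grid)),
               tolerance = 1e-8)
  t2 <- simulate(net, grid)
  expect_identical(t1$values, t2$values)
})

test_that("summaries implement peak, earliest-argmax and trapezoid area", {
  grid <- seq(0, 100, by = 10)
  traj <- structure(list(grid = grid,
                         values = matrix(5, 1, length(grid),
                                         dimnames = list("X", NULL)),
                         species = "X"), class = "trajectory")
  s <- summarize(traj, "X")
  expect_equal(s$peak_amplitude, 5)
  expect_equal(s$peak_time, 0)
  expect_equal(s$integrated_response, 500)

  traj$values[1, ] <- seq(0, 10, length.out = length(grid))
  s <- summarize(traj, "X")
  expect_equal(s$integrated_response, 500)
  expect_equal(s$peak_time, 100)

  ## two equal maxima: the earlier time wins
  traj$values[1, ] <- c(0, 3, 7, 3, 7, 3, 0, 0, 0, 0, 0)
  expect_equal(summarize(traj, "X")$peak_time, 20)
})

test_that("killing-rate normalisation is proportional and scale-invariant", {
  kp <- killing_panel(c(A = 200, B = 100))
  expect_equal(unname(kp$rates), c(95, 47.5))
  expect_equal(kp$argmax, "A")
  expect_equal(killing_panel(c(A = 3, B = 3))$rates,
               c(A = 95, B = 95))
  k1 <- killing_panel(c(A = 200, B = 100, C = 40))
  k2 <- killing_panel(c(A = 200, B = 100, C = 40) * 17.3)
  expect_equal(k1$rates, k2$rates)
  expect_error(killing_panel(c(A = 0, B = 0)), "zero")
})

test_that("halving integrator tolerances barely moves the response summaries", {
  net <- apply_condition(the_complement(),
                         condition(initiation = "PC", pH = 6.5,
                                   calcium = 2.0, crp_scale = 10),
                         the_affinity())
  grid <- time_grid(7200, 100)
  s1 <- summarize(simulate(net, grid, rtol = 1e-8, atol = 1e-12,
                           check_conservation = FALSE), "C3_dep", net)
  s2 <- summarize(simulate(net, grid, rtol = 5e-9, atol = 5e-13,
                           check_conservation = FALSE), "C3_dep", net)
  expect_lt(abs(s1$peak_amplitude - s2$peak_amplitude) /
              s2$peak_amplitude, 1e-3)
  expect_lt(abs(s1$integrated_response - s2$integrated_response) /
              s2$integrated_response, 1e-3)
})

test_that("a complement run without initiating ligands deposits no C3", {
  net <- the_complement()
  net$species$init[match(c("PC", "GlcNAc"), net$species$name)] <- 0
  traj <- simulate(net, time_grid(3600, 400), check_conservation = FALSE)
  expect_equal(max(series(traj, "C3_dep", net)), 0)
})

test_that("the vectorised ensemble integrator agrees with lsoda", {
  net <- toy_model("cascade3")
  grid <- time_grid(1800, 100)
  ref <- simulate(net, grid)
  out <- ensemble_simulate(net, matrix(initial_state(net), 1, 3,
                                       dimnames = list(NULL,
                                                       net$species$name)),
                           param_values(net), grid, substeps = 10)
  expect_equal(out$values[1, , ], unname(ref$values), tolerance = 1e-6)
  expect_false(any(out$failed))
})
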