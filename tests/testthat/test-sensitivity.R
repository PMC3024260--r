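test_that("local scaled sensitivity recovers analytic slopes", {
  ## A -> B: the whole-trajectory response of B scales linearly with A(0),
  ## so the scaled coefficient is 1 for both summaries
  net <- toy_model("chain2")
  out <- local_scaled_sensitivity(net, inputs = "A", output = "B",
                                  delta = 0.01, grid = time_grid(600, 100))
  expect_equal(out$coefficient, c(1, 1), tolerance = 1e-6)

  ## an input disconnected from the output path has coefficient 0
  net2 <- build_network(
    species = data.frame(name = c("A", "B", "Z"), role = "fluid-phase",
                         init = c(100, 0, 50)),
    reactions = list(
      reaction("r1", "A", "B", rate_law("mass_action", k = "k1")),
      reaction("r2", "Z", character(), rate_law("mass_action", k = "k2"))),
    params = data.frame(name = c("k1", "k2"), value = c(0.01, 0.01),
                        lo = 0.001, hi = 0.1, known = TRUE))
  out <- local_scaled_sensitivity(net2, inputs = "Z", output = "B",
                                  grid = time_grid(600, 100))
  expect_equal(out$coefficient, c(0, 0))

  ## a squared response has log-log slope 2 (up to O(delta^2))
  net3 <- build_network(
    species = data.frame(name = c("A", "P"), role = "fluid-phase",
                         init = c(10, 0)),
    reactions = list(
      reaction("r1", c("A", "A"), c("A", "A", "P"),
               rate_law("mass_action", k = "k1"))),
    params = data.frame(name = "k1", value = 1e-4, lo = 0, hi = 1,
                        known = TRUE))
  out <- local_scaled_sensitivity(net3, inputs = "A", output = "P",
                                  delta = 0.01, grid = time_grid(100, 10))
  expect_equal(out$coefficient, c(2, 2), tolerance = 1e-3)
})

test_that("MPSA: dominance case, null dummy, range and reproducibility", {
  net <- cascade3_with_dummy()
  grid <- time_grid(1800, 300)
  dbn <- build_dbn(net, J = 4000, grid = grid, seed = 21, substeps = 15)
  truth <- param_values(net)[!net$params$known]
  ds <- generate_dataset(net, truth, conditions = list(base = NULL),
                         sample_times = grid,
                         noise = noise_model(cv = 0.05), seed = 7,
                         normalise = FALSE)
  res <- mpsa(dbn, ds, n_samples = 500, seed = 13)
  expect_true(all(res$ks >= 0 & res$ks <= 1))
  expect_equal(attr(res, "n_good") + attr(res, "n_bad"), 500)

  ## the parameter entering no equation stays at the sampling-noise floor
  expect_lte(res$ks[res$parameter == "k_dummy"], 0.15)
  ## the dynamical parameters dominate the dummy
  expect_gt(max(res$ks[res$parameter != "k_dummy"]),
            res$ks[res$parameter == "k_dummy"])

  res2 <- mpsa(dbn, ds, n_samples = 500, seed = 13)
  expect_identical(res$ks, res2$ks)

  ## a constructed dominance case: observe only A, whose dynamics depend
  ## only on k1 and k3 -> the top-ranked parameter is one of them
  dsA <- ds
  dsA$observations <- dsA$observations[dsA$observations$species == "A", ]
  resA <- mpsa(dbn, dsA, n_samples = 500, seed = 17)
  expect_true(resA$parameter[which.max(resA$ks)] %in% c("k1", "k3"))
})
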