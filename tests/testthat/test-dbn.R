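test_that("parent structure follows the right-hand-side dependency rule", {
  st <- derive_structure(toy_model("decay1"))
  expect_setequal(st$parents$A, c("A", "k1"))
  expect_identical(st$parents$k1, "k1")

  st <- derive_structure(toy_model("chain2"))
  expect_setequal(st$parents$B, c("A", "B", "k1"))

  net <- the_complement()
  st <- derive_structure(net)
  for (p in st$param_nodes)
    expect_identical(st$parents[[p]], p)
  expect_gte(st$u_max, 1)
})

test_that("the coverage heuristic is K * I^u with an overflow guard", {
  expect_equal(required_samples(5, 3, 5), 625)
  expect_equal(required_samples(5, 0, 7), 7)
  expect_error(required_samples(5, 15, 5), "cap")
  expect_equal(required_samples(5, 15, 5, override = TRUE), 5 * 5^15)
})

test_that("discretisation: equal-width parameters, quantile variables, degeneracy", {
  net <- toy_model("decay1")
  net$params$lo <- 0; net$params$hi <- 10
  pil <- list(values = array(runif(1 * 1 * 500), c(1, 1, 500)),
              species = "A")
  d <- make_discretization(net, pil, n_var = 6, n_param = 5)
  expect_equal(d$k1$boundaries, seq(0, 10, by = 2))

  set.seed(3)
  pil$values <- array(runif(4000), c(1, 1, 4000))
  d <- make_discretization(net, pil, n_var = 6)
  expect_equal(d$A$boundaries[2:6], (1:5) / 6, tolerance = 0.05)

  pil$values <- array(0, c(1, 1, 100))
  d <- make_discretization(net, pil, n_var = 6)
  expect_true(d$A$degenerate)
  expect_equal(compdbn:::n_intervals(d, "A"), 1L)
})

test_that("sampled ensembles are seeded, prior-respecting and codable", {
  net <- toy_model("decay1")
  grid <- time_grid(400, 50)
  pr <- default_prior(net)
  pil <- pilot_ensemble(net, pr, J = 100, grid = grid, seed = 4)
  d <- make_discretization(net, pil)
  e1 <- sample_trajectories(net, pr, d, J = 100, grid = grid, seed = 9)
  e2 <- sample_trajectories(net, pr, d, J = 100, grid = grid, seed = 9)
  expect_identical(e1$codes, e2$codes)
  expect_identical(e1$param_codes, e2$param_codes)
  expect_true(all(as.integer(e1$codes) >= 1 & as.integer(e1$codes) <= 6))

  ## a point prior produces identical trajectories and constant codes
  pr$k1 <- list(type = "point", value = 0.01)
  e3 <- sample_trajectories(net, pr, d, J = 50, grid = grid, seed = 2)
  for (ti in seq_along(grid))
    expect_equal(length(unique(as.integer(e3$codes[, 1, ti]))), 1)
})

test_that("counted CPT rows are normalised; deterministic dynamics give point masses", {
  net <- toy_model("decay1")
  grid <- time_grid(400, 50)
  pr <- default_prior(net)
  pr$k1 <- list(type = "point", value = 0.01)
  dbn <- build_dbn(net, pr, J = 500, grid = grid, seed = 6)
  for (sl in dbn$cpts$A$slices) {
    expect_equal(rowSums(sl$cpt), rep(1, nrow(sl$cpt)), tolerance = 1e-9)
    ## single initial interval, fixed parameter: every row is deterministic
    expect_true(all(apply(sl$cpt, 1, max) == 1))
  }
})

test_that("DBN serialisation round-trips the CPTs exactly", {
  net <- toy_model("chain2")
  dbn <- build_dbn(net, J = 300, grid = time_grid(300, 50), seed = 3)
  path <- tempfile(fileext = ".json")
  write_dbn(dbn, path)
  back <- read_dbn(path)
  for (nd in dbn$species_nodes) {
    for (t in seq_along(dbn$cpts[[nd]]$slices)) {
      expect_equal(back$cpts[[nd]]$slices[[t]]$cpt,
                   dbn$cpts[[nd]]$slices[[t]]$cpt)
      expect_equal(back$cpts[[nd]]$slices[[t]]$support,
                   dbn$cpts[[nd]]$slices[[t]]$support)
    }
  }
  expect_equal(back$disc$A$boundaries, dbn$disc$A$boundaries)
  unlink(path)
})
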