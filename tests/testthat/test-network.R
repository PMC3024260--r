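test_that("a toy specification builds and validates", {
  sp <- toy_spec_ab()
  net <- build_network(sp$species, sp$reactions, sp$params)
  expect_s3_class(net, "reaction_network")
  expect_equal(nrow(net$species), 2)
  expect_equal(length(net$reactions), 1)

  bad <- sp
  bad$reactions <- list(reaction("r1", "A", "Z",
                                 rate_law("mass_action", k = "k")))
  expect_error(build_network(bad$species, bad$reactions, bad$params),
               "unknown species")
  bad <- sp
  bad$params$value <- -1
  expect_error(build_network(bad$species, bad$reactions, bad$params),
               "negative rate constant")
  bad <- sp
  bad$reactions <- c(sp$reactions, sp$reactions)
  expect_error(build_network(bad$species, bad$reactions, bad$params),
               "duplicate reaction id")
  expect_warning(build_network(sp$species, sp$reactions, sp$params,
                               expect = list(species = 3)),
                 "counts differ")
})

test_that("mass-action and Michaelis-Menten right-hand sides are correct", {
  ## A + B -> C at k = 2 with A = 3, B = 4: rate 24
  net <- build_network(
    species = data.frame(name = c("A", "B", "C"), role = "fluid-phase",
                         init = c(3, 4, 0)),
    reactions = list(reaction("r1", c("A", "B"), "C",
                              rate_law("mass_action", k = "k"))),
    params = data.frame(name = "k", value = 2, lo = 0, hi = 10,
                        known = TRUE))
  dx <- ode_rhs(net)(0, initial_state(net), param_values(net))[[1]]
  expect_equal(dx, c(-24, -24, 24))

  ## zero reactant concentration silences the reaction
  dx0 <- ode_rhs(net)(0, c(A = 0, B = 4, C = 0), param_values(net))[[1]]
  expect_equal(dx0, c(0, 0, 0))

  ## enzyme cleavage: c = 3, c_half = 4, E = 2, S = 4 -> dS/dt = -3
  mm <- build_network(
    species = data.frame(name = c("E", "S", "P"), role = "fluid-phase",
                         init = c(2, 4, 0)),
    reactions = list(reaction("r1", "S", "P",
                              rate_law("michaelis_menten", c = "c",
                                       c_half = "ch"),
                              modifiers = "E")),
    params = data.frame(name = c("c", "ch"), value = c(3, 4),
                        lo = 0, hi = 10, known = TRUE))
  dx <- ode_rhs(mm)(0, initial_state(mm), param_values(mm))[[1]]
  expect_equal(dx, c(0, -3, 3))
})

test_that("rate evaluation is non-negative for non-negative states", {
  net <- toy_model("cascade3")
  rhs <- ode_rhs(net)
  set.seed(42)
  for (i in 1:20) {
    x <- setNames(runif(3, 0, 200), net$species$name)
    dx <- rhs(0, x, param_values(net))[[1]]
    ## derivative of a species can be negative, but only through reactions
    ## consuming it: a species at zero cannot decrease
    x0 <- x; x0[i %% 3 + 1] <- 0
    dx0 <- rhs(0, x0, param_values(net))[[1]]
    expect_gte(dx0[i %% 3 + 1], 0)
  }
})

test_that("unresolved unknown parameters are rejected", {
  sp <- toy_spec_ab()
  sp$params$value <- NA_real_
  net <- build_network(sp$species, sp$reactions, sp$params)
  expect_error(param_values(net), "unresolved UNKNOWN")
  expect_error(simulate(net, time_grid(10, 5)), "unresolved UNKNOWN")
})

test_that("conservation groups of every shipped model close analytically", {
  for (nm in c("chain2", "mm2")) {
    net <- toy_model(nm)
    res <- conservation_residual(net)
    expect_true(all(abs(res) < 1e-12))
  }
  net <- the_complement()
  set.seed(7)
  x <- setNames(runif(42, 0, 100), net$species$name)
  res <- conservation_residual(net, x = x)
  expect_true(all(abs(res) < 1e-9 * max(abs(x))))
})
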