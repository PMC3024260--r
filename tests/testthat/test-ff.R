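test_that("the t = 0 marginals equal the prior", {
  dbn <- random_small_dbn(1)
  marg <- ff_forward(dbn)
  for (nd in dbn$species_nodes)
    expect_equal(marg$marginals[[nd]][, 1], dbn$prior[[nd]]$probs,
                 tolerance = 1e-12)
})

test_that("a self-parent-only node reduces to a Markov chain (matrix-power oracle)", {
  dbn <- random_small_dbn(2, n_nodes = 1, m = 4, n_steps = 5)
  marg <- ff_forward(dbn)
  p <- dbn$prior$A$probs
  for (t in seq_len(5)) {
    P <- dbn$cpts$A$slices[[t]]$cpt  # rows indexed by own interval
    p <- drop(p %*% P)
    expect_equal(marg$marginals$A[, t + 1], p, tolerance = 1e-12)
  }
})

test_that("marginals stay normalised at machine precision at every step", {
  dbn <- random_small_dbn(3)
  marg <- ff_forward(dbn)
  for (nd in dbn$species_nodes)
    expect_equal(colSums(marg$marginals[[nd]]),
                 rep(1, length(dbn$grid)), tolerance = 1e-12)
})

test_that("factored frontier tracks exact enumeration on small DBNs", {
  worst <- 0
  for (seed in 1:20) {
    dbn <- random_small_dbn(seed)
    ff <- ff_forward(dbn)
    ex <- exact_marginals(dbn)
    for (nd in dbn$species_nodes) {
      l1 <- max(colSums(abs(ff$marginals[[nd]] - ex[[nd]])))
      worst <- max(worst, l1)
    }
  }
  expect_lt(worst, 0.05)

  ## with fully deterministic CPTs the product approximation is exact
  for (seed in 1:5) {
    dbn <- random_small_dbn(seed + 100, deterministic = TRUE)
    ff <- ff_forward(dbn)
    ex <- exact_marginals(dbn)
    for (nd in dbn$species_nodes)
      expect_equal(ff$marginals[[nd]], ex[[nd]], tolerance = 1e-12)
  }
})

test_that("contradictory evidence fails loudly, naming the node and time", {
  dbn <- random_small_dbn(4, n_nodes = 1)
  dbn$prior$A$probs <- c(1, 0, 0, 0)
  expect_error(ff_forward(dbn, list(ff_evidence("A", 0, interval = 3L))),
               "contradictory evidence.*A")
})

test_that("a clamped parameter node stays clamped forever", {
  net <- toy_model("decay1")
  dbn <- build_dbn(net, J = 400, grid = time_grid(300, 50), seed = 5)
  marg <- ff_forward(dbn, list(ff_evidence("k1", 0, interval = 4L)))
  expect_true(all(abs(marg$marginals$k1[4, ] - 1) < 1e-12))
})

test_that("expected values use interval midpoints", {
  dbn <- random_small_dbn(5, n_nodes = 1, m = 2, n_steps = 1)
  dbn$disc$A$boundaries <- c(2, 4, 6)
  dbn$prior$A <- list(type = "interval", probs = c(1, 0),
                      boundaries = dbn$disc$A$boundaries)
  marg <- ff_forward(dbn)
  expect_equal(expected_series(marg, "A")[1], 3)
  dbn$prior$A$probs <- c(0.5, 0.5)
  marg <- ff_forward(dbn)
  expect_equal(expected_series(marg, "A")[1], 4)
})

test_that("factored-frontier expected decay follows the closed form", {
  net <- toy_model("decay1")
  grid <- time_grid(400, 50)
  pr <- default_prior(net)
  pr$k1 <- list(type = "point", value = 0.01)
  dbn <- build_dbn(net, pr, J = 3000, grid = grid, seed = 8)
  es <- expected_series(ff_forward(dbn), "A")
  truth <- 100 * exp(-0.01 * grid)
  width <- max(diff(dbn$disc$A$boundaries))
  expect_lt(max(abs(es - truth)), width)
})
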