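test_that("zero-noise datasets reproduce the simulation exactly", {
  net <- toy_model("cascade3")
  st <- seq(0, 1800, by = 300)
  ds <- generate_dataset(net, param_values(net),
                         conditions = list(base = NULL), sample_times = st,
                         noise = noise_model(cv = 0), seed = 1,
                         normalise = FALSE)
  traj <- simulate(net, sort(unique(c(0, st))))
  for (s in c("A", "B", "C")) {
    got <- ds$observations$value[ds$observations$species == s]
    expect_equal(got, unname(series(traj, s)[match(st, traj$grid)]),
                 tolerance = 1e-9)
  }
})

test_that("generation is seeded and the PC design observes the right species", {
  net <- the_complement()
  cond <- condition(initiation = "PC", pH = 6.5, calcium = 2.0,
                    crp_scale = 10)
  obs <- list(PC = c("CRP_dep", "C4_dep", "C3_dep", "C4BP_dep"))
  d1 <- generate_dataset(net, param_values(net)[!net$params$known],
                         conditions = list(PC = cond), observed = obs,
                         seed = 4, affinity_model = the_affinity())
  d2 <- generate_dataset(net, param_values(net)[!net$params$known],
                         conditions = list(PC = cond), observed = obs,
                         seed = 4, affinity_model = the_affinity())
  expect_identical(d1$observations, d2$observations)
  expect_setequal(unique(d1$observations$species),
                  c("CRP_dep", "C4_dep", "C3_dep", "C4BP_dep"))
  expect_equal(length(unique(d1$observations$time_s)), 8)
  expect_lte(max(d1$observations$time_s), 12600)
})

test_that("the empirical noise level converges to the configured CV", {
  set.seed(99)
  nm <- noise_model(cv = 0.1)
  x <- compdbn:::apply_noise(rep(50, 1000), nm)
  expect_equal(mean(x), 50, tolerance = 0.02)
  expect_equal(sd(x) / mean(x), 0.1, tolerance = 0.1)
})
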