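test_that("the neutral condition leaves the network unchanged", {
  net <- the_complement()
  out <- apply_condition(net, condition(initiation = "both", pH = 7.4,
                                        calcium = 2.5), the_affinity())
  expect_equal(out$params$value, net$params$value)
  expect_equal(out$species$init, net$species$init)
  expect_true(all(vapply(out$reactions, `[[`, TRUE, "active")))
})

test_that("the inflammation condition scales the crosstalk association 100-fold", {
  net <- the_complement()
  out <- apply_condition(net, condition(initiation = "both", pH = 6.5,
                                        calcium = 2.0), the_affinity())
  i <- match("kd01_1", net$params$name)
  expect_equal(out$params$value[i] / net$params$value[i], 100,
               tolerance = 1e-6)
})

test_that("branch suppression deactivates exactly the other branch", {
  net <- the_complement()
  pc <- apply_condition(net, condition(initiation = "PC"), the_affinity())
  expect_equal(pc$species$init[match("GlcNAc", pc$species$name)], 0)
  for (r in pc$reactions) {
    if (length(intersect(r$tags, c("lectin", "amplification-GlcNAc"))))
      expect_false(r$active)
    if (length(intersect(r$tags, c("classical", "amplification-PC"))))
      expect_true(r$active)
  }
  ## suppressed-branch rate expressions vanish for any state: the compiled
  ## RHS of a PC-initiated network never moves lectin-only species
  rhs <- ode_rhs(pc)
  set.seed(1)
  x <- setNames(runif(42, 0, 50), pc$species$name)
  dx <- rhs(0, x, param_values(pc))[[1]]
  names(dx) <- pc$species$name
  ## Fic_GN only participates in lectin reactions, so its derivative must
  ## be identically zero whatever the state
  expect_equal(unname(dx["Fic_GN_M2"]), 0)
})

test_that("knockouts remove only the tagged reactions and commute with suppression", {
  net <- the_complement()
  af <- the_affinity()
  kd <- apply_condition(net, condition(knockouts = "d"), af)
  off <- vapply(kd$reactions, function(r) !r$active, TRUE)
  expect_equal(vapply(kd$reactions, `[[`, "", "id")[off], "m31")
  ## natural decay reaction retained
  d43 <- kd$reactions[[match("d43", vapply(kd$reactions, `[[`, "", "id"))]]
  expect_true(d43$active)
  expect_error(apply_condition(net, condition(knockouts = c("a", "b")), af),
               NA)

  ## order of suppression and knockout does not matter
  c1 <- condition(initiation = "PC", knockouts = "d")
  a <- apply_condition(net, c1, af)
  b <- apply_condition(apply_condition(net, condition(knockouts = "d"), af),
                       condition(initiation = "PC"), af)
  expect_equal(vapply(a$reactions, `[[`, TRUE, "active"),
               vapply(b$reactions, `[[`, TRUE, "active"))
})

test_that("depletion zeroes initials and unknown species are rejected", {
  net <- the_complement()
  dep <- apply_condition(net, condition(depleted = c("CRP", "Lficolin")),
                         the_affinity())
  expect_equal(dep$species$init[match(c("CRP", "Lficolin"),
                                      dep$species$name)], c(0, 0))
  expect_error(realize_condition(net, c(NotASpecies = 1)),
               "unknown species")
})
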