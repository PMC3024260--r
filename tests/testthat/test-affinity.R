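test_that("the fitted affinity model pins the 100-fold inflammation ratio", {
  m <- the_affinity()
  expect_equal(affinity(m, 6.5, 2.0) / affinity(m, 7.4, 2.5), 100,
               tolerance = 1e-9)
  expect_equal(affinity(m, 7.4, 2.5), 1, tolerance = 1e-9)
})

test_that("a flat anchor table fits a constant model", {
  anchors <- data.frame(pH = c(5.5, 6.0, 6.5, 7.0, 7.4), calcium_mM = 2.0,
                        affinity = 1)
  m <- fit_affinity(anchors, degree = 3)
  expect_equal(affinity(m, 6.0, 2.0), 1, tolerance = 1e-9)
  expect_equal(affinity(m, 7.2, 2.0), 1, tolerance = 1e-9)
})

test_that("polynomial regression recovers known generating coefficients", {
  ## anchors sampled exactly from a cubic in log10 affinity
  coefs <- c(3, -1.2, 0.25, -0.02)
  ph <- seq(5.5, 7.4, length.out = 9)
  la <- coefs[1] + coefs[2] * ph + coefs[3] * ph^2 + coefs[4] * ph^3
  anchors <- data.frame(pH = ph, calcium_mM = 2.5, affinity = 10^la)
  m <- fit_affinity(anchors, degree = 3)
  got <- m$fits[["2.5"]]$coef
  expect_equal(unname(got), coefs, tolerance = 1e-8)
})

test_that("default affinity is continuous and non-increasing in pH", {
  m <- the_affinity()
  for (ca in c(2.0, 2.5)) {
    ph <- seq(5.5, 7.4, by = 0.01)
    v <- affinity(m, ph, ca)
    expect_true(all(v > 0))
    expect_true(all(diff(v) <= 1e-9))
    ## continuity: no jumps beyond the local slope scale
    expect_lt(max(abs(diff(log(v)))), 0.1)
  }
})

test_that("insufficient anchors per calcium level raise an error", {
  anchors <- data.frame(pH = c(6.0, 7.0), calcium_mM = 2.0,
                        affinity = c(10, 1))
  expect_error(fit_affinity(anchors, degree = 3), "anchors")
})
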