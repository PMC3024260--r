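test_that("the killing panel report is traceable and flags its maximum", {
  rep <- run_killing_panel(the_complement(), the_affinity())
  expect_s3_class(rep, "scenario_report")
  expect_equal(nrow(rep$results), 9)
  expect_equal(max(rep$results$killing_rate), 95)
  expect_equal(rep$flags$argmax,
               rep$results$condition[which.max(rep$results$c3_dep_nM)])
  ## doubly depleted serum cannot initiate at all
  expect_equal(rep$results$c3_dep_nM[rep$results$condition ==
                                       "patient_both_depl"], 0)
})

test_that("titration at scale 1 equals the baseline simulation", {
  net <- the_complement(); af <- the_affinity()
  rep <- run_c4bp_titration(net, af, initiation = "PC", scales = 1,
                            horizon = 7200)
  cond <- condition(initiation = "PC", pH = 6.5, calcium = 2.0,
                    crp_scale = 10)
  ref <- summarize(simulate(apply_condition(net, cond, af),
                            time_grid(7200, 100),
                            check_conservation = FALSE,
                            rtol = 1e-6, atol = 1e-9), "C3_dep", net)
  expect_equal(rep$results$peak_amplitude, ref$peak_amplitude,
               tolerance = 1e-8)
  expect_equal(rep$results$peak_time, ref$peak_time)
})

test_that("an empty knockout set reproduces the baseline exactly", {
  rep <- run_knockouts(the_complement(), the_affinity(), horizon = 5400)
  base <- rep$results[rep$results$knockout == "none", ]
  expect_equal(base$auc_delta_rel, 0)
  expect_true(all(c("a", "b", "c", "d") %in% rep$results$knockout))
})

test_that("competition variants coincide when the crosstalk is absent", {
  net <- the_complement(); af <- the_affinity()
  rep <- run_competition_variants(net, af, strengths = 1, endpoint = 1800,
                                  crp_scale = 1)
  v <- rep$results
  expect_equal(v$c3_dep_nM[v$variant == "simultaneous"],
               v$c3_dep_nM[v$variant == "competitive"], tolerance = 0.02)
  ## and the simultaneous model amplifies under inflammation strength
  ## while the competitive variant falls behind it
  rep2 <- run_competition_variants(net, af, strengths = c(1, 100),
                                   endpoint = 1800, crp_scale = 1)
  v2 <- rep2$results
  sim100 <- v2$c3_dep_nM[v2$variant == "simultaneous" & v2$strength == 100]
  cmp100 <- v2$c3_dep_nM[v2$variant == "competitive" & v2$strength == 100]
  expect_gt(sim100, cmp100)
})
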