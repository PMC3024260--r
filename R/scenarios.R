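# Scripted in-silico experiments over the fitted complement model: the
# killing-rate validation panel, pH/calcium response grids, C4BP titration,
# mechanism knockouts, and the competitive-binding variants. Every scenario
# is a pure function of (network, condition configuration, affinity model)
# and returns a machine-readable `scenario_report`.

scenario_report <- function(id, conditions, results, flags = list()) {
  structure(list(scenario = id, conditions = conditions, results = results,
                 flags = flags), class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("scenario_report:", x$scenario, "-", length(x$conditions),
      "conditions\n")
  if (is.data.frame(x$results)) print(x$results)
  for (f in names(x$flags)) cat(" ", f, ":", format(x$flags[[f]]), "\n")
  invisible(x)
}

#' Condition set of the killing-rate validation panel
#'
#' Patient (infection-inflammation: pH 6.5, 2.0 mM calcium, acute-phase
#' CRP) and normal (pH 7.4, 2.5 mM calcium) serum, each whole, CRP-depleted,
#' L-ficolin-depleted and doubly depleted, plus the high-CRP normal serum
#' control.
#'
#' @param patient_crp_scale acute-phase CRP multiplier of the patient serum.
#' @param high_crp_scale CRP multiplier of the high-CRP normal control.
#' @return named list of [condition()] objects.
#' @export
killing_conditions <- function(patient_crp_scale = 10, high_crp_scale = 10) {
  pat <- function(...) condition(initiation = "both", pH = 6.5,
                                 calcium = 2.0,
                                 crp_scale = patient_crp_scale, ...)
  nor <- function(...) condition(initiation = "both", pH = 7.4,
                                 calcium = 2.5, ...)
  list(patient_whole = pat(),
       patient_crp_depl = pat(depleted = "CRP"),
       patient_fic_depl = pat(depleted = "Lficolin"),
       patient_both_depl = pat(depleted = c("CRP", "Lficolin")),
       normal_whole = nor(),
       normal_crp_depl = nor(depleted = "CRP"),
       normal_fic_depl = nor(depleted = "Lficolin"),
       normal_both_depl = nor(depleted = c("CRP", "Lficolin")),
       normal_high_crp = nor(crp_scale = high_crp_scale))
}

simulate_condition <- function(network, cond, affinity_model, grid,
                               params = NULL) {
  net <- apply_condition(network, cond, affinity_model)
  list(net = net,
       traj = simulate(net, grid, params = params,
                       check_conservation = FALSE,
                       rtol = 1e-6, atol = 1e-9))
}

#' Killing-rate panel
#'
#' Simulates deposited C3 at the endpoint (1 h) for every panel condition
#' and normalises across the panel so the maximum equals 95% — the
#' predicted bacterial killing rates of the validation experiment.
#'
#' @param network the complement `reaction_network` (fitted values
#'   registered, or supplied via `theta`).
#' @param affinity_model an `affinity_model`.
#' @param theta optional named parameter overrides.
#' @param endpoint endpoint time in seconds (1 h).
#' @param conditions panel conditions ([killing_conditions()]).
#' @return a `scenario_report` whose `results` holds per-condition deposited
#'   C3 (nM) and killing rate (%), flagging the argmax condition.
#' @export
run_killing_panel <- function(network, affinity_model, theta = NULL,
                              endpoint = 3600,
                              conditions = killing_conditions()) {
  grid <- time_grid(endpoint, 100)
  vals <- vapply(names(conditions), function(lab) {
    s <- simulate_condition(network, conditions[[lab]], affinity_model,
                            grid, params = theta)
    series(s$traj, "C3_dep", s$net)[length(grid)]
  }, 0)
  kp <- killing_panel(vals)
  scenario_report("killing_panel", conditions,
                  data.frame(condition = names(vals), c3_dep_nM = unname(vals),
                             killing_rate = unname(kp$rates)),
                  flags = list(argmax = kp$argmax, endpoint_s = endpoint))
}

#' pH / calcium response grid
#'
#' Simulates C3 deposition over the full profile horizon (3.5 h) for every
#' pH and calcium combination, plus the dose-response endpoint at 1.5 h.
#'
#' @param network,affinity_model,theta as in [run_killing_panel()].
#' @param pH vector of pH values (5.5-7.4).
#' @param calcium vector of calcium levels (mM).
#' @param horizon profile horizon (s).
#' @param endpoint dose-response endpoint (s).
#' @param initiation ligand condition for the grid (bacterial surface:
#'   both).
#' @return `scenario_report` with per-cell peak amplitude, peak time,
#'   integrated response and the endpoint response.
#' @export
run_ph_ca_grid <- function(network, affinity_model, theta = NULL,
                           pH = seq(5.5, 7.4, by = 0.1),
                           calcium = c(2.0, 2.5), horizon = 12600,
                           endpoint = 5400, initiation = "both") {
  grid <- time_grid(horizon, 100)
  out <- NULL
  conds <- list()
  for (ca in calcium) for (p in pH) {
    cond <- condition(initiation = initiation, pH = p, calcium = ca)
    lab <- sprintf("pH%.2f_Ca%.1f", p, ca)
    conds[[lab]] <- cond
    s <- simulate_condition(network, cond, affinity_model, grid,
                            params = theta)
    y <- series(s$traj, "C3_dep", s$net)
    ss <- summarize(s$traj, "C3_dep", s$net)
    out <- rbind(out, data.frame(
      pH = p, calcium_mM = ca,
      peak_amplitude = ss$peak_amplitude, peak_time = ss$peak_time,
      integrated_response = ss$integrated_response,
      endpoint_response = y[match(endpoint, grid)]))
  }
  scenario_report("ph_ca_grid", conds, out,
                  flags = list(endpoint_s = endpoint))
}

#' C4BP titration
#'
#' Varies the initial C4BP concentration around the 260 nM plasma level and
#' simulates PC- or GlcNAc-initiated activation under infection-inflammation
#' conditions for 5 h, reporting the peak summaries and the qualitative
#' orderings (does C4BP delay the peak, does it lower the amplitude).
#'
#' @param network,affinity_model,theta as above.
#' @param initiation `"PC"` or `"GlcNAc"`.
#' @param scales multipliers on the C4BP initial.
#' @param horizon simulation horizon (s), 5 h.
#' @param crp_scale acute-phase CRP multiplier of the serum.
#' @return `scenario_report`; flags `peak_time_increasing`,
#'   `amplitude_decreasing`, `amplitude_range_rel`, `peak_time_span_s`.
#' @export
run_c4bp_titration <- function(network, affinity_model, theta = NULL,
                               initiation = "PC", scales = c(0.5, 1, 2),
                               horizon = 18000, crp_scale = 10) {
  grid <- time_grid(horizon, 100)
  out <- NULL
  conds <- list()
  for (s in scales) {
    cond <- condition(initiation = initiation, pH = 6.5, calcium = 2.0,
                      crp_scale = crp_scale, c4bp_scale = s)
    lab <- sprintf("c4bp_x%g", s)
    conds[[lab]] <- cond
    r <- simulate_condition(network, cond, affinity_model, grid,
                            params = theta)
    ss <- summarize(r$traj, "C3_dep", r$net)
    out <- rbind(out, data.frame(c4bp_scale = s,
                                 peak_amplitude = ss$peak_amplitude,
                                 peak_time = ss$peak_time,
                                 integrated_response = ss$integrated_response))
  }
  out <- out[order(out$c4bp_scale), ]
  scenario_report(paste0("c4bp_titration_", initiation), conds, out,
                  flags = list(
                    peak_time_increasing = !is.unsorted(out$peak_time,
                                                        strictly = TRUE),
                    amplitude_decreasing =
                      !is.unsorted(rev(out$peak_amplitude), strictly = TRUE),
                    amplitude_range_rel =
                      diff(range(out$peak_amplitude)) /
                      max(out$peak_amplitude),
                    peak_time_span_s = diff(range(out$peak_time))))
}

#' C4BP mechanism knockouts
#'
#' Simulates baseline plus each single mechanism knockout (a-d) under
#' PC-initiated infection-inflammation conditions and reports the change in
#' the integrated C3-deposition response, flagging the mechanism whose
#' removal enhances activation the most.
#'
#' @param network,affinity_model,theta as above.
#' @param initiation initiating ligand.
#' @param horizon simulation horizon (s).
#' @param crp_scale acute-phase CRP multiplier.
#' @return `scenario_report`; flags `max_enhancer`.
#' @export
run_knockouts <- function(network, affinity_model, theta = NULL,
                          initiation = "PC", horizon = 12600,
                          crp_scale = 10) {
  grid <- time_grid(horizon, 100)
  mechs <- c("none", "a", "b", "c", "d")
  out <- NULL
  conds <- list()
  base_auc <- NA
  for (m in mechs) {
    cond <- condition(initiation = initiation, pH = 6.5, calcium = 2.0,
                      crp_scale = crp_scale,
                      knockouts = if (m == "none") character() else m)
    conds[[paste0("ko_", m)]] <- cond
    r <- simulate_condition(network, cond, affinity_model, grid,
                            params = theta)
    ss <- summarize(r$traj, "C3_dep", r$net)
    if (m == "none") base_auc <- ss$integrated_response
    out <- rbind(out, data.frame(knockout = m,
                                 peak_amplitude = ss$peak_amplitude,
                                 peak_time = ss$peak_time,
                                 integrated_response = ss$integrated_response,
                                 auc_delta_rel =
                                   (ss$integrated_response - base_auc) /
                                   base_auc))
  }
  ko <- out[out$knockout != "none", ]
  scenario_report(paste0("knockouts_", initiation), conds, out,
                  flags = list(max_enhancer =
                                 ko$knockout[which.max(ko$auc_delta_rel)]))
}

#' Competitive-binding model variants
#'
#' Compares the simultaneous-binding model (the deposited CRP:L-ficolin
#' complex recruits C1 or MASP-2 while keeping its own ligand engaged) with
#' the competitive variant (the complex cannot recruit the partner
#' protease, so crosstalk only sequesters the initiators), sweeping the
#' crosstalk strength (the affinity scale factor applied to the
#' CRP:L-ficolin association). Each cell is classified against the
#' no-crosstalk baseline as up-regulating, down-regulating or having no
#' effect.
#'
#' @param network,affinity_model,theta as above.
#' @param strengths affinity fold factors to sweep.
#' @param endpoint comparison endpoint (s).
#' @param rel_tol relative change below which a cell counts as "none".
#' @param crp_scale acute-phase CRP multiplier.
#' @return `scenario_report` with per (variant, strength) deposited C3 and
#'   outcome class.
#' @export
run_competition_variants <- function(network, affinity_model, theta = NULL,
                                     strengths = c(1, 10, 100),
                                     endpoint = 3600, rel_tol = 0.02,
                                     crp_scale = 10) {
  grid <- time_grid(endpoint, 100)
  ph_for <- function(f) {
    ## pH at which the affinity model returns the requested fold factor
    ## (calcium 2.0); strength 1 uses the normal reference
    if (f <= 1) return(list(pH = 7.4, ca = 2.5))
    g <- function(p) affinity(affinity_model, p, 2.0) - f
    list(pH = stats::uniroot(g, c(5.5, 7.4))$root, ca = 2.0)
  }
  ## no-crosstalk baseline: competition irrelevant, affinity factor ~ 0
  base_net <- apply_condition(network,
                              condition(initiation = "both", pH = 7.4,
                                        calcium = 2.5,
                                        crp_scale = crp_scale), NULL)
  base_net <- set_params(base_net, c(kd01_1 = 0))
  base <- series(simulate(base_net, grid, params = theta,
                          check_conservation = FALSE, rtol = 1e-6,
                          atol = 1e-9), "C3_dep", base_net)[length(grid)]
  out <- NULL
  conds <- list()
  for (variant in c("simultaneous", "competitive")) {
    for (f in strengths) {
      at <- ph_for(f)
      cond <- condition(initiation = "both", pH = at$pH, calcium = at$ca,
                        crp_scale = crp_scale,
                        competition_mode = variant == "competitive")
      lab <- sprintf("%s_x%g", variant, f)
      conds[[lab]] <- cond
      r <- simulate_condition(network, cond, affinity_model, grid,
                              params = theta)
      v <- series(r$traj, "C3_dep", r$net)[length(grid)]
      rel <- (v - base) / base
      out <- rbind(out, data.frame(
        variant = variant, strength = f, c3_dep_nM = v,
        rel_change = rel,
        outcome = if (abs(rel) <= rel_tol) "none"
        else if (rel > 0) "up" else "down"))
    }
  }
  scenario_report("competition_variants", conds, out,
                  flags = list(baseline_nM = base,
                               outcome_classes = unique(out$outcome)))
}
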