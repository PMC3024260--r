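# compdbn

Kinetic modelling of classical and lectin complement activation with a
dynamic Bayesian network (DBN) approximation for inference.

The complement system kills invading bacteria by depositing C3b on their
surface. Its activity is tuned both up — under local infection-inflammation
conditions (mild acidosis, hypocalcaemia) the initiators CRP and L-ficolin
associate up to 100-fold more strongly and open amplification routes
between the classical and lectin arms — and down, by the plasma inhibitor
C4b-binding protein (C4BP), which interferes with CRP, C4b and the C3
convertase C4bC2a through four distinct mechanisms. `compdbn` is for
systems biologists who want to study this balance quantitatively: it
provides the reaction network, the probabilistic machinery to calibrate it
against sparse time-series data, global sensitivity analysis, and the
in-silico experiments (killing-rate panel, pH/calcium response, C4BP
titration, mechanism knockouts).

## The model and the method

The core is a mass-action / Michaelis–Menten ODE system over 42 species,
45 reactions and 85 kinetic parameters (71 unknown),

dx_i/dt = Σ_j ± e_ij f_ij,  f_ij = k ∏ x_reactants  or  f_ij = c·[E]·[S]/(c_half + [S]),

terminating at surface-deposited C3b, the proxy for bactericidal activity.
Because 71 unknown rate constants defeat direct search, the ODE dynamics
are approximated as a two-slice, time-variant DBN: variables are
discretised into 6 quantile intervals, parameters into 5 equal intervals;
trajectories sampled from the prior are binned; and per-slice conditional
probability tables are obtained by counting. Inference uses the factored
frontier algorithm (product-of-marginals propagation with evidence
filtering). Estimation is two-stage: a stochastic ranking evolution
strategy (SRES) first finds the maximum-likelihood combination of
parameter intervals by scoring blocks through the DBN (shrinking the
search space by 1/5^71), then searches the winning box continuously
against ODE simulations. Global sensitivity uses multi-parametric
sensitivity analysis: Latin-hypercube parameter samples classified good or
bad by objective threshold, scored per parameter by the Kolmogorov–Smirnov
distance between class distributions.

The full supplementary parameterisation of the original study is not
publicly deposited; the shipped model is a clearly-labelled synthetic
transcription calibrated to reproduce the published quantitative behaviour
(see the methods vignette, `vignettes/complement-dbn-methods.Rmd`).

## Worked example

Predicted bacterial killing rates: deposited C3 after 1 h under patient
(pH 6.5, 2.0 mM Ca, acute-phase CRP) and normal (pH 7.4, 2.5 mM Ca) serum
conditions, whole and depleted, normalised so the panel maximum is 95%:

```r
library(compdbn)
net <- complement_model()   # validates 42 species / 45 reactions / 85 (71 unknown)
af  <- fit_affinity()       # pH/calcium affinity model, pinned to 100x
rep <- run_killing_panel(net, af)
rep$results
#>           condition c3_dep_nM killing_rate
#> 1     patient_whole      5051        95.00
#> 2  patient_crp_depl      1729        32.51
#> 3  patient_fic_depl      1295        24.36
#> 4 patient_both_depl         0         0.00
#> 5      normal_whole      1585        29.80
#> 6   normal_crp_depl       943        17.74
#> 7   normal_fic_depl       488         9.17
#> 8  normal_both_depl         0         0.00
#> 9   normal_high_crp      1644        30.93
```

Reading the numbers: under infection-inflammation conditions whole serum
kills efficiently (95%); depleting CRP or L-ficolin collapses the rate to
~33% or ~24%, so the synergistic crosstalk carries roughly 40% of the
enhanced killing. Under normal conditions the whole-serum rate is ~30%,
the depletions cost proportionally less, and raising CRP ten-fold alone
buys ~1 point — the crosstalk needs the inflammatory milieu, not just more
CRP.

Downstream analyses follow the same pattern:

```r
dbn <- build_dbn(net_pc, J = 600, grid = time_grid(12600, 600),
                 integrator = "lsoda")          # DBN of a conditioned network
marg <- ff_forward(dbn)                         # factored-frontier marginals
fit <- estimate_two_stage(net, dbns, data)      # block search + refinement
sens <- mpsa(dbn, data, n_samples = 2500)       # KS sensitivity screen
run_c4bp_titration(net, af, initiation = "PC")  # in-silico experiments
```

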