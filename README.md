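# mousEB — dynamic energy balance modeling of C57BL/6 mouse metabolism

mousEB predicts the time course of body weight (BW), fat mass (FM),
fat-free mass (FFM), energy expenditure (EE) and respiratory quotient
(RQ) in adult male C57BL/6 mice from a single driving input: the
metabolizable energy-intake schedule and the macronutrient composition of
the diet. It is aimed at investigators of murine obesity and energy
metabolism who want to ask quantitatively whether an observed weight
change is explained by intake, expenditure, or both — without continuous
indirect calorimetry.

## The model

Energy conservation couples intake to tissue change,

    EI − EE = ρ_FM·dFM/dt + ρ_FFM·dFFM/dt,

with lean change tied to fat change by the empirical mouse partition
function α(FM) = c + d·exp(k·FM), dFFM/dt = α(FM)·dFM/dt. Expenditure is

    EE = K + γ_FFM·FFM + γ_FM·FM + λ·BW + β·ΔEI
         + η_FM·dFM/dt + η_FFM·dFFM/dt,

i.e. basal thermogenesis, tissue-mass-dependent metabolic rate
(quarter-power rescaled from human values), body-weight-proportional
physical activity with diet-dependent switching dynamics (an immediate
drop to λ_H on high fat; a jump to λ_C1 relaxing to λ_C2 with τ = 14 d on
return to chow), diet-induced thermogenesis, and tissue deposition costs.
The implicit EE/rate system is linear in dFM/dt and solved in closed
form. Net macronutrient oxidation rates, RQ and the diet food quotient
(FQ) follow from the carbohydrate-balance assumption and standard
indirect-calorimetry gas-exchange constants.

The free parameters {K, λ_C0, λ_H, λ_C1, λ_C2} are calibrated against
longitudinal group-mean BW/FM data by adaptive random-walk Metropolis
MCMC, with intake-measurement uncertainty propagated through per-interval
intake nuisance parameters, Geweke convergence diagnostics, and posterior
credible bands for predicted EE. A synthetic-study generator reproduces
the statistical structure of the calibration/validation experiments so
the whole pipeline is testable end to end.

## Worked example

Seven weeks of high-fat feeding followed by a switch back to chow, with
the observed post-switch intake crash:

```r
library(mousEB)
p   <- model_parameters()                         # published values
sch <- intake_schedule(c(0, 49, 56), c(13.5, 6, 10),
                       list(diet_high_fat(), diet_chow(), diet_chow()),
                       baseline_EI = 12)          # kcal/d
act <- activity_schedule(c(0, 49), c("hf", "chow"))
traj <- simulate_mouse(body_state(FM = 4, FFM = 23), sch, act, p,
                       horizon = 140)
traj <- annotate_fuel(traj, sch, act, p)
traj[traj$t %in% c(0, 49, 56, 140),
     c("t", "BW", "FM", "EE", "lambda", "RQ", "FQ")]
```

    #>       t      BW        FM        EE    lambda        RQ        FQ
    #> 1     0 27.0000  4.000000  9.857273 0.1300000 0.8359786 0.8021856
    #> 50   49 40.5313 15.829782 14.602589 0.2700000 0.7994613 0.9210607
    #> 57   56 34.5405 10.807873 13.350191 0.2385225 0.8674100 0.9210607
    #> 141 140 27.4349  4.394914 10.101620 0.1901203 0.9188853 0.9210607

The mouse gains ~13.6 g (mostly fat) in seven weeks of high-fat feeding;
on the switch to chow, activity jumps (λ 0.13 → 0.27), EE rises even as
intake collapses, weight falls rapidly, and RQ relaxes toward the chow
food quotient 0.92 as balance is restored.

Calibration on synthetic data:

```r
study <- generate_study(seed = 1)          # five-group study design
obs   <- as_observation_set(study)
post  <- run_metropolis(obs, seed = 1)     # 100k iterations
post                                        # posterior quantiles, acceptance
predict_EE_interval(post, obs)             # 95% EE credible bands
```

A thin command-line wrapper over these functions (subcommands `simulate`,
`fuel`, `synth`, `calibrate`) ships at `inst/scripts/mousEB.R`
(`system.file("scripts", "mousEB.R", package = "mousEB")` once
installed); a small example intake CSV is under `inst/extdata/`.

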