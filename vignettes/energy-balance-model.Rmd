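---
title: "Modeling mouse energy balance, body composition and fuel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mouse energy balance, body composition and fuel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousEB)
```

## The model

mousEB implements a dynamic energy-balance model of adult male C57BL/6
mice. The state is the body composition (fat mass FM and fat-free mass
FFM, in grams); the only driving input is the metabolizable energy-intake
schedule EI(t) (kcal/d) together with the macronutrient composition of the
diet. Internal units are fixed throughout: grams, days, kcal. Inputs in
other units are rejected rather than converted.

Energy conservation states

$$EI - EE = \rho_{FM}\,\frac{dFM}{dt} + \rho_{FFM}\,\frac{dFFM}{dt},$$

with tissue energy densities $\rho_{FM} = 9.4$ and $\rho_{FFM} = 1.8$
kcal/g. Lean and fat change are coupled by the empirical partition
function

$$\alpha(FM) = c + d\,e^{k\,FM}, \qquad
  \frac{dFFM}{dt} = \alpha(FM)\,\frac{dFM}{dt},$$

with $c = 0.1$, $d = 1.89\times 10^{-4}$, $k = 0.45\ \mathrm{g^{-1}}$.
Unlike the human (Forbes) relationship, $\alpha$ *increases* with
adiposity in mice: very fat animals accrete proportionally more lean
tissue per gram of fat change. The function was measured on adult mice,
so evaluation is restricted to FM $\in [0.1, 60]$ g and the simulator
fails loudly (naming the time) if a trajectory leaves this domain rather
than extrapolating.

Energy expenditure is modeled as

$$EE = K + \gamma_{FFM}\,FFM + \gamma_{FM}\,FM + \lambda\,BW
       + \beta\,\Delta EI + \eta_{FM}\,\frac{dFM}{dt}
       + \eta_{FFM}\,\frac{dFFM}{dt},$$

comprising constant basal thermogenesis $K$ (kcal/d, calibrated; valid
for individually housed mice at 22 °C), tissue-specific metabolic rates
$\gamma_{FFM} = 0.15$ and $\gamma_{FM} = 0.03$ kcal/g/d, physical
activity with cost proportional to body weight, diet-induced thermogenesis
(DIT) $\beta\,\Delta EI$ with $\beta = 0.4$ and $\Delta EI$ the intake
change from the chow baseline, and tissue deposition costs
$\eta_{FM} = 0.18$, $\eta_{FFM} = 0.23$ kcal/g. The deposition terms carry
the sign of the tissue rates, so mobilization *reduces* EE, and
$\Delta EI$ may be negative (voluntary restriction after a diet switch
lowers DIT). The $\gamma$ values derive from human per-kilogram
coefficients (22 and 3.6 kcal/kg/d) by quarter-power allometric
rescaling — basal metabolic rate scales as $BW^{3/4}$ across species, so
specific rates scale as $BW^{-1/4}$ (`rescale_gamma()`). The reference
masses, 70 kg and 30 g, are exposed arguments; the fat coefficient is
reproducible only to one significant figure under any nearby mass choice.

### The implicit system and its closed form

EE depends on the tissue rates and the rates on EE. Because the coupling
is linear in $dFM/dt$, the simultaneous solution of the balance equation
and the expenditure model is closed-form: with $A = \alpha(FM)$ and
$M = K + \gamma_{FFM} FFM + \gamma_{FM} FM + \lambda BW + \beta \Delta EI$,

$$\frac{dFM}{dt} =
  \frac{EI - M}{\rho_{FM} + A\rho_{FFM} + \eta_{FM} + A\eta_{FFM}},$$

and $EE = EI - (\rho_{FM} + A\rho_{FFM})\,dFM/dt$.
`resolve_energy_balance()` implements exactly this; the test suite checks
it against an independent fixed-point iteration (alternating the EE and
rate equations to convergence) on 1000 random states, and the balance
identity holds algebraically at every trajectory sample.

### Physical activity switching

The activity coefficient $\lambda(t)$ (kcal/g/d) depends on the diet: it
is $\lambda_{C0} = 0.22$ on baseline chow, drops immediately to
$\lambda_H = 0.13$ at a switch to high fat (0.16 for Ensure-supplemented
groups), and at a switch back to chow jumps to $\lambda_{C1} = 0.27$ and
relaxes exponentially to $\lambda_{C2} = 0.19$ with time constant
$\tau = 14$ d. The original impulse/step formulation is realized as exact
piecewise evaluation rather than a stiff ODE. Protocols with any number
of switches are supported as an ordered event list — the minimal
generalization consistent with the two-switch form: every switch to high
fat sets $\lambda_H$ instantly; every return to chow restarts the
$\lambda_{C1} \to \lambda_{C2}$ relaxation.

## Fuel selection

Over time scales of days, glycogen stores are negligible relative to
carbohydrate intake, so the system is treated as in average carbohydrate
balance. The net macronutrient oxidation rates (which absorb de novo
lipogenesis and gluconeogenesis) are then fully determined by the intakes
and the tissue rates:

$$\mathrm{NetCarbOx} = I_C,\qquad
  \mathrm{NetProtOx} = I_P - \rho_{FFM}\frac{dFFM}{dt},\qquad
  \mathrm{NetFatOx} = I_F - \rho_{FM}\frac{dFM}{dt},$$

where fat-free-mass change is treated as body protein plus its associated
intracellular water, so its full energy density is protein energy. The
three rates sum to EE exactly, by construction.

The respiratory quotient is computed by converting each oxidation rate to
an oxygen-consumption rate with the standard energy-per-liter-O₂ yields
(carbohydrate 5.047, fat 4.686, protein 4.485 kcal/L) and averaging the
macronutrient RQs (1.00, 0.71, 0.835) with these O₂-volume weights. The
food quotient FQ applies the same weighting to the diet's energy
fractions; this reproduces FQ = 0.92 for chow (24/12/64% of energy from
protein/fat/carbohydrate) and FQ = 0.80 for the high-fat diet (14/59/27)
at two decimals. A plain energy-fraction-weighted mean of the
macronutrient RQs does *not* reproduce these values (it gives 0.93 for
chow), which is why the O₂-weighted form is used for both RQ and FQ. In
energy and macronutrient balance RQ = FQ exactly. Because carbohydrate
balance only holds over several days, RQ within two days of a schedule
discontinuity is flagged approximate (`RQ_approx`) in annotated output.

## Numerical choices

* **Integration.** `simulate_mouse()` uses deSolve's adaptive `ode45`
  with rtol $10^{-8}$ / atol $10^{-10}$, restarting at every schedule
  discontinuity (switch times are known, so no root-finding is needed).
  A cumulative energy-balance state is co-integrated, making energy
  conservation auditable to round-off on every trajectory.
* **Fast path.** The MCMC likelihood solves the ODE tens of thousands of
  times, so it uses a compiled classical RK4 core with a fixed step
  (default 0.5 d; 1 d in the reduced-scale tests). Against the adaptive
  reference the fixed-step error is below $10^{-4}$ g over a 24-week
  multi-switch protocol — orders of magnitude below measurement noise.
* **Partition quadrature.** `ffm_from_fm_path()` integrates $\alpha$ by
  adaptive quadrature at $10^{-10}$ absolute tolerance so that it never
  dominates solver error; tests check it against the closed-form
  antiderivative.
* **Degenerate inputs.** Diet fractions must sum to 1 within $10^{-6}$;
  FM outside $[0.1, 60]$ g and non-positive masses are errors; an RQ of
  an all-zero fuel mix is an error rather than NaN.

## Calibration

The free parameters are $K$ and the four activity coefficients; all other
parameters are fixed a priori. The likelihood is Gaussian for the
observed group-mean BW and FM series at their standard errors. Intake
measurement uncertainty is propagated by treating the intake of every
schedule interval as a nuisance parameter with a Gaussian prior centered
on the measured value. When repeated intake measurements fall within one
schedule interval they are averaged first and the interval's prior
standard error shrinks by $\sqrt{n}$ — the analogue of fitting measured
intake to a curve before using it as a model input, and the correctly
specified estimator when intake is constant per interval with independent
measurement noise (the per-group intake standard errors are 0.39–0.55
kcal/d). Priors on the five structural parameters are flat on the
positive half-line.

Sampling is random-walk Metropolis (acceptance $\min(1, r)$ with $r$ the
posterior ratio), run by default for 100,000 iterations with a 30,000
burn-in and one-fifth thinning. The posterior has a pronounced ridge
coupling $K$, the $\lambda$'s and the intake offsets: $K$ trades almost
exactly against a constant activity-cost offset when body weight varies
little, so $K$ is the least identified parameter and its credible
intervals are wide unless groups spanning different body-weight ranges
are fitted jointly. A diagonal random-walk proposal mixes far too slowly
along this ridge; the sampler therefore adapts the full proposal
covariance to the empirical chain covariance (scaled by $2.38^2/d$)
during burn-in, with a global scale tuned by Robbins–Monro recursion
toward 0.25 acceptance. Both are frozen at the end of burn-in, so the
retained draws come from a fixed, reversible kernel. Convergence is
monitored by the Geweke diagnostic — the z-score comparing the means of
the first 10% and last 50% of the chain with autoregressive
spectral-density-at-zero variance estimates — plus trace inspection;
multi-chain statistics are out of scope. Credible bands for predicted EE
are the pointwise 2.5th/97.5th percentiles of EE re-simulated under each
retained draw.

The likelihood is a sum over groups, so a joint fit shares
$\{K, \lambda\}$ across groups; fitting one group at a time is simply a
one-group observation set.

## The synthetic-study generator

`generate_study()` reproduces the statistical structure of the
calibration and validation experiments: five ad-libitum groups (chow
control; high fat for 4, 7 or 20 weeks before returning to chow; and one
double-switch group), weekly observations of group-mean BW, FM and EI,
independent Gaussian noise at the stated intake standard errors
(0.42–0.55 kcal/d per group) and group-mean body-composition errors of
0.5 g (BW) and 0.4 g (FM). Initial composition is 27 g BW / 4 g FM,
typical of three-month-old C57BL/6 males. Intake levels emulate observed
feeding behavior: 12 kcal/d on chow, 13.5 kcal/d high-fat hyperphagia,
and a one-week voluntary intake crash after each return to chow (6 kcal/d
after early switches; 9.5 kcal/d after the week-20 switch, when the drop
is smaller) followed by recovery to 10–10.5 kcal/d. These values were
fixed once from energy-balance arithmetic so that the simulated design
reproduces the qualitative regimes of interest — slow gain on chow, rapid
gain on high fat, rapid post-switch loss, a transient RQ dip after early
(but not late) switches, and a larger post-switch EE rise at week 20 than
at week 7.

What the generator does *not* emulate: per-animal variation (litter,
cage), autocorrelated intake fluctuations, digestibility differences
between diets, and measurement-occasion effects. Passing parameter
recovery on these data therefore demonstrates the internal consistency of
the calibration machinery at realistic noise levels, not robustness to
the additional structure of real experiments.

The desk-scale recovery experiment in the test suite fits three groups
jointly — the chow control plus the 7-week and 20-week
high-fat-to-chow groups, whose body-weight trajectories span 27–45 g
and so separate $K$ from the activity coefficients — across 20
replicate studies, with 30,000-iteration chains (10,000 burn-in) and a
1 d likelihood step.

## Known limitations

* The model's time scale is days; within-day fed/fasted dynamics are out
  of scope, and RQ is approximate for ~2 days after abrupt diet changes.
* $K$ (and other parameters) are valid for individually housed mice at
  22 °C without running wheels; temperature dependence of thermogenesis
  is not modeled.
* Activity coefficients are diet-indexed constants; spontaneous activity
  changes unrelated to diet must be supplied as schedule events.
* The Ensure-supplemented arm is supported only through a user-composed
  mixed diet specification and $\lambda_H = 0.16$.
* No per-animal stochastic simulation: the dynamics are deterministic
  group means.

## A worked example

```{r example}
p <- model_parameters()
sch <- intake_schedule(c(0, 49, 56), c(13.5, 6, 10),
                       list(diet_high_fat(), diet_chow(), diet_chow()),
                       baseline_EI = 12)
act <- activity_schedule(c(0, 49), c("hf", "chow"))
traj <- simulate_mouse(body_state(4, 23), sch, act, p, horizon = 140)
traj <- annotate_fuel(traj, sch, act, p)
traj[traj$t %in% c(0, 49, 56, 140),
     c("t", "BW", "FM", "EE", "lambda", "RQ", "FQ")]
```
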