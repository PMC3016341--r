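# Shared fixtures and independent oracles used across test files.

default_p <- model_parameters()

# Fixed-point oracle for the implicit EE / tissue-rate system: iterate
# EE -> rates -> EE until convergence. Independent of the closed-form
# solution used by resolve_energy_balance().
fixed_point_rates <- function(FM, FFM, EI, dEI, lambda, p,
                              tol = 1e-12, max_iter = 200) {
  A <- p$alpha_c + p$alpha_d * exp(p$alpha_k * FM)
  EE <- p$K + p$gamma_FFM * FFM + p$gamma_FM * FM + lambda * (FM + FFM) +
    p$beta * dEI
  for (i in seq_len(max_iter)) {
    dFM <- (EI - EE) / (p$rho_FM + A * p$rho_FFM)
    dFFM <- A * dFM
    EE_new <- p$K + p$gamma_FFM * FFM + p$gamma_FM * FM +
      lambda * (FM + FFM) + p$beta * dEI +
      p$eta_FM * dFM + p$eta_FFM * dFFM
    if (abs(EE_new - EE) < tol) break
    EE <- EE_new
  }
  list(EE = EE_new, dFM_dt = dFM, dFFM_dt = dFFM)
}

# Closed-form integral of the partition function (hand antiderivative),
# independent of the quadrature path.
alpha_integral <- function(f1, f2, p = default_p) {
  p$alpha_c * (f2 - f1) +
    p$alpha_d / p$alpha_k * (exp(p$alpha_k * f2) - exp(p$alpha_k * f1))
}

# Forward-Euler reference integrator (pure R) for the FM/FFM system.
euler_simulate <- function(init, intake, activity, p, horizon, dt) {
  n <- ceiling(horizon / dt)
  FM <- init$FM; FFM <- init$FFM
  t <- 0
  for (i in seq_len(n)) {
    h <- min(dt, horizon - t)
    r <- resolve_energy_balance(FM, FFM, ei_at(t, intake),
                                delta_ei_at(t, intake),
                                lambda_at(t, activity), p)
    FM <- FM + h * r$dFM_dt
    FFM <- FFM + h * r$dFFM_dt
    t <- t + h
  }
  list(FM = FM, FFM = FFM)
}

# A small two-group protocol (chow control + 7-week high-fat then chow)
# that identifies all five free parameters; used by the calibration tests.
two_group_protocol <- function() study_protocols()[c("control", "hf7_chow")]
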