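#' Resolve the implicit energy-expenditure / tissue-rate system
#'
#' The energy-balance equation states
#' `EI - EE = rho_FM * dFM/dt + rho_FFM * dFFM/dt`, while the expenditure
#' model states
#' `EE = K + gamma_FFM*FFM + gamma_FM*FM + lambda*BW + beta*dEI
#'      + eta_FM*dFM/dt + eta_FFM*dFFM/dt`,
#' with `dFFM/dt = alpha(FM) * dFM/dt`. Because EE depends on the tissue
#' rates and the rates on EE, the system is implicit; it is linear in
#' `dFM/dt`, so the unique simultaneous solution is available in closed
#' form. Writing `A = alpha(FM)` and
#' `M = K + gamma_FFM*FFM + gamma_FM*FM + lambda*(FM+FFM) + beta*dEI`:
#' \deqn{dFM/dt = (EI - M) / (\rho_{FM} + A\rho_{FFM} + \eta_{FM} +
#'   A\eta_{FFM}),}
#' `dFFM/dt = A * dFM/dt`, and `EE = EI - (rho_FM + A*rho_FFM) * dFM/dt`.
#' Deposition costs carry the sign of the tissue rates, so negative rates
#' (tissue mobilization) reduce EE, and `dEI` may be negative (intake below
#' the chow baseline lowers diet-induced thermogenesis).
#'
#' @param FM,FFM body composition state (g), both > 0
#' @param EI total metabolizable energy intake (kcal/d)
#' @param dEI intake change relative to the chow baseline (kcal/d)
#' @param lambda physical-activity coefficient (kcal/g/d)
#' @param p a `mouse_parameters` object
#' @return A list of class `energy_rates` with elements `EE` (kcal/d),
#'   `dFM_dt`, `dFFM_dt` (g/d) and `components`, a named vector splitting EE
#'   into basal `K`, `gamma_FFM.FFM`, `gamma_FM.FM`, activity `lambda.BW`,
#'   `DIT` and `deposition` (each kcal/d, summing to EE).
#' @export
#' @examples
#' resolve_energy_balance(FM = 4, FFM = 23, EI = 12, dEI = 0, lambda = 0.22)
resolve_energy_balance <- function(FM, FFM, EI, dEI, lambda,
                                   p = model_parameters()) {
  if (FM <= 0 || FFM <= 0) stop("FM and FFM must be positive (g)")
  A <- alpha_fm(FM, p)
  BW <- FM + FFM
  M <- p$K + p$gamma_FFM * FFM + p$gamma_FM * FM + lambda * BW + p$beta * dEI
  denom <- p$rho_FM + A * p$rho_FFM + p$eta_FM + A * p$eta_FFM
  stopifnot(denom > 0)
  dFM <- (EI - M) / denom
  dFFM <- A * dFM
  EE <- EI - (p$rho_FM + A * p$rho_FFM) * dFM
  comp <- c(K = p$K,
            gamma_FFM.FFM = p$gamma_FFM * FFM,
            gamma_FM.FM = p$gamma_FM * FM,
            lambda.BW = lambda * BW,
            DIT = p$beta * dEI,
            deposition = p$eta_FM * dFM + p$eta_FFM * dFFM)
  structure(list(EE = EE, dFM_dt = dFM, dFFM_dt = dFFM, components = comp),
            class = "energy_rates")
}

#' Quarter-power allometric rescaling of specific metabolic rates
#'
#' Basal metabolic rate scales across species as body mass to the 3/4 power
#' (Kleiber's law), so mass-specific metabolic-rate coefficients scale as
#' mass to the -1/4. `rescale_gamma()` maps a reference per-kilogram rate
#' measured at mass `m_ref` to a target mass and converts to per-gram units:
#' `gamma_target = gamma_ref * (m_ref / m_target)^(1/4) / 1000` kcal/g/d.
#'
#' The published mouse coefficients follow from human values of
#' 22 kcal/kg/d (fat-free mass) and 3.6 kcal/kg/d (fat mass) rescaled from
#' a 70 kg human to a 30 g mouse.
#'
#' @param gamma_ref reference specific metabolic rate (kcal/kg/d)
#' @param m_ref_kg reference body mass (kg), default 70 (human)
#' @param m_target_kg target body mass (kg), default 0.030 (mouse)
#' @return specific metabolic rate at the target mass, in kcal/g/d
#' @export
#' @examples
#' rescale_gamma(22)   # ~0.15 kcal/g/d for fat-free mass
#' rescale_gamma(3.6)  # ~0.025 kcal/g/d for fat mass
rescale_gamma <- function(gamma_ref, m_ref_kg = 70, m_target_kg = 0.030) {
  if (m_ref_kg <= 0 || m_target_kg <= 0)
    stop("masses must be positive (kg)")
  gamma_ref * (m_ref_kg / m_target_kg)^0.25 / 1000
}

#' Effective EE-regression coefficients in indirect-calorimetry units
#'
#' Under the expenditure model, regressing total EE on FFM and FM yields
#' slope coefficients `gamma_FFM + lambda` and `gamma_FM + lambda`, since
#' activity cost `lambda*BW = lambda*(FFM + FM)` loads on both masses.
#' Expressed in cal/g/min (the unit customary for mouse indirect
#' calorimetry) these can be compared directly with published regression
#' estimates from calorimetry studies.
#'
#' @param p a `mouse_parameters` object
#' @param lambda_mean the activity coefficient averaged over the diets of
#'   interest (kcal/g/d); default is the chow/high-fat average of the
#'   published values, (0.22 + 0.13)/2
#' @return named vector `c(FFM = , FM = )` in cal/g/min
#' @export
#' @examples
#' ee_coefficients()  # ~0.23 and ~0.14 cal/g/min
ee_coefficients <- function(p = model_parameters(),
                            lambda_mean = (0.22 + 0.13) / 2) {
  kcal_d_to_cal_min <- 1000 / 1440
  c(FFM = (p$gamma_FFM + lambda_mean) * kcal_d_to_cal_min,
    FM = (p$gamma_FM + lambda_mean) * kcal_d_to_cal_min)
}

#' Maintenance energy intake for a body-composition state
#'
#' The intake at which the state is stationary (`dFM/dt = dFFM/dt = 0` and
#' `EE = EI`), assuming the baseline reference equals the maintenance intake
#' itself so the diet-induced thermogenesis term vanishes:
#' `EI_maint = K + gamma_FFM*FFM + gamma_FM*FM + lambda*(FM + FFM)`.
#'
#' @inheritParams resolve_energy_balance
#' @return maintenance EI (kcal/d)
#' @export
maintenance_EI <- function(FM, FFM, lambda, p = model_parameters()) {
  p$K + p$gamma_FFM * FFM + p$gamma_FM * FM + lambda * (FM + FFM)
}
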