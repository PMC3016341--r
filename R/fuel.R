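#' Macronutrient gas-exchange constants
#'
#' Standard indirect-calorimetry constants for the three macronutrients:
#' the respiratory quotient of pure oxidation (`RQ`) and the energy yield
#' per liter of oxygen consumed (`kcal_per_L_O2`). Oxidizing fat, protein
#' and carbohydrate yields 4.686, 4.485 and 5.047 kcal/L O2 at RQs of 0.71,
#' 0.835 and 1.00 respectively.
#'
#' @return A data frame with rows `carb`, `fat`, `prot`.
#' @export
gas_exchange_constants <- function() {
  data.frame(row.names = c("carb", "fat", "prot"),
             RQ = c(1.00, 0.71, 0.835),
             kcal_per_L_O2 = c(5.047, 4.686, 4.485))
}

#' Net macronutrient oxidation rates at a trajectory point
#'
#' Under the average-carbohydrate-balance assumption (glycogen stores are
#' negligible relative to daily carbohydrate intake), the net oxidation
#' rates implied by the macronutrient balances and the body-composition
#' dynamics are
#' \deqn{NetCarbOx = I_C,}
#' \deqn{NetProtOx = I_P - \rho_{FFM}\,dFFM/dt,}
#' \deqn{NetFatOx = I_F - \rho_{FM}\,dFM/dt,}
#' where fat-free-mass change is taken to be body protein plus its
#' associated intracellular water, so its full energy density (1.8 kcal/g)
#' is protein energy. "Net" rates absorb de novo lipogenesis and
#' gluconeogenesis. The three rates sum identically to EE by energy
#' balance.
#'
#' @param I_P,I_F,I_C macronutrient intake rates (kcal/d)
#' @param dFM_dt,dFFM_dt tissue rates of change (g/d)
#' @param p a `mouse_parameters` object
#' @return Named vector `c(NetProtOx, NetFatOx, NetCarbOx)` in kcal/d.
#' @export
net_oxidation <- function(I_P, I_F, I_C, dFM_dt, dFFM_dt,
                          p = model_parameters()) {
  c(NetProtOx = I_P - p$rho_FFM * dFFM_dt,
    NetFatOx = I_F - p$rho_FM * dFM_dt,
    NetCarbOx = I_C)
}

# O2-volume-weighted mean RQ of an energy mix (kcal/d or energy fractions).
rq_of_mix <- function(prot, fat, carb) {
  gc <- gas_exchange_constants()
  vO2 <- c(prot / gc["prot", "kcal_per_L_O2"],
           fat / gc["fat", "kcal_per_L_O2"],
           carb / gc["carb", "kcal_per_L_O2"])
  tot <- sum(vO2)
  if (abs(tot) < 1e-12)
    stop("total oxidation is zero; RQ is undefined")
  sum(vO2 * c(gc["prot", "RQ"], gc["fat", "RQ"], gc["carb", "RQ"])) / tot
}

#' Respiratory quotient from net oxidation rates
#'
#' RQ is the CO2 production rate over the O2 consumption rate. Each
#' macronutrient oxidation rate (kcal/d) is converted to an oxygen
#' consumption via its energy yield per liter O2, and the macronutrient RQs
#' are averaged with these O2-volume weights. Net lipogenesis (negative net
#' fat oxidation) can push RQ above 1.
#'
#' @param fuel named vector with `NetProtOx`, `NetFatOx`, `NetCarbOx`
#'   (kcal/d), as returned by [net_oxidation()]
#' @return RQ (dimensionless)
#' @export
#' @examples
#' compute_RQ(c(NetProtOx = 0, NetFatOx = 0, NetCarbOx = 5))  # 1.0
compute_RQ <- function(fuel) {
  rq_of_mix(fuel[["NetProtOx"]], fuel[["NetFatOx"]], fuel[["NetCarbOx"]])
}

#' Food quotient of a diet
#'
#' The RQ that would be measured had the food been combusted directly: the
#' O2-volume-weighted mean of the macronutrient RQs, weighted by the diet's
#' energy fractions. In energy and macronutrient balance, RQ equals FQ; the
#' standard chow diet gives FQ = 0.92 and the high-fat diet FQ = 0.80 (two
#' decimals).
#'
#' @param diet a `diet_spec`
#' @return FQ (dimensionless)
#' @export
#' @examples
#' compute_FQ(diet_chow())      # 0.921
#' compute_FQ(diet_high_fat())  # 0.802
compute_FQ <- function(diet) {
  if (!inherits(diet, "diet_spec")) stop("'diet' must be a diet_spec")
  rq_of_mix(diet$frac_protein, diet$frac_fat, diet$frac_carb)
}

#' Append fuel-selection columns to a simulated trajectory
#'
#' Computes the net macronutrient oxidation rates, RQ and the diet FQ at
#' every trajectory sample. RQ within `transition_window` days after a
#' schedule discontinuity is flagged approximate (`RQ_approx = TRUE`):
#' the carbohydrate-balance assumption holds on a time scale of several
#' days, so RQ during rapid transitions immediately after a diet switch has
#' slight inaccuracies.
#'
#' @param traj a `mouse_trajectory` from [simulate_mouse()]
#' @param intake the `intake_schedule` used for the simulation
#' @param activity the `activity_schedule` used for the simulation (for
#'   flagging switch transients); optional
#' @param p a `mouse_parameters` object
#' @param transition_window days after a discontinuity during which RQ is
#'   flagged approximate (default 2)
#' @return `traj` with added columns `I_P`, `I_F`, `I_C`, `NetProtOx`,
#'   `NetFatOx`, `NetCarbOx` (kcal/d), `RQ`, `FQ` and logical `RQ_approx`.
#' @export
annotate_fuel <- function(traj, intake, activity = NULL,
                          p = model_parameters(), transition_window = 2) {
  stopifnot(inherits(traj, "mouse_trajectory"),
            inherits(intake, "intake_schedule"))
  n <- nrow(traj)
  I <- matrix(0, n, 3L, dimnames = list(NULL, c("I_P", "I_F", "I_C")))
  fuel <- matrix(0, n, 3L,
                 dimnames = list(NULL, c("NetProtOx", "NetFatOx", "NetCarbOx")))
  RQ <- FQ <- numeric(n)
  for (i in seq_len(n)) {
    d <- diet_at(traj$t[i], intake)
    I[i, ] <- split_intake(ei_at(traj$t[i], intake), d)
    fuel[i, ] <- net_oxidation(I[i, "I_P"], I[i, "I_F"], I[i, "I_C"],
                               traj$dFM_dt[i], traj$dFFM_dt[i], p)
    RQ[i] <- compute_RQ(fuel[i, ])
    FQ[i] <- compute_FQ(d)
  }
  disc <- intake$times
  if (!is.null(activity)) disc <- c(disc, activity$switch_times)
  disc <- sort(unique(disc[disc > 0]))
  approx_flag <- vapply(traj$t, function(t)
    any(t >= disc & t < disc + transition_window), logical(1))
  out <- cbind(as.data.frame(traj), I, fuel,
               data.frame(RQ = RQ, FQ = FQ, RQ_approx = approx_flag))
  class(out) <- c("mouse_trajectory", "data.frame")
  out
}
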