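#' Study protocols mirroring the validation experiment design
#'
#' Five ad-libitum-fed groups of individually housed male C57BL/6 mice:
#' a chow control, and four groups fed the high fat diet for 4, 7 or 20
#' weeks (one with a double switch) before returning to chow. Intake
#' levels emulate the observed feeding behavior: chow maintenance-plus
#' intake of 12 kcal/d, high-fat hyperphagia at 13.5 kcal/d, a one-week
#' voluntary intake crash after each switch back to chow (to 6 kcal/d
#' after early switches, 9.5 kcal/d after the week-20 switch, when the
#' drop of intake is smaller) followed by recovery (10 / 10.5 kcal/d).
#' The chow baseline for diet-induced thermogenesis is 12 kcal/d.
#'
#' @param baseline_EI chow reference intake (kcal/d)
#' @return A list of group protocols, each a list with `name`, `init`
#'   (`body_state`), `intake` (`intake_schedule`), `switch_times`,
#'   `switch_to`, `horizon` (d) and `EI_se` (kcal/d).
#' @export
study_protocols <- function(baseline_EI = 12) {
  chow <- diet_chow(); hf <- diet_high_fat()
  init <- body_state(FM = 4, FFM = 23)
  g <- function(name, times, EI, diets, sw_t, sw_to, horizon, EI_se)
    list(name = name, init = init,
         intake = intake_schedule(times, EI, diets,
                                  baseline_EI = baseline_EI),
         switch_times = sw_t, switch_to = sw_to,
         horizon = horizon, EI_se = EI_se)
  list(
    control = g("control", 0, baseline_EI, list(chow),
                numeric(0), character(0), 140, 0.42),
    hf7_chow = g("hf7_chow", c(0, 49, 56), c(13.5, 6.0, 10.0),
                 list(hf, chow, chow), c(0, 49), c("hf", "chow"), 140, 0.48),
    hf_c_hf_c = g("hf_c_hf_c",
                  c(0, 49, 56, 70, 140, 147),
                  c(13.5, 6.0, 10.0, 13.5, 9.5, 10.5),
                  list(hf, chow, chow, hf, chow, chow),
                  c(0, 49, 70, 140), c("hf", "chow", "hf", "chow"),
                  168, 0.50),
    hf20_chow = g("hf20_chow", c(0, 140, 147), c(13.5, 9.5, 10.5),
                  list(hf, chow, chow), c(0, 140), c("hf", "chow"),
                  168, 0.53),
    hf4_chow = g("hf4_chow", c(0, 28, 35), c(13.5, 6.0, 10.0),
                 list(hf, chow, chow), c(0, 28), c("hf", "chow"), 140, 0.55)
  )
}

#' Generate a synthetic study dataset
#'
#' Simulates ground-truth trajectories for each protocol group under the
#' given "true" free parameters, then adds independent Gaussian
#' measurement noise to the weekly energy-intake, body-weight and fat-mass
#' observations at the configured standard errors. The result has the
#' statistical structure of the calibration/validation experiments and is
#' deterministic under a fixed seed.
#'
#' @param protocol list of group protocols (see [study_protocols()])
#' @param p fixed `mouse_parameters`; `p$K` is part of the truth
#' @param true_theta named truth for the free parameters (defaults:
#'   published values, `K` taken from `p`)
#' @param seed integer seed
#' @param BW_se,FM_se observation standard errors for group-mean body
#'   weight and fat mass (g)
#' @param cadence observation interval (d), default weekly
#' @param dt_truth integration step for the ground truth (d)
#' @return A list of class `synthetic_study`: `groups` (per group: `name`,
#'   `times`, noisy `BW`/`FM`/`EI_obs`, the SEs, `intake_obs` built from
#'   the noisy intake, the true `intake`, `switch_times`/`switch_to`,
#'   `init`, `truth` data frame of noise-free states at observation
#'   times), plus `true_theta`, `seed` and the noise settings.
#' @export
generate_study <- function(protocol = study_protocols(),
                           p = model_parameters(),
                           true_theta = c(K = p$K, lambda_C0 = 0.22,
                                          lambda_H = 0.13, lambda_C1 = 0.27,
                                          lambda_C2 = 0.19),
                           seed = 1, BW_se = 0.5, FM_se = 0.4,
                           cadence = 7, dt_truth = 0.1) {
  set.seed(seed)
  pg <- p; pg$K <- true_theta[["K"]]
  groups <- lapply(protocol, function(g) {
    act <- activity_schedule(g$switch_times, g$switch_to,
                             lambda_C0 = true_theta[["lambda_C0"]],
                             lambda_C1 = true_theta[["lambda_C1"]],
                             lambda_C2 = true_theta[["lambda_C2"]],
                             lambda_H = true_theta[["lambda_H"]],
                             tau = pg$tau)
    times <- seq(0, g$horizon, by = cadence)
    truth <- simulate_fast(g$init, g$intake, act, pg, times = times,
                           dt = dt_truth)
    truth$BW <- truth$FM + truth$FFM
    EI_true <- ei_at(times, g$intake)
    BW_obs <- truth$BW + rnorm(length(times), 0, BW_se)
    FM_obs <- truth$FM + rnorm(length(times), 0, FM_se)
    EI_obs <- pmax(EI_true + rnorm(length(times), 0, g$EI_se), 0.1)
    bp <- utils::head(times, -1L)
    intake_obs <- intake_schedule(
      bp, utils::head(EI_obs, -1L),
      lapply(bp, function(t) diet_at(t, g$intake)),
      baseline_EI = g$intake$baseline_EI)
    list(name = g$name, times = times, BW = BW_obs, FM = FM_obs,
         EI_obs = EI_obs, BW_se = BW_se, FM_se = FM_se, EI_se = g$EI_se,
         intake_obs = intake_obs, intake = g$intake,
         switch_times = g$switch_times, switch_to = g$switch_to,
         init = g$init, truth = truth)
  })
  structure(list(groups = groups, true_theta = true_theta, seed = seed,
                 BW_se = BW_se, FM_se = FM_se, cadence = cadence),
            class = "synthetic_study")
}

#' Convert a synthetic study to an observation set for calibration
#'
#' By default (`intake_intervals = "segment"`) the noisy weekly intake
#' observations are averaged within each interval of the group's
#' protocol intake schedule — the analogue of fitting the measured intake
#' data to a curve before using it as a model input — and each interval's
#' nuisance prior gets standard error `EI_se / sqrt(n)` with `n` the
#' number of weekly observations averaged. `"weekly"` instead uses the
#' raw weekly observations as a piecewise-constant schedule with the full
#' `EI_se` per week. `"true"` uses the noise-free schedule (useful for
#' likelihood-shape checks).
#'
#' @param study a `synthetic_study`
#' @param intake_intervals `"segment"`, `"weekly"` or `"true"`
#' @return An `observation_set`.
#' @export
as_observation_set <- function(study,
                               intake_intervals = c("segment", "weekly",
                                                    "true")) {
  stopifnot(inherits(study, "synthetic_study"))
  intake_intervals <- match.arg(intake_intervals)
  observation_set(lapply(study$groups, function(g) {
    if (intake_intervals == "segment") {
      s <- g$intake
      idx <- pmax(findInterval(g$times, s$times), 1L)
      n_j <- tabulate(idx, nbins = length(s$times))
      EI_mean <- vapply(seq_along(s$times), function(j)
        if (n_j[j] > 0) mean(g$EI_obs[idx == j]) else s$EI[j], numeric(1))
      intake <- intake_schedule(s$times, EI_mean, s$diet,
                                baseline_EI = s$baseline_EI)
      EI_se <- g$EI_se / sqrt(pmax(n_j, 1))
    } else if (intake_intervals == "weekly") {
      intake <- g$intake_obs
      EI_se <- g$EI_se
    } else {
      intake <- g$intake
      EI_se <- g$EI_se
    }
    obs_group(g$name, g$times, g$BW, g$FM, g$BW_se, g$FM_se, EI_se,
              intake = intake, switch_times = g$switch_times,
              switch_to = g$switch_to, init = g$init)
  }))
}

#' Write a synthetic study to disk
#'
#' Writes `obs.csv` (noisy weekly observations, one row per group x time),
#' `truth.csv` (noise-free states) and `protocol.json` (switch protocol,
#' truth parameters, noise levels) into `dir`.
#'
#' @param study a `synthetic_study`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- do.call(rbind, lapply(study$groups, function(g)
    data.frame(group = g$name, time_d = g$times, BW_g = g$BW, FM_g = g$FM,
               EI_kcal_d = g$EI_obs)))
  truth <- do.call(rbind, lapply(study$groups, function(g)
    data.frame(group = g$name, g$truth)))
  write.csv(obs, file.path(dir, "obs.csv"), row.names = FALSE)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  proto <- lapply(study$groups, function(g)
    list(switch_times = g$switch_times, switch_to = g$switch_to,
         EI_se = g$EI_se, init_FM = g$init$FM, init_FFM = g$init$FFM))
  jsonlite::write_json(list(groups = proto,
                            true_theta = as.list(study$true_theta),
                            BW_se = study$BW_se, FM_se = study$FM_se,
                            seed = study$seed),
                       file.path(dir, "protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
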