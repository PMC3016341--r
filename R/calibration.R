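#' Longitudinal observations for one experimental group
#'
#' Bundles the group-mean body weight and fat mass series (with standard
#' errors), the measured intake schedule, the diet-switch protocol and the
#' initial body composition for one group of mice.
#'
#' @param name group label
#' @param times observation times (d), sorted increasing
#' @param BW,FM observed group-mean body weight and fat mass (g)
#' @param BW_se,FM_se standard errors of the group means (g), > 0
#' @param EI_se standard error of the group's energy intake (kcal/d), > 0;
#'   either a scalar or one value per intake-schedule interval (the prior
#'   spread of that interval's nuisance offset)
#' @param intake measured `intake_schedule` for the group
#' @param switch_times,switch_to diet-switch protocol (see
#'   [activity_schedule()]); the activity coefficients themselves are free
#'   parameters supplied at likelihood evaluation
#' @param init initial `body_state`
#' @param tau activity relaxation time constant (d)
#' @return A list of class `obs_group`.
#' @export
obs_group <- function(name, times, BW, FM, BW_se, FM_se, EI_se, intake,
                      switch_times = numeric(0), switch_to = character(0),
                      init, tau = 14) {
  stopifnot(length(times) == length(BW), length(times) == length(FM),
            inherits(intake, "intake_schedule"), inherits(init, "body_state"))
  if (is.unsorted(times, strictly = TRUE))
    stop("observation times must be strictly increasing")
  if (any(c(BW_se, FM_se, EI_se) <= 0))
    stop("all standard errors must be positive")
  if (!length(EI_se) %in% c(1L, length(intake$times)))
    stop("EI_se must be scalar or one value per intake interval")
  EI_se <- rep_len(EI_se, length(intake$times))
  structure(list(name = name, times = times, BW = BW, FM = FM,
                 BW_se = BW_se, FM_se = FM_se, EI_se = EI_se,
                 intake = intake, switch_times = switch_times,
                 switch_to = switch_to, init = init, tau = tau),
            class = "obs_group")
}

#' Observation set across groups
#'
#' @param ... `obs_group` objects (or a single list of them)
#' @return A list of class `observation_set`.
#' @export
observation_set <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1L]], "obs_group")) gs <- gs[[1L]]
  if (!all(vapply(gs, inherits, logical(1), "obs_group")))
    stop("all elements must be obs_group objects")
  names(gs) <- vapply(gs, `[[`, character(1), "name")
  structure(gs, class = "observation_set")
}

free_parameter_names <- function(obs) {
  c("K", "lambda_C0", "lambda_H", "lambda_C1", "lambda_C2",
    unlist(lapply(obs, function(g)
      paste0("eps_", g$name, "_", seq_along(g$intake$times)))))
}

# Activity schedule for a group under candidate activity coefficients.
act_from_theta <- function(theta, g) {
  activity_schedule(g$switch_times, g$switch_to,
                    lambda_C0 = theta[["lambda_C0"]],
                    lambda_C1 = theta[["lambda_C1"]],
                    lambda_C2 = theta[["lambda_C2"]],
                    lambda_H = theta[["lambda_H"]], tau = g$tau)
}

# Shift a piecewise-constant intake schedule by per-interval offsets
# (kcal/d, recycled if scalar); returns NULL if any interval goes negative.
shift_intake <- function(s, eps) {
  EI <- s$EI + eps
  if (any(EI < 0)) return(NULL)
  s$EI <- EI
  s
}

# Extract a group's per-interval EI offsets from theta (zeros if absent).
eps_from_theta <- function(theta, g) {
  nm <- paste0("eps_", g$name, "_", seq_along(g$intake$times))
  eps <- rep(0, length(nm))
  hit <- nm %in% names(theta)
  eps[hit] <- theta[nm[hit]]
  eps
}

#' Log posterior density of the free model parameters
#'
#' Gaussian log-likelihood of the observed group-mean BW and FM series
#' given the trajectory simulated under candidate parameters, at the
#' observation standard errors, summed over groups. Energy-intake
#' measurement uncertainty is propagated by treating the intake on each
#' schedule interval as a nuisance parameter: the offset
#' `eps_<group>_<interval>` (kcal/d) shifts that interval's measured value
#' and carries a Gaussian prior centered at zero with the group's stated
#' intake standard error. Priors on the five structural parameters (`K`,
#' `lambda_C0`, `lambda_H`, `lambda_C1`, `lambda_C2`) are flat on the
#' positive half-line. A failed or out-of-domain simulation yields `-Inf`.
#'
#' @param theta named vector with elements `K`, `lambda_C0`, `lambda_H`,
#'   `lambda_C1`, `lambda_C2` and optionally `eps_<group>_<i>` per intake
#'   interval (missing offsets are taken as 0)
#' @param obs an `observation_set`
#' @param p fixed (non-calibrated) `mouse_parameters`
#' @param dt fixed-step integration step for the likelihood (d)
#' @return log posterior density (scalar; `-Inf` outside the support)
#' @export
log_posterior <- function(theta, obs, p = model_parameters(), dt = 0.5) {
  main <- c("K", "lambda_C0", "lambda_H", "lambda_C1", "lambda_C2")
  if (!all(main %in% names(theta)))
    stop("theta must name: ", paste(main, collapse = ", "))
  if (any(theta[main] <= 0)) return(-Inf)
  lp <- 0
  for (g in obs) {
    eps <- eps_from_theta(theta, g)
    sch <- shift_intake(g$intake, eps)
    if (is.null(sch)) return(-Inf)
    pg <- p; pg$K <- theta[["K"]]
    sim <- tryCatch(
      simulate_fast(g$init, sch, act_from_theta(theta, g), pg,
                    times = g$times, dt = dt),
      error = function(e) NULL)
    if (is.null(sim)) return(-Inf)
    lp <- lp +
      sum(dnorm(g$BW, sim$FM + sim$FFM, g$BW_se, log = TRUE)) +
      sum(dnorm(g$FM, sim$FM, g$FM_se, log = TRUE)) +
      sum(dnorm(eps, 0, g$EI_se, log = TRUE))
  }
  lp
}

# Precomputed numeric views of an observation set for the MCMC inner loop:
# per group the piecewise segment table (with activity kind per segment:
# 0 = baseline chow, 1 = high fat, 2 = post-switch relaxation) so that a
# likelihood evaluation is pure numeric work plus one compiled RK4 call.
# Equivalent to log_posterior(); the equality is covered by tests.
prep_obs_cache <- function(obs, dt) {
  eps_start <- 6L
  out <- lapply(obs, function(g) {
    horizon <- max(g$times)
    # activity kinds are theta-independent; coefficients come from theta
    act0 <- activity_schedule(g$switch_times, g$switch_to, tau = g$tau)
    breaks <- schedule_breaks(g$intake, act0, horizon)
    t0 <- c(0, breaks); t1 <- c(breaks, horizon)
    kind <- integer(length(t0)); tref <- numeric(length(t0))
    if (length(g$switch_times)) {
      idx <- findInterval(t0, g$switch_times)
      has <- idx > 0L
      kind[has] <- ifelse(g$switch_to[idx[has]] == "hf", 1L, 2L)
      tref[has] <- g$switch_times[pmax(idx[has], 1L)]
    }
    list(name = g$name, t0 = t0, t1 = t1,
         EI = ei_at(t0, g$intake), baseline_EI = g$intake$baseline_EI,
         seg_interval = interval_index(t0, g$intake),
         n_eps = length(g$intake$times),
         kind = kind, tref = tref, tau = g$tau, times = g$times,
         FM0 = g$init$FM, FFM0 = g$init$FFM,
         BW = g$BW, FM = g$FM, BW_se = g$BW_se, FM_se = g$FM_se,
         EI_se = g$EI_se, dt = dt)
  })
  for (gi in seq_along(out)) {
    out[[gi]]$eps_idx <- seq.int(eps_start, length.out = out[[gi]]$n_eps)
    eps_start <- eps_start + out[[gi]]$n_eps
  }
  out
}

log_posterior_cached <- function(theta, cache, pvec, dt) {
  if (any(theta[1:5] <= 0)) return(-Inf)
  lp <- 0
  for (gi in seq_along(cache)) {
    g <- cache[[gi]]
    eps <- theta[g$eps_idx]
    EI <- g$EI + eps[g$seg_interval]
    if (any(EI < 0)) return(-Inf)
    lam_a <- c(theta[["lambda_C0"]], theta[["lambda_H"]],
               theta[["lambda_C2"]])[g$kind + 1L]
    lam_b <- ifelse(g$kind == 2L, theta[["lambda_C1"]] - theta[["lambda_C2"]],
                    0)
    pvec[["K"]] <- theta[["K"]]
    m <- sim_rk4(g$FM0, g$FFM0, g$t0, g$t1, EI, EI - g$baseline_EI,
                 lam_a, lam_b, g$tref, g$tau, pvec, dt)
    if (anyNA(m)) return(-Inf)
    FMs <- approx(m[, 1L], m[, 2L], xout = g$times, rule = 2)$y
    FFMs <- approx(m[, 1L], m[, 3L], xout = g$times, rule = 2)$y
    lp <- lp + sum(dnorm(g$BW, FMs + FFMs, g$BW_se, log = TRUE)) +
      sum(dnorm(g$FM, FMs, g$FM_se, log = TRUE)) +
      sum(dnorm(eps, 0, g$EI_se, log = TRUE))
  }
  lp
}

#' Random-walk Metropolis calibration of the free parameters
#'
#' Samples the posterior of `{K, lambda_C0, lambda_H, lambda_C1,
#' lambda_C2}` (plus one energy-intake offset per intake interval and
#' group) with a Gaussian random-walk proposal centered on the current
#' value. Because the intake nuisances make the posterior high-dimensional
#' and strongly correlated with `K` and the activity coefficients, the
#' proposal covariance is adapted during burn-in to the empirical chain
#' covariance (scaled by the usual 2.38^2/d factor), with a global scale
#' tuned by Robbins-Monro recursion toward a target acceptance rate of
#' 0.25; both are frozen at the end of burn-in, preserving detailed
#' balance for the retained draws. After burn-in, every `thin`-th draw is
#' kept. Default chain settings mirror the published calibration (100,000
#' iterations, 30,000 burn-in, keep one fifth).
#'
#' @param obs an `observation_set`
#' @param p fixed `mouse_parameters`
#' @param init optional named starting vector (defaults: published
#'   parameter values, zero intake offsets)
#' @param n_iter total chain length
#' @param burn_in iterations discarded (and used for proposal adaptation)
#' @param thin keep every `thin`-th post-burn-in draw
#' @param target_accept acceptance rate targeted during adaptation
#' @param seed integer seed for reproducibility (chains are bit-identical
#'   under a fixed seed)
#' @param dt likelihood integration step (d)
#' @return A list of class `mouse_posterior` with elements `draws` (matrix,
#'   retained draws by parameter), `log_post` (vector), `diagnostics`
#'   (list: `acceptance` post-burn-in rate, `geweke_z` per parameter,
#'   `proposal_sd`), and `settings`.
#' @export
run_metropolis <- function(obs, p = model_parameters(), init = NULL,
                           n_iter = 100000, burn_in = 30000, thin = 5,
                           target_accept = 0.25, seed = NULL, dt = 0.5) {
  stopifnot(inherits(obs, "observation_set"), burn_in < n_iter)
  if (!is.null(seed)) set.seed(seed)
  pn <- free_parameter_names(obs)
  theta <- setNames(numeric(length(pn)), pn)
  theta[c("K", "lambda_C0", "lambda_H", "lambda_C1", "lambda_C2")] <-
    c(p$K, 0.22, 0.13, 0.27, 0.19)
  if (!is.null(init)) theta[names(init)] <- init
  # per-parameter relative proposal scales; one global factor is adapted
  rel <- setNames(pmax(abs(theta) * 0.05, 0.005), pn)
  rel[grep("^eps_", pn)] <- unlist(lapply(obs, function(g)
    rep_len(g$EI_se / 2, length(g$intake$times))))
  log_s <- 0

  cache <- prep_obs_cache(obs, dt)
  pvec <- unclass(validate_parameters(p))[c("rho_FM", "rho_FFM", "gamma_FM",
                                            "gamma_FFM", "eta_FM", "eta_FFM",
                                            "beta", "K", "alpha_c", "alpha_d",
                                            "alpha_k")]
  lp <- log_posterior_cached(theta, cache, pvec, dt)
  if (!is.finite(lp))
    stop("log posterior is -Inf at the starting point; check init")
  d <- length(pn)
  n_keep <- (n_iter - burn_in) %/% thin
  draws <- matrix(NA_real_, n_keep, d, dimnames = list(NULL, pn))
  lps <- numeric(n_keep)
  n_acc_post <- 0L
  kept <- 0L
  # proposal: theta + exp(log_s) * t(R) %*% z with R the Cholesky factor of
  # the adapted covariance; starts diagonal, switches to the scaled
  # empirical chain covariance once enough burn-in history has accrued
  R <- diag(rel)
  mu <- theta
  M2 <- matrix(0, d, d)
  refresh <- max(500L, d * 10L)
  for (i in seq_len(n_iter)) {
    prop <- theta + exp(log_s) * drop(crossprod(R, rnorm(d)))
    lp_prop <- log_posterior_cached(prop, cache, pvec, dt)
    a <- min(1, exp(lp_prop - lp))
    if (runif(1) < a) {
      theta <- prop
      lp <- lp_prop
      if (i > burn_in) n_acc_post <- n_acc_post + 1L
    }
    if (i <= burn_in) {
      log_s <- log_s + i^-0.6 * (a - target_accept)
      delta <- theta - mu
      mu <- mu + delta / i
      M2 <- M2 + tcrossprod(delta, theta - mu)
      if (i %% refresh == 0L && i >= 4L * d) {
        S <- (M2 / (i - 1L)) * (2.38^2 / d) + diag(1e-8 * rel^2, d)
        Rn <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(Rn)) R <- Rn
      }
    } else if ((i - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- theta
      lps[kept] <- lp
    }
  }
  acc <- n_acc_post / (n_iter - burn_in)
  if (acc < 0.02 || acc > 0.98)
    warning(sprintf("post-adaptation acceptance rate %.3f is degenerate; ",
                    acc), "inspect the chain")
  gz <- apply(draws, 2L, function(x)
    tryCatch(geweke_z(x), error = function(e) NA_real_))
  structure(list(draws = draws, log_post = lps,
                 diagnostics = list(acceptance = acc, geweke_z = gz,
                                    proposal_sd = exp(log_s) * rel),
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 thin = thin, target_accept = target_accept,
                                 seed = seed, dt = dt)),
            class = "mouse_posterior")
}

#' @export
print.mouse_posterior <- function(x, ...) {
  cat(sprintf("Metropolis posterior: %d retained draws, acceptance %.2f\n",
              nrow(x$draws), x$diagnostics$acceptance))
  print(round(t(apply(x$draws, 2L, quantile,
                      probs = c(0.025, 0.5, 0.975))), 4))
  invisible(x)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2` via a z-score, using spectral-density-at-zero estimates of
#' the segment variances (autoregressive fit, Yule-Walker) to account for
#' autocorrelation. |z| above ~2-3 indicates the early chain has not
#' converged to the late chain's distribution.
#'
#' @param x numeric vector of draws for one parameter (length >= 100)
#' @param frac1 leading fraction (default 0.1)
#' @param frac2 trailing fraction (default 0.5)
#' @return z-score (scalar)
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 100L) stop("chain too short for the Geweke diagnostic (need >= 100)")
  if (var(x) == 0) stop("degenerate (constant) chain; z is undefined")
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  (mean(a) - mean(b)) / sqrt(spectrum0(a) / length(a) +
                             spectrum0(b) / length(b))
}

# Spectral density at frequency zero via a Yule-Walker AR fit (order by
# AIC); falls back to the sample variance for white-noise-like segments.
spectrum0 <- function(x) {
  if (var(x) == 0) return(0)
  fit <- tryCatch(ar.yw(x, aic = TRUE, demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || fit$order == 0L) return(var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Posterior credible band for predicted energy expenditure
#'
#' For each retained posterior draw, re-simulates the model and evaluates
#' EE at the requested times; returns the pointwise 2.5th and 97.5th
#' percentiles across draws (the 95% credible band), per group.
#'
#' @param post a `mouse_posterior`
#' @param obs the `observation_set` the posterior was fit to
#' @param times prediction times (d); default each group's observation
#'   times
#' @param p fixed `mouse_parameters`
#' @param max_draws cap on the number of draws used (draws are subsampled
#'   evenly above this); default 500
#' @param dt integration step (d)
#' @return Named list (one element per group) of data frames with columns
#'   `t`, `EE_lower`, `EE_median`, `EE_upper` (kcal/d).
#' @export
predict_EE_interval <- function(post, obs, times = NULL,
                                p = model_parameters(), max_draws = 500,
                                dt = 0.5) {
  stopifnot(inherits(post, "mouse_posterior"),
            inherits(obs, "observation_set"))
  nd <- nrow(post$draws)
  if (nd < 100L) stop("need at least 100 retained draws for a credible band")
  use <- if (nd > max_draws) round(seq(1L, nd, length.out = max_draws)) else
    seq_len(nd)
  out <- list()
  for (g in obs) {
    tt <- if (is.null(times)) g$times else times
    EE <- matrix(NA_real_, length(use), length(tt))
    for (j in seq_along(use)) {
      theta <- post$draws[use[j], ]
      eps <- eps_from_theta(theta, g)
      sch <- shift_intake(g$intake, eps)
      pg <- p; pg$K <- theta[["K"]]
      act <- act_from_theta(theta, g)
      sim <- simulate_fast(g$init, sch, act, pg, times = tt, dt = dt)
      lam <- lambda_at(tt, act)
      for (k in seq_along(tt))
        EE[j, k] <- resolve_energy_balance(sim$FM[k], sim$FFM[k],
                                           ei_at(tt[k], sch),
                                           delta_ei_at(tt[k], sch),
                                           lam[k], pg)$EE
    }
    qs <- apply(EE, 2L, quantile, probs = c(0.025, 0.5, 0.975))
    out[[g$name]] <- data.frame(t = tt, EE_lower = qs[1L, ],
                                EE_median = qs[2L, ], EE_upper = qs[3L, ])
  }
  out
}
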