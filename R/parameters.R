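#' Model parameters for the mouse energy-balance model
#'
#' Constructs the full parameter set of the energy-balance model. Defaults
#' are the published values for individually housed adult male C57BL/6 mice
#' at 22 degrees C. All internal units are g, d, kcal.
#'
#' @param rho_FM energy density of fat-mass change (kcal/g)
#' @param rho_FFM energy density of fat-free-mass change (kcal/g)
#' @param gamma_FM metabolic rate per gram fat mass (kcal/g/d)
#' @param gamma_FFM metabolic rate per gram fat-free mass (kcal/g/d)
#' @param eta_FM fat deposition cost (kcal/g)
#' @param eta_FFM fat-free-mass deposition cost (kcal/g)
#' @param beta diet-induced thermogenesis fraction (dimensionless, in \[0,1))
#' @param K basal thermogenesis rate (kcal/d); a free (calibrated) parameter
#' @param alpha_c,alpha_d,alpha_k shape constants of the body-composition
#'   partition function `alpha(FM) = alpha_c + alpha_d * exp(alpha_k * FM)`;
#'   `alpha_k` has units 1/g, the other two are dimensionless
#' @param tau physical-activity relaxation time constant (d)
#'
#' @return A validated object of class `mouse_parameters` (named list).
#' @seealso [validate_parameters()], [alpha_fm()], [resolve_energy_balance()]
#' @export
#' @examples
#' p <- model_parameters()
#' p$rho_FM
model_parameters <- function(rho_FM = 9.4, rho_FFM = 1.8,
                             gamma_FM = 0.03, gamma_FFM = 0.15,
                             eta_FM = 0.18, eta_FFM = 0.23,
                             beta = 0.4, K = 2.1,
                             alpha_c = 0.1, alpha_d = 1.89e-4,
                             alpha_k = 0.45, tau = 14) {
  p <- list(rho_FM = rho_FM, rho_FFM = rho_FFM,
            gamma_FM = gamma_FM, gamma_FFM = gamma_FFM,
            eta_FM = eta_FM, eta_FFM = eta_FFM,
            beta = beta, K = K,
            alpha_c = alpha_c, alpha_d = alpha_d, alpha_k = alpha_k,
            tau = tau)
  class(p) <- "mouse_parameters"
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks sign and range invariants of a `mouse_parameters` object: all
#' energy densities, metabolic-rate coefficients, deposition costs, `K` and
#' `tau` must be strictly positive; `beta` must lie in \[0, 1).
#'
#' @param p a `mouse_parameters` object (or plain named list with the same
#'   fields)
#' @return `p`, invisibly classed as `mouse_parameters`, if valid; otherwise
#'   an error is raised naming the offending field.
#' @export
validate_parameters <- function(p) {
  needed <- c("rho_FM", "rho_FFM", "gamma_FM", "gamma_FFM", "eta_FM",
              "eta_FFM", "beta", "K", "alpha_c", "alpha_d", "alpha_k", "tau")
  missing <- setdiff(needed, names(p))
  if (length(missing))
    stop("parameter set is missing fields: ", paste(missing, collapse = ", "))
  for (f in needed) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  strictly_pos <- c("rho_FM", "rho_FFM", "gamma_FM", "gamma_FFM", "eta_FM",
                    "eta_FFM", "K", "tau")
  for (f in strictly_pos)
    if (p[[f]] <= 0)
      stop("parameter '", f, "' must be strictly positive (got ", p[[f]],
           "); energy densities and rates are in kcal and days")
  if (p$beta < 0 || p$beta >= 1)
    stop("beta (diet-induced thermogenesis fraction) must be in [0, 1), got ",
         p$beta)
  if (p$alpha_c < 0 || p$alpha_d < 0)
    stop("partition-function constants alpha_c and alpha_d must be >= 0")
  class(p) <- "mouse_parameters"
  p
}

#' @export
print.mouse_parameters <- function(x, ...) {
  cat("Mouse energy-balance model parameters (g / d / kcal)\n")
  for (f in names(x)) cat(sprintf("  %-9s %g\n", f, x[[f]]))
  invisible(x)
}

#' Read / write a parameter configuration file
#'
#' Parameters are stored as a flat JSON object keyed by the symbol names
#' used throughout the package (`rho_FM`, `gamma_FFM`, ...). Round-trips are
#' bit-identical: numbers are written at full precision.
#'
#' @param path file path of the JSON document
#' @return `read_parameters()` returns a validated `mouse_parameters`
#'   object; `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_parameters, lapply(as.list(raw), as.numeric))
}

#' @rdname read_parameters
#' @param p a `mouse_parameters` object
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
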