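#' Body-composition partition function alpha(FM)
#'
#' The empirical, time-invariant function coupling fat-free-mass change to
#' fat-mass change in adult male C57BL/6 mice,
#' \deqn{\alpha(FM) = c + d\,e^{k\,FM},}
#' so that \eqn{dFFM/dt = \alpha(FM)\,dFM/dt}. With the default constants
#' (`c = 0.1`, `d = 1.89e-4`, `k = 0.45` 1/g) alpha increases with adiposity:
#' fatter mice accrete proportionally more lean tissue per gram of fat
#' gained. The function was measured on adult mice only, so evaluation is
#' restricted to FM in \[0.1, 60\] g; values outside raise an error rather
#' than extrapolate.
#'
#' @param FM fat mass (g), in \[0.1, 60\]; vectorized
#' @param p a `mouse_parameters` object
#' @return dimensionless dFFM/dFM, same length as `FM`
#' @export
#' @examples
#' alpha_fm(c(5, 20), model_parameters())
alpha_fm <- function(FM, p = model_parameters()) {
  if (!is.numeric(FM) || any(!is.finite(FM)))
    stop("FM must be finite (g)")
  if (any(FM < 0.1 - 1e-12) || any(FM > 60 + 1e-12))
    stop("FM = ", format(FM[which(FM < 0.1 | FM > 60)[1L]]),
         " g is outside the measured partition-function domain [0.1, 60] g")
  p$alpha_c + p$alpha_d * exp(p$alpha_k * FM)
}

#' Integrate the partition function along a fat-mass path
#'
#' Computes the fat-free mass reached when fat mass moves from `FM_start`
#' to `FM_end`, `FFM_end = FFM_start + int_{FM_start}^{FM_end} alpha(f) df`,
#' by adaptive quadrature (absolute tolerance 1e-10). Because alpha depends
#' on FM only, the result is path independent.
#'
#' @param FM_start,FM_end fat mass at the start and end of the path (g)
#' @param FFM_start fat-free mass at the start (g)
#' @param p a `mouse_parameters` object
#' @return `FFM_end` (g)
#' @export
ffm_from_fm_path <- function(FM_start, FM_end, FFM_start,
                             p = model_parameters()) {
  if (FM_start == FM_end) return(FFM_start)
  q <- integrate(function(f) alpha_fm(f, p), lower = FM_start,
                 upper = FM_end, abs.tol = 1e-10, rel.tol = 1e-10)
  if (!is.finite(q$value))
    stop("quadrature of the partition function failed over [",
         FM_start, ", ", FM_end, "] g")
  FFM_start + q$value
}
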