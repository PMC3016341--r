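#' Diet composition specification
#'
#' A diet is described by the fractions of metabolizable energy supplied by
#' protein, fat and carbohydrate. Fractions must be non-negative and sum to
#' one (tolerance 1e-6).
#'
#' @param name diet label (character)
#' @param frac_protein,frac_fat,frac_carb energy fractions (dimensionless)
#' @return An object of class `diet_spec`.
#' @export
#' @examples
#' diet_spec("chow", 0.24, 0.12, 0.64)
diet_spec <- function(name, frac_protein, frac_fat, frac_carb) {
  fr <- c(frac_protein, frac_fat, frac_carb)
  if (!is.numeric(fr) || length(fr) != 3L || any(!is.finite(fr)))
    stop("diet fractions must be three finite numbers")
  if (any(fr < 0))
    stop("diet '", name, "': energy fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-6)
    stop("diet '", name, "': energy fractions must sum to 1 (got ",
         format(sum(fr)), ")")
  structure(list(name = as.character(name),
                 frac_protein = frac_protein,
                 frac_fat = frac_fat,
                 frac_carb = frac_carb),
            class = "diet_spec")
}

#' Standard study diets
#'
#' The two diets of the calibration and validation experiments: standard
#' chow (24% protein / 12% fat / 64% carbohydrate by energy) and the high
#' fat diet (14% / 59% / 27%).
#'
#' @return A `diet_spec`.
#' @export
diet_chow <- function() diet_spec("chow", 0.24, 0.12, 0.64)

#' @rdname diet_chow
#' @export
diet_high_fat <- function() diet_spec("high_fat", 0.14, 0.59, 0.27)

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf("Diet '%s': protein %.0f%% / fat %.0f%% / carb %.0f%% of energy\n",
              x$name, 100 * x$frac_protein, 100 * x$frac_fat,
              100 * x$frac_carb))
  invisible(x)
}

#' Split total energy intake into macronutrient intakes
#'
#' Distributes a metabolizable energy intake rate over protein, fat and
#' carbohydrate in proportion to the diet's energy fractions.
#'
#' @param EI total metabolizable energy intake rate (kcal/d), >= 0
#' @param diet a `diet_spec`
#' @return For scalar `EI`, a named numeric vector `c(I_P, I_F, I_C)` in
#'   kcal/d; for vector `EI`, a matrix with one row per element and columns
#'   `I_P`, `I_F`, `I_C`. Components sum to `EI`.
#' @export
#' @examples
#' split_intake(10, diet_chow())  # 2.4 / 1.2 / 6.4 kcal/d
split_intake <- function(EI, diet) {
  if (!inherits(diet, "diet_spec")) stop("'diet' must be a diet_spec")
  if (!is.numeric(EI) || any(!is.finite(EI)) || any(EI < 0))
    stop("EI must be finite and non-negative (kcal/d)")
  out <- cbind(I_P = EI * diet$frac_protein,
               I_F = EI * diet$frac_fat,
               I_C = EI * diet$frac_carb)
  if (length(EI) == 1L) out[1L, ] else out
}
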