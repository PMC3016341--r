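#' Metabolizable energy-intake schedule
#'
#' A piecewise time series of total metabolizable energy intake (kcal/d)
#' with the diet fed over each interval. `times[i]` starts the interval on
#' which `EI[i]` and `diet[[i]]` apply; the last interval extends to the end
#' of any simulation. Between breakpoints EI is piecewise-constant by
#' default; `interp = "spline"` instead passes a monotone cubic through the
#' `(times, EI)` points, mirroring the practice of fitting measured intake
#' data to a smooth curve before using it as a model input.
#'
#' `baseline_EI` is the reference chow intake used for the diet-induced
#' thermogenesis term (`dEI = EI(t) - baseline_EI`). If omitted it defaults
#' to the mean EI over the leading chow intervals; schedules that start on
#' a non-chow diet must supply it explicitly.
#'
#' @param times interval start times (d), strictly increasing, first = 0
#' @param EI total metabolizable intake per interval (kcal/d), >= 0
#' @param diet a single `diet_spec` or a list of one per interval
#' @param baseline_EI reference chow intake (kcal/d) for the DIT term
#' @param interp `"constant"` (default) or `"spline"`
#' @return An object of class `intake_schedule`.
#' @export
#' @examples
#' sch <- intake_schedule(c(0, 49), c(12, 13.5),
#'                        list(diet_chow(), diet_high_fat()))
#' ei_at(c(10, 60), sch)
intake_schedule <- function(times, EI, diet, baseline_EI = NULL,
                            interp = c("constant", "spline")) {
  interp <- match.arg(interp)
  if (length(times) != length(EI))
    stop("times and EI must have equal length")
  if (length(times) == 0L) stop("schedule must have at least one interval")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing (d)")
  if (times[1L] != 0) stop("the schedule must start at t = 0")
  if (any(!is.finite(EI)) || any(EI < 0))
    stop("EI must be finite and >= 0 (kcal/d)")
  if (inherits(diet, "diet_spec")) diet <- rep(list(diet), length(times))
  if (!is.list(diet) || length(diet) != length(times) ||
      !all(vapply(diet, inherits, logical(1), "diet_spec")))
    stop("diet must be a diet_spec or a list of diet_spec, one per interval")
  if (is.null(baseline_EI)) {
    chow_lead <- cumprod(vapply(diet, function(d) d$name == "chow",
                                logical(1))) == 1
    if (!any(chow_lead))
      stop("schedule does not start on chow; supply baseline_EI explicitly")
    baseline_EI <- mean(EI[chow_lead])
  }
  if (!is.finite(baseline_EI) || baseline_EI < 0)
    stop("baseline_EI must be finite and >= 0 (kcal/d)")
  s <- list(times = as.numeric(times), EI = as.numeric(EI), diet = diet,
            baseline_EI = baseline_EI, interp = interp)
  if (interp == "spline")
    s$spline <- splinefun(times, EI, method = "monoH.FC")
  class(s) <- "intake_schedule"
  s
}

interval_index <- function(t, s) {
  pmax(findInterval(t, s$times), 1L)
}

#' Evaluate an intake schedule
#'
#' `ei_at()` returns total EI(t); `delta_ei_at()` returns
#' `EI(t) - baseline_EI`, the intake change driving diet-induced
#' thermogenesis; `diet_at()` returns the `diet_spec` fed at `t` (scalar
#' `t` only); `macro_intake_at()` returns the protein/fat/carbohydrate
#' intakes at `t`.
#'
#' @param t time (d); vectorized except for `diet_at()`
#' @param s an `intake_schedule`
#' @return kcal/d values (or a `diet_spec` / named intake vector).
#' @export
ei_at <- function(t, s) {
  stopifnot(inherits(s, "intake_schedule"))
  if (s$interp == "spline") {
    # clamp outside the data range to the boundary values
    pmax(s$spline(pmin(pmax(t, s$times[1L]), max(s$times))), 0)
  } else {
    s$EI[interval_index(t, s)]
  }
}

#' @rdname ei_at
#' @export
delta_ei_at <- function(t, s) ei_at(t, s) - s$baseline_EI

#' @rdname ei_at
#' @export
diet_at <- function(t, s) {
  stopifnot(inherits(s, "intake_schedule"), length(t) == 1L)
  s$diet[[interval_index(t, s)]]
}

#' @rdname ei_at
#' @export
macro_intake_at <- function(t, s) {
  split_intake(ei_at(t, s), diet_at(t, s))
}

#' @export
print.intake_schedule <- function(x, ...) {
  cat(sprintf("Intake schedule: %d interval(s), baseline EI %.2f kcal/d, %s EI\n",
              length(x$times), x$baseline_EI, x$interp))
  for (i in seq_along(x$times))
    cat(sprintf("  t >= %5.1f d: %5.2f kcal/d of '%s'\n", x$times[i],
                x$EI[i], x$diet[[i]]$name))
  invisible(x)
}

#' Read an intake schedule from CSV
#'
#' The CSV must have columns `time_d`, `EI_kcal_d` and `diet_name`; diet
#' definitions are looked up by name in `diets` (defaults to the standard
#' chow and high-fat study diets).
#'
#' @param path CSV file path
#' @param diets named list of `diet_spec` objects
#' @param baseline_EI,interp passed to [intake_schedule()]
#' @return An `intake_schedule`.
#' @export
read_intake_csv <- function(path,
                            diets = list(chow = diet_chow(),
                                         high_fat = diet_high_fat()),
                            baseline_EI = NULL, interp = "constant") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_d", "EI_kcal_d", "diet_name")
  if (!all(needed %in% names(d)))
    stop("intake CSV must have columns: ", paste(needed, collapse = ", "))
  unknown <- setdiff(unique(d$diet_name), names(diets))
  if (length(unknown))
    stop("unknown diet name(s) in CSV: ", paste(unknown, collapse = ", "))
  intake_schedule(d$time_d, d$EI_kcal_d, lapply(d$diet_name, function(n) diets[[n]]),
                  baseline_EI = baseline_EI, interp = interp)
}
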