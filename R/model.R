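# Canonical parameter names of the six-component model.
# Compartments: 3 absorption delay, 4 hepatocytes, 5 plasma, 6 larger
# exchangeable store, 7 smaller exchangeable pool, 8 nonexchangeable tissue
# delay; 0/10 are losses.
.RATE_NAMES  <- c("L(4,3)", "L(0,3)", "L(5,4)", "L(6,5)", "L(7,5)",
                  "L(5,6)", "L(5,7)", "L(10,6)", "L(8,5)", "L(10,8)")
.DELAY_NAMES <- c("DT(3)", "DT(8)")
.DEFAULT_STATUS <- c(
  "DT(3)" = "adjustable", "L(5,4)" = "adjustable", "L(6,5)" = "adjustable",
  "L(7,5)" = "adjustable", "L(5,6)" = "adjustable", "L(5,7)" = "adjustable",
  "L(10,6)" = "adjustable",
  "L(4,3)" = "fixed", "L(0,3)" = "fixed", "L(8,5)" = "fixed",
  "L(10,8)" = "fixed", "DT(8)" = "fixed")

#' Construct a six-component whole-body retinol kinetics model
#'
#' Builds and validates the model used throughout the package: an absorption
#' delay (component 3) feeding hepatocytes (compartment 4), plasma (5)
#' exchanging with a larger storage pool (6) and a smaller extravascular pool
#' (7), and an irreversible route through a nonexchangeable tissue delay (8).
#' Irreversible losses leave via the unabsorbed split `L(0,3)`, via `L(10,6)`
#' from the large store, and via component 8 (`L(10,8)` fixed at 1).
#'
#' `L(4,3)` and `L(0,3)` are split *fractions* applied when the dose exits the
#' absorption delay (they must sum to 1); all other `L(I,J)` are fractional
#' transfer coefficients in 1/day. Delay times are in days.
#'
#' @param rates named numeric vector of fractional transfer coefficients;
#'   required names: `r paste0('\x60', .RATE_NAMES, '\x60', collapse = ", ")`.
#' @param delays named numeric vector with `DT(3)` and `DT(8)`, in days.
#' @param status named character vector mapping parameter names to
#'   `"fixed"` or `"adjustable"`; defaults to the conventional split
#'   (absorption fractions, `L(8,5)`, `L(10,8)` and `DT(8)` fixed).
#' @return an object of class `va_model`.
#' @examples
#' m <- va_group("bangladesh")$model
#' m
#' @export
va_model <- function(rates, delays, status = NULL) {
  rates <- unlist(rates); delays <- unlist(delays)
  missing_r <- setdiff(.RATE_NAMES, names(rates))
  missing_d <- setdiff(.DELAY_NAMES, names(delays))
  if (length(missing_r) || length(missing_d))
    stop("missing model parameters: ",
         paste(c(missing_r, missing_d), collapse = ", "))
  rates <- rates[.RATE_NAMES]; delays <- delays[.DELAY_NAMES]
  if (any(!is.finite(rates)) || any(!is.finite(delays)))
    stop("non-finite model parameters")
  if (any(rates < 0))
    stop("negative fractional transfer coefficient: ",
         paste(names(rates)[rates < 0], collapse = ", "))
  if (any(delays <= 0)) stop("delay times must be positive")
  if (abs(rates[["L(4,3)"]] + rates[["L(0,3)"]] - 1) > 1e-8)
    stop("absorption split fractions L(4,3) + L(0,3) must sum to 1")
  if (abs(rates[["L(10,8)"]] - 1) > 1e-8)
    stop("L(10,8) must be 1 (component 8 is a pure pass-through delay)")
  st <- .DEFAULT_STATUS
  if (!is.null(status)) {
    bad <- setdiff(names(status), names(st))
    if (length(bad)) stop("unknown parameter in status: ",
                          paste(bad, collapse = ", "))
    if (!all(status %in% c("fixed", "adjustable")))
      stop("status values must be 'fixed' or 'adjustable'")
    st[names(status)] <- status
  }
  structure(list(rates = rates, delays = delays, status = st),
            class = "va_model")
}

#' @export
print.va_model <- function(x, ...) {
  cat("Six-component whole-body retinol kinetics model\n")
  cat("  Fractional transfer coefficients (1/d):\n")
  for (nm in names(x$rates))
    cat(sprintf("    %-8s %-10.4g [%s]\n", nm, x$rates[[nm]],
                x$status[[nm]]))
  cat("  Delay times (d):\n")
  for (nm in names(x$delays))
    cat(sprintf("    %-8s %-10.4g [%s]\n", nm, x$delays[[nm]],
                x$status[[nm]]))
  invisible(x)
}

# Flat named parameter vector (short names) used by the numerical core.
.pvec <- function(model) {
  r <- model$rates; d <- model$delays
  c(DT3 = d[["DT(3)"]], DT8 = d[["DT(8)"]],
    L43 = r[["L(4,3)"]], L03 = r[["L(0,3)"]], L54 = r[["L(5,4)"]],
    L65 = r[["L(6,5)"]], L75 = r[["L(7,5)"]], L56 = r[["L(5,6)"]],
    L57 = r[["L(5,7)"]], L106 = r[["L(10,6)"]], L85 = r[["L(8,5)"]])
}

# Inverse of .pvec: build a va_model from a short-name vector.
.pvec_model <- function(p, status = NULL) {
  va_model(
    rates = c("L(4,3)" = p[["L43"]], "L(0,3)" = p[["L03"]],
              "L(5,4)" = p[["L54"]], "L(6,5)" = p[["L65"]],
              "L(7,5)" = p[["L75"]], "L(5,6)" = p[["L56"]],
              "L(5,7)" = p[["L57"]], "L(10,6)" = p[["L106"]],
              "L(8,5)" = p[["L85"]], "L(10,8)" = 1),
    delays = c("DT(3)" = p[["DT3"]], "DT(8)" = p[["DT8"]]),
    status = status)
}

#' Fixed plasma-to-tissue loss rate L(8,5) from intake and plasma pool
#'
#' Under steady state the whole-body disposal rate equals absorbed intake,
#' `absorption_fraction * U(3)`. A stated share of that disposal is routed
#' through the nonexchangeable tissue pathway (component 8); dividing it by
#' the plasma retinol pool gives the fixed fractional rate
#' `L(8,5) = loss_share * absorption_fraction * U(3) / M(5)`.
#'
#' @param intake_u3 adjusted vitamin A intake U(3), µmol RAE/d.
#' @param plasma_pool_m5 plasma retinol pool M(5), µmol.
#' @param absorption_fraction fraction of intake absorbed; default 0.8.
#' @param loss_share share of disposal leaving via component 8; default 0.5.
#' @return L(8,5) in 1/day.
#' @examples
#' compute_l85(1.22, 0.382)  # ~1.28 /d
#' @export
compute_l85 <- function(intake_u3, plasma_pool_m5,
                        absorption_fraction = 0.8, loss_share = 0.5) {
  stopifnot(is.numeric(intake_u3), is.numeric(plasma_pool_m5))
  if (intake_u3 <= 0) stop("intake U(3) must be positive")
  if (plasma_pool_m5 <= 0) stop("plasma pool M(5) must be positive")
  if (absorption_fraction <= 0 || absorption_fraction > 1)
    stop("absorption_fraction must be in (0, 1]")
  if (loss_share < 0 || loss_share > 1)
    stop("loss_share must be in [0, 1]")
  loss_share * absorption_fraction * intake_u3 / plasma_pool_m5
}

#' Build a model from a named parameter table
#'
#' Convenience constructor taking adjustable parameters plus the conventional
#' fixed values in one flat table; thin wrapper over [va_model()].
#'
#' @param parameter_table named numeric vector or list holding `DT(3)`,
#'   `L(5,4)`, `L(6,5)`, `L(7,5)`, `L(5,6)`, `L(5,7)`, `L(10,6)` and `L(8,5)`.
#' @param l43 absorption split fraction into hepatocytes; default 0.8
#'   (`L(0,3)` is its complement).
#' @param dt8_days nonexchangeable-tissue delay, days; default 75 min.
#' @return a `va_model`.
#' @export
build_group_model <- function(parameter_table, l43 = 0.8,
                              dt8_days = 75 / 1440) {
  p <- unlist(parameter_table)
  need <- c("DT(3)", "L(5,4)", "L(6,5)", "L(7,5)", "L(5,6)", "L(5,7)",
            "L(10,6)", "L(8,5)")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter: ", paste(miss, collapse = ", "))
  va_model(
    rates = c(p[setdiff(need, "DT(3)")],
              "L(4,3)" = l43, "L(0,3)" = 1 - l43, "L(10,8)" = 1),
    delays = c("DT(3)" = p[["DT(3)"]], "DT(8)" = dt8_days))
}

# Fitted group parameters and group constants for the three study populations
# (fractional coefficients in 1/d, delays in d, pools in umol, intake in
# umol RAE/d, weight in kg, plasma retinol in umol/L, dose in umol).
.GROUPS <- list(
  bangladesh = list(
    rates = c("L(5,4)" = 2.15, "L(7,5)" = 13.9, "L(5,7)" = 1.59,
              "L(6,5)" = 12.3, "L(5,6)" = 0.0217, "L(10,6)" = 0.00246,
              "L(8,5)" = 1.30),
    dt3 = 0.206, M5 = 0.382, U3 = 1.22,
    weight_kg = 8.4, retinol_umol_l = 0.785),
  philippines = list(
    rates = c("L(5,4)" = 1.22, "L(7,5)" = 3.07, "L(5,7)" = 0.340,
              "L(6,5)" = 12.3, "L(5,6)" = 0.00884, "L(10,6)" = 0.00194,
              "L(8,5)" = 2.21),
    dt3 = 0.206, M5 = 0.462, U3 = 2.56,
    weight_kg = 8.8, retinol_umol_l = 1.02),
  guatemala = list(
    rates = c("L(5,4)" = 1.22, "L(7,5)" = 3.07, "L(5,7)" = 0.340,
              "L(6,5)" = 12.3, "L(5,6)" = 0.00884, "L(10,6)" = 0.00108,
              "L(8,5)" = 1.34),
    dt3 = 0.206, M5 = 0.848, U3 = 2.83,
    weight_kg = 15, retinol_umol_l = 1.24))

#' Fitted group models and constants for the three study populations
#'
#' Returns the published partially-parallel fit for one of the three study
#' groups: the fitted `va_model`, the geometric-mean plasma retinol pool
#' `M5` (µmol), the adjusted vitamin A intake `U3` (µmol RAE/d), mean body
#' weight, mean plasma retinol concentration and the tracer dose (1.17 µmol
#' of labelled retinyl acetate). `pv_slope` is a back-solved proportional
#' plasma-volume coefficient (L/kg), a synthetic calibration chosen so that
#' mean weight and retinol concentration reproduce `M5`; it is a stand-in for
#' the study's plasma-volume regression, which is not published in the main
#' text.
#'
#' @param group one of `"bangladesh"`, `"philippines"`, `"guatemala"`.
#' @return a list of class `va_group`.
#' @examples
#' g <- va_group("guatemala")
#' g$M5
#' @export
va_group <- function(group = c("bangladesh", "philippines", "guatemala")) {
  group <- match.arg(group)
  g <- .GROUPS[[group]]
  model <- build_group_model(c(g$rates, "DT(3)" = g$dt3))
  structure(list(
    label = group, model = model, M5 = g$M5, U3 = g$U3,
    weight_kg = g$weight_kg, retinol_umol_l = g$retinol_umol_l,
    dose_umol = 1.17,
    pv_slope = g$M5 / (g$retinol_umol_l * g$weight_kg)),
    class = "va_group")
}

#' @export
print.va_group <- function(x, ...) {
  cat(sprintf("Study group '%s': M(5) = %.3g umol, U(3) = %.3g umol RAE/d,\n",
              x$label, x$M5, x$U3))
  cat(sprintf("  mean weight %.3g kg, plasma retinol %.3g umol/L, dose %.3g umol\n",
              x$weight_kg, x$retinol_umol_l, x$dose_umol))
  invisible(x)
}
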