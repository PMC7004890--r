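#' Mean transit times of the exchanging compartments
#'
#' The transit time of a compartment is the mean time a retinol molecule
#' spends there per visit: the inverse of its total fractional exit rate,
#' `t(I) = 1 / sum_J L(J,I)`. Plasma: `1/[L(6,5)+L(7,5)+L(8,5)]`; large
#' store: `1/[L(5,6)+L(10,6)]`; small pool: `1/L(5,7)`.
#'
#' @param model a [va_model()].
#' @return named vector `t5_d`, `t5_h`, `t6_d`, `t7_d` (days; plasma also in
#'   hours).
#' @examples
#' transit_times(va_group("bangladesh")$model)["t5_h"]  # ~0.873 h
#' @export
transit_times <- function(model) {
  stopifnot(inherits(model, "va_model"))
  p <- .pvec(model)
  ex5 <- p[["L65"]] + p[["L75"]] + p[["L85"]]
  ex6 <- p[["L56"]] + p[["L106"]]
  ex7 <- p[["L57"]]
  if (ex5 <= 0 || ex6 <= 0 || ex7 <= 0)
    stop("every exchanging compartment needs a positive total exit rate")
  c(t5_d = 1 / ex5, t5_h = 24 / ex5, t6_d = 1 / ex6, t7_d = 1 / ex7)
}

#' Residence times, recycling number and recycling time
#'
#' For a molecule that has just reached plasma, computes the mean total time
#' it will spend in plasma and in each exchangeable pool before irreversible
#' loss, by two independent routes that must agree:
#'
#' * Markov closed forms. Per plasma exit the probability of eventually
#'   returning is
#'   `p = [L(7,5) + L(6,5) L(5,6)/(L(5,6)+L(10,6))] / [L(6,5)+L(7,5)+L(8,5)]`
#'   (the small pool always returns; the large store returns with probability
#'   `L(5,6)/(L(5,6)+L(10,6))`; the tissue route never returns). The plasma
#'   recycling number is the geometric-series mean `nu(5) = p/(1-p)`; plasma
#'   residence `T(5,5) = t(5) (1 + nu(5))`; pool residences
#'   `T(I,5) = L(I,5) T(5,5) t(I)` (number of entries times transit time);
#'   recycling time `tt(5) = [T(6,5)+T(7,5)] / nu(5)`.
#' * Matrix route. The mean-residence-time matrix of the {4,5,6,7} system is
#'   `-A^{-1}`; its column for unit entry into plasma gives every `T(I,5)`
#'   directly, and `nu(5) = T(5,5)/t(5) - 1`.
#'
#' The returned values are the closed forms; the matrix values and the
#' maximum relative discrepancy are attached for verification.
#'
#' @param model a [va_model()].
#' @return object of class `derived_kinetics`: transit times, residence times
#'   `T(5,5)`, `T(6,5)`, `T(7,5)`, system residence `T(SYS)`, recycling
#'   number `nu5`, recycling time `tt5_d`, plus `matrix_residence` and
#'   `max_rel_discrepancy`.
#' @examples
#' residence_kinetics(va_group("bangladesh")$model)$nu5  # ~9.77
#' @export
residence_kinetics <- function(model) {
  stopifnot(inherits(model, "va_model"))
  p <- .pvec(model)
  if (p[["L106"]] <= 0 && p[["L85"]] <= 0)
    stop("closed system: no irreversible loss from plasma or the large store;",
         " residence times are infinite")
  tt <- transit_times(model)
  ex5 <- p[["L65"]] + p[["L75"]] + p[["L85"]]
  ret6 <- p[["L56"]] / (p[["L56"]] + p[["L106"]])
  pret <- (p[["L75"]] + p[["L65"]] * ret6) / ex5
  nu5 <- pret / (1 - pret)
  T55 <- tt[["t5_d"]] * (1 + nu5)
  T65 <- p[["L65"]] * T55 * tt[["t6_d"]]
  T75 <- p[["L75"]] * T55 * tt[["t7_d"]]
  TSYS <- T55 + T65 + T75
  tt5 <- if (nu5 > 0) (T65 + T75) / nu5 else NA_real_

  A <- .amat(p)
  Theta <- tryCatch(solve(-A), error = function(e)
    stop("singular residence-time matrix (closed system)"))
  mres <- Theta %*% c(0, 1, 0, 0)   # unit entry into plasma
  matrix_res <- c("T(5,5)" = mres[2L], "T(6,5)" = mres[3L],
                  "T(7,5)" = mres[4L])
  closed <- c(T55, T65, T75)
  disc <- max(abs(closed - matrix_res) / matrix_res)

  structure(list(
    transit = tt,
    residence = c("T(5,5)" = T55, "T(6,5)" = T65, "T(7,5)" = T75),
    T_sys = TSYS, nu5 = nu5, tt5_d = tt5,
    matrix_residence = matrix_res, max_rel_discrepancy = disc),
    class = "derived_kinetics")
}

#' @export
print.derived_kinetics <- function(x, ...) {
  cat("Derived residence and recycling kinetics\n")
  cat(sprintf("  Transit times: t(5) = %.3g h, t(6) = %.3g d, t(7) = %.3g d\n",
              x$transit[["t5_h"]], x$transit[["t6_d"]], x$transit[["t7_d"]]))
  cat(sprintf("  Residence: T(5,5) = %.3g d, T(6,5) = %.3g d, T(7,5) = %.3g d, T(SYS) = %.3g d\n",
              x$residence[["T(5,5)"]], x$residence[["T(6,5)"]],
              x$residence[["T(7,5)"]], x$T_sys))
  cat(sprintf("  Recycling number nu(5) = %.3g; recycling time = %.3g d\n",
              x$nu5, x$tt5_d))
  cat(sprintf("  Closed-form vs matrix route max rel. discrepancy: %.2e\n",
              x$max_rel_discrepancy))
  invisible(x)
}
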