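#' Retinol isotope dilution coefficients Fa, S and FaS
#'
#' From a simulated tracer response and the steady-state tracee solution,
#' computes the time courses of the RID equation coefficients:
#' `Fa(t) = F(6) + F(7)`, the fraction of the oral dose absorbed and retained
#' in the storage pools; `S(t) = [F(5)/M(5)] / {Fa(t)/[M(6)+M(7)]}`, the
#' plasma-to-stores specific-activity ratio; and their product `FaS`. The two
#' definitions collapse algebraically to
#' `FaS(t) = F(5)(t) * TBS / M(5)`, which is used as an internal identity
#' check. `S` and `FaS` are undefined (masked `NA`) before any tracer has
#' reached the stores.
#'
#' @param model a [va_model()].
#' @param tracee a matching [solve_steady_state()] result.
#' @param times days post-dose; default integer days 4 to 28.
#' @return data.frame of class `rid_coefficients`: `time_d`, `Fa`, `S`,
#'   `FaS`, `SAp` (plasma specific activity `F(5)/M(5)`, fraction of dose
#'   per µmol).
#' @examples
#' g <- va_group("guatemala")
#' rc <- rid_coefficients(g$model, solve_steady_state(g$model, g$M5, g$U3),
#'                        times = 4)
#' rc$FaS  # ~2.93
#' @export
rid_coefficients <- function(model, tracee, times = 4:28) {
  stopifnot(inherits(model, "va_model"), inherits(tracee, "tracee_solution"))
  crv <- simulate_tracer(model, times = times)
  M5 <- tracee$masses[["M(5)"]]
  TBS <- tracee$TBS
  Fa <- crv$F6 + crv$F7
  SAp <- crv$F5 / M5
  S <- ifelse(Fa > 0, SAp / (Fa / TBS), NA_real_)
  out <- data.frame(time_d = times, Fa = Fa, S = S, FaS = Fa * S, SAp = SAp)
  class(out) <- c("rid_coefficients", "data.frame")
  out
}

#' Total body stores from the RID equation
#'
#' Applies `TBS = Fa * S / SAp = FaS / SAp`, where `SAp` is the plasma
#' retinol specific activity measured in an individual (fraction of dose per
#' µmol plasma retinol) and `FaS` is the model-predicted composite
#' coefficient at the same time post-dose.
#'
#' @param fas composite coefficient FaS (dimensionless).
#' @param sap plasma retinol specific activity, 1/µmol (> 0).
#' @return total body stores, µmol.
#' @examples
#' rid_tbs(2, 0.01)  # 200 umol
#' @export
rid_tbs <- function(fas, sap) {
  if (any(!is.finite(fas)) || any(!is.finite(sap)))
    stop("non-finite inputs")
  if (any(sap <= 0)) stop("plasma specific activity must be positive")
  fas / sap
}
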