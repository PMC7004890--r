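.ADJUSTABLE <- c("DT(3)", "L(5,4)", "L(7,5)", "L(5,7)", "L(6,5)", "L(5,6)",
                 "L(10,6)")
.DEFAULT_FIXED <- c("L(4,3)" = 0.8, "L(0,3)" = 0.2, "DT(8)" = 75 / 1440,
                    "L(10,8)" = 1)

#' Composite (super-child) tracer dataset
#'
#' One group's composite isotope-response data: geometric-mean fraction of
#' dose in plasma per (geometric-mean) sampling time, the per-time number of
#' children, fractional-standard-deviation weights, the measured plasma pool
#' `M(5)` and the adjusted vitamin A intake `U(3)` used as a weighted datum.
#' Default weights follow the study convention: FSD 0.05 everywhere except
#' 0.025 at the anchor time (where many more children are sampled).
#'
#' @param group group label.
#' @param time_d strictly increasing positive times, days.
#' @param fdp positive geometric-mean fractions of dose.
#' @param n_children samples per time (default 1).
#' @param fsd per-observation FSD weights; defaults from `anchor`.
#' @param M5 plasma retinol pool, µmol.
#' @param U3 adjusted vitamin A intake, µmol RAE/d.
#' @param intake_fsd FSD weight of the intake datum; default 0.05.
#' @param anchor anchor time (d) receiving FSD 0.025; default 4.
#' @return object of class `composite_dataset`.
#' @export
composite_dataset <- function(group, time_d, fdp, n_children = 1L,
                              fsd = NULL, M5, U3, intake_fsd = 0.05,
                              anchor = 4) {
  if (any(time_d <= 0)) stop("times must be positive")
  if (is.unsorted(time_d, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(fdp <= 0)) stop("FDp values must be positive")
  if (length(fdp) != length(time_d)) stop("time_d and fdp lengths differ")
  if (is.null(fsd)) fsd <- ifelse(abs(time_d - anchor) < 1e-9, 0.025, 0.05)
  if (any(fsd <= 0) || any(n_children < 1)) stop("invalid fsd or n_children")
  if (M5 <= 0 || U3 <= 0) stop("M5 and U3 must be positive")
  structure(list(
    group = as.character(group),
    observations = data.frame(time_d = time_d, fdp = fdp,
                              n_children = as.integer(n_children), fsd = fsd),
    M5 = M5, U3 = U3, intake_fsd = intake_fsd),
    class = "composite_dataset")
}

#' @export
print.composite_dataset <- function(x, ...) {
  cat(sprintf("Composite super-child dataset '%s': %d times, %d samples\n",
              x$group, nrow(x$observations), sum(x$observations$n_children)))
  cat(sprintf("  M(5) = %.4g umol; U(3) = %.4g umol RAE/d (FSD %.3g)\n",
              x$M5, x$U3, x$intake_fsd))
  invisible(x)
}

#' Parameter-sharing map for partially parallel multi-group fits
#'
#' Declares, for every adjustable parameter, whether a single value is shared
#' by all groups, each group has its own value, or only a named subset of
#' groups breaks away from the shared value. The published final model is
#' `sharing_map(independent = "L(10,6)", independent_for =
#' list("L(5,4)" = "bangladesh", "L(7,5)" = "bangladesh",
#' "L(5,7)" = "bangladesh", "L(5,6)" = "bangladesh"))`.
#'
#' @param adjustable adjustable parameter names; default the seven
#'   conventional ones.
#' @param independent parameters estimated independently for every group.
#' @param independent_for named list: parameter -> group labels that get
#'   their own value (the remaining groups share one).
#' @return object of class `sharing_map`.
#' @export
sharing_map <- function(adjustable = .ADJUSTABLE,
                        independent = character(),
                        independent_for = list()) {
  if (anyDuplicated(adjustable)) stop("duplicated adjustable parameter")
  bad <- setdiff(c(independent, names(independent_for)), adjustable)
  if (length(bad))
    stop("not an adjustable parameter: ", paste(bad, collapse = ", "))
  both <- intersect(independent, names(independent_for))
  if (length(both))
    stop("parameter both independent and independent_for: ",
         paste(both, collapse = ", "))
  structure(list(adjustable = adjustable, independent = independent,
                 independent_for = independent_for),
            class = "sharing_map")
}

# One row per estimated parameter instance. group NA = shared instance.
.instances <- function(sharing, labels) {
  rows <- list()
  for (par in sharing$adjustable) {
    if (par %in% sharing$independent) {
      for (g in labels)
        rows[[length(rows) + 1L]] <- data.frame(param = par, group = g)
    } else if (par %in% names(sharing$independent_for)) {
      own <- sharing$independent_for[[par]]
      miss <- setdiff(own, labels)
      if (length(miss)) stop("independent_for names unknown group: ",
                             paste(miss, collapse = ", "))
      for (g in own)
        rows[[length(rows) + 1L]] <- data.frame(param = par, group = g)
      if (length(setdiff(labels, own)))
        rows[[length(rows) + 1L]] <- data.frame(param = par,
                                                group = NA_character_)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(param = par,
                                              group = NA_character_)
    }
  }
  inst <- do.call(rbind, rows)
  inst$instance <- ifelse(is.na(inst$group), inst$param,
                          paste0(inst$param, "[", inst$group, "]"))
  inst
}

# Map a named theta (by instance) to one full short-name parameter vector
# per group. fixed_by_group: named list of named vectors (canonical names).
.expand_theta <- function(theta, inst, labels, fixed_by_group) {
  lapply(stats::setNames(labels, labels), function(g) {
    full <- fixed_by_group[[g]]
    for (par in unique(inst$param)) {
      i <- which(inst$param == par & (is.na(inst$group) | inst$group == g))
      i <- if (any(!is.na(inst$group[i]))) i[!is.na(inst$group[i])] else i
      full[[par]] <- theta[[inst$instance[i[1L]]]]
    }
    c(DT3 = full[["DT(3)"]], DT8 = full[["DT(8)"]],
      L43 = full[["L(4,3)"]], L03 = full[["L(0,3)"]],
      L54 = full[["L(5,4)"]], L65 = full[["L(6,5)"]],
      L75 = full[["L(7,5)"]], L56 = full[["L(5,6)"]],
      L57 = full[["L(5,7)"]], L106 = full[["L(10,6)"]],
      L85 = full[["L(8,5)"]])
  })
}

.fixed_by_group <- function(datasets, fixed, l85) {
  out <- list()
  for (d in datasets) {
    fx <- fixed
    fx[["L(8,5)"]] <- if (!is.null(l85) && d$group %in% names(l85))
      l85[[d$group]] else compute_l85(d$U3, d$M5)
    out[[d$group]] <- fx
  }
  out
}

#' Weighted residual vector of the super-child objective
#'
#' For a candidate parameter set, returns the stacked weighted residuals the
#' fit minimises: for every plasma observation
#' `(y - F5(t)) / (FSD * y)`, and per group one intake residual
#' `(U3 - predicted_intake) / (intake_FSD * U3)`, where the model-predicted
#' intake is `[L(10,6) M(6) + L(8,5) M(5)] / L(4,3)` with `M(6)` from the
#' steady-state balance. The weighted sum of squares is the sum of squared
#' residuals (attached as attribute `wss`, with the plasma-only per-group
#' split as `wss_plasma`).
#'
#' @param theta named numeric vector of adjustable-parameter instances
#'   (natural scale); shared instances named by parameter, group-specific
#'   ones `"param[group]"`.
#' @param datasets list of [composite_dataset()]s (or a single one).
#' @param sharing a [sharing_map()].
#' @param fixed named fixed parameter values common to all groups.
#' @param l85 optional named per-group `L(8,5)` override; by default computed
#'   from each dataset's intake and plasma pool via [compute_l85()].
#' @param include_intake include the intake datum residuals; default TRUE.
#' @return weighted residual vector with attributes `wss` and `wss_plasma`.
#' @export
fit_residuals <- function(theta, datasets, sharing = sharing_map(),
                          fixed = .DEFAULT_FIXED, l85 = NULL,
                          include_intake = TRUE) {
  if (inherits(datasets, "composite_dataset")) datasets <- list(datasets)
  labels <- vapply(datasets, `[[`, "", "group")
  if (anyDuplicated(labels)) stop("duplicated group labels")
  inst <- .instances(sharing, labels)
  miss <- setdiff(inst$instance, names(theta))
  if (length(miss)) stop("theta missing instances: ",
                         paste(miss, collapse = ", "))
  if (any(theta <= 0)) stop("parameters must be positive")
  fbg <- .fixed_by_group(datasets, fixed, l85)
  pv <- .expand_theta(theta, inst, labels, fbg)
  res <- c(); wssp <- stats::setNames(numeric(length(labels)), labels)
  for (d in datasets) {
    p <- pv[[d$group]]
    obs <- d$observations
    pred <- .f5_curve(p, obs$time_d)
    r <- (obs$fdp - pred) / (obs$fsd * obs$fdp)
    wssp[[d$group]] <- sum(r^2)
    if (include_intake) {
      M6 <- p[["L65"]] * d$M5 / (p[["L56"]] + p[["L106"]])
      pred_u <- (p[["L106"]] * M6 + p[["L85"]] * d$M5) / p[["L43"]]
      r <- c(r, (d$U3 - pred_u) / (d$intake_fsd * d$U3))
    }
    res <- c(res, r)
  }
  attr(res, "wss") <- sum(res^2)
  attr(res, "wss_plasma") <- wssp
  res
}

#' Fit the model to one or several composite datasets
#'
#' Weighted nonlinear least squares (Levenberg–Marquardt via
#' [minpack.lm::nls.lm()]) on log-transformed parameters, so every rate and
#' delay stays positive by construction over the four orders of magnitude the
#' parameters span. Several groups are fitted simultaneously under a
#' [sharing_map()] (the partially parallel design); each group's data
#' comprise its plasma observations plus its intake datum. Parameter
#' uncertainty (FSD = SE/estimate) comes from the standard weighted
#' least-squares covariance, the scaled inverse Gauss–Newton Hessian at the
#' optimum; on the log scale the standard error of log(theta) is itself the
#' FSD of theta.
#'
#' @inheritParams fit_residuals
#' @param init named starting values: one value per adjustable parameter
#'   (applied to all its instances) and/or per instance name.
#' @param n_starts number of multistart replicates (log-uniform perturbation
#'   of `init` within a factor of 2); best objective wins. Default 1.
#' @param seed RNG seed for the multistart perturbations (required when
#'   `n_starts > 1`).
#' @param control passed to [minpack.lm::nls.lm.control()]; defaults: maxiter
#'   500, ftol/ptol 1e-10.
#' @return object of class `fit_result`: `estimates` data.frame (instance,
#'   param, group, estimate, se, fsd, poorly_identified), `models` (fitted
#'   [va_model()] per group), `wss`, `wss_plasma`, `dof`, `objective`,
#'   `converged`, `info`, `message`, `singular_covariance`.
#' @export
fit_superchild <- function(datasets, sharing = sharing_map(), init,
                           fixed = .DEFAULT_FIXED, l85 = NULL,
                           include_intake = TRUE, n_starts = 1L, seed = NULL,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-10, ptol = 1e-10)) {
  if (inherits(datasets, "composite_dataset")) datasets <- list(datasets)
  labels <- vapply(datasets, `[[`, "", "group")
  inst <- .instances(sharing, labels)
  theta0 <- stats::setNames(numeric(nrow(inst)), inst$instance)
  for (k in seq_len(nrow(inst))) {
    nm <- inst$instance[k]
    theta0[k] <- if (nm %in% names(init)) init[[nm]]
    else if (inst$param[k] %in% names(init)) init[[inst$param[k]]]
    else stop("no starting value for ", nm)
  }
  if (any(theta0 <= 0)) stop("starting values must be positive")

  starts <- list(log(theta0))
  if (n_starts > 1L) {
    if (is.null(seed)) stop("seed required for multistart")
    set.seed(seed)
    for (k in seq_len(n_starts - 1L))
      starts[[k + 1L]] <- log(theta0) +
        stats::runif(length(theta0), log(0.5), log(2))
  }

  fn <- function(ltheta) {
    as.numeric(fit_residuals(stats::setNames(exp(ltheta), names(theta0)),
                             datasets, sharing, fixed, l85, include_intake))
  }
  best <- NULL
  for (s in starts) {
    f <- minpack.lm::nls.lm(par = s, fn = fn, control = control)
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  fit <- best
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("fit did not converge (info = ", fit$info, "): ", fit$message)

  theta <- stats::setNames(exp(fit$par), names(theta0))
  res <- fit_residuals(theta, datasets, sharing, fixed, l85, include_intake)
  ndata <- length(res)
  dof <- ndata - length(theta)
  sigma2 <- if (dof > 0) attr(res, "wss") / dof else NA_real_

  # covariance of log-theta from a central-difference Jacobian at the optimum
  J <- matrix(0, ndata, length(theta))
  h <- 1e-6
  for (j in seq_along(theta)) {
    lp <- fit$par; lm_ <- fit$par
    lp[j] <- lp[j] + h; lm_[j] <- lm_[j] - h
    J[, j] <- (fn(lp) - fn(lm_)) / (2 * h)
  }
  singular <- FALSE
  se_log <- rep(NA_real_, length(theta))
  cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cv) || any(!is.finite(diag(cv))) || any(diag(cv) < 0)) {
    singular <- TRUE
  } else se_log <- sqrt(diag(cv))

  estimates <- data.frame(
    instance = names(theta), param = inst$param, group = inst$group,
    estimate = unname(theta), se = unname(theta * se_log),
    fsd = unname(se_log))
  estimates$poorly_identified <- is.na(estimates$fsd) | estimates$fsd > 0.5

  fbg <- .fixed_by_group(datasets, fixed, l85)
  pvs <- .expand_theta(theta, inst, labels, fbg)
  models <- lapply(pvs, .pvec_model)

  structure(list(
    estimates = estimates, models = models, theta = theta,
    wss = attr(res, "wss"), wss_plasma = attr(res, "wss_plasma"),
    dof = dof, objective = fit$deviance, converged = converged,
    info = fit$info, message = fit$message, niter = fit$niter,
    singular_covariance = singular, sharing = sharing,
    include_intake = include_intake),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Super-child fit: %s, WSS = %.4g, dof = %d, %d iterations\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$wss, x$dof, x$niter))
  cat("  Plasma WSS per group:",
      paste(sprintf("%s %.3g", names(x$wss_plasma), x$wss_plasma),
            collapse = ", "), "\n")
  print(x$estimates, digits = 4, row.names = FALSE)
  if (x$singular_covariance)
    cat("  NOTE: singular covariance; FSDs unavailable\n")
  invisible(x)
}

#' Parameter-identifiability report
#'
#' Tabulates per-instance FSDs (standard error over estimate) from a fit and
#' flags parameters whose FSD exceeds a threshold as poorly identified, the
#' usual working rule for compartmental fits.
#'
#' @param result a [fit_superchild()] result.
#' @param threshold FSD above which a parameter is flagged; default 0.5.
#' @return data.frame of estimates with logical `poorly_identified`.
#' @export
fsd_report <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "fit_result"))
  out <- result$estimates
  out$poorly_identified <- is.na(out$fsd) | out$fsd > threshold
  out
}
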