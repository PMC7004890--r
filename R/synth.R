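#' Super-child study design
#'
#' Describes a sparse-sampling design: the candidate sampling schedule, the
#' anchor time at which every child (or a stated large count) is sampled, and
#' how children are allotted to the remaining times. With
#' `samples_per_child = 2` every child is sampled at the anchor plus one
#' randomly assigned additional time; with `samples_per_child = 1` each child
#' contributes a single sample and `counts` fixes the number of children per
#' time. When `counts` is not given, children are allocated as evenly as
#' possible over the non-anchor times.
#'
#' @param n_children number of children.
#' @param schedule candidate sampling times, days (6, 9, 12 h encoded as
#'   0.25, 0.375, 0.5 d).
#' @param anchor anchor time, must be in `schedule`; default 4 d.
#' @param samples_per_child 1 or 2.
#' @param counts optional per-time child counts (named by time or aligned
#'   with `schedule`); for two-sample designs the anchor entry must equal
#'   `n_children`.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_children,
                         schedule = c(0.25, 0.375, 0.5, 1, 2, 4, 7, 11, 16,
                                      22, 28),
                         anchor = 4, samples_per_child = 2, counts = NULL) {
  if (!anchor %in% schedule) stop("anchor time must be in the schedule")
  if (!samples_per_child %in% 1:2) stop("samples_per_child must be 1 or 2")
  others <- setdiff(schedule, anchor)
  if (is.null(counts)) {
    if (samples_per_child == 1)
      stop("single-sample designs need explicit per-time counts")
    k <- length(others)
    base <- n_children %/% k; extra <- n_children %% k
    cnt <- stats::setNames(rep(base, k), others)
    if (extra > 0) cnt[seq_len(extra)] <- cnt[seq_len(extra)] + 1L
    counts <- c(stats::setNames(n_children, as.character(anchor)), cnt)
  } else {
    if (is.null(names(counts))) names(counts) <- schedule
    counts <- counts[as.character(schedule)]
    if (any(is.na(counts))) stop("counts must cover every schedule time")
  }
  counts <- counts[order(as.numeric(names(counts)))]
  n_other <- sum(counts[names(counts) != as.character(anchor)])
  if (samples_per_child == 2) {
    if (counts[[as.character(anchor)]] != n_children || n_other != n_children)
      stop("infeasible design: two-sample counts must put every child at the",
           " anchor and exactly one other time")
  } else if (sum(counts) != n_children) {
    stop("infeasible design: per-time counts must sum to n_children")
  }
  structure(list(n_children = as.integer(n_children),
                 schedule = sort(schedule), anchor = anchor,
                 samples_per_child = as.integer(samples_per_child),
                 counts = counts),
            class = "study_design")
}

#' Preset study designs
#'
#' `"philippines"` (n = 120) and `"guatemala"` (n = 135): every child sampled
#' at 4 d plus one randomly assigned time among 6, 9, 12 h and 1, 2, 7, 11,
#' 16, 22, 28 d. `"bangladesh"` (n = 87): one sample per child, 40 children
#' at 4 d, the rest spread evenly over the other 10 times.
#' `"future_design"`: the recommended next-generation design — 60 children,
#' 13 times spanning 5 h to 42 d, anchored at 7 d.
#'
#' @param preset design name.
#' @return a [study_design()].
#' @export
design_preset <- function(preset = c("bangladesh", "philippines", "guatemala",
                                     "future_design")) {
  preset <- match.arg(preset)
  switch(preset,
    philippines = study_design(120, samples_per_child = 2),
    guatemala = study_design(135, samples_per_child = 2),
    bangladesh = {
      sched <- c(0.25, 0.375, 0.5, 1, 2, 4, 7, 11, 16, 22, 28)
      others <- setdiff(sched, 4)
      pool <- 87 - 40
      cnt <- stats::setNames(rep(pool %/% 10, 10), others)
      cnt[seq_len(pool %% 10)] <- cnt[seq_len(pool %% 10)] + 1L
      study_design(87, sched, anchor = 4, samples_per_child = 1,
                   counts = c("4" = 40, cnt))
    },
    future_design = study_design(
      60, schedule = c(5 / 24, 0.5, 1, 2, 4, 7, 10, 14, 18, 24, 30, 36, 42),
      anchor = 7, samples_per_child = 2))
}

#' Plasma volume from body weight
#'
#' Linear-in-weight plasma volume model
#' `PV = coefficients[1] + coefficients[2] * weight`. The coefficients are
#' required configuration: the regression used in the original field studies
#' is not publicly documented, so no default is supplied. The group
#' presets carry a back-solved proportional slope (`va_group()$pv_slope`) as
#' an explicitly synthetic calibration.
#'
#' @param weight_kg body weight, kg (> 0).
#' @param coefficients numeric length 2: intercept (L) and slope (L/kg).
#' @return plasma volume, L.
#' @examples
#' pv_model(8.4, c(0, 0.05))  # 0.42 L
#' @export
pv_model <- function(weight_kg, coefficients) {
  if (missing(coefficients) || length(coefficients) != 2)
    stop("plasma-volume coefficients (intercept, slope) are required")
  if (any(weight_kg <= 0)) stop("weight must be positive")
  pv <- coefficients[1] + coefficients[2] * weight_kg
  if (any(pv <= 0)) stop("coefficients yield nonpositive plasma volume")
  pv
}

#' Generate a synthetic super-child cohort
#'
#' Simulates per-child sparse tracer samples under a [study_design()]: each
#' child draws a body weight, a plasma volume from [pv_model()], a plasma
#' retinol concentration, and its own kinetic parameters (the group truth
#' multiplied by log-normal factors with the stated geometric SDs). The
#' child's true plasma fraction of dose at each assigned time is its own
#' model curve; the observed FDp adds multiplicative log-normal measurement
#' noise. Concentrations follow from FDp, dose and plasma volume, so every
#' record is internally consistent.
#'
#' @param group a [va_group()] (or a list with `label`, `model`, `M5`, `U3`,
#'   `weight_kg`, `retinol_umol_l`, `dose_umol`).
#' @param design a [study_design()].
#' @param pv_coefficients plasma-volume coefficients for [pv_model()]
#'   (required).
#' @param variability named geometric SDs of inter-child parameter
#'   variability (canonical names); default GSD 1.2 on `L(10,6)`, `L(5,6)`,
#'   `L(5,4)`. GSD 1 disables variability.
#' @param noise_cv log-scale SD of multiplicative measurement noise on FDp;
#'   default 0.10.
#' @param weight_cv coefficient of variation of body weight; default 0.12.
#' @param retinol_gsd geometric SD of plasma retinol concentration across
#'   children; default 1.15.
#' @param seed RNG seed (required).
#' @return data.frame of class `child_records`, one row per sample: columns
#'   `child_id`, `weight_kg`, `dose_umol`, `time_nominal_d`, `time_d`,
#'   `c13_retinol_umol_l`, `total_retinol_umol_l`, `plasma_volume_l`, `fdp`,
#'   `pool_umol`; attributes `group`, `U3`, `anchor`, `seed`.
#' @export
generate_children <- function(group, design, pv_coefficients,
                              variability = c("L(10,6)" = 1.2,
                                              "L(5,6)" = 1.2,
                                              "L(5,4)" = 1.2),
                              noise_cv = 0.10, weight_cv = 0.12,
                              retinol_gsd = 1.15, seed) {
  stopifnot(inherits(design, "study_design"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  truth <- .pvec(group$model)
  short <- c("DT(3)" = "DT3", "L(5,4)" = "L54", "L(6,5)" = "L65",
             "L(7,5)" = "L75", "L(5,6)" = "L56", "L(5,7)" = "L57",
             "L(10,6)" = "L106", "L(8,5)" = "L85")
  bad <- setdiff(names(variability), names(short))
  if (length(bad)) stop("variability on unknown parameter: ",
                        paste(bad, collapse = ", "))

  n <- design$n_children
  anchor_chr <- as.character(design$anchor)
  cnt <- design$counts
  if (design$samples_per_child == 2) {
    extra_times <- rep(as.numeric(names(cnt)[names(cnt) != anchor_chr]),
                       cnt[names(cnt) != anchor_chr])
    assigned <- lapply(sample(extra_times), function(t) c(design$anchor, t))
  } else {
    all_times <- rep(as.numeric(names(cnt)), cnt)
    assigned <- as.list(sample(all_times))
  }

  weight <- pmax(stats::rnorm(n, group$weight_kg,
                              weight_cv * group$weight_kg),
                 0.3 * group$weight_kg)
  pvol <- pv_model(weight, pv_coefficients)
  conc <- group$retinol_umol_l *
    exp(stats::rnorm(n, 0, log(retinol_gsd)))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- truth
    for (par in names(variability)) {
      if (variability[[par]] != 1)
        p[[short[[par]]]] <- p[[short[[par]]]] *
          exp(stats::rnorm(1, 0, log(variability[[par]])))
    }
    tms <- sort(assigned[[i]])
    fdp_true <- .f5_curve(p, tms)
    fdp <- fdp_true * exp(stats::rnorm(length(tms), 0, noise_cv))
    rows[[i]] <- data.frame(
      child_id = i, weight_kg = weight[i], dose_umol = group$dose_umol,
      time_nominal_d = tms, time_d = tms,
      c13_retinol_umol_l = fdp * group$dose_umol / pvol[i],
      total_retinol_umol_l = conc[i], plasma_volume_l = pvol[i],
      fdp = fdp, pool_umol = conc[i] * pvol[i])
  }
  out <- do.call(rbind, rows)
  attr(out, "group") <- group$label
  attr(out, "U3") <- group$U3
  attr(out, "anchor") <- design$anchor
  attr(out, "seed") <- seed
  class(out) <- c("child_records", "data.frame")
  out
}

.geomean <- function(x) exp(mean(log(x)))

#' Composite a synthetic cohort into a super-child dataset
#'
#' Groups per-child samples by nominal slot and takes the geometric mean of
#' the actual sampling times and of FDp at each slot, recording the per-slot
#' sample count; the group plasma retinol pool is the geometric mean over all
#' samples. Weights follow the study convention (FSD 0.05; 0.025 at the
#' anchor).
#'
#' @param children a [generate_children()] result (or a data.frame with the
#'   same columns and attributes).
#' @param fsd,anchor_fsd FSD weights off/at the anchor time.
#' @param intake_fsd FSD of the intake datum; default 0.05.
#' @return a [composite_dataset()].
#' @export
composite_children <- function(children, fsd = 0.05, anchor_fsd = 0.025,
                               intake_fsd = 0.05) {
  slots <- sort(unique(children$time_nominal_d))
  if (!length(slots)) stop("no samples to composite")
  tm <- fd <- numeric(length(slots)); nn <- integer(length(slots))
  for (k in seq_along(slots)) {
    sub <- children[children$time_nominal_d == slots[k], ]
    if (!nrow(sub)) stop("empty schedule slot at ", slots[k], " d")
    tm[k] <- .geomean(sub$time_d)
    fd[k] <- .geomean(sub$fdp)
    nn[k] <- nrow(sub)
  }
  anchor <- attr(children, "anchor")
  composite_dataset(
    group = attr(children, "group"), time_d = tm, fdp = fd, n_children = nn,
    fsd = ifelse(abs(slots - anchor) < 1e-9, anchor_fsd, fsd),
    M5 = .geomean(children$pool_umol), U3 = attr(children, "U3"),
    intake_fsd = intake_fsd, anchor = anchor)
}
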