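# Noise-free composite dataset generated directly from a group's model.
exact_dataset <- function(group, times = c(0.25, 0.375, 0.5, 1, 2, 4, 7, 11,
                                           16, 22, 28)) {
  g <- va_group(group)
  fdp <- simulate_tracer(g$model, times = times)$fdp
  composite_dataset(group, times, fdp, M5 = g$M5, U3 = g$U3)
}

adjustable_init <- function(model) {
  c("DT(3)" = model$delays[["DT(3)"]],
    model$rates[c("L(5,4)", "L(7,5)", "L(5,7)", "L(6,5)", "L(5,6)",
                  "L(10,6)")])
}

test_that("residuals vanish at the generating truth on noise-free data", {
  g <- va_group("philippines")
  ds <- exact_dataset("philippines")
  theta <- adjustable_init(g$model)
  r <- fit_residuals(theta, ds, l85 = c(philippines = g$model$rates[["L(8,5)"]]))
  # plasma residuals are exactly zero; the intake residual reflects only the
  # small rounding inconsistency of the printed parameter set
  expect_lt(max(abs(r[1:11])), 1e-9)
  expect_lt(attr(r, "wss"), 1)
  # perturbing L(10,6) by +10% makes the objective strictly positive
  theta2 <- theta; theta2[["L(10,6)"]] <- 1.1 * theta2[["L(10,6)"]]
  r2 <- fit_residuals(theta2, ds,
                      l85 = c(philippines = g$model$rates[["L(8,5)"]]))
  expect_gt(attr(r2, "wss"), attr(r, "wss") + 0.01)
})

test_that("doubling all FSDs rescales the objective without moving the argmin", {
  g <- va_group("guatemala")
  ds1 <- exact_dataset("guatemala")
  obs <- ds1$observations
  ds2 <- composite_dataset("guatemala", obs$time_d, obs$fdp,
                           fsd = 2 * obs$fsd, M5 = ds1$M5, U3 = ds1$U3,
                           intake_fsd = 2 * ds1$intake_fsd)
  theta <- adjustable_init(g$model)
  theta[["L(6,5)"]] <- 1.3 * theta[["L(6,5)"]]
  r1 <- fit_residuals(theta, ds1)
  r2 <- fit_residuals(theta, ds2)
  expect_equal(attr(r1, "wss"), 4 * attr(r2, "wss"))
})

test_that("the anchor-time observation carries 4x the weight", {
  ds <- exact_dataset("bangladesh")
  obs <- ds$observations
  expect_equal(obs$fsd[obs$time_d == 4], 0.025)
  expect_true(all(obs$fsd[obs$time_d != 4] == 0.05))
  # an equal relative residual at 4 d contributes 4x the squared residual
  expect_equal((1 / 0.025)^2 / (1 / 0.05)^2, 4)
})

test_that("noise-free fit recovers truth from a 2x-perturbed start", {
  g <- va_group("philippines")
  ds <- exact_dataset("philippines")
  truth <- adjustable_init(g$model)
  fit <- fit_superchild(ds, init = truth * 2,
                        l85 = c(philippines = g$model$rates[["L(8,5)"]]),
                        include_intake = FALSE)
  expect_true(fit$converged)
  expect_lt(max(rel_err(fit$theta[names(truth)], truth)), 1e-4)
  expect_true(all(fit$estimates$fsd < 1e-3 |
                    is.na(fit$estimates$fsd)))
})

test_that("a fully shared fit on duplicated datasets equals the single fit", {
  g <- va_group("guatemala")
  dsA <- exact_dataset("guatemala")
  dsB <- dsA; dsB$group <- "guatemala2"
  truth <- adjustable_init(g$model)
  init <- truth * 1.5
  l85 <- g$model$rates[["L(8,5)"]]
  single <- fit_superchild(dsA, init = init, l85 = c(guatemala = l85),
                           include_intake = FALSE)
  dup <- fit_superchild(list(dsA, dsB), init = init,
                        l85 = c(guatemala = l85, guatemala2 = l85),
                        include_intake = FALSE)
  expect_equal(unname(dup$theta[names(single$theta)]),
               unname(single$theta), tolerance = 1e-6)
  pa <- retkin:::.pvec(dup$models$guatemala)
  pb <- retkin:::.pvec(dup$models$guatemala2)
  expect_identical(pa, pb)
})

test_that("the partially parallel sharing map lays out instances correctly", {
  sh <- sharing_map(independent = "L(10,6)",
                    independent_for = list("L(5,4)" = "bangladesh",
                                           "L(7,5)" = "bangladesh",
                                           "L(5,7)" = "bangladesh",
                                           "L(5,6)" = "bangladesh"))
  inst <- retkin:::.instances(sh, GROUPS)
  # 2 fully shared + 3 independent + 4 x (bangladesh + shared rest) = 13
  expect_equal(nrow(inst), 13)
  expect_equal(sum(inst$param == "L(10,6)"), 3)
  expect_equal(sum(inst$param == "DT(3)"), 1)
  expect_equal(sum(inst$param == "L(5,4)"), 2)
  expect_error(sharing_map(independent = "L(8,5)"), "not an adjustable")
  expect_error(sharing_map(independent = "L(10,6)",
                           independent_for = list("L(10,6)" = "x")),
               "both")
})

test_that("three-group partially parallel fit recovers all generating models", {
  datasets <- lapply(GROUPS, exact_dataset)
  sh <- sharing_map(independent = "L(10,6)",
                    independent_for = list("L(5,4)" = "bangladesh",
                                           "L(7,5)" = "bangladesh",
                                           "L(5,7)" = "bangladesh",
                                           "L(5,6)" = "bangladesh"))
  init <- adjustable_init(va_group("philippines")$model) * 1.4
  l85 <- vapply(GROUPS, function(g) va_group(g)$model$rates[["L(8,5)"]], 0)
  fit <- fit_superchild(datasets, sh, init = init, l85 = l85,
                        include_intake = FALSE)
  expect_true(fit$converged)
  for (g in GROUPS) {
    truth <- retkin:::.pvec(va_group(g)$model)
    got <- retkin:::.pvec(fit$models[[g]])
    expect_lt(max(rel_err(got, truth)), 1e-3)
  }
})

test_that("a structurally unidentifiable fit raises the singularity flag", {
  # two indistinguishable return rates: with L(10,6) ~ 0 and the store and
  # small pool given identical kinetics, their split is undetermined
  g <- va_group("philippines")
  m <- build_group_model(c(
    "DT(3)" = 0.206, "L(5,4)" = 1.22, "L(7,5)" = 3, "L(5,7)" = 0.01,
    "L(6,5)" = 3, "L(5,6)" = 0.01, "L(10,6)" = 1e-9, "L(8,5)" = 2.21))
  times <- c(0.5, 1, 2, 4, 7, 11, 16, 22, 28)
  fdp <- simulate_tracer(m, times = times)$fdp
  ds <- composite_dataset("toy", times, fdp, M5 = 0.462, U3 = 2.56)
  init <- adjustable_init(m)
  fit <- suppressWarnings(
    fit_superchild(ds, init = init, l85 = c(toy = 2.21),
                   include_intake = FALSE,
                   control = minpack.lm::nls.lm.control(maxiter = 50)))
  rep <- fsd_report(fit)
  expect_true(fit$singular_covariance || any(rep$poorly_identified))
})

test_that("fsd_report flags large uncertainties", {
  g <- va_group("philippines")
  ds <- exact_dataset("philippines")
  fit <- fit_superchild(ds, init = adjustable_init(g$model),
                        l85 = c(philippines = g$model$rates[["L(8,5)"]]),
                        include_intake = FALSE)
  rep <- fsd_report(fit, threshold = 1e-9)
  expect_true(all(rep$poorly_identified | rep$fsd <= 1e-9))
  expect_s3_class(rep, "data.frame")
})
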