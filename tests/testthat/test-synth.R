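test_that("study designs allocate children per the stated patterns", {
  d <- design_preset("bangladesh")
  expect_equal(d$n_children, 87L)
  expect_equal(d$samples_per_child, 1L)
  expect_equal(unname(d$counts[["4"]]), 40)
  others <- d$counts[names(d$counts) != "4"]
  expect_equal(sum(d$counts), 87)
  expect_true(all(others %in% 4:6))

  d2 <- design_preset("philippines")
  expect_equal(d2$n_children, 120L)
  expect_equal(unname(d2$counts[["4"]]), 120)
  expect_equal(sum(d2$counts[names(d2$counts) != "4"]), 120)

  fd <- design_preset("future_design")
  expect_equal(fd$n_children, 60L)
  expect_equal(fd$anchor, 7)
  expect_equal(length(fd$schedule), 13)
  expect_equal(range(fd$schedule), c(5 / 24, 42))

  expect_error(study_design(10, samples_per_child = 1,
                            counts = c("4" = 20)), "every schedule time")
  expect_error(study_design(10, schedule = c(1, 2), anchor = 4), "anchor")
  expect_error(study_design(10, schedule = c(1, 2, 4), anchor = 4,
                            samples_per_child = 1,
                            counts = c("1" = 9, "2" = 9, "4" = 9)),
               "infeasible")
})

test_that("generated per-time counts match the design exactly", {
  g <- va_group("bangladesh")
  ch <- generate_children(g, design_preset("bangladesh"),
                          pv_coefficients = c(0, g$pv_slope), seed = 3)
  counts <- table(ch$time_nominal_d)
  d <- design_preset("bangladesh")
  expect_equal(unname(c(counts[as.character(sort(as.numeric(names(d$counts))))])),
               unname(c(d$counts[as.character(sort(as.numeric(names(d$counts))))])))
  expect_equal(length(unique(ch$child_id)), 87)
  expect_true(all(table(ch$child_id) == 1))

  g2 <- va_group("philippines")
  ch2 <- generate_children(g2, design_preset("philippines"),
                           pv_coefficients = c(0, g2$pv_slope), seed = 3)
  expect_true(all(table(ch2$child_id) == 2))
  expect_equal(sum(ch2$time_nominal_d == 4), 120)
})

test_that("a fixed seed regenerates the cohort bit-identically", {
  g <- va_group("guatemala")
  a <- generate_children(g, design_preset("guatemala"),
                         pv_coefficients = c(0, g$pv_slope), seed = 99)
  b <- generate_children(g, design_preset("guatemala"),
                         pv_coefficients = c(0, g$pv_slope), seed = 99)
  expect_identical(a, b)
  c2 <- generate_children(g, design_preset("guatemala"),
                          pv_coefficients = c(0, g$pv_slope), seed = 100)
  expect_false(identical(a$fdp, c2$fdp))
  expect_error(generate_children(g, design_preset("guatemala"),
                                 pv_coefficients = c(0, g$pv_slope)),
               "seed")
})

test_that("with variability and noise off, every child sits on the group curve", {
  g <- va_group("philippines")
  ch <- generate_children(g, design_preset("philippines"),
                          pv_coefficients = c(0, g$pv_slope),
                          variability = c("L(10,6)" = 1),
                          noise_cv = 0, weight_cv = 0, retinol_gsd = 1,
                          seed = 5)
  truth <- simulate_tracer(g$model, times = sort(unique(ch$time_d)))
  lookup <- setNames(truth$fdp, truth$time_d)
  expect_equal(ch$fdp, unname(lookup[as.character(ch$time_d)]),
               tolerance = 1e-12)
  # and the composite then equals the truth curve at the slot times
  comp <- composite_children(ch)
  expect_equal(comp$observations$fdp,
               unname(lookup[as.character(comp$observations$time_d)]),
               tolerance = 1e-12)
  expect_equal(comp$M5, g$M5, tolerance = 1e-12)
})

test_that("child records are internally consistent", {
  g <- va_group("bangladesh")
  ch <- generate_children(g, design_preset("bangladesh"),
                          pv_coefficients = c(0, g$pv_slope), seed = 21)
  expect_equal(ch$fdp,
               ch$c13_retinol_umol_l * ch$plasma_volume_l / ch$dose_umol)
  expect_equal(ch$pool_umol, ch$total_retinol_umol_l * ch$plasma_volume_l)
  expect_true(all(ch$fdp > 0 & ch$pool_umol > 0 & ch$plasma_volume_l > 0))
})

test_that("geometric-mean compositing is exact on log-normal noise", {
  expect_equal(retkin:::.geomean(c(0.001, 0.004)), 0.002)
  # expected log composite equals log truth: Monte Carlo at n = 1000
  g <- va_group("philippines")
  d <- study_design(1000, schedule = c(2, 4), anchor = 4,
                    samples_per_child = 2)
  ch <- generate_children(g, d, pv_coefficients = c(0, g$pv_slope),
                          variability = c("L(10,6)" = 1), noise_cv = 0.10,
                          weight_cv = 0, retinol_gsd = 1, seed = 8)
  comp <- composite_children(ch)
  truth <- simulate_tracer(g$model, times = comp$observations$time_d)$fdp
  se <- 0.10 / sqrt(comp$observations$n_children)
  expect_true(all(abs(log(comp$observations$fdp) - log(truth)) < 3 * se))
})

test_that("pv_model demands coefficients and is linear in weight", {
  expect_equal(pv_model(8.4, c(0, 0.05)), 0.42)
  expect_equal(pv_model(16.8, c(0, 0.05)), 2 * pv_model(8.4, c(0, 0.05)))
  expect_error(pv_model(8.4), "required")
  expect_error(pv_model(-1, c(0, 0.05)), "positive")
  expect_error(pv_model(8.4, c(0, -0.05)), "nonpositive")
})
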