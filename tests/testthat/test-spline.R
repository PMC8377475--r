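# penalized spline engine: fits, derivative bands, constant runs, monotone

test_that("order-2 penalty reproduces lines and constants exactly", {
  x <- seq(0, 10, length.out = 200)
  f <- fit_pspline(x, 2 * x + 3)
  expect_lt(max(abs(predict(f, x) - (2 * x + 3))), 1e-8)
  fc <- fit_pspline(x, rep(5, 200))
  expect_lt(max(abs(predict(fc, x) - 5)), 1e-8)
  expect_lt(max(abs(predict(fc, x, deriv = 1))), 1e-8)
})

test_that("dense noise-free sinusoid is reproduced within 1% of amplitude", {
  x <- seq(0, 2 * pi, length.out = 400)
  f <- fit_pspline(x, sin(x))
  expect_lt(max(abs(predict(f, x) - sin(x))), 0.01)
})

test_that("input validation: too few points, constant x, domain", {
  expect_error(fit_pspline(1:4, 1:4), "at least 5")
  expect_error(fit_pspline(rep(1, 10), rnorm(10)), "rank deficiency")
  f <- fit_pspline(seq(0, 1, length.out = 50), rnorm(50))
  expect_error(predict(f, 2), "outside the training domain")
  expect_error(derivative_band(f, seq(0, 2, by = 0.5)), "outside")
})

test_that("spline derivative agrees with finite differences of predictions", {
  set.seed(21)
  x <- seq(0, 10, length.out = 150)
  f <- fit_pspline(x, sin(x) + rnorm(150, 0, 0.05))
  g <- seq(0.5, 9.5, length.out = 200)
  h <- 1e-5
  fd <- (predict(f, g + h) - predict(f, g - h)) / (2 * h)
  an <- predict(f, g, deriv = 1)
  expect_equal(an, fd, tolerance = 1e-6)
})

test_that("derivative band: signal vs flat, and modes", {
  x <- seq(0, 10, length.out = 100)
  f <- fit_pspline(x, 2 * x)
  b <- derivative_band(f, x)
  expect_true(all(b$lower > 0))                 # band excludes 0 for y = 2x
  expect_equal(b$estimate, rep(2, 100), tolerance = 1e-6)
  expect_true(all(b$lower <= b$estimate & b$estimate <= b$upper))
  # simulation mode is seed-reproducible and close to analytic
  set.seed(31)
  fn <- fit_pspline(x, 2 * x + rnorm(100, 0, 0.5))
  b1 <- derivative_band(fn, x, mode = "simulation", seed = 5, nsim = 2000)
  b2 <- derivative_band(fn, x, mode = "simulation", seed = 5, nsim = 2000)
  expect_identical(b1, b2)
  ba <- derivative_band(fn, x)
  expect_equal(mean(b1$upper - b1$lower), mean(ba$upper - ba$lower),
               tolerance = 0.1)
  expect_error(derivative_band(fn, x, mode = "simulation"), "seed")
})

test_that("band width shrinks with sample size", {
  width_at <- function(n, seed) {
    set.seed(seed)
    x <- seq(0, 1, length.out = n)
    f <- fit_pspline(x, sin(2 * pi * x) + rnorm(n, 0, 0.1), basis_dim = 15)
    b <- derivative_band(f, seq(0.1, 0.9, length.out = 50))
    mean(b$upper - b$lower)
  }
  expect_lt(width_at(500, 2), width_at(50, 1))
})

test_that("find_constant_runs: filter contract and plateau localization", {
  x <- seq(0, 10, length.out = 100)
  b <- derivative_band(fit_pspline(x, 2 * x), x)
  expect_identical(nrow(find_constant_runs(b)), 0L)
  # ramp-then-plateau, noise-free: exactly one run inside the plateau
  d <- seq(0, 1000, by = 2.49)
  y <- pmin(d / 400, 1) * 30000
  f <- fit_pspline(d, y, basis_dim = 180, penalty_order = 1)
  runs <- find_constant_runs(derivative_band(f, d), min_run_length = 10)
  expect_identical(nrow(runs), 1L)
  expect_gt(runs$start, 400 - 2 * 2.49)   # plateau begins at d = 400
  expect_gt(runs$end, 0.95 * max(d))      # and covers its interior
  # min_run_length larger than any run -> empty
  expect_identical(nrow(find_constant_runs(derivative_band(f, d),
                                           min_run_length = length(d) + 1L)),
                   0L)
})

test_that("monotone fit: inactive and binding constraint, noisy logistic", {
  x <- seq(0, 10, length.out = 60)
  # strictly increasing noise-free data (derivative bounded away from 0):
  # the constraint is inactive and both fits coincide
  fm <- fit_monotone_pspline(x, exp(0.3 * x))
  fu <- fit_pspline(x, exp(0.3 * x))
  expect_equal(predict(fm, x), predict(fu, x), tolerance = 1e-6)
  # decreasing data: fitted curve never decreases (near-constant)
  fd <- fit_monotone_pspline(1:20, 20:1)
  dense <- seq(1, 20, length.out = 500)
  expect_gte(min(diff(predict(fd, dense))), -1e-8 * 19)
  expect_lt(diff(range(predict(fd, dense))), 1e-6 * 19)
  # noisy logistic: predictions within 3 noise sd of truth at sampling dates
  st <- std_season(seed = 3)
  season <- generate_season(st)
  w1 <- season$widths[season$widths$tree == "t1", ]
  f1 <- fit_monotone_pspline(w1$doy, w1$w_incr)
  truth <- logistic(w1$doy, st$asym_incr[1], st$mid_incr[1], st$scale_days[1])
  expect_true(all(abs(predict(f1, w1$doy) - truth) <
                    3 * st$noise_frac * st$asym_incr[1]))
})

test_that("every monotone fit is nondecreasing on a 1-unit grid", {
  set.seed(17)
  for (rep in 1:5) {
    x <- sort(runif(30, 0, 100))
    y <- cumsum(abs(rnorm(30))) + rnorm(30, 0, 2)
    f <- fit_monotone_pspline(x, y)
    g <- seq(ceiling(min(x)), floor(max(x)), by = 1)
    expect_gte(min(diff(predict(f, g))), -1e-8 * diff(range(y)))
  }
})
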