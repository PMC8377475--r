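# heterogeneity correction, seasonal fits, critical dates, durations, rates

test_that("width correction follows the cell-counting formula", {
  s <- data.frame(tree = "a", doy = c(100, 120, 140), w_prev = c(2, 1, 0.5),
                  w_incr = c(10, 10, 10))
  cs <- correct_widths(s)
  m <- mean(c(2, 1, 0.5))
  expect_equal(cs$w_incr, 10 * c(2, 1, 0.5) / m)
  # all w_prev equal -> corrected = observed
  s2 <- data.frame(tree = "a", doy = 1:6 * 10, w_prev = 3,
                   w_incr = c(1, 4, 9, 16, 25, 36))
  expect_equal(correct_widths(s2)$w_incr, s2$w_incr)
  # arithmetic check: w_obs=10, w_prev=2, mean(w_prev)=1 -> w_cor=20
  s3 <- data.frame(tree = "a", doy = 1:3, w_prev = c(2, 0.5, 0.5),
                   w_incr = c(10, 5, 5))
  expect_equal(correct_widths(s3)$w_incr[1], 20)
  expect_error(correct_widths(transform(s3, w_prev = c(2, 0, 1))), "positive")
  # brute-force re-evaluation on a random table, all width columns
  set.seed(41)
  tab <- data.frame(tree = rep(c("a", "b"), each = 8), doy = rep(1:8, 2),
                    w_prev = runif(16, 0.5, 2), w_incr = runif(16, 0, 100),
                    w_maturing = runif(16, 0, 50), w_mat = runif(16, 0, 50))
  ct <- correct_widths(tab)
  for (tr in c("a", "b")) {
    i <- tab$tree == tr
    for (cl in c("w_incr", "w_maturing", "w_mat"))
      expect_equal(ct[[cl]][i],
                   tab[[cl]][i] * tab$w_prev[i] / mean(tab$w_prev[i]))
  }
})

test_that("seasonal fits are monotone, accurate, and shift equivariant", {
  st <- std_season(seed = 2, noise_frac = 0)
  season <- generate_season(st)
  curves <- fit_seasonal_curve(season$widths, "w_incr")
  for (k in 1:4) {
    cv <- curves[[paste0("t", k)]]
    expect_true(all(diff(cv$daily$pred) >= -1e-8 * st$asym_incr[k]))
    truth <- logistic(cv$daily$doy, st$asym_incr[k], st$mid_incr[k],
                      st$scale_days[k])
    expect_lt(max(abs(cv$daily$pred - truth)) / st$asym_incr[k], 0.01)
  }
  # adding a constant shifts predictions by that constant
  w1 <- season$widths[season$widths$tree == "t1", ]
  w1b <- transform(w1, w_incr = w_incr + 500)
  c1 <- fit_seasonal_curve(w1, "w_incr")[["t1"]]
  c1b <- fit_seasonal_curve(w1b, "w_incr")[["t1"]]
  expect_equal(c1b$daily$pred, c1$daily$pred + 500,
               tolerance = 1e-6)
  expect_error(fit_seasonal_curve(w1[1:5, ], "w_incr"), "at least 6")
})

test_that("final width is the median prediction of the last three dates", {
  st <- std_season(seed = 6, noise_frac = 0)
  season <- generate_season(st)
  cv <- fit_seasonal_curve(season$widths, "w_incr")[["t2"]]
  fw <- final_width(cv)
  last3 <- sort(cv$doys, decreasing = TRUE)[1:3]
  expect_equal(fw, stats::median(predict(cv$fit, last3)))
  expect_equal(fw, st$asym_incr[2], tolerance = 0.01)
  expect_error(final_width(cv, doys = c(1, 2)), "at least 3")
})

test_that("critical dates match the closed-form logistic crossings", {
  # noise-free logistic evaluated on a daily grid, final width = asymptote
  A <- 1200; t0 <- 160; s <- 20
  doy <- 75:320
  daily <- data.frame(doy = doy, pred = logistic(doy, A, t0, s))
  cd <- critical_dates(daily, A)
  expect_equal(cd$tb, logistic_frac_day(0.05, t0, s), tolerance = 0.005)
  expect_equal(cd$te, logistic_frac_day(0.95, t0, s), tolerance = 0.005)
  expect_equal(cd$wb, 0.05 * A)
  expect_equal(cd$we, 0.95 * A)
  expect_false(cd$censored)
  # step curve: both critical dates fall on the jump day
  step <- data.frame(doy = 1:50, pred = c(rep(0, 24), rep(1000, 26)))
  cds <- critical_dates(step, 1000)
  expect_identical(ceiling(cds$tb), 25)
  expect_identical(ceiling(cds$te), 25)
  expect_lt(cds$te - cds$tb, 1)
  # censoring when 95% unreachable
  half <- data.frame(doy = 1:50, pred = seq(0, 400, length.out = 50))
  cdh <- critical_dates(half, 1000)
  expect_true(cdh$censored)
  expect_equal(cdh$te, 50)
  expect_error(critical_dates(data.frame(doy = 1:10, pred = rep(0, 10)), 100),
               "never reached")
})

test_that("durations and rates: printed worked examples and flags", {
  p1 <- durations_and_rates(list(tb = 100, te = 277, wb = 0, we = 0))
  expect_equal(p1$incr$d, 177)
  p2 <- durations_and_rates(list(tb = 122, te = 256, wb = 0, we = 0))
  expect_equal(p2$incr$d, 134)
  p3 <- durations_and_rates(list(tb = 100, te = 200, wb = 50, we = 950))
  expect_equal(p3$incr$r, 9)
  # d_xylo spans from the start of size growth to the end of maturation
  p4 <- durations_and_rates(list(tb = 100, te = 200, wb = 1, we = 19),
                            list(tb = 120, te = 260, wb = 1, we = 19))
  expect_equal(p4$d_xylo, 160)
  # te == tb: rate undefined and flagged
  p5 <- durations_and_rates(list(tb = 150, te = 150, wb = 0, we = 10))
  expect_true(p5$incr$rate_undefined)
  expect_true(is.na(p5$incr$r))
})

test_that("daily rates: slope, telescoping, inflection recovery", {
  lin <- data.frame(doy = 1:100, pred = 3 * (1:100))
  r <- daily_rates(lin)
  expect_true(all(r$rate == 3))
  st <- std_season(seed = 4)
  season <- generate_season(st)
  cv <- fit_seasonal_curve(correct_widths(season$widths), "w_incr")[["t3"]]
  rr <- daily_rates(cv$daily)
  expect_equal(sum(rr$rate),
               cv$daily$pred[nrow(cv$daily)] - cv$daily$pred[1],
               tolerance = 1e-10)
  # argmax of the daily rate sits at the logistic inflection (midpoint);
  # asserted on the noise-free season, where the oracle is exact
  st0 <- std_season(seed = 4, noise_frac = 0)
  cv0 <- fit_seasonal_curve(generate_season(st0)$widths, "w_incr")[["t3"]]
  rr0 <- daily_rates(cv0$daily)
  expect_lt(abs(rr0$doy[which.max(rr0$rate)] - st0$mid_incr[3]), 3)
})

test_that("phenology is scale equivariant in the widths", {
  st <- std_season(seed = 9)
  season <- generate_season(st)
  tab1 <- phenology_table(season$widths)
  w2 <- season$widths
  w2$w_incr <- w2$w_incr * 3; w2$w_mat <- w2$w_mat * 3
  w2$w_maturing <- w2$w_maturing * 3
  tab2 <- phenology_table(w2)
  expect_equal(tab2$tb_incr, tab1$tb_incr, tolerance = 1e-6)
  expect_equal(tab2$te_incr, tab1$te_incr, tolerance = 1e-6)
  expect_equal(tab2$r_incr, 3 * tab1$r_incr, tolerance = 1e-6)
  expect_equal(tab2$w_final_incr, 3 * tab1$w_final_incr, tolerance = 1e-6)
})

test_that("per-tree recovery at study scale and process ordering", {
  # recovery medians over five independent seasons (4 trees each); single
  # seasons occasionally draw an unlucky tb at 3% noise, the typical-case
  # property is about the run of seasons
  meds <- t(vapply(11:15, function(sd) {
    season <- generate_season(std_season(seed = sd))
    tab <- phenology_table(season$widths)
    td <- season$truth_dates
    c(tb = median(abs(tab$tb_incr - td$tb_incr)),
      te = median(abs(tab$te_incr - td$te_incr)))
  }, numeric(2)))
  expect_lte(median(meds[, "tb"]), 14)
  expect_lte(median(meds[, "te"]), 14)
  # mature-width process lags size growth by construction
  st <- std_season(seed = 14)
  tab <- phenology_table(generate_season(st)$widths)
  expect_true(all(tab$tb_incr <= tab$tb_mat + 1e-9))
  expect_true(all(tab$te_incr <= tab$te_mat + 1e-9))
  expect_true(all(tab$d_xylo >= tab$d_incr - 1e-9))
})
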