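# cambium / transition detection and width arithmetic

test_that("cambium: flat-bottomed valley is located at its centre", {
  # noise-free generator valley centred at 150
  p <- std_profile(std_ring(noise_sd = 0))
  cam <- detect_cambium(p, c(20, 300))
  expect_lt(abs(cam$cambium_pos - 150), 2 * attr(p, "voxel_pitch"))
  # entirely constant window: the whole window is the run, median returned
  pos <- seq(0, by = 2.49, length.out = 100)
  flat <- gray_profile(pos, rep(12000, 100),
                       kind = "cell_wall", voxel_pitch = 2.49)
  camf <- detect_cambium(flat, c(0, 250))
  expect_equal(camf$cambium_pos, stats::median(flat$position), tolerance = 0.02)
  # strictly monotone window: no flat part -> error
  mono <- gray_profile(pos, seq(1000, 20800, length.out = 100),
                       kind = "cell_wall", voxel_pitch = 2.49)
  expect_error(detect_cambium(mono, c(0, 250)), "widen the window")
})

test_that("cambium recovery under 1% noise across seeds", {
  errs <- vapply(1:8, function(sd) {
    p <- std_profile(std_ring(noise_sd = 300, seed = sd))
    detect_cambium(p, c(20, 300))$cambium_pos - 150
  }, numeric(1))
  expect_lt(median(abs(errs)), 3 * 2.49)
})

test_that("transition: noise-free corner recovered within 2 grid steps", {
  tr <- ring_truth(100, 400, 1000, noise_sd = 0)
  p <- generate_profile(tr, 450)
  dt <- detect_transition(p, 100, 1000)
  expect_lt(abs(dt$transition_pos - 400), 2 * tr$voxel_pitch)
  expect_false(dt$no_plateau)
})

test_that("transition edge cases: fully mature and no-plateau rings", {
  # constant throughout the ring: transition at distance 0 (end of season)
  trM <- ring_truth(100, 101, 1000, noise_sd = 0, valley_halfwidth = 0.4)
  pM <- generate_profile(trM, 450)
  dtM <- detect_transition(pM, 100, 1000)
  expect_false(dtM$no_plateau)
  expect_lt(dtM$w_maturing, 2 * trM$voxel_pitch)
  # monotone ramp with no plateau: flag set, whole ring still maturing
  trE <- ring_truth(100, 1100, 1120, noise_sd = 0)
  pE <- generate_profile(trE, 450)
  dtE <- detect_transition(pE, 100, 1000)
  expect_true(dtE$no_plateau)
  expect_equal(dtE$w_maturing, 900)
  expect_error(detect_transition(pE, 990, 1000), "degenerate ring")
  expect_error(detect_transition(pE, 1000, 100), "bark-ward")
})

test_that("measure_widths arithmetic, additivity and flags", {
  tr <- ring_truth(100, 500, 1100, noise_sd = 0)
  p <- generate_profile(tr, 500)
  w <- measure_widths(p, 100, 1100)
  expect_equal(w$w_incr, 1000)
  expect_equal(w$w_maturing, 400, tolerance = 0.02)
  expect_equal(w$w_maturing + w$w_mat, w$w_incr)
  # no-plateau ring: w_mat = 0
  trE <- ring_truth(100, 1100, 1120, noise_sd = 0)
  wE <- measure_widths(generate_profile(trE, 450), 100, 1000)
  expect_true(wE$no_plateau)
  expect_equal(wE$w_mat, 0)
  expect_equal(wE$w_maturing + wE$w_mat, wE$w_incr)
  expect_error(measure_widths(p, 1100, 100), "negative increment")
})

test_that("detection is translation equivariant and gray-scale invariant", {
  tr <- ring_truth(150, 500, 1050, noise_sd = 0)
  p <- generate_profile(tr, 500)
  w0 <- measure_widths(p, 150, 1050)
  # shift the radial axis by a whole number of pitches
  shift <- 10 * tr$voxel_pitch
  p2 <- gray_profile(p$position + shift, p$value, kind = "cell_wall",
                     voxel_pitch = tr$voxel_pitch)
  w2 <- measure_widths(p2, 150 + shift, 1050 + shift)
  expect_equal(w2$transition_pos - shift, w0$transition_pos, tolerance = 1e-6)
  expect_equal(w2$w_maturing, w0$w_maturing, tolerance = 1e-6)
  expect_equal(w2$w_mat, w0$w_mat, tolerance = 1e-6)
  # multiplying gray values leaves positions unchanged (noise-free)
  p3 <- gray_profile(p$position, p$value * 1.8, kind = "cell_wall",
                     voxel_pitch = tr$voxel_pitch)
  w3 <- measure_widths(p3, 150, 1050)
  expect_equal(w3$transition_pos, w0$transition_pos, tolerance = 1e-6)
  cam0 <- detect_cambium(p, c(50, 320))$cambium_pos
  cam3 <- detect_cambium(p3, c(50, 320))$cambium_pos
  expect_equal(cam0, cam3, tolerance = 1e-9)
})

test_that("width recovery across maturing fractions at 1% noise (subsample)", {
  # reduced-size version of the acceptance sweep: 12 rings
  errs <- vapply(1:12, function(i) {
    wm <- max(900 * (i - 0.5) / 12, 50)
    tr <- ring_truth(150, 150 + wm, 1050, noise_sd = 300, seed = i)
    p <- generate_profile(tr, 500)
    wd <- measure_widths(p, 150, 1050)
    abs(wd$w_maturing - wm)
  }, numeric(1))
  expect_lt(median(errs), 3 * 2.49)
})

test_that("microtomy increment arithmetic", {
  expect_equal(microtomy_increment(600, 400, 40), 1020)
  expect_equal(microtomy_increment(0, 0, 0), 0)
  expect_equal(microtomy_increment(750, 0, 0), 750)
  expect_error(microtomy_increment(-1, 0, 0), "nonnegative")
})
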