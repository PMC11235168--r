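test_that("exchange fraction matches hand-computed and degenerate cases", {
  # forward-simulated sample with true delta_ne = -80, x_e = 0.35
  expect_equal(compute_exchange_fraction(-83.892, -185.3836), 0.35,
               tolerance = 1e-10)
  # exchange-free material: both equilibrations coincide
  expect_equal(compute_exchange_fraction(-100, -100), 0)
  expect_equal(compute_exchange_fraction(-57.3, -57.3,
                                         delta_w1 = -100, delta_w2 = -300), 0)
  # x_e is linear in the equilibration spread with slope 1/(alpha (w1-w2))
  spread <- c(-5, 0, 12, 40)
  xe <- compute_exchange_fraction(-100 + spread, -100)
  expect_equal(xe, spread / (1.082 * (-160 - -428)))
  expect_error(compute_exchange_fraction(-80, -90, delta_w1 = -160,
                                         delta_w2 = -160),
               "degenerate water pair")
  expect_error(compute_exchange_fraction(-1500, -90), "finite")
})

test_that("nonexchangeable delta reduction matches hand arithmetic from both pairs", {
  expect_equal(compute_delta_ne(-83.892, 0.35, -160), -80, tolerance = 1e-12)
  expect_equal(compute_delta_ne(-185.3836, 0.35, -428), -80, tolerance = 1e-12)
  # x_e = 0: nothing exchanged, delta passes through
  expect_equal(compute_delta_ne(-123.4, 0, -160), -123.4)
  expect_error(compute_delta_ne(-80, 1, -160), "undefined")
})

test_that("forward equilibration inverts the reduction and handles the limits", {
  expect_equal(forward_equilibrate(-80, 0.35, -160), -83.892)
  expect_equal(forward_equilibrate(-80, 0, -160), -80)
  # fully exchanged: result depends only on the water
  expect_equal(forward_equilibrate(-80, 1, -160), -91.12)
  expect_equal(forward_equilibrate(-250, 1, -160), -91.12)
  expect_error(forward_equilibrate(-80, 1.2, -160), "\\[0, 1\\]")

  # round trip over a grid of (delta_ne, x_e)
  grid <- expand.grid(ne = c(-240, -120, -80, 0, 30),
                      xe = c(0, 0.21, 0.35, 0.6, 0.95))
  e1 <- forward_equilibrate(grid$ne, grid$xe, -160)
  e2 <- forward_equilibrate(grid$ne, grid$xe, -428)
  xe_hat <- compute_exchange_fraction(e1, e2)
  expect_equal(xe_hat, grid$xe, tolerance = 1e-12)
  expect_equal(compute_delta_ne(e1, xe_hat, -160), grid$ne, tolerance = 1e-9)
})

test_that("offset correction is an additive shift preserving differences", {
  expect_equal(offset_correct(-83.9, standard_measured = -105,
                              standard_known = -100), -78.9)
  x <- c(-120, -80.5, -33)
  shifted <- offset_correct(x, -105, -100)
  expect_equal(diff(shifted), diff(x))
  expect_equal(offset_correct(x, -100, -100), x)
})

test_that("VSMOW calibration is the affine standard mapping", {
  std <- data.frame(measured_delta = c(-90, -45), known_delta = c(-80, -40))
  expect_equal(calibrate_to_vsmow(-70, std), -62.2222222, tolerance = 1e-7)
  # identity when standards measure true
  id_std <- data.frame(measured_delta = c(-90, -45), known_delta = c(-90, -45))
  expect_equal(calibrate_to_vsmow(c(-70, -10), id_std), c(-70, -10))
  # affinity: calibrating a sum shifts consistently
  a <- -70; b <- 12
  slope <- 40 / 45
  expect_equal(calibrate_to_vsmow(a + b, std),
               calibrate_to_vsmow(a, std) + slope * b, tolerance = 1e-9)
  # three standards on one line: least squares recovers the same line
  std3 <- data.frame(measured_delta = c(-90, -45, 0),
                     known_delta = c(-80, -40, 0))
  expect_equal(calibrate_to_vsmow(-70, std3), -62.2222222, tolerance = 1e-7)
  expect_error(calibrate_to_vsmow(-70, std[c(1, 1), ]), "distinct")
  expect_error(calibrate_to_vsmow(-70, std[1, , drop = FALSE]),
               "at least two")
})

test_that("batch reduction flags but keeps bad records and survives failures", {
  m <- random_measurements(20)
  out <- process_equilibration_batch(m)
  expect_equal(out$sample_id, m$sample_id)  # order preserved
  expect_equal(out$delta_ne, m$true_ne, tolerance = 1e-9)
  expect_equal(out$x_e, m$true_xe, tolerance = 1e-12)
  expect_true(all(out$qc_flags == ""))
  expect_true(all(is.na(out$error)))

  # inject an out-of-range exchange fraction and a degenerate water pair
  bad <- m[1:2, ]
  bad$sample_id <- c("xe_high", "degenerate")
  bad$delta_e1[1] <- forward_equilibrate(-80, 1, -160) + 60  # x_e > 1 spread
  bad$delta_e2[1] <- forward_equilibrate(-80, 1, -428) - 60
  bad$delta_w2[2] <- bad$delta_w1[2]
  out2 <- process_equilibration_batch(dplyr::bind_rows(m, bad))
  expect_equal(nrow(out2), 22)
  expect_match(out2$qc_flags[out2$sample_id == "xe_high"], "X_E_OUT_OF_RANGE")
  expect_match(out2$error[out2$sample_id == "degenerate"], "degenerate")

  # PEF-style drift standard shifts, then reduction, then VSMOW scaling
  std <- data.frame(measured_delta = c(-90, -45), known_delta = c(-80, -40))
  out3 <- process_equilibration_batch(m, offset_standard = list(
    measured_delta = -105, known_delta = -100), vsmow_standards = std)
  manual <- calibrate_to_vsmow(
    compute_delta_ne(m$delta_e1 + 5,
                     compute_exchange_fraction(m$delta_e1 + 5,
                                               m$delta_e2 + 5), -160), std)
  expect_equal(out3$delta_ne, manual, tolerance = 1e-9)
})
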