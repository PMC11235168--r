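test_that("forward two-pool model matches hand arithmetic and its limits", {
  expect_equal(re_forward(-50, -79.3), -113.108)
  expect_equal(re_forward(-42, -80, re_params(f = 0)), -42 - 171)
  expect_equal(re_forward(-42, -80, re_params(f = 1)), -80 + 158)
  # affine in every argument
  p <- re_params()
  expect_equal(re_forward(-50 + 10, -79.3, p) - re_forward(-50, -79.3, p),
               (1 - p$f) * 10)
  expect_equal(re_forward(-50, -79.3 + 10, p) - re_forward(-50, -79.3, p),
               p$f * 10)
  df <- 0.01
  expect_equal((re_forward(-50, -79.3, re_params(f = 0.36 + df)) -
                  re_forward(-50, -79.3, p)) / df,
               (-79.3 + 158) - (-50 - 171), tolerance = 1e-9)
})

test_that("residual uses the observed-minus-modeled sign convention", {
  expect_equal(re_residual(-100, -113.108), 13.108)
  expect_equal(re_residual(-113.108, -113.108), 0)
  expect_gt(re_residual(-100, -120), 0)
})

test_that("single-parameter inversions are exact algebraic round trips", {
  for (f in c(-0.2, 0, 0.36, 1, 1.3)) {
    p <- re_params(f = f)
    obs <- re_forward(-48.2, -81.7, p)
    f_hat <- invert_f(obs, -48.2, -81.7)
    expect_equal(as.numeric(f_hat), f, tolerance = 1e-9)
    expect_equal(attr(f_hat, "out_of_range"), f < 0 || f > 1)
    if (f != 0) {
      expect_equal(invert_eps_h(obs, -48.2, -81.7, f = f), 158,
                   tolerance = 1e-9)
    }
  }
  expect_equal(as.numeric(invert_f(-100, -50, -79.3)), 121 / 299.7,
               tolerance = 1e-12)
  # dynamic autotrophic fractionation can push apparent f negative
  f_dyn <- invert_f(-115, -50, -79.3, eps_a_used = -60)
  expect_equal(as.numeric(f_dyn), -5 / 188.7, tolerance = 1e-9)
  expect_true(attr(f_dyn, "out_of_range"))
  expect_equal(invert_eps_h(-113.108, -50, -79.3, f = 0.36), 158,
               tolerance = 1e-9)
  expect_error(invert_eps_h(-113.108, -50, -79.3, f = 0), "unidentifiable")
  expect_error(invert_f(-100, -50, -50 - 171 - 158), "degenerate")

  # smaller f amplifies the inferred heterotrophic fractionation
  obs <- re_forward(-50, -79.3, re_params()) + 5  # model misfit of +5
  eh <- vapply(c(0.36, 0.2, 0.1, 0.05),
               function(f) invert_eps_h(obs, -50, -79.3, f = f), numeric(1))
  expect_true(all(diff(abs(eh - 158)) > 0))
})

test_that("source-water substitution shifts predictions by f times the water offset", {
  p <- re_params()
  expect_equal(source_sensitivity(-50, -85, -85, p), 0)
  expect_equal(source_sensitivity(-50, -85, -85 + 6.7, re_params(f = 0)), 0)
  expect_equal(source_sensitivity(-50, -86, -86 + 6.7, p), 0.36 * 6.7)
  # uniform-shift robustness: every prediction moves by the same amount
  lw <- c(-55, -50, -45)
  expect_equal(source_sensitivity(lw, -86, -80, p),
               rep(p$f * 6, 3))
})

test_that("tabular prediction and inversion run from a record table", {
  s <- generate_n_experiment(synthetic_config(noise_sd = 0))
  pred <- re_predict_table(s)
  expect_true(all(pred$residual == pred$observed - pred$modeled))
  # generator and model disagree by design (apparent vs theoretical
  # fractionations), so residuals are structured, not zero
  expect_true(all(is.finite(pred$residual)))

  inv_const <- re_inversion_table(s, eps_a_mode = "constant")
  expect_equal(nrow(inv_const), 7)
  inv_dyn <- re_inversion_table(s, eps_a_mode = "sugars")
  expect_equal(nrow(inv_dyn), 7)
  # dynamic mode uses measured sugar fractionation, so eps_a_used varies
  expect_true(all(inv_const$eps_a_used == -171))
  expect_gt(diff(range(inv_dyn$eps_a_used)), 1)

  # soil source: predictions shift by f * (soil - root) everywhere
  pred_soil <- re_predict_table(s, source = "soil")
  merged <- merge(pred, pred_soil, by = c("treatment", "replicate"))
  expect_equal(merged$modeled.y - merged$modeled.x,
               rep(0.36 * 6.7, nrow(merged)), tolerance = 1e-9)

  inv_rep <- re_inversion_table(s, by = "replicate")
  expect_true(nrow(inv_rep) > nrow(inv_const))
  expect_true("replicate" %in% names(inv_rep))
})
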