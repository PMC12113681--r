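test_that("percent inhibition follows (1 - a/b) * 100 and its properties", {
  expect_equal(inhibition_rate(1, 1), 0)
  expect_equal(inhibition_rate(0, 1), 100)
  expect_equal(inhibition_rate(0.5, 1.0), 50)
  expect_error(inhibition_rate(0.5, 0), "positive")
  # antitone in a; 100% at a = 0 for any b > 0
  a <- seq(0, 2, by = 0.25)
  for (b in c(0.1, 1, 7)) {
    expect_true(all(diff(inhibition_rate(a, b)) < 0))
    expect_equal(inhibition_rate(0, b), 100)
  }
})

test_that("IC50 fit round-trips a noiseless logistic exactly", {
  d <- sim_dose_response(ic50 = 12.76, hill = 1)
  f <- fit_ic50(d)
  expect_equal(f$ic50, 12.76, tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-6)
  expect_equal(tidy(f)$estimate[1], f$ic50)
})

test_that("flat zero response is flagged as no inhibition", {
  d <- tibble::tibble(conc_uM = c(1, 5, 20, 80), inhibition = c(0, 0.5, 0, 1))
  f <- fit_ic50(d)
  expect_true(f$no_inhibition)
  expect_true(is.na(f$ic50))
})

test_that("noisy replicate IC50 fits land within 10% of truth", {
  errs <- vapply(1:20, function(s) {
    d <- sim_dose_response(ic50 = 12.76, hill = 1, noise_sd = 3, seed = s)
    abs(fit_ic50(d)$ic50 - 12.76) / 12.76
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("reversibility is called from origin intercepts and falling slopes", {
  rev <- sim_reversibility(k_cat_scale = 5, ki = 10)
  expect_equal(classify_reversibility(rev)$call, "reversible")

  irr <- sim_reversibility(k_cat_scale = 5, ki = 10,
                           irreversible_intercept = 0.02)
  expect_equal(classify_reversibility(irr)$call, "irreversible-suspect")

  only0 <- sim_reversibility(i_grid = 0)
  expect_error(classify_reversibility(only0), "two inhibitor levels")
})

test_that("Lineweaver-Burk lines match the mixed-model closed form", {
  km <- 0.2; vmax <- 1; ki <- 10.73; alpha <- 3.01
  d <- sim_mixed_inhibition(km, vmax, ki, alpha)
  lines <- fit_lb_lines(d)
  for (j in seq_len(nrow(lines))) {
    i <- lines$i_uM[j]
    expect_equal(lines$slope[j], (km / vmax) * (1 + i / ki), tolerance = 1e-9)
    expect_equal(lines$intercept[j], (1 / vmax) * (1 + i / (alpha * ki)),
                 tolerance = 1e-9)
  }
  # uninhibited limit: slope = Km/Vmax, intercept = 1/Vmax exactly
  base <- lines[lines$i_uM == 0, ]
  expect_equal(base$slope, km / vmax, tolerance = 1e-12)
  expect_equal(base$intercept, 1 / vmax, tolerance = 1e-12)
})

test_that("duplicated points leave the OLS line unchanged", {
  d <- sim_mixed_inhibition(ki = 8, alpha = 2, i_grid = c(0, 10))
  d2 <- dplyr::bind_rows(d, d)
  expect_equal(fit_lb_lines(d2)$slope, fit_lb_lines(d)$slope)
})

test_that("zero rates are dropped with a warning", {
  d <- sim_mixed_inhibition(ki = 8, alpha = 2, i_grid = 0)
  d$v[1] <- 0
  expect_warning(fit_lb_lines(d), "non-positive")
})

test_that("intersection geometry classifies each canonical mechanism", {
  # competitive limit: alpha very large, intercepts constant, meet on y-axis
  comp <- sim_mixed_inhibition(ki = 10, alpha = 1e8)
  expect_equal(classify_inhibition(fit_lb_lines(comp))$type, "competitive")

  # pure non-competitive: alpha = 1; Vmax falls, Km unchanged; meet on x-axis
  nc <- sim_mixed_inhibition(ki = 6.76, alpha = 1)
  call_nc <- classify_inhibition(fit_lb_lines(nc))
  expect_equal(call_nc$type, "non-competitive")

  # mixed: alpha = 3.01; intersection in the second quadrant
  mx <- sim_mixed_inhibition(ki = 10.73, alpha = 3.01)
  call_mx <- classify_inhibition(fit_lb_lines(mx))
  expect_equal(call_mx$type, "mixed")
  expect_equal(call_mx$quadrant, "second")
  expect_lt(call_mx$x_intersect, 0)
  expect_gt(call_mx$y_intersect, 0)

  # uncompetitive: equal slopes, shifted intercepts -> parallel
  par_lines <- tibble::tibble(
    i_uM = c(0, 10, 20), slope = 0.2,
    intercept = 1 + c(0, 0.5, 1), r2 = 1, n = 5
  )
  class(par_lines) <- c("lb_lines", class(par_lines))
  expect_equal(classify_inhibition(par_lines)$type, "uncompetitive")
})

test_that("secondary plots recover Ki, alpha-Ki and alpha to 1e-6 relative", {
  for (truth in list(c(ki = 10.73, alpha = 3.01), c(ki = 6.76, alpha = 1))) {
    d <- sim_mixed_inhibition(km = 0.2, vmax = 1,
                              ki = truth[["ki"]], alpha = truth[["alpha"]])
    sec <- fit_secondary(fit_lb_lines(d))
    expect_equal(sec$ki, truth[["ki"]], tolerance = 1e-6)
    expect_equal(sec$alpha, truth[["alpha"]], tolerance = 1e-6)
    expect_equal(sec$alpha_ki, truth[["alpha"]] * truth[["ki"]],
                 tolerance = 1e-6)
    expect_equal(sec$km, 0.2, tolerance = 1e-9)
    expect_equal(sec$vmax, 1, tolerance = 1e-9)
  }
})

test_that("slopes independent of inhibitor flag an absent competitive component", {
  # uncompetitive-only pattern: slope fixed, intercept rises with i
  lines <- tibble::tibble(
    i_uM = c(0, 10, 20, 50), slope = 0.2,
    intercept = 1 * (1 + c(0, 10, 20, 50) / 30), r2 = 1, n = 5
  )
  class(lines) <- c("lb_lines", class(lines))
  sec <- fit_secondary(lines)
  expect_true(sec$no_competitive)
  expect_equal(sec$ki, Inf)
})

test_that("linearised and global nonlinear estimates agree on noiseless data", {
  d <- sim_mixed_inhibition(km = 0.2, vmax = 1, ki = 10.73, alpha = 3.01)
  sec <- fit_secondary(fit_lb_lines(d))
  glob <- fit_mixed_global(d)
  expect_equal(glob$ki, sec$ki, tolerance = 1e-6)
  expect_equal(glob$alpha, sec$alpha, tolerance = 1e-6)
  expect_equal(glob$km, sec$km, tolerance = 1e-6)
  expect_equal(glob$vmax, sec$vmax, tolerance = 1e-6)
})

test_that("alpha = 1 data keeps the apparent Km constant across inhibitor levels", {
  d <- sim_mixed_inhibition(km = 0.3, vmax = 2, ki = 5, alpha = 1)
  lines <- fit_lb_lines(d)
  km_app <- lines$slope / lines$intercept
  expect_true(all(abs(km_app - 0.3) < 1e-9))
})
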