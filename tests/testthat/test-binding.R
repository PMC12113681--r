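test_that("Stern-Volmer fit recovers the generating constant and Kq = Ksv/tau0", {
  for (ksv in c(5.25e3, 2.64e3)) {
    sv <- stern_volmer_fit(make_sv_series(ksv))
    expect_equal(sv$ksv, ksv, tolerance = 1e-9)
    expect_equal(sv$kq, ksv / 1e-8, tolerance = 1e-9)
    expect_identical(sv$kq * sv$tau0, sv$ksv)
    expect_equal(sv$intercept, 1, tolerance = 1e-9)
  }
})

test_that("unquenched intensities give Ksv = 0 and a warning for negative slopes", {
  flat <- tibble::tibble(q_molL = seq(0, 50e-6, length.out = 5), f = 1000)
  expect_equal(stern_volmer_fit(flat)$ksv, 0)
  rising <- tibble::tibble(q_molL = seq(0, 50e-6, length.out = 5),
                           f = 1000 * (1 + seq(0, 1, length.out = 5)))
  expect_warning(stern_volmer_fit(rising), "no quenching")
})

test_that("quenching mechanism classification covers all evidence patterns", {
  falling <- tibble::tibble(temperature_K = c(298, 304, 310),
                            ksv = c(5.25e3, 4.72e3, 4.25e3))
  falling$kq <- falling$ksv / 1e-8
  expect_equal(classify_quenching(falling)$mechanism, "static")

  rising <- tibble::tibble(temperature_K = c(298, 310), ksv = c(10, 20),
                           kq = c(1e9, 2e9))
  expect_equal(classify_quenching(rising)$mechanism, "dynamic")

  conflict <- tibble::tibble(temperature_K = c(298, 310), ksv = c(500, 600),
                             kq = c(5e10, 6e10))
  expect_equal(classify_quenching(conflict)$mechanism, "indeterminate")

  single <- falling[1, ]
  out <- classify_quenching(single)
  expect_equal(out$mechanism, "static")
  expect_true(out$low_confidence)
})

test_that("double-log fit round-trips the static-binding isotherm", {
  # F = F0 / (1 + Ka q^n) reproduces the double-log relation exactly
  ka <- 8.595e4; n <- 1.052; f0 <- 1000
  q <- seq(5e-6, 50e-6, length.out = 7)
  series <- tibble::tibble(q_molL = c(0, q), f = c(f0, f0 / (1 + ka * q^n)))
  dl <- double_log_fit(series)
  expect_equal(dl$ka, ka, tolerance = 1e-6)
  expect_equal(dl$n, n, tolerance = 1e-6)
})

test_that("with n = 1 the double-log Ka equals the Stern-Volmer constant", {
  series <- make_sv_series(5.25e3)
  expect_equal(double_log_fit(series)$ka, stern_volmer_fit(series)$ksv,
               tolerance = 1e-9)
})

test_that("two quenched points give the exact line through both", {
  ka <- 2e4; f0 <- 500
  q <- c(1e-5, 4e-5)
  series <- tibble::tibble(q_molL = c(0, q), f = c(f0, f0 / (1 + ka * q)))
  dl <- double_log_fit(series)
  expect_equal(dl$ka, ka, tolerance = 1e-9)
  expect_equal(dl$r2, 1)
})

test_that("points at or above F0 are excluded with a warning", {
  series <- tibble::tibble(q_molL = c(0, 1e-5, 2e-5, 3e-5),
                           f = c(1000, 1001, 800, 700))
  expect_warning(double_log_fit(series), "F >= F0")
})

test_that("Van't Hoff regression reproduces the published enthalpies", {
  vh_p <- vant_hoff_fit(table4_piboserod)
  expect_equal(vh_p$dh / 1000, -35.77, tolerance = 0.05 / 35.77)
  vh_r <- vant_hoff_fit(table4_rotigotine)
  expect_equal(vh_r$dh / 1000, -79.41, tolerance = 0.05 / 79.41)
  # decreasing ln Ka with T implies a negative fitted enthalpy
  expect_lt(vh_p$dh, 0)
})

test_that("temperature-independent Ka gives zero enthalpy", {
  flat <- tibble::tibble(temperature_K = c(298, 304, 310), ka = 1e4)
  expect_equal(vant_hoff_fit(flat)$dh, 0, tolerance = 1e-9)
  expect_error(vant_hoff_fit(flat[1, ]), "two distinct temperatures")
})

test_that("Van't Hoff round-trip on exactly generated data is machine-precise", {
  dh <- -50000; ds <- -80
  temps <- c(288, 298, 308, 318)
  d <- tibble::tibble(temperature_K = temps,
                      ka = exp(-dh / (8.314 * temps) + ds / 8.314))
  fit <- vant_hoff_fit(d)
  expect_equal(fit$dh, dh, tolerance = 1e-10)
  expect_equal(fit$ds, ds, tolerance = 1e-10)
  # dG = dH - T dS equals -RT ln Ka for every generated temperature
  expect_equal(fit$gibbs$dg, -8.314 * temps * log(d$ka), tolerance = 1e-8)
})

test_that("Gibbs relation reproduces the published energies exactly", {
  expect_equal(gibbs_energy(-35770, -44.61, 298) / 1000, -22.48,
               tolerance = 0.01 / 22.48)
  expect_equal(gibbs_energy(-35770, -44.61, 310) / 1000, -21.94,
               tolerance = 0.01 / 21.94)
  expect_equal(gibbs_energy(-1000, 0, 298), -1000)
  expect_error(gibbs_energy(-1000, 0, -5), "positive")
})

test_that("binding-force rules map thermodynamic signs to interactions", {
  hb <- classify_forces(-35770, -44.61, 298)
  expect_match(hb$forces, "hydrogen bonding")
  expect_equal(hb$driven_by, "enthalpy")
  expect_true(hb$spontaneous)

  hydrophobic <- classify_forces(10000, 100, 298)
  expect_equal(hydrophobic$forces, "hydrophobic")
  expect_equal(hydrophobic$driven_by, "entropy")

  nonspont <- classify_forces(5000, -10, 298)
  expect_false(nonspont$spontaneous)
})

test_that("lifetime fits round-trip clean and Poisson-noised decays", {
  clean <- sim_decay(tau_s = 1e-8, amplitudes = 1000)
  f <- fit_lifetime(clean)
  expect_equal(f$components$tau_s, 1e-8, tolerance = 1e-9)

  noisy <- sim_decay(tau_s = 1e-8, amplitudes = 5000, noise = "poisson",
                     seed = 12)
  fn <- fit_lifetime(noisy)
  expect_equal(fn$components$tau_s, 1e-8, tolerance = 0.05)
})

test_that("equal lifetimes with and without quencher support static quenching", {
  a <- fit_lifetime(sim_decay(tau_s = 1e-8, amplitudes = 1000))
  b <- fit_lifetime(sim_decay(tau_s = 1e-8, amplitudes = 700))
  cmp <- compare_lifetimes(a, b)
  expect_match(cmp$call, "static")

  shorter <- fit_lifetime(sim_decay(tau_s = 0.5e-8, amplitudes = 1000))
  expect_match(compare_lifetimes(a, shorter)$call, "dynamic")
})

test_that("the full binding report ties the stages together", {
  titr <- sim_titration(f0 = 1000, dh = -35770, ds = -25.49, n = 1)
  rep <- binding_report(titr)
  g <- glance(rep)
  expect_equal(g$mechanism, "static")
  expect_equal(g$dh_kJmol, -35.77, tolerance = 1e-3)
  expect_equal(g$driven_by, "enthalpy")
  expect_true(g$spontaneous)
  expect_equal(nrow(tidy(rep)), 3)
})
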