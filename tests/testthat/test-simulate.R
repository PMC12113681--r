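test_that("every generator is bit-reproducible under a fixed seed", {
  gens <- list(
    function(s) sim_mixed_inhibition(ki = 8, alpha = 2, noise_sd = 0.02, seed = s),
    function(s) sim_reversibility(noise_sd = 0.01, seed = s),
    function(s) sim_dose_response(noise_sd = 3, seed = s),
    function(s) sim_titration(noise_sd = 5, seed = s),
    function(s) sim_decay(noise = "poisson", seed = s),
    function(s) sim_candidate_table(n = 40, n_pass = 6, seed = s)
  )
  for (gen in gens) {
    expect_identical(gen(123), gen(123))
    expect_false(identical(gen(123), gen(124)))
  }
  f1 <- sim_fingerprints(20, 20, n_bits = 64, separation = 0.5, seed = 99)
  f2 <- sim_fingerprints(20, 20, n_bits = 64, separation = 0.5, seed = 99)
  expect_identical(f1$x[, ], f2$x[, ])
  expect_identical(f1$y, f2$y)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(sim_mixed_inhibition(ki = 5, alpha = 2, noise_sd = 0.1, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("noiseless rates equal the closed-form mixed model", {
  km <- 0.2; vmax <- 1; ki <- 10; alpha <- 2
  d <- sim_mixed_inhibition(km, vmax, ki, alpha)
  expect_identical(
    d$v,
    vmax * d$s_mM / (km * (1 + d$i_uM / ki) + d$s_mM * (1 + d$i_uM / (alpha * ki)))
  )
  # i = 0 rows reduce to plain Michaelis-Menten
  base <- d[d$i_uM == 0, ]
  expect_identical(base$v, vmax * base$s_mM / (km + base$s_mM))
})

test_that("large alpha approaches the competitive limit (constant intercepts)", {
  d <- sim_mixed_inhibition(ki = 10, alpha = 1e9)
  lines <- fit_lb_lines(d)
  expect_lt(diff(range(lines$intercept)) / lines$intercept[1], 1e-6)
  expect_gt(diff(range(lines$slope)) / lines$slope[1], 1)
})

test_that("titration generator obeys its stated closed forms", {
  d <- sim_titration(f0 = 1000, dh = -35770, ds = -25.49, n = 1)
  gt <- ground_truth(d)
  # q = 0 rows return exactly F0
  expect_true(all(d$f[d$q_molL == 0] == 1000))
  # ka(T) follows the Van't Hoff law used by the generator
  temps <- as.numeric(names(gt$params$ka))
  expect_equal(unname(gt$params$ka),
               exp(35770 / (8.314 * temps) - 25.49 / 8.314), tolerance = 1e-12)
  # noiseless single-temperature series round-trips through the SV fit
  one <- d[d$temperature_K == 298, ]
  expect_equal(stern_volmer_fit(one)$ksv, unname(gt$params$ka["298"]),
               tolerance = 1e-9)
})

test_that("dose-response generator hits its anchor points", {
  d <- sim_dose_response(ic50 = 10, hill = 2, conc_grid = c(1, 10, 1e6))
  expect_equal(d$inhibition[d$conc_uM == 10], 50)
  expect_gt(d$inhibition[d$conc_uM == 1e6], 99.9)
})

test_that("decay generator components are additive", {
  a <- sim_decay(tau_s = 1e-8, amplitudes = 500)
  b <- sim_decay(tau_s = 3e-8, amplitudes = 200)
  ab <- sim_decay(tau_s = c(1e-8, 3e-8), amplitudes = c(500, 200))
  expect_equal(ab$counts, a$counts + b$counts, tolerance = 1e-12)
})

test_that("candidate generator edge cases: all pass and empty table", {
  all_pass <- sim_candidate_table(n = 25, n_pass = 25, seed = 4)
  expect_equal(nrow(run_cascade(all_pass)$survivors), 25)
  empty <- sim_candidate_table(n = 0, n_pass = 0, seed = 4)
  expect_equal(nrow(empty), 0)
})

test_that("fingerprint separation drives AUC between chance and perfection", {
  none <- sim_fingerprints(100, 100, n_bits = 64, separation = 0, seed = 8)
  # exchangeable classes: bit-count score stays near 0.5 AUC
  expect_lt(abs(roc_auc(none$y, rowSums(none$x)) - 0.5), 0.1)
  full <- sim_fingerprints(100, 100, n_bits = 64, separation = 1, seed = 8)
  info <- ground_truth(full$x)$params$informative_bits
  expect_equal(roc_auc(full$y, rowSums(full$x[, info])), 1)
  expect_error(sim_fingerprints(separation = 1.5), "0, 1")
})
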