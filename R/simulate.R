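# Seeded generators producing every input the pipeline consumes. Each
# returns a tibble carrying its full parameterisation as a ground-truth
# attribute (see ground_truth()), and with noise_sd = 0 reproduces the
# stated closed form exactly.

#' Simulate mixed-inhibition Michaelis-Menten rates
#'
#' Rates follow the general mixed-inhibition law
#' `v = vmax * s / (km * (1 + i/ki) + s * (1 + i/(alpha*ki)))` with additive
#' Gaussian noise. The default substrate and inhibitor grids mirror the
#' kinetic assay design (substrate 0.05-0.8 mM, inhibitor 0-50 uM).
#'
#' @param km Michaelis constant, mM.
#' @param vmax Maximal rate (delta-OD/min scale).
#' @param ki Competitive inhibition constant, uM.
#' @param alpha Ratio of uncompetitive to competitive constants
#'   (alpha = 1 is pure non-competitive; large alpha approaches competitive).
#' @param s_grid Substrate concentrations, mM.
#' @param i_grid Inhibitor concentrations, uM.
#' @param noise_sd SD of additive Gaussian rate noise (0 = exact model).
#' @param seed Integer seed.
#' @return Tibble with columns `v`, `s_mM`, `i_uM` and a ground-truth
#'   attribute.
#' @export
sim_mixed_inhibition <- function(km = 0.2, vmax = 1, ki = 10, alpha = 2,
                                 s_grid = c(0.05, 0.1, 0.2, 0.4, 0.8),
                                 i_grid = c(0, 10, 20, 50),
                                 noise_sd = 0, seed = 1) {
  if (length(s_grid) == 0 || length(i_grid) == 0) abort("Grids must be non-empty.")
  if (any(c(km, vmax, ki, alpha) <= 0)) abort("Kinetic parameters must be positive.")
  grid <- tidyr::expand_grid(i_uM = i_grid, s_mM = s_grid)
  mu <- vmax * grid$s_mM /
    (km * (1 + grid$i_uM / ki) + grid$s_mM * (1 + grid$i_uM / (alpha * ki)))
  v <- if (noise_sd > 0) {
    with_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  } else {
    mu
  }
  out <- tibble::tibble(v = v, s_mM = grid$s_mM, i_uM = grid$i_uM)
  set_ground_truth(out, "mixed_inhibition",
                   list(km = km, vmax = vmax, ki = ki, alpha = alpha,
                        alpha_ki = alpha * ki),
                   seed, sprintf("gaussian(sd = %g)", noise_sd))
}

#' Simulate rate-versus-enzyme reversibility data
#'
#' A reversible inhibitor scales the catalytic slope without adding an
#' intercept: `v = k * e / (1 + i/ki)` plus Gaussian noise, so every line
#' passes through the origin and slopes fall as inhibitor rises. Setting
#' `irreversible_intercept > 0` adds an intercept growing with inhibitor
#' concentration, emulating time-dependent enzyme depletion.
#'
#' @param k_cat_scale Uninhibited slope (rate per U/mL).
#' @param ki Inhibition constant, uM.
#' @param e_grid Enzyme concentrations, U/mL.
#' @param i_grid Inhibitor concentrations, uM.
#' @param noise_sd SD of additive Gaussian noise.
#' @param irreversible_intercept Intercept added per uM of inhibitor
#'   (default 0: reversible).
#' @param seed Integer seed.
#' @return Tibble with columns `v`, `e_UmL`, `i_uM` plus ground truth.
#' @export
sim_reversibility <- function(k_cat_scale = 5, ki = 10,
                              e_grid = c(0.025, 0.05, 0.1, 0.2),
                              i_grid = c(0, 10, 20, 50),
                              noise_sd = 0, irreversible_intercept = 0,
                              seed = 1) {
  if (length(e_grid) == 0 || length(i_grid) == 0) abort("Grids must be non-empty.")
  grid <- tidyr::expand_grid(i_uM = i_grid, e_UmL = e_grid)
  mu <- k_cat_scale * grid$e_UmL / (1 + grid$i_uM / ki) +
    irreversible_intercept * grid$i_uM
  v <- if (noise_sd > 0) {
    with_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  } else {
    mu
  }
  out <- tibble::tibble(v = v, e_UmL = grid$e_UmL, i_uM = grid$i_uM)
  set_ground_truth(out, "reversibility",
                   list(k_cat_scale = k_cat_scale, ki = ki,
                        irreversible_intercept = irreversible_intercept),
                   seed, sprintf("gaussian(sd = %g)", noise_sd))
}

#' Simulate a percent-inhibition dose-response
#'
#' `inhibition = 100 / (1 + (ic50 / c)^hill)` plus Gaussian noise.
#'
#' @param ic50 True IC50, uM.
#' @param hill Hill slope.
#' @param conc_grid Inhibitor concentrations, uM.
#' @param noise_sd SD of additive Gaussian noise in percent.
#' @param seed Integer seed.
#' @return Tibble with columns `conc_uM`, `inhibition` plus ground truth.
#' @export
sim_dose_response <- function(ic50 = 12.76, hill = 1,
                              conc_grid = c(0.5, 1, 2, 5, 10, 20, 50, 100),
                              noise_sd = 0, seed = 1) {
  if (ic50 <= 0 || hill <= 0) abort("`ic50` and `hill` must be positive.")
  if (length(conc_grid) == 0) abort("`conc_grid` must be non-empty.")
  mu <- 100 / (1 + (ic50 / conc_grid)^hill)
  inh <- if (noise_sd > 0) {
    with_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  } else {
    mu
  }
  out <- tibble::tibble(conc_uM = conc_grid, inhibition = inh)
  set_ground_truth(out, "dose_response", list(ic50 = ic50, hill = hill),
                   seed, sprintf("gaussian(sd = %g%%)", noise_sd))
}

#' Simulate static-quenching titrations across temperatures
#'
#' The binding constant follows the Van't Hoff law
#' `ka(T) = exp(-dh/(R T) + ds/R)` and intensities follow the static
#' quenching isotherm `F = f0 / (1 + ka * q^n)`, which reproduces the
#' double-log relation exactly and the Stern-Volmer relation when n = 1.
#' Default temperatures are the experimental set 298, 304 and 310 K, and the
#' default quencher grid spans 0-50 uM in 7 steps (a 0 row supplies F0).
#'
#' @param f0 Unquenched intensity.
#' @param dh Binding enthalpy, J/mol.
#' @param ds Binding entropy, J/mol/K.
#' @param n Binding-site number (exponent on \[Q\]).
#' @param temperatures_K Temperatures, K.
#' @param q_grid Quencher concentrations, mol/L (should include 0).
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param seed Integer seed.
#' @return Tibble with columns `temperature_K`, `q_molL`, `f` plus ground
#'   truth (including the per-temperature `ka`).
#' @export
sim_titration <- function(f0 = 1000, dh = -35770, ds = -25.5, n = 1,
                          temperatures_K = c(298, 304, 310),
                          q_grid = seq(0, 50e-6, length.out = 7),
                          noise_sd = 0, seed = 1) {
  if (f0 <= 0) abort("`f0` must be positive.")
  if (length(q_grid) == 0 || length(temperatures_K) == 0) {
    abort("Grids must be non-empty.")
  }
  ka <- exp(-dh / (.R_GAS * temperatures_K) + ds / .R_GAS)
  grid <- tidyr::expand_grid(temperature_K = temperatures_K, q_molL = q_grid)
  ka_row <- ka[match(grid$temperature_K, temperatures_K)]
  mu <- f0 / (1 + ka_row * grid$q_molL^n)
  f <- if (noise_sd > 0) {
    with_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  } else {
    mu
  }
  out <- tibble::tibble(temperature_K = grid$temperature_K,
                        q_molL = grid$q_molL, f = f)
  set_ground_truth(out, "titration",
                   list(f0 = f0, dh = dh, ds = ds, n = n,
                        ka = setNames(ka, temperatures_K)),
                   seed, sprintf("gaussian(sd = %g)", noise_sd))
}

#' Simulate a fluorescence decay trace
#'
#' Multi-exponential decay `I(t) = sum_i amp_i exp(-t / tau_i)` with
#' optional Gaussian or Poisson count noise.
#'
#' @param tau_s Lifetimes, s.
#' @param amplitudes Component amplitudes (same length as `tau_s`).
#' @param t_grid Time grid, s.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise SD (ignored otherwise).
#' @param seed Integer seed.
#' @return Tibble with columns `time_s`, `counts` plus ground truth.
#' @export
sim_decay <- function(tau_s = 1e-8, amplitudes = 1000,
                      t_grid = seq(0, 5e-8, length.out = 100),
                      noise = c("none", "gaussian", "poisson"),
                      noise_sd = 10, seed = 1) {
  noise <- match.arg(noise)
  if (length(tau_s) != length(amplitudes)) {
    abort("`tau_s` and `amplitudes` must have equal length.")
  }
  if (any(tau_s <= 0)) abort("Lifetimes must be positive.")
  mu <- rowSums(vapply(
    seq_along(tau_s),
    function(j) amplitudes[j] * exp(-t_grid / tau_s[j]),
    numeric(length(t_grid))
  ))
  counts <- switch(
    noise,
    none = mu,
    gaussian = with_seed(seed, pmax(mu + rnorm(length(mu), 0, noise_sd), 0)),
    poisson = with_seed(seed, rpois(length(mu), mu))
  )
  out <- tibble::tibble(time_s = t_grid, counts = counts)
  set_ground_truth(out, "decay",
                   list(tau_s = tau_s, amplitudes = amplitudes),
                   seed, noise)
}

#' Simulate a candidate descriptor table with known cascade survivors
#'
#' Builds `n` screening candidates whose descriptors are drawn so that a
#' chosen subset passes every stage of the cascade while each remaining
#' record is constructed to fail at a randomly assigned stage. The
#' ground-truth attribute lists the intended survivor ids, so cascade output
#' can be checked exactly.
#'
#' @param n Number of candidates.
#' @param n_pass Number of candidates constructed to pass all stages.
#' @param seed Integer seed.
#' @param thresholds The [cascade_thresholds()] the table is built against.
#' @return Tibble with the full candidate schema (`id`, `smiles`,
#'   `probability`, `docking_score`, `cns`, `qplogbb`, `bbb_score`,
#'   `qppcaco`, `hoa`, `mw`, `logp`, `hbd`, `hba`, `logs`, `metab`) plus
#'   ground truth (the intended survivors under `params$pass_ids`).
#' @export
sim_candidate_table <- function(n = 100, n_pass = 12, seed = 1,
                                thresholds = cascade_thresholds()) {
  if (n_pass > n) abort("`n_pass` cannot exceed `n`.")
  th <- thresholds
  if (n == 0) {
    out <- passing_candidates(0, th)
    return(set_ground_truth(out, "candidate_table",
                            list(n = 0, pass_ids = character()), seed, "none"))
  }
  with_seed(seed, {
    out <- passing_candidates(n, th)
    stages <- cascade_stage_names()
    fail_idx <- if (n > n_pass) (n_pass + 1):n else integer()
    fail_stage <- sample(stages, length(fail_idx), replace = TRUE)
    for (k in seq_along(fail_idx)) {
      j <- fail_idx[k]
      switch(
        fail_stage[k],
        probability = {
          out$probability[j] <- runif(1, 0, th$prob_min)
        },
        docking = {
          out$docking_score[j] <- th$dock_max + runif(1, 0.1, 3)
        },
        cns = {
          out$cns[j] <- th$cns_min - sample(0:1, 1)
        },
        absorption = {
          out$qppcaco[j] <- runif(1, th$caco_ro3_min + 1, th$qppcaco_min)
        },
        druglikeness = {
          # two Lipinski violations: heavy and greasy
          out$mw[j] <- runif(1, 520, 700)
          out$logp[j] <- runif(1, 5.2, 7)
        }
      )
    }
    out <- out[sample(n), , drop = FALSE]
    set_ground_truth(out, "candidate_table",
                     list(n = n, n_pass = n_pass,
                          pass_ids = sort(out$id[out$id %in% sprintf("cand_%04d", seq_len(n_pass))]),
                          fail_stage = setNames(fail_stage,
                                                sprintf("cand_%04d", fail_idx))),
                     seed, "uniform descriptor sampling")
  })
}

# Descriptor draws that satisfy every stage of `th`.
passing_candidates <- function(n, th) {
  tibble::tibble(
    id = sprintf("cand_%04d", seq_len(n)),
    smiles = rep("CCO", n),
    probability = runif(n, th$prob_min + 0.05, 1),
    docking_score = runif(n, -11, th$dock_max - 0.1),
    cns = th$cns_min + sample(1:2, n, replace = TRUE),
    qplogbb = runif(n, th$qplogbb_min + 0.5, 1),
    bbb_score = runif(n, th$bbb_min + 0.2, 6),
    qppcaco = runif(n, th$qppcaco_min + 50, 3000),
    hoa = runif(n, th$hoa_min + 5, 100),
    mw = runif(n, 200, 480),
    logp = runif(n, 0.5, 4.5),
    hbd = sample(0:4, n, replace = TRUE),
    hba = sample(1:9, n, replace = TRUE),
    logs = runif(n, th$logs_min + 0.5, -1),
    metab = sample(0:(th$metab_max - 1), n, replace = TRUE)
  )
}

#' Simulate two-class binary fingerprint data
#'
#' Actives and inactives share a sparse background bit distribution; a block
#' of informative bits fires with probability `0.5 + separation/2` in
#' actives and `0.5 - separation/2` in inactives. `separation = 0` makes the
#' classes exchangeable (expected AUC 0.5); `separation = 1` makes the
#' informative block deterministic (AUC 1).
#'
#' @param n_active,n_inactive Class sizes.
#' @param n_bits Fingerprint length.
#' @param separation Class separation in \[0, 1\].
#' @param n_informative Number of informative bits (default 64).
#' @param background_rate Firing probability of uninformative bits.
#' @param seed Integer seed.
#' @return List with `x` (0/1 matrix), `y` (0/1 labels, 1 = active), and a
#'   ground-truth attribute on `x`.
#' @export
sim_fingerprints <- function(n_active = 300, n_inactive = 300, n_bits = 2048,
                             separation = 0.5, n_informative = 64,
                             background_rate = 0.05, seed = 1) {
  if (separation < 0 || separation > 1) abort("`separation` must be in [0, 1].")
  if (n_informative > n_bits) abort("`n_informative` cannot exceed `n_bits`.")
  n <- n_active + n_inactive
  y <- c(rep(1L, n_active), rep(0L, n_inactive))
  with_seed(seed, {
    x <- matrix(rbinom(n * n_bits, 1, background_rate), nrow = n)
    p_active <- 0.5 + separation / 2
    p_inactive <- 0.5 - separation / 2
    info <- seq_len(n_informative)
    x[y == 1, info] <- rbinom(n_active * n_informative, 1, p_active)
    x[y == 0, info] <- rbinom(n_inactive * n_informative, 1, p_inactive)
    ord <- sample(n)
    x <- x[ord, , drop = FALSE]
    y <- y[ord]
    x <- set_ground_truth(x, "fingerprints",
                          list(n_active = n_active, n_inactive = n_inactive,
                               separation = separation,
                               informative_bits = info),
                          seed, "bernoulli bits")
    list(x = x, y = y)
  })
}
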