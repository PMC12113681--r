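#' Stern-Volmer fit of a quenching titration
#'
#' Ordinary least squares of F0/F against quencher concentration
#' (`F0/F = 1 + Ksv * [Q]`), fitted with a free intercept so deviation from
#' the theoretical value 1 is visible. The bimolecular quenching rate
#' constant follows as `Kq = Ksv / tau0`, with `tau0` the fluorophore's
#' unquenched average lifetime (1e-8 s for tryptophan-dominated protein
#' emission by default).
#'
#' @param series Titration table: columns `q_molL` (quencher, mol/L) and `f`
#'   (intensity); the intensity at q = 0 supplies F0 unless `f0` is given.
#' @param tau0 Unquenched fluorescence lifetime in seconds (default 1e-8).
#' @param f0 Optional explicit F0; defaults to the intensity at the smallest
#'   (zero) quencher concentration.
#' @return An object of class `sv_fit`: `ksv` (L/mol), `kq` (L/mol/s),
#'   `intercept`, `r2`, `tau0`, `temperature` (copied from a `temperature_K`
#'   column when present).
#' @export
stern_volmer_fit <- function(series, tau0 = 1e-8, f0 = NULL) {
  check_columns(series, c("q_molL", "f"), "`series`")
  series <- dplyr::arrange(tibble::as_tibble(series), .data$q_molL)
  if (is.null(f0)) f0 <- series$f[1]
  if (!is.finite(f0) || f0 <= 0) abort("F0 must be positive.")
  pts <- series[series$q_molL > 0, , drop = FALSE]
  if (nrow(pts) < 3) abort("At least 3 nonzero quencher concentrations needed.")
  if (any(pts$f <= 0)) abort("Intensities must be positive.")
  l <- ols_line(pts$q_molL, f0 / pts$f)
  if (l$slope < 0) warn("Negative Stern-Volmer slope: no quenching detected.")
  structure(
    list(ksv = l$slope, kq = l$slope / tau0, intercept = l$intercept,
         r2 = l$r2, tau0 = tau0, f0 = f0,
         temperature = if ("temperature_K" %in% names(series)) {
           series$temperature_K[1]
         } else {
           NA_real_
         }),
    class = "sv_fit"
  )
}

#' @exportS3Method
tidy.sv_fit <- function(x, ...) {
  tibble::tibble(term = c("ksv", "kq", "intercept"),
                 estimate = c(x$ksv, x$kq, x$intercept),
                 unit = c("L/mol", "L/mol/s", ""))
}

#' @exportS3Method
glance.sv_fit <- function(x, ...) {
  tibble::tibble(temperature_K = x$temperature, ksv = x$ksv, kq = x$kq,
                 intercept = x$intercept, r2 = x$r2, tau0 = x$tau0)
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer: Ksv = %.4g L/mol, Kq = %.4g L/mol/s (r2 = %.4f)\n",
              x$ksv, x$kq, x$r2))
  invisible(x)
}

#' Classify the quenching mechanism
#'
#' Static quenching (ground-state complex formation) is indicated when the
#' bimolecular quenching constant exceeds the diffusion-controlled ceiling
#' (2.0e10 L/mol/s) and Ksv falls with temperature; dynamic (collisional)
#' quenching shows Kq at or below the ceiling with Ksv rising with
#' temperature. Conflicting evidence yields `"indeterminate"`. With a single
#' temperature the call rests on Kq alone and is flagged low-confidence.
#'
#' @param results A data frame with columns `temperature_K`, `ksv`, `kq`
#'   (e.g. bound [glance.sv_fit()] rows), or a list of `sv_fit` objects.
#' @param kq_threshold Maximum diffusion-collision quenching constant,
#'   L/mol/s.
#' @return A list of class `quenching_call`: `mechanism` ("static",
#'   "dynamic" or "indeterminate"), `low_confidence`, `kq_max`, `ksv_trend`.
#' @export
classify_quenching <- function(results, kq_threshold = 2.0e10) {
  if (is.list(results) && !is.data.frame(results) &&
      all(purrr::map_lgl(results, inherits, "sv_fit"))) {
    results <- purrr::map_dfr(results, glance)
  }
  check_columns(results, c("temperature_K", "ksv", "kq"), "`results`")
  results <- dplyr::arrange(tibble::as_tibble(results), .data$temperature_K)
  kq_max <- max(results$kq)
  if (nrow(results) < 2) {
    mech <- if (kq_max > kq_threshold) "static" else "dynamic"
    return(structure(
      list(mechanism = mech, low_confidence = TRUE, kq_max = kq_max,
           ksv_trend = NA_character_),
      class = "quenching_call"
    ))
  }
  d <- diff(results$ksv)
  trend <- if (all(d <= 0)) "non-increasing" else if (all(d > 0)) "increasing" else "mixed"
  mech <- if (kq_max > kq_threshold && trend == "non-increasing") {
    "static"
  } else if (kq_max <= kq_threshold && trend == "increasing") {
    "dynamic"
  } else {
    "indeterminate"
  }
  structure(
    list(mechanism = mech, low_confidence = FALSE, kq_max = kq_max,
         ksv_trend = trend),
    class = "quenching_call"
  )
}

#' @export
print.quenching_call <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s (max Kq = %.3g L/mol/s, Ksv %s)%s\n",
              x$mechanism, x$kq_max, x$ksv_trend %||% "single T",
              if (x$low_confidence) " [low confidence: one temperature]" else ""))
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Least squares of `log10((F0 - F)/F)` on `log10([Q])`: the intercept gives
#' the binding constant (`Ka = 10^intercept`, L/mol) and the slope the
#' number of binding sites `n`. Points with F >= F0 carry no quenching
#' signal and are excluded with a warning.
#'
#' @inheritParams stern_volmer_fit
#' @return An object of class `dlog_fit`: `ka` (L/mol), `n`, `r2`,
#'   `temperature`.
#' @export
double_log_fit <- function(series, f0 = NULL) {
  check_columns(series, c("q_molL", "f"), "`series`")
  series <- dplyr::arrange(tibble::as_tibble(series), .data$q_molL)
  if (is.null(f0)) f0 <- series$f[1]
  pts <- series[series$q_molL > 0, , drop = FALSE]
  bad <- pts$f >= f0
  if (any(bad)) {
    warn(sprintf("Excluded %d point(s) with F >= F0 from the double-log fit.",
                 sum(bad)))
    pts <- pts[!bad, , drop = FALSE]
  }
  if (nrow(pts) < 2) abort("At least 2 quenched points are required.")
  l <- ols_line(log10(pts$q_molL), log10((f0 - pts$f) / pts$f))
  structure(
    list(ka = 10^l$intercept, n = l$slope, r2 = l$r2, f0 = f0,
         temperature = if ("temperature_K" %in% names(series)) {
           series$temperature_K[1]
         } else {
           NA_real_
         }),
    class = "dlog_fit"
  )
}

#' @exportS3Method
glance.dlog_fit <- function(x, ...) {
  tibble::tibble(temperature_K = x$temperature, ka = x$ka, n = x$n, r2 = x$r2)
}

#' @export
print.dlog_fit <- function(x, ...) {
  cat(sprintf("Double-log fit: Ka = %.4g L/mol, n = %.4g (r2 = %.4f)\n",
              x$ka, x$n, x$r2))
  invisible(x)
}

#' Van't Hoff regression of binding constants over temperature
#'
#' Fits `ln Ka = -dH/(R T) + dS/R` by least squares of ln(Ka) on 1/T,
#' yielding the binding enthalpy from the slope and the entropy from the
#' intercept (R = 8.314 J/mol/K). Gibbs energies `dG(T) = dH - T dS` are
#' evaluated at each supplied temperature.
#'
#' @param data Data frame with columns `temperature_K` and `ka` (L/mol).
#' @return An object of class `vant_hoff`: `dh` (J/mol), `ds` (J/mol/K, from
#'   the intercept), `r2`, and `gibbs` (tibble of `temperature_K`, `dg`).
#' @examples
#' vant_hoff_fit(tibble::tibble(
#'   temperature_K = c(298, 304, 310),
#'   ka = c(8.595e4, 6.724e4, 4.912e4)
#' ))
#' @export
vant_hoff_fit <- function(data) {
  check_columns(data, c("temperature_K", "ka"), "`data`")
  if (any(data$ka <= 0)) abort("Binding constants must be positive.")
  if (length(unique(data$temperature_K)) < 2) {
    abort("At least two distinct temperatures are required.")
  }
  if (nrow(data) < 3) {
    warn("Fewer than 3 temperatures: Van't Hoff fit has no residual check.")
  }
  l <- ols_line(1 / data$temperature_K, log(data$ka))
  dh <- -l$slope * .R_GAS
  ds <- l$intercept * .R_GAS
  structure(
    list(
      dh = dh, ds = ds, r2 = l$r2,
      gibbs = tibble::tibble(
        temperature_K = sort(unique(data$temperature_K)),
        dg = gibbs_energy(dh, ds, sort(unique(data$temperature_K)))
      ),
      data = tibble::as_tibble(data)
    ),
    class = "vant_hoff"
  )
}

#' @exportS3Method
tidy.vant_hoff <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = c("dh", "ds"), estimate = c(x$dh, x$ds),
                   unit = c("J/mol", "J/mol/K")),
    tibble::tibble(term = sprintf("dg_%gK", x$gibbs$temperature_K),
                   estimate = x$gibbs$dg, unit = "J/mol")
  )
}

#' @exportS3Method
glance.vant_hoff <- function(x, ...) {
  tibble::tibble(dh_kJmol = x$dh / 1000, ds_JmolK = x$ds, r2 = x$r2,
                 n_temperatures = nrow(x$data))
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat(sprintf("Van't Hoff: dH = %.2f kJ/mol, dS = %.2f J/mol/K (r2 = %.4f)\n",
              x$dh / 1000, x$ds, x$r2))
  for (j in seq_len(nrow(x$gibbs))) {
    cat(sprintf("  dG(%g K) = %.2f kJ/mol\n",
                x$gibbs$temperature_K[j], x$gibbs$dg[j] / 1000))
  }
  invisible(x)
}

#' @exportS3Method
autoplot.vant_hoff <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = 1 / .data$temperature_K, y = log(.data$ka))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = -object$dh / .R_GAS,
                         intercept = object$ds / .R_GAS,
                         colour = "firebrick") +
    ggplot2::labs(x = "1/T (1/K)", y = "ln Ka",
                  title = sprintf("Van't Hoff plot: dH = %.2f kJ/mol",
                                  object$dh / 1000))
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T * dS`, exact arithmetic.
#'
#' @param dh Enthalpy change, J/mol.
#' @param ds Entropy change, J/mol/K.
#' @param temperature_K Absolute temperature(s), K (> 0).
#' @return Gibbs energy in J/mol (vectorised over `temperature_K`).
#' @examples
#' gibbs_energy(-35770, -44.61, c(298, 310)) / 1000
#' @export
gibbs_energy <- function(dh, ds, temperature_K) {
  if (any(temperature_K <= 0)) abort("Temperature must be positive (K).")
  dh - temperature_K * ds
}

#' Classify the dominant binding forces
#'
#' Sign-based thermodynamic rules: dH < 0 with dS < 0 points to hydrogen
#' bonding / van der Waals contacts; dH > 0 with dS > 0 to hydrophobic
#' interactions; dH < 0 with dS > 0 to electrostatic forces. The driving
#' term (enthalpy vs entropy) is decided by comparing |dH| with |T dS|, and
#' spontaneity by the sign of dG.
#'
#' @param dh Enthalpy change, J/mol.
#' @param ds Entropy change, J/mol/K.
#' @param temperature_K Reference temperature, K (default 298).
#' @return A one-row tibble: `forces`, `driven_by`, `spontaneous`, `dg`.
#' @export
classify_forces <- function(dh, ds, temperature_K = 298) {
  forces <- dplyr::case_when(
    dh < 0 & ds < 0 ~ "hydrogen bonding / van der Waals",
    dh > 0 & ds > 0 ~ "hydrophobic",
    dh < 0 & ds >= 0 ~ "electrostatic",
    TRUE ~ "unfavourable (dH > 0, dS < 0)"
  )
  tds <- temperature_K * ds
  dg <- gibbs_energy(dh, ds, temperature_K)
  tibble::tibble(
    forces = forces,
    driven_by = ifelse(abs(dh) > abs(tds), "enthalpy", "entropy"),
    spontaneous = dg < 0,
    dg = dg
  )
}

#' Fit exponential fluorescence decay lifetimes
#'
#' Nonlinear least squares of a 1- or 2-component exponential decay
#' `I(t) = sum_i a_i exp(-t / tau_i)` to a time-resolved trace, returning
#' the lifetimes, amplitudes and a reduced chi-square diagnostic.
#'
#' @param trace Data frame with columns `time_s` and `counts` (>= 20 points).
#' @param n_components 1 or 2 exponential components.
#' @return An object of class `lifetime_fit`: tibble `components`
#'   (`tau_s`, `amplitude`, `fraction`), `mean_tau`, `chisq_reduced`.
#' @export
fit_lifetime <- function(trace, n_components = 1) {
  check_columns(trace, c("time_s", "counts"), "`trace`")
  if (nrow(trace) < 20) abort("At least 20 time points are required.")
  if (any(trace$counts < 0)) abort("Counts must be non-negative.")
  if (!n_components %in% 1:2) abort("`n_components` must be 1 or 2.")
  t <- trace$time_s; y <- trace$counts
  a0 <- max(y)
  # crude initial lifetime from the 1/e crossing
  tau0 <- t[which.min(abs(y - a0 / exp(1)))]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- stats::median(t)
  df <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (n_components == 1) {
      minpack.lm::nlsLM(y ~ a1 * exp(-t / tau1), data = df,
                        start = list(a1 = a0, tau1 = tau0),
                        lower = c(a1 = 0, tau1 = 1e-15),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2), data = df,
                        start = list(a1 = a0 * 0.6, tau1 = tau0 * 0.5,
                                     a2 = a0 * 0.4, tau2 = tau0 * 2),
                        lower = rep(1e-15, 4),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) {
    abort(sprintf(
      "Lifetime fit failed to converge (initial guesses a = %.3g, tau = %.3g s): %s",
      a0, tau0, conditionMessage(e)
    ))
  })
  cf <- coef(fit)
  taus <- cf[grepl("^tau", names(cf))]
  amps <- cf[grepl("^a", names(cf))]
  ord <- order(taus)
  comp <- tibble::tibble(
    tau_s = unname(taus[ord]), amplitude = unname(amps[ord]),
    fraction = unname(amps[ord] / sum(amps))
  )
  resid <- y - predict(fit)
  # Poisson-weighted reduced chi-square (variance ~ counts)
  w <- pmax(y, 1)
  chisq <- sum(resid^2 / w) / (length(y) - length(cf))
  structure(
    list(components = comp,
         mean_tau = sum(comp$tau_s * comp$amplitude) / sum(comp$amplitude),
         chisq_reduced = chisq, fit = fit),
    class = "lifetime_fit"
  )
}

#' @exportS3Method
tidy.lifetime_fit <- function(x, ...) x$components

#' @exportS3Method
glance.lifetime_fit <- function(x, ...) {
  tibble::tibble(mean_tau_s = x$mean_tau,
                 n_components = nrow(x$components),
                 chisq_reduced = x$chisq_reduced)
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("Lifetime fit: mean tau = %.4g s (%d component%s, chi2red = %.3g)\n",
              x$mean_tau, nrow(x$components),
              if (nrow(x$components) > 1) "s" else "", x$chisq_reduced))
  invisible(x)
}

#' Compare fluorescence lifetimes across quencher levels
#'
#' Static quenching leaves the excited-state lifetime unchanged (the
#' quencher removes fluorophores before excitation), whereas dynamic
#' quenching shortens it. Given lifetime fits at two quencher levels, this
#' helper reports whether the lifetime changed beyond a relative tolerance.
#'
#' @param fit_ref,fit_quenched `lifetime_fit` objects without and with
#'   quencher.
#' @param rel_tol Relative change regarded as unchanged (default 0.05).
#' @return A one-row tibble: `tau_ref_s`, `tau_quenched_s`, `rel_change`,
#'   `call` ("lifetime unchanged (supports static quenching)" or
#'   "lifetime shortened (supports dynamic quenching)").
#' @export
compare_lifetimes <- function(fit_ref, fit_quenched, rel_tol = 0.05) {
  stopifnot(inherits(fit_ref, "lifetime_fit"),
            inherits(fit_quenched, "lifetime_fit"))
  rel <- (fit_quenched$mean_tau - fit_ref$mean_tau) / fit_ref$mean_tau
  call <- if (abs(rel) <= rel_tol) {
    "lifetime unchanged (supports static quenching)"
  } else if (rel < 0) {
    "lifetime shortened (supports dynamic quenching)"
  } else {
    "lifetime lengthened (check data)"
  }
  tibble::tibble(tau_ref_s = fit_ref$mean_tau,
                 tau_quenched_s = fit_quenched$mean_tau,
                 rel_change = rel, call = call)
}
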