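#' Percent inhibition from sample and blank rates
#'
#' `(1 - a/b) * 100`, where `a` is the enzymatic rate in the presence of
#' inhibitor and `b` the uninhibited blank rate (both in delta-OD per minute
#' from the colorimetric thiocholine assay).
#'
#' @param a Sample rate(s), >= 0.
#' @param b Blank rate(s), > 0.
#' @return Percent inhibition (100 means complete inhibition; negative values
#'   indicate apparent activation).
#' @examples
#' inhibition_rate(0.5, 1.0)
#' @export
inhibition_rate <- function(a, b) {
  if (any(is.na(b)) || any(b <= 0)) abort("Blank rate `b` must be positive.")
  (1 - a / b) * 100
}

#' Fit a dose-response curve for IC50
#'
#' Four-parameter logistic on log concentration,
#' `inh = bottom + (top - bottom) / (1 + (ic50 / c)^hill)`, with the top and
#' bottom plateaus constrained to 100% and 0% by default (inhibition is
#' already expressed on a percent scale). Nonlinear least squares via
#' Levenberg-Marquardt.
#'
#' @param data Data frame of dose-response points.
#' @param conc_col Inhibitor-concentration column (uM); must span the
#'   transition with at least 4 levels.
#' @param inhibition_col Percent-inhibition column.
#' @param constrain_plateaus If `TRUE` (default) fix bottom = 0 and
#'   top = 100; otherwise both are fitted.
#' @return An object of class `ic50_fit` with elements `ic50`, `hill`,
#'   `ic50_se`, `hill_se`, `top`, `bottom`, `converged`, `no_inhibition`,
#'   `data`, `fit`.
#' @export
fit_ic50 <- function(data, conc_col = "conc_uM", inhibition_col = "inhibition",
                     constrain_plateaus = TRUE) {
  check_columns(data, c(conc_col, inhibition_col), "`data`")
  conc <- data[[conc_col]]
  inh <- data[[inhibition_col]]
  ok <- !is.na(conc) & !is.na(inh) & conc > 0
  conc <- conc[ok]; inh <- inh[ok]
  if (length(unique(conc)) < 4) {
    abort("At least 4 positive concentrations are required for an IC50 fit.")
  }
  base <- list(data = tibble::tibble(conc_uM = conc, inhibition = inh),
               constrained = constrain_plateaus)
  if (max(inh) < 5) {
    return(structure(
      c(base, list(ic50 = NA_real_, hill = NA_real_, ic50_se = NA_real_,
                   hill_se = NA_real_, top = NA_real_, bottom = NA_real_,
                   converged = FALSE, no_inhibition = TRUE, fit = NULL)),
      class = "ic50_fit"
    ))
  }
  # parameterise ic50 on the log10 scale for a well-conditioned fit
  start_ic50 <- tryCatch(
    exp(stats::approx(inh, log(conc), xout = 50, ties = mean)$y),
    error = function(e) NA_real_
  )
  if (!is.finite(start_ic50)) start_ic50 <- stats::median(conc)
  df <- data.frame(conc = conc, inh = inh)
  fit <- tryCatch({
    if (constrain_plateaus) {
      minpack.lm::nlsLM(
        inh ~ 100 / (1 + (10^lic50 / conc)^hill), data = df,
        start = list(lic50 = log10(start_ic50), hill = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        inh ~ bottom + (top - bottom) / (1 + (10^lic50 / conc)^hill),
        data = df,
        start = list(lic50 = log10(start_ic50), hill = 1, top = max(inh),
                     bottom = min(inh)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    }
  }, error = function(e) {
    abort(sprintf(
      "IC50 fit failed to converge (start ic50 = %.3g uM): %s",
      start_ic50, conditionMessage(e)
    ))
  })
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  ic50 <- 10^cf[["lic50"]]
  structure(
    c(base, list(
      ic50 = ic50, hill = cf[["hill"]],
      # delta method: se(ic50) = ln(10) * ic50 * se(log10 ic50)
      ic50_se = log(10) * ic50 * unname(se["lic50"]),
      hill_se = unname(se["hill"]),
      top = if (constrain_plateaus) 100 else cf[["top"]],
      bottom = if (constrain_plateaus) 0 else cf[["bottom"]],
      converged = TRUE, no_inhibition = FALSE, fit = fit
    )),
    class = "ic50_fit"
  )
}

#' @export
tidy.ic50_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ic50", "hill"),
    estimate = c(x$ic50, x$hill),
    std.error = c(x$ic50_se, x$hill_se)
  )
}

#' @export
glance.ic50_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, hill = x$hill, top = x$top, bottom = x$bottom,
                 converged = x$converged, no_inhibition = x$no_inhibition,
                 n = nrow(x$data))
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$no_inhibition) {
    cat("Dose-response fit: no inhibition detected (all responses near 0%)\n")
  } else {
    cat(sprintf("IC50 = %.4g uM (SE %.2g), Hill slope = %.3g\n",
                x$ic50, x$ic50_se, x$hill))
  }
  invisible(x)
}

#' @export
autoplot.ic50_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$conc_uM, y = .data$inhibition)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[inhibitor] (uM)", y = "Inhibition (%)")
  if (isTRUE(object$converged)) {
    grid <- tibble::tibble(conc_uM = exp(seq(log(min(object$data$conc_uM)),
                                             log(max(object$data$conc_uM)),
                                             length.out = 200)))
    grid$inhibition <- object$bottom + (object$top - object$bottom) /
      (1 + (object$ic50 / grid$conc_uM)^object$hill)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick") +
      ggplot2::labs(title = sprintf("IC50 = %.3g uM", object$ic50))
  }
  p
}

#' Classify inhibition reversibility from rate-vs-enzyme lines
#'
#' For a reversible inhibitor, plots of rate against enzyme concentration at
#' fixed inhibitor levels are straight lines through the origin whose slopes
#' fall as inhibitor rises; a positive intercept growing with inhibitor
#' concentration is the signature of irreversible (time-dependent enzyme
#' depleting) behaviour.
#'
#' @param data Long-format rates: columns `v`, `e_UmL` (enzyme, U/mL),
#'   `i_uM` (inhibitor, uM). At least 3 enzyme levels per inhibitor level and
#'   at least 2 inhibitor levels.
#' @param intercept_tol Relative tolerance on the intercept: a line is
#'   "through the origin" when |intercept| < `intercept_tol` * max(v).
#' @return A list of class `reversibility_call`: `call` ("reversible" or
#'   "irreversible-suspect"), `lines` (per-inhibitor slope/intercept tibble),
#'   and the failed checks, if any.
#' @export
classify_reversibility <- function(data, intercept_tol = 0.05) {
  check_columns(data, c("v", "e_UmL", "i_uM"), "`data`")
  if (length(unique(data$i_uM)) < 2) {
    abort("At least two inhibitor levels are required.")
  }
  lines <- data |>
    dplyr::group_by(i_uM = .data$i_uM) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$e_UmL)) < 3) {
        abort("At least 3 enzyme concentrations per inhibitor level.")
      }
      l <- ols_line(d$e_UmL, d$v)
      tibble::tibble(slope = l$slope, intercept = l$intercept, r2 = l$r2)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$i_uM)
  vmax_obs <- max(abs(data$v))
  origin_ok <- all(abs(lines$intercept) < intercept_tol * vmax_obs)
  slopes_decreasing <- all(diff(lines$slope) < 0)
  call <- if (origin_ok && slopes_decreasing) "reversible" else "irreversible-suspect"
  structure(
    list(call = call, lines = lines, origin_ok = origin_ok,
         slopes_decreasing = slopes_decreasing),
    class = "reversibility_call"
  )
}

#' @export
print.reversibility_call <- function(x, ...) {
  cat(sprintf(
    "Reversibility: %s (origin intercepts %s, slopes %s with [I])\n",
    x$call, if (x$origin_ok) "ok" else "non-zero",
    if (x$slopes_decreasing) "decreasing" else "not monotone"
  ))
  invisible(x)
}

#' @exportS3Method
tidy.reversibility_call <- function(x, ...) x$lines

#' Fit Lineweaver-Burk lines per inhibitor level
#'
#' Ordinary (unweighted) least squares of 1/v on 1/\[S\] within each inhibitor
#' concentration: the double-reciprocal linearisation of the Michaelis-Menten
#' law. Points with v = 0 cannot be reciprocated and are dropped with a
#' warning.
#'
#' @param data Long-format rates: columns `v` (rate), `s_mM` (substrate, mM),
#'   `i_uM` (inhibitor, uM); at least 3 substrate levels per inhibitor level.
#' @return An object of class `lb_lines`: a tibble with one row per inhibitor
#'   level (`i_uM`, `slope` = Km_app/Vmax_app, `intercept` = 1/Vmax_app,
#'   `r2`, `n`).
#' @export
fit_lb_lines <- function(data) {
  check_columns(data, c("v", "s_mM", "i_uM"), "`data`")
  zero <- data$v <= 0 | data$s_mM <= 0
  if (any(zero)) {
    warn(sprintf("Dropped %d point(s) with non-positive rate or substrate.",
                 sum(zero)))
    data <- data[!zero, , drop = FALSE]
  }
  lines <- data |>
    dplyr::group_by(i_uM = .data$i_uM) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$s_mM)) < 3) {
        abort("At least 3 substrate levels per inhibitor level.")
      }
      l <- ols_line(1 / d$s_mM, 1 / d$v)
      tibble::tibble(slope = l$slope, intercept = l$intercept, r2 = l$r2,
                     n = nrow(d))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$i_uM)
  class(lines) <- c("lb_lines", class(lines))
  lines
}

#' @exportS3Method
autoplot.lb_lines <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(colour = factor(.data$i_uM))) +
    ggplot2::geom_abline(ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = factor(.data$i_uM))) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::expand_limits(
      x = c(-1.2 * max(object$slope / object$intercept)^-1, 25),
      y = c(0, max(object$intercept) * 3)
    ) +
    ggplot2::labs(x = "1/[S] (1/mM)", y = "1/v", colour = "[I] (uM)",
                  title = "Lineweaver-Burk primary plot")
}

#' Classify the inhibition mode from Lineweaver-Burk lines
#'
#' Diagnoses the mechanism from where the double-reciprocal lines intersect:
#' on the y-axis (competitive), on the x-axis (non-competitive), parallel
#' (uncompetitive), or in the second/third quadrant (mixed). Intersections
#' are computed for every pair of lines and summarised by their medians;
#' axis membership uses tolerance bands scaled by the uninhibited 1/Km and
#' 1/Vmax.
#'
#' @param lines An `lb_lines` object (>= 2 inhibitor levels).
#' @param tol_axis Relative half-width of the axis bands: on-y-axis if
#'   |x*| < `tol_axis`/Km; on-x-axis if |y*| < `tol_axis`/Vmax.
#' @param parallel_tol Lines are parallel when the relative slope spread is
#'   below this value.
#' @param consistency_tol Pairwise intersections scattered (in x) by more
#'   than this fraction of their median magnitude yield the call `"none"`.
#' @return A list of class `inhibition_call`: `type`, `quadrant`,
#'   `x_intersect`, `y_intersect`, `parallel`, `intersections` (pairwise
#'   tibble).
#' @export
classify_inhibition <- function(lines, tol_axis = 0.05, parallel_tol = 1e-3,
                                consistency_tol = 0.5) {
  stopifnot(inherits(lines, "lb_lines"))
  if (nrow(lines) < 2) abort("At least two inhibitor levels are required.")
  base <- lines[which.min(lines$i_uM), ]
  vmax <- 1 / base$intercept
  km <- base$slope / base$intercept

  spread <- (max(lines$slope) - min(lines$slope)) / stats::median(abs(lines$slope))
  if (spread < parallel_tol) {
    return(structure(
      list(type = "uncompetitive", quadrant = NA_character_,
           x_intersect = NA_real_, y_intersect = NA_real_, parallel = TRUE,
           intersections = tibble::tibble()),
      class = "inhibition_call"
    ))
  }

  pairs <- utils::combn(nrow(lines), 2)
  inter <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- lines[pairs[1, j], ]; b <- lines[pairs[2, j], ]
    if (abs(a$slope - b$slope) < 1e-12 * max(abs(a$slope), abs(b$slope))) {
      return(tibble::tibble())
    }
    x <- (b$intercept - a$intercept) / (a$slope - b$slope)
    tibble::tibble(i1 = a$i_uM, i2 = b$i_uM, x = x, y = a$slope * x + a$intercept)
  })
  mx <- stats::median(inter$x); my <- stats::median(inter$y)

  if (nrow(inter) > 1) {
    scatter <- stats::sd(inter$x) / max(abs(mx), 1e-12)
    if (is.finite(scatter) && scatter > consistency_tol) {
      return(structure(
        list(type = "none", quadrant = NA_character_, x_intersect = mx,
             y_intersect = my, parallel = FALSE, intersections = inter),
        class = "inhibition_call"
      ))
    }
  }

  on_y <- abs(mx) < tol_axis / km
  on_x <- abs(my) < tol_axis / vmax
  type <- if (on_y) {
    "competitive"
  } else if (on_x && mx < 0) {
    "non-competitive"
  } else if (mx < 0) {
    "mixed"
  } else {
    "none"
  }
  quadrant <- if (type == "mixed") {
    if (my > 0) "second" else "third"
  } else {
    NA_character_
  }
  structure(
    list(type = type, quadrant = quadrant, x_intersect = mx, y_intersect = my,
         parallel = FALSE, intersections = inter),
    class = "inhibition_call"
  )
}

#' @export
print.inhibition_call <- function(x, ...) {
  if (x$parallel) {
    cat("Inhibition type: uncompetitive (parallel Lineweaver-Burk lines)\n")
  } else {
    cat(sprintf("Inhibition type: %s%s (median intersection x = %.4g, y = %.4g)\n",
                x$type,
                if (!is.na(x$quadrant)) paste0(" (", x$quadrant, " quadrant)") else "",
                x$x_intersect, x$y_intersect))
  }
  invisible(x)
}

#' Secondary-plot estimation of Ki, alpha-Ki and alpha
#'
#' Regresses the Lineweaver-Burk slopes and y-intercepts on inhibitor
#' concentration. Under the general mixed-inhibition law the slope grows as
#' `Km/Vmax * (1 + [I]/Ki)` and the intercept as `1/Vmax * (1 + [I]/(alpha*Ki))`,
#' so the two secondary slopes yield the competitive constant Ki and the
#' uncompetitive-side constant alpha-Ki; their ratio is alpha. Km and Vmax
#' are taken from the uninhibited (lowest-\[I\]) line.
#'
#' @param lines An `lb_lines` object with at least 3 inhibitor levels.
#' @return An object of class `mm_secondary` with fields `km` (mM), `vmax`,
#'   `ki` (uM), `alpha_ki` (uM), `alpha`, the two secondary regressions'
#'   r-squared, and flags for absent competitive/uncompetitive components.
#' @export
fit_secondary <- function(lines) {
  stopifnot(inherits(lines, "lb_lines"))
  if (nrow(lines) < 3) abort("At least three inhibitor levels are required.")
  base <- lines[which.min(lines$i_uM), ]
  vmax <- 1 / base$intercept
  km <- base$slope / base$intercept

  slope_reg <- ols_line(lines$i_uM, lines$slope)
  int_reg <- ols_line(lines$i_uM, lines$intercept)

  slope_scale <- base$slope / max(lines$i_uM)
  no_competitive <- abs(slope_reg$slope) < 1e-9 * slope_scale
  ki <- if (no_competitive) Inf else (km / vmax) / slope_reg$slope
  int_scale <- base$intercept / max(lines$i_uM)
  no_uncompetitive <- abs(int_reg$slope) < 1e-9 * int_scale
  alpha_ki <- if (no_uncompetitive) Inf else (1 / vmax) / int_reg$slope
  if (!no_competitive && ki <= 0) {
    abort(sprintf(
      "Fitted Ki is non-positive (%.4g uM): slopes fall with [I]; check data.",
      ki
    ))
  }
  alpha <- alpha_ki / ki
  structure(
    list(km = km, vmax = vmax, ki = ki, alpha_ki = alpha_ki, alpha = alpha,
         slope_r2 = slope_reg$r2, intercept_r2 = int_reg$r2,
         no_competitive = no_competitive, no_uncompetitive = no_uncompetitive,
         lines = lines),
    class = "mm_secondary"
  )
}

#' @exportS3Method
tidy.mm_secondary <- function(x, ...) {
  tibble::tibble(
    term = c("km", "vmax", "ki", "alpha_ki", "alpha"),
    estimate = c(x$km, x$vmax, x$ki, x$alpha_ki, x$alpha),
    unit = c("mM", "rate", "uM", "uM", "")
  )
}

#' @exportS3Method
glance.mm_secondary <- function(x, ...) {
  tibble::tibble(km = x$km, vmax = x$vmax, ki = x$ki, alpha_ki = x$alpha_ki,
                 alpha = x$alpha, slope_r2 = x$slope_r2,
                 intercept_r2 = x$intercept_r2)
}

#' @export
print.mm_secondary <- function(x, ...) {
  cat(sprintf("Km = %.4g mM, Vmax = %.4g\n", x$km, x$vmax))
  if (x$no_competitive) {
    cat("Ki = Inf (no competitive component: slopes independent of [I])\n")
  } else {
    cat(sprintf("Ki = %.4g uM, alpha*Ki = %.4g uM, alpha = %.4g\n",
                x$ki, x$alpha_ki, x$alpha))
  }
  invisible(x)
}

#' Global nonlinear fit of the mixed-inhibition rate law
#'
#' Direct Levenberg-Marquardt fit of
#' `v = Vmax * s / (Km * (1 + i/Ki) + s * (1 + i/(alpha*Ki)))` to the raw
#' rates; serves as a cross-check on the linearised Lineweaver-Burk +
#' secondary-plot route, which remains the default analysis.
#'
#' @param data Long-format rates (`v`, `s_mM`, `i_uM`).
#' @param start Optional named starting values (`km`, `vmax`, `ki`, `alpha`);
#'   by default seeded from the linearised pipeline.
#' @return A tibble with one row: `km`, `vmax`, `ki`, `alpha_ki`, `alpha`.
#' @export
fit_mixed_global <- function(data, start = NULL) {
  check_columns(data, c("v", "s_mM", "i_uM"), "`data`")
  if (is.null(start)) {
    sec <- fit_secondary(fit_lb_lines(data))
    start <- list(km = sec$km, vmax = sec$vmax,
                  ki = if (is.finite(sec$ki)) sec$ki else 1e6,
                  alpha = if (is.finite(sec$alpha)) sec$alpha else 1)
  }
  fit <- minpack.lm::nlsLM(
    v ~ vmax * s_mM / (km * (1 + i_uM / ki) + s_mM * (1 + i_uM / (alpha * ki))),
    data = data, start = start,
    lower = c(km = 1e-9, vmax = 1e-9, ki = 1e-9, alpha = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- as.list(coef(fit))
  tibble::tibble(km = cf$km, vmax = cf$vmax, ki = cf$ki,
                 alpha_ki = cf$alpha * cf$ki, alpha = cf$alpha)
}
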