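# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Generators take an explicit seed; nothing uses global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Attach a ground-truth record (generator name, parameters, seed, noise model)
# to a generated dataset so round-trip tests can recover the simulation truth.
set_ground_truth <- function(data, generator, params, seed, noise) {
  attr(data, "ground_truth") <- list(
    generator = generator,
    params = params,
    seed = seed,
    noise = noise
  )
  data
}

#' Retrieve the ground-truth record attached to a simulated dataset
#'
#' Every `sim_*()` generator stores the parameters it was called with
#' alongside the data it returns. `ground_truth()` retrieves that record.
#'
#' @param data A tibble produced by one of the `sim_*()` generators.
#' @return A list with elements `generator`, `params`, `seed` and `noise`,
#'   or `NULL` if `data` carries no ground-truth record.
#' @export
ground_truth <- function(data) {
  attr(data, "ground_truth", exact = TRUE)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

is_missing_num <- function(x) is.na(x) | !is.finite(x)

# Unweighted least-squares line y ~ x returning slope, intercept, r2.
ols_line <- function(x, y) {
  fit <- lm(y ~ x)
  cf <- coef(fit)
  ybar <- mean(y)
  ss_tot <- sum((y - ybar)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(residuals(fit)^2) / ss_tot
  list(
    slope = unname(cf[2]), intercept = unname(cf[1]),
    r2 = r2, fit = fit
  )
}

#' @importFrom stats residuals
NULL
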