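# CSV input validation and versioned JSON report rendering.

input_schemas <- list(
  compounds = c("smiles", "ic50_nM"),
  candidates = c("id", "smiles", "probability", "docking_score", "cns",
                 "qplogbb", "bbb_score", "qppcaco", "hoa", "mw", "logp",
                 "hbd", "hba", "logs", "metab"),
  rates = c("v", "s_mM", "i_uM"),
  reversibility = c("v", "e_UmL", "i_uM"),
  titration = c("temperature_K", "q_molL", "f"),
  dose_response = c("conc_uM", "inhibition"),
  decay = c("time_s", "counts")
)

#' Read and validate a pipeline input CSV
#'
#' Reads one of the documented long-format CSV schemas and fails loudly,
#' naming the offending column, when the header does not match.
#'
#' @param path CSV file path.
#' @param kind One of `"compounds"`, `"candidates"`, `"rates"`,
#'   `"reversibility"`, `"titration"`, `"dose_response"`, `"decay"`.
#' @return A tibble with at least the schema's columns.
#' @export
read_input_csv <- function(path, kind = names(input_schemas)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  data <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  check_columns(data, input_schemas[[kind]], sprintf("CSV '%s'", path))
  data
}

#' Render a versioned JSON analysis report
#'
#' Wraps arbitrary result sections in a stable envelope carrying the report
#' schema version, package version, the effective configuration and content
#' hashes of the input files, then writes pretty-printed JSON.
#'
#' @param sections Named list of report content (coerced by jsonlite).
#' @param path Output file; the report list is also returned invisibly.
#' @param config Named list echoed verbatim into the report.
#' @param inputs Character vector of input file paths to hash.
#' @return The report list, invisibly.
#' @export
write_report <- function(sections, path, config = list(), inputs = character()) {
  hashes <- if (length(inputs)) {
    as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs)))
  } else {
    NULL
  }
  report <- c(
    list(
      schema_version = "1.0",
      package = "bchescreen",
      package_version = as.character(utils::packageVersion("bchescreen")),
      config = config,
      input_md5 = hashes
    ),
    sections
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}

#' Full binding-biophysics report for a multi-temperature titration
#'
#' Runs the complete quenching workflow on a titration table: per-temperature
#' Stern-Volmer and double-log fits, quenching-mechanism classification,
#' Van't Hoff thermodynamics, Gibbs energies and binding-force assignment.
#'
#' @param titration Table with columns `temperature_K`, `q_molL`, `f`
#'   (one q = 0 row per temperature supplies F0).
#' @param tau0 Unquenched fluorescence lifetime, s.
#' @return A list of class `binding_report`: `per_temperature` (tibble with
#'   ksv, kq, ka, n per temperature), `quenching`, `thermo` (`vant_hoff`
#'   object), `forces`.
#' @export
binding_report <- function(titration, tau0 = 1e-8) {
  check_columns(titration, c("temperature_K", "q_molL", "f"), "`titration`")
  per_t <- titration |>
    dplyr::group_by(temperature_K = .data$temperature_K) |>
    dplyr::group_modify(function(d, key) {
      d$temperature_K <- key$temperature_K
      sv <- stern_volmer_fit(d, tau0 = tau0)
      dl <- double_log_fit(d)
      tibble::tibble(ksv = sv$ksv, kq = sv$kq, sv_r2 = sv$r2,
                     ka = dl$ka, n = dl$n, dlog_r2 = dl$r2)
    }) |>
    dplyr::ungroup()
  quench <- classify_quenching(per_t)
  thermo <- vant_hoff_fit(per_t[, c("temperature_K", "ka")])
  forces <- classify_forces(thermo$dh, thermo$ds, min(per_t$temperature_K))
  structure(
    list(per_temperature = per_t, quenching = quench, thermo = thermo,
         forces = forces),
    class = "binding_report"
  )
}

#' @export
print.binding_report <- function(x, ...) {
  print(x$per_temperature)
  print(x$quenching)
  print(x$thermo)
  cat(sprintf("Forces: %s, %s-driven, %sspontaneous\n",
              x$forces$forces, x$forces$driven_by,
              if (x$forces$spontaneous) "" else "NOT "))
  invisible(x)
}

#' @exportS3Method
tidy.binding_report <- function(x, ...) x$per_temperature

#' @exportS3Method
glance.binding_report <- function(x, ...) {
  tibble::tibble(
    mechanism = x$quenching$mechanism,
    dh_kJmol = x$thermo$dh / 1000, ds_JmolK = x$thermo$ds,
    forces = x$forces$forces, driven_by = x$forces$driven_by,
    spontaneous = x$forces$spontaneous
  )
}

#' Full kinetics report for a rate table
#'
#' Lineweaver-Burk lines, inhibition-mode call and secondary-plot constants
#' in one step, with the global nonlinear fit as an optional cross-check.
#'
#' @param rates Long-format rate table (`v`, `s_mM`, `i_uM`).
#' @param cross_check Also run [fit_mixed_global()] and report its estimates.
#' @return A list of class `kinetics_report`: `lines`, `call` (inhibition
#'   type), `params` (`mm_secondary`), optionally `global`.
#' @export
kinetics_report <- function(rates, cross_check = FALSE) {
  lines <- fit_lb_lines(rates)
  call <- classify_inhibition(lines)
  params <- fit_secondary(lines)
  out <- list(lines = lines, call = call, params = params)
  if (cross_check) out$global <- fit_mixed_global(rates)
  structure(out, class = "kinetics_report")
}

#' @export
print.kinetics_report <- function(x, ...) {
  print(x$call)
  print(x$params)
  if (!is.null(x$global)) {
    cat("Global nonlinear cross-check:\n")
    print(x$global)
  }
  invisible(x)
}

#' @exportS3Method
glance.kinetics_report <- function(x, ...) {
  dplyr::mutate(glance(x$params), type = x$call$type,
                quadrant = x$call$quadrant, .before = 1)
}
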