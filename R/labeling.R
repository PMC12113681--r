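#' Label compounds by potency
#'
#' Assigns the two-class activity label used to train the QSAR classifier:
#' `active` for potencies strictly below `active_max`, `inactive` strictly
#' above `inactive_min`, and `excluded` for everything in between (the
#' ambiguous mid-potency band) or missing. Both inequalities are strict, so a
#' potency exactly at a threshold is excluded.
#'
#' @param data A data frame of compounds.
#' @param potency_col Name of the column holding IC50 potencies in nM.
#' @param active_max Upper potency bound (nM, exclusive) for actives.
#'   Default 1000 nM.
#' @param inactive_min Lower potency bound (nM, exclusive) for inactives.
#'   Default 100,000 nM.
#' @return `data` as a tibble with an added `label` column (factor with
#'   levels active, inactive, excluded).
#' @examples
#' label_by_potency(tibble::tibble(ic50_nM = c(500, 1000, 50000, 2e5, NA)))
#' @export
label_by_potency <- function(data, potency_col = "ic50_nM",
                             active_max = 1000, inactive_min = 100000) {
  check_columns(data, potency_col, "`data`")
  if (!is.numeric(active_max) || !is.numeric(inactive_min) ||
      active_max <= 0 || inactive_min <= 0) {
    abort("Potency thresholds must be positive.")
  }
  if (active_max >= inactive_min) {
    abort("`active_max` must be strictly below `inactive_min`.")
  }
  potency <- data[[potency_col]]
  if (any(!is.na(potency) & potency <= 0)) {
    abort("Potencies must be positive (or missing).")
  }
  label <- dplyr::case_when(
    is.na(potency) ~ "excluded",
    potency < active_max ~ "active",
    potency > inactive_min ~ "inactive",
    TRUE ~ "excluded"
  )
  dplyr::mutate(
    tibble::as_tibble(data),
    label = factor(label, levels = c("active", "inactive", "excluded"))
  )
}

#' Deduplicate and clean a compound table
#'
#' Drops records with missing structure or potency, canonicalises each SMILES
#' (structures that fail to parse are dropped with a warning naming them), and
#' keeps the first occurrence of each canonical structure.
#'
#' @param data Data frame with a SMILES column and a potency column.
#' @param smiles_col,potency_col Column names; defaults `"smiles"`,
#'   `"ic50_nM"`.
#' @return A tibble with one row per canonical structure and an added
#'   `canonical_smiles` column.
#' @export
clean_compounds <- function(data, smiles_col = "smiles",
                            potency_col = "ic50_nM") {
  check_columns(data, c(smiles_col, potency_col), "`data`")
  out <- tibble::as_tibble(data)
  keep <- !is.na(out[[smiles_col]]) & nzchar(out[[smiles_col]]) &
    !is.na(out[[potency_col]])
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  canon <- canonicalize_smiles(out[[smiles_col]])
  bad <- is.na(canon)
  if (any(bad)) {
    warn(sprintf(
      "Dropped %d record(s) with unparseable SMILES: %s",
      sum(bad), paste(utils::head(out[[smiles_col]][bad], 5), collapse = ", ")
    ))
  }
  out$canonical_smiles <- canon
  out <- out[!bad, , drop = FALSE]
  dplyr::distinct(out, .data$canonical_smiles, .keep_all = TRUE)
}
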