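#' Screening-cascade thresholds
#'
#' Bundles every cutoff of the sequential virtual-screening filter. Defaults
#' follow the published cascade: predicted-activity probability strictly
#' above 0.5; docking score at or below -7.000 kcal/mol; CNS activity score
#' strictly above 0, brain/blood partition coefficient (QPlogBB) strictly
#' above -3 and blood-brain-barrier (BBB) score strictly above 3; Caco-2
#' permeability strictly above 500 nm/s and human oral absorption strictly
#' above 70%; at most one Lipinski rule-of-five violation and no Jorgensen
#' rule-of-three violation.
#'
#' @param prob_min Probability cutoff (exclusive).
#' @param dock_max Docking-score cutoff in kcal/mol (inclusive; scores are
#'   negative, more negative is better).
#' @param cns_min,qplogbb_min,bbb_min CNS-penetration cutoffs (all exclusive).
#' @param qppcaco_min Caco-2 permeability cutoff, nm/s (exclusive).
#' @param hoa_min Human oral absorption cutoff, percent (exclusive).
#' @param lipinski_max_violations Maximum allowed rule-of-five violations.
#' @param jorgensen_max_violations Maximum allowed rule-of-three violations.
#' @param logs_min,caco_ro3_min,metab_max Jorgensen rule-of-three bounds:
#'   predicted aqueous solubility logS strictly above `logs_min`, Caco-2
#'   permeability strictly above `caco_ro3_min` nm/s, and fewer than
#'   `metab_max` predicted primary metabolites.
#' @return A list of class `cascade_thresholds`.
#' @export
cascade_thresholds <- function(prob_min = 0.5, dock_max = -7.000,
                               cns_min = 0, qplogbb_min = -3, bbb_min = 3,
                               qppcaco_min = 500, hoa_min = 70,
                               lipinski_max_violations = 1,
                               jorgensen_max_violations = 0,
                               logs_min = -5.7, caco_ro3_min = 22,
                               metab_max = 7) {
  structure(
    list(
      prob_min = prob_min, dock_max = dock_max,
      cns_min = cns_min, qplogbb_min = qplogbb_min, bbb_min = bbb_min,
      qppcaco_min = qppcaco_min, hoa_min = hoa_min,
      lipinski_max_violations = lipinski_max_violations,
      jorgensen_max_violations = jorgensen_max_violations,
      logs_min = logs_min, caco_ro3_min = caco_ro3_min, metab_max = metab_max
    ),
    class = "cascade_thresholds"
  )
}

# keep/reason pair for one stage; missing descriptors fail conservatively.
stage_eval <- function(values, test) {
  missing <- Reduce(`|`, lapply(values, is_missing_num))
  ok <- !missing & test
  ok[is.na(ok)] <- FALSE
  reason <- rep(NA_character_, length(ok))
  reason[missing] <- "missing_field"
  reason[!ok & !missing] <- "threshold"
  list(keep = ok, reason = reason)
}

#' Individual cascade stages
#'
#' Each stage returns the records that survive it. Records with a missing
#' descriptor fail the stage (conservative) rather than passing silently.
#'
#' @param records Candidate table (see [sim_candidate_table()] for the full
#'   column schema).
#' @param thresholds A [cascade_thresholds()] object.
#' @param prob_min,dock_max Stage-specific overrides.
#' @return The surviving rows of `records`, as a tibble.
#' @name cascade_stages
NULL

#' @rdname cascade_stages
#' @export
probability_stage <- function(records, prob_min = 0.5) {
  check_columns(records, "probability", "`records`")
  ev <- stage_eval(records["probability"], records$probability > prob_min)
  tibble::as_tibble(records)[ev$keep, , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
docking_stage <- function(records, dock_max = -7.000) {
  check_columns(records, "docking_score", "`records`")
  ev <- stage_eval(records["docking_score"], records$docking_score <= dock_max)
  tibble::as_tibble(records)[ev$keep, , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
cns_stage <- function(records, thresholds = cascade_thresholds()) {
  check_columns(records, c("cns", "qplogbb", "bbb_score"), "`records`")
  ev <- stage_eval(
    records[c("cns", "qplogbb", "bbb_score")],
    records$cns > thresholds$cns_min &
      records$qplogbb > thresholds$qplogbb_min &
      records$bbb_score > thresholds$bbb_min
  )
  tibble::as_tibble(records)[ev$keep, , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
absorption_stage <- function(records, thresholds = cascade_thresholds()) {
  check_columns(records, c("qppcaco", "hoa"), "`records`")
  ev <- stage_eval(
    records[c("qppcaco", "hoa")],
    records$qppcaco > thresholds$qppcaco_min & records$hoa > thresholds$hoa_min
  )
  tibble::as_tibble(records)[ev$keep, , drop = FALSE]
}

#' Lipinski rule-of-five violation counts
#'
#' Counts violations against MW <= 500 Da, logP <= 5, hydrogen-bond donors
#' <= 5 and acceptors <= 10.
#'
#' @param records Table with columns `mw`, `logp`, `hbd`, `hba`.
#' @param max_violations Violations tolerated before a record fails
#'   (default 1, the customary allowance).
#' @return `records` with added `lipinski_violations` (0-4) and
#'   `lipinski_pass` columns.
#' @export
lipinski_violations <- function(records, max_violations = 1) {
  check_columns(records, c("mw", "logp", "hbd", "hba"), "`records`")
  v <- (records$mw > 500) + (records$logp > 5) +
    (records$hbd > 5) + (records$hba > 10)
  dplyr::mutate(tibble::as_tibble(records),
                lipinski_violations = as.integer(v),
                lipinski_pass = !is.na(v) & v <= max_violations)
}

#' Jorgensen rule-of-three violation counts
#'
#' Counts violations against predicted solubility logS > -5.7, Caco-2
#' permeability > 22 nm/s and fewer than 7 predicted primary metabolites.
#'
#' @param records Table with columns `logs`, `qppcaco`, `metab`.
#' @param max_violations Violations tolerated (default 0: all three bounds
#'   must hold).
#' @param logs_min,caco_min,metab_max Configurable bounds.
#' @return `records` with added `jorgensen_violations` (0-3) and
#'   `jorgensen_pass` columns.
#' @export
jorgensen_violations <- function(records, max_violations = 0,
                                 logs_min = -5.7, caco_min = 22,
                                 metab_max = 7) {
  check_columns(records, c("logs", "qppcaco", "metab"), "`records`")
  v <- (records$logs <= logs_min) + (records$qppcaco <= caco_min) +
    (records$metab >= metab_max)
  dplyr::mutate(tibble::as_tibble(records),
                jorgensen_violations = as.integer(v),
                jorgensen_pass = !is.na(v) & v <= max_violations)
}

#' Run the full screening cascade
#'
#' Applies the five stages in their published order — predicted-activity
#' probability, docking score, CNS/BBB penetration, gastrointestinal
#' absorption, drug-likeness (Lipinski + Jorgensen) — and reports per-stage
#' survivor counts and, for every failing record, the first stage it failed
#' and why. Because the stages are conjunctive, the final survivor set does
#' not depend on stage order; only the attributed first failure does.
#'
#' @param records Candidate table with the documented descriptor columns.
#' @param thresholds A [cascade_thresholds()] object.
#' @return An object of class `cascade_report`: `records` (input plus `pass`,
#'   `first_failure`, `failure_reason`), `stage_counts` (tibble of stage name
#'   and survivors), `survivors` (tibble of passing records).
#' @export
run_cascade <- function(records, thresholds = cascade_thresholds()) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  if (n == 0) {
    empty <- tibble::tibble(stage = cascade_stage_names(), survivors = 0L)
    return(structure(
      list(records = records, stage_counts = empty, survivors = records,
           thresholds = thresholds),
      class = "cascade_report"
    ))
  }
  evals <- cascade_stage_evals(records, thresholds)
  alive <- rep(TRUE, n)
  first_failure <- rep(NA_character_, n)
  failure_reason <- rep(NA_character_, n)
  counts <- integer(length(evals))
  for (j in seq_along(evals)) {
    ev <- evals[[j]]
    newly_failed <- alive & !ev$keep
    first_failure[newly_failed] <- names(evals)[j]
    failure_reason[newly_failed] <- ev$reason[newly_failed]
    alive <- alive & ev$keep
    counts[j] <- sum(alive)
  }
  out <- dplyr::mutate(records, pass = alive,
                       first_failure = first_failure,
                       failure_reason = failure_reason)
  structure(
    list(
      records = out,
      stage_counts = tibble::tibble(stage = names(evals), survivors = counts),
      survivors = out[alive, , drop = FALSE],
      thresholds = thresholds
    ),
    class = "cascade_report"
  )
}

cascade_stage_names <- function() {
  c("probability", "docking", "cns", "absorption", "druglikeness")
}

cascade_stage_evals <- function(records, th) {
  lip <- lipinski_violations(records, th$lipinski_max_violations)
  jor <- jorgensen_violations(records, th$jorgensen_max_violations,
                              th$logs_min, th$caco_ro3_min, th$metab_max)
  list(
    probability = stage_eval(records["probability"],
                             records$probability > th$prob_min),
    docking = stage_eval(records["docking_score"],
                         records$docking_score <= th$dock_max),
    cns = stage_eval(records[c("cns", "qplogbb", "bbb_score")],
                     records$cns > th$cns_min &
                       records$qplogbb > th$qplogbb_min &
                       records$bbb_score > th$bbb_min),
    absorption = stage_eval(records[c("qppcaco", "hoa")],
                            records$qppcaco > th$qppcaco_min &
                              records$hoa > th$hoa_min),
    druglikeness = stage_eval(records[c("mw", "logp", "hbd", "hba",
                                        "logs", "qppcaco", "metab")],
                              lip$lipinski_pass & jor$jorgensen_pass)
  )
}

#' @exportS3Method
tidy.cascade_report <- function(x, ...) x$records

#' @exportS3Method
glance.cascade_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$stage_counts, names_from = "stage",
                             values_from = "survivors")
  dplyr::mutate(wide, n_input = nrow(x$records), .before = 1)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("Screening cascade: %d candidates in, %d survivors\n",
              nrow(x$records), nrow(x$survivors)))
  for (j in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  after %-12s %d\n",
                x$stage_counts$stage[j], x$stage_counts$survivors[j]))
  }
  invisible(x)
}

#' @exportS3Method
autoplot.cascade_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(stage = "input", survivors = nrow(object$records)),
    object$stage_counts
  )
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$survivors)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$survivors), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "Surviving candidates",
                  title = "Screening-cascade funnel")
}
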