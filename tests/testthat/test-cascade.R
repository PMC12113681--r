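cand <- function(...) {
  defaults <- list(
    id = "x", smiles = "CCO", probability = 0.9, docking_score = -8,
    cns = 1, qplogbb = -0.5, bbb_score = 4.2, qppcaco = 800, hoa = 85,
    mw = 350, logp = 2, hbd = 1, hba = 4, logs = -3, metab = 3
  )
  tibble::as_tibble(modifyList(defaults, list(...)))
}

test_that("probability and docking stages honour their boundary conventions", {
  d <- dplyr::bind_rows(cand(id = "a", probability = 0.7946475),
                        cand(id = "b", probability = 0.5),
                        cand(id = "c", probability = 0.2))
  expect_equal(probability_stage(d)$id, "a")  # 0.5 exactly is removed
  expect_equal(nrow(probability_stage(d[0, ])), 0)

  d <- dplyr::bind_rows(cand(id = "a", docking_score = -7.942),
                        cand(id = "b", docking_score = -7.000),
                        cand(id = "c", docking_score = -6.9))
  # scores at exactly the cutoff are kept (<=)
  expect_equal(docking_stage(d)$id, c("a", "b"))
})

test_that("CNS and absorption stages are strict conjunctions", {
  d <- dplyr::bind_rows(
    cand(id = "ok", cns = 1, qplogbb = -0.5, bbb_score = 4.2),
    cand(id = "cns0", cns = 0),
    cand(id = "bbb3", bbb_score = 3.0),
    cand(id = "qplogbb", qplogbb = -3)
  )
  expect_equal(cns_stage(d)$id, "ok")

  d <- dplyr::bind_rows(
    cand(id = "ok", qppcaco = 800, hoa = 85),
    cand(id = "caco500", qppcaco = 500),
    cand(id = "hoa70", hoa = 70)
  )
  expect_equal(absorption_stage(d)$id, "ok")
})

test_that("missing descriptors fail conservatively with a named reason", {
  d <- dplyr::bind_rows(cand(id = "ok"), cand(id = "noprob", probability = NA))
  rep <- run_cascade(d)
  expect_equal(rep$survivors$id, "ok")
  expect_equal(rep$records$failure_reason[rep$records$id == "noprob"],
               "missing_field")
})

test_that("Lipinski violation counts cover the boundary cases", {
  d <- dplyr::bind_rows(
    cand(id = "clean", mw = 180.2, logp = 1.2, hbd = 1, hba = 4),
    cand(id = "all4", mw = 520, logp = 5.5, hbd = 6, hba = 11),
    cand(id = "mw501", mw = 501)
  )
  out <- lipinski_violations(d)
  expect_equal(out$lipinski_violations, c(0L, 4L, 1L))
  expect_equal(out$lipinski_pass, c(TRUE, FALSE, TRUE))  # default allows 1
})

test_that("Jorgensen violation counts follow the rule-of-three bounds", {
  d <- dplyr::bind_rows(
    cand(id = "clean", logs = -3, qppcaco = 100, metab = 3),
    cand(id = "logs", logs = -6, qppcaco = 100, metab = 3),
    cand(id = "all3", logs = -6, qppcaco = 10, metab = 8)
  )
  out <- jorgensen_violations(d)
  expect_equal(out$jorgensen_violations, c(0L, 1L, 3L))
  expect_equal(out$jorgensen_pass, c(TRUE, FALSE, FALSE))
})

test_that("cascade survivors equal the generator's ground-truth set", {
  tab <- sim_candidate_table(n = 100, n_pass = 12, seed = 42)
  rep <- run_cascade(tab)
  expect_setequal(rep$survivors$id, ground_truth(tab)$params$pass_ids)
  expect_equal(nrow(rep$survivors), 12)
})

test_that("survivor counts are monotone along stages and under tightening", {
  tab <- sim_candidate_table(n = 100, n_pass = 30, seed = 7)
  rep <- run_cascade(tab)
  expect_true(all(diff(rep$stage_counts$survivors) <= 0))

  base_n <- nrow(rep$survivors)
  tighter <- list(
    cascade_thresholds(prob_min = 0.8),
    cascade_thresholds(dock_max = -9),
    cascade_thresholds(bbb_min = 4),
    cascade_thresholds(qppcaco_min = 1500),
    cascade_thresholds(hoa_min = 90),
    cascade_thresholds(lipinski_max_violations = 0)
  )
  for (th in tighter) {
    expect_lte(nrow(run_cascade(tab, th)$survivors), base_n)
  }
})

test_that("fully relaxed thresholds keep every record", {
  tab <- sim_candidate_table(n = 50, n_pass = 5, seed = 3)
  loose <- cascade_thresholds(
    prob_min = -Inf, dock_max = Inf, cns_min = -Inf, qplogbb_min = -Inf,
    bbb_min = -Inf, qppcaco_min = -Inf, hoa_min = -Inf,
    lipinski_max_violations = 4, jorgensen_max_violations = 3
  )
  expect_equal(nrow(run_cascade(tab, loose)$survivors), 50)
})

test_that("the survivor set is order-insensitive; only failure attribution is not", {
  tab <- sim_candidate_table(n = 80, n_pass = 10, seed = 11)
  rep <- run_cascade(tab)
  # conjunctive filters applied independently give the same survivor set
  manual <- tab |>
    probability_stage() |>
    docking_stage() |>
    cns_stage() |>
    absorption_stage()
  manual <- lipinski_violations(manual)
  manual <- jorgensen_violations(manual)
  manual <- manual[manual$lipinski_pass & manual$jorgensen_pass, ]
  expect_setequal(rep$survivors$id, manual$id)
  # reversed evaluation order: same set
  evals <- bchescreen:::cascade_stage_evals(tab, cascade_thresholds())
  keep_rev <- Reduce(`&`, rev(lapply(evals, `[[`, "keep")))
  expect_setequal(tab$id[keep_rev], rep$survivors$id)
  # every failing record carries exactly one first-failure stage
  failed <- rep$records[!rep$records$pass, ]
  expect_true(all(!is.na(failed$first_failure)))
  expect_true(all(is.na(rep$records$first_failure[rep$records$pass])))
})

test_that("empty input yields an empty report", {
  tab <- sim_candidate_table(n = 0, n_pass = 0, seed = 1)
  rep <- run_cascade(tab)
  expect_equal(nrow(rep$survivors), 0)
  expect_true(all(rep$stage_counts$survivors == 0))
})
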