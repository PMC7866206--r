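# Candidate scoring, tumor concordance, ledger validation, reporting.

.fake_fit <- function(rel, aet) {
  list(sample_id = "T", exposures = rel * 1000, relative = rel,
       residual_norm = 0, aetiology = aet)
}

.kn3 <- function() {
  make_knowledge(c("REPAIR1", "ADH1"), c(TRUE, TRUE),
                 list(c("dna_repair"), c("cell_adhesion")),
                 list(c("dna repair"), c("cell adhesion")))
}

test_that("tumor concordance lifts DNA-repair candidates in MMR patients", {
  kn <- .kn3()
  aet <- c(SBS1 = "clock_like", SBS15 = "mmr_deficiency")
  mmr_fit <- .fake_fit(c(SBS1 = 0.7, SBS15 = 0.3), aet)
  cand <- rbind(
    make_record(patient_id = "Pt11", pos = 1, gene_symbol = "REPAIR1"),
    make_record(patient_id = "Pt02", pos = 1, gene_symbol = "REPAIR1"))
  cand$inheritance_model <- "dominant"
  scored <- score_candidates(cand, list(Pt11 = list(sbs = mmr_fit)), kn)
  s11 <- scored[scored$patient_id == "Pt11", ]
  s02 <- scored[scored$patient_id == "Pt02", ]
  expect_true(s11$concordant)
  expect_false(s02$concordant)
  expect_equal(s11$score - s02$score, selection_config()$concordance_bonus)
  expect_lt(s11$rank, s02$rank)
  # below the minimum signature fraction there is no bonus
  weak <- .fake_fit(c(SBS1 = 0.97, SBS15 = 0.03), aet)
  scored2 <- score_candidates(cand, list(Pt11 = list(sbs = weak)), kn)
  expect_false(any(scored2$concordant))
  # a non-repair gene gets no bonus from MMR signatures
  cand_adh <- cand; cand_adh$gene_symbol <- "ADH1"
  scored3 <- score_candidates(cand_adh, list(Pt11 = list(sbs = mmr_fit)), kn)
  expect_false(any(scored3$concordant))
})

test_that("patients without tumor data score on categories alone", {
  kn <- .kn3()
  cand <- make_record(patient_id = "PtX", gene_symbol = "REPAIR1")
  cand$inheritance_model <- "dominant"
  scored <- score_candidates(cand, list(), kn)
  w <- selection_config()$category_weights
  expect_equal(scored$score,
               unname(w[["is_cancer_predisposition"]] + w[["dna_repair"]]))
})

test_that("removing tumor data never raises a score; ties break deterministically", {
  kn <- fixture_knowledge()
  cohort <- random_cohort(80L, seed = 61)
  cohort$inheritance_model <- "dominant"
  aet <- synthetic_sbs96_catalog()$aetiology
  fits <- list(Pt01 = list(sbs = .fake_fit(
    c(SBS1 = 0.2, SBS5 = 0.2, SBS15 = 0.6, SBS19 = 0, SBS21 = 0), aet)))
  with_t <- score_candidates(cohort, fits, kn)
  without_t <- score_candidates(cohort, list(), kn)
  key <- function(d) paste(d$patient_id, d$pos, d$ref, d$alt)
  m <- match(key(without_t), key(with_t))
  expect_true(all(without_t$score <= with_t$score[m]))
  # identical inputs produce the identical ranking
  again <- score_candidates(cohort, fits, kn)
  expect_identical(with_t, again)
})

test_that("shifting all category weights preserves ranking at equal category counts", {
  kn <- make_knowledge(c("G1", "G2"), c(FALSE, FALSE),
                       list(c("dna_repair", "apoptosis"),
                            c("cell_adhesion", "stomach_function")),
                       list(character(0), character(0)))
  cand <- rbind(make_record(patient_id = "PtA", pos = 1, gene_symbol = "G1"),
                make_record(patient_id = "PtB", pos = 2, gene_symbol = "G2"))
  cand$inheritance_model <- "dominant"
  w <- selection_config()$category_weights
  base <- score_candidates(cand, list(), kn,
                           selection_config(category_weights = w))
  shifted <- score_candidates(cand, list(), kn,
                              selection_config(category_weights = w + 1))
  # both genes carry exactly two categories, so a constant shift adds the
  # same amount to both scores and the ranking is unchanged
  expect_equal(shifted$score - base$score, rep(2, 2))
  expect_identical(base$patient_id[order(base$rank)],
                   shifted$patient_id[order(shifted$rank)])
})

test_that("ledger validation flags exactly the published failure modes", {
  ok <- ledger_add(stage_ledger(), "prevalidation", 285L, 189L,
                   c(non_coding = 40L, repetitive = 30L, few_reads = 26L))
  expect_length(validate_ledger(ok), 0L)
  bad <- ledger_add(stage_ledger(), "prevalidation", 285L, 190L,
                    c(non_coding = 96L))
  expect_match(validate_ledger(bad), "reason histogram|input",
               all = FALSE)
  neg <- stage_ledger()
  neg$stages <- "x"; neg$input <- -1L; neg$retained <- -1L
  neg$discarded <- 0L; neg$reasons <- list(setNames(integer(0), character(0)))
  expect_match(validate_ledger(neg), "negative", all = FALSE)
  # chained stages must hand over their retained count
  chain <- ledger_add(stage_ledger(), "a", 100L, 60L)
  chain <- ledger_add(chain, "b", 59L, 59L)
  expect_match(validate_ledger(chain), "retained 60 != next input 59",
               all = FALSE)
})

test_that("reports are deterministic and complete", {
  kn <- .kn3()
  cand <- make_record(patient_id = "Pt01", gene_symbol = "REPAIR1")
  cand$inheritance_model <- "dominant"
  cand$matched_categories <- "dna_repair"
  cand$stage_trail <- "quality=retained"
  scored <- score_candidates(cand, list(), kn)
  led <- ledger_add(stage_ledger(), "quality", 1L, 1L)
  tmb <- compute_tmb(50L, 0.5, sample_id = "Pt01")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(scored, led, tmb, list(), d1)
  write_report(scored, led, tmb, list(), d2)
  for (f in c("candidates.tsv", "tmb.tsv", "exposures.tsv",
              "run_summary.json", "summary.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  js <- jsonlite::read_json(file.path(d1, "run_summary.json"))
  expect_equal(js$n_candidates, 1L)
  expect_length(js$ledger_violations, 0L)
  # empty candidate set still writes a ledger section
  d3 <- withr::local_tempdir()
  write_report(scored[0, ], led, NULL, list(), d3)
  expect_true(file.exists(file.path(d3, "candidates.tsv")))
  js3 <- jsonlite::read_json(file.path(d3, "run_summary.json"))
  expect_equal(js3$n_candidates, 0L)
})
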