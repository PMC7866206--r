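# The five-stage filtering cascade.

test_that("single-stage predicates behave at their boundaries", {
  cfg <- filter_config()
  # quality
  r <- make_records(
    make_record(pos = 1, total_depth = 60, alt_depth = 28, call_quality = 99),
    make_record(pos = 2, total_depth = 8, alt_depth = 6),
    make_record(pos = 3, alt_depth = 3),
    make_record(pos = 4, total_depth = 10, alt_depth = 4, call_quality = 30))
  q <- quality_filter(r, cfg)
  expect_equal(q$retained$pos, c(1L, 4L))
  expect_true(all(q$discarded$reason == "quality"))
  # consequence: missense and LoF retained, synonymous/other discarded
  r <- make_records(make_record(pos = 1, consequence = "missense"),
                    make_record(pos = 2, consequence = "synonymous"),
                    make_record(pos = 3, consequence = "frameshift"),
                    make_record(pos = 4, consequence = "other"))
  cq <- consequence_filter(r, cfg)
  expect_equal(cq$retained$pos, c(1L, 3L))
  # frequency: strict threshold, missing treated as rare
  r <- make_records(make_record(pos = 1, max_pop_af = 0.30),
                    make_record(pos = 2, max_pop_af = 0.0005),
                    make_record(pos = 3, max_pop_af = NA),
                    make_record(pos = 4, max_pop_af = 0.01))
  fq <- frequency_filter(r, cfg)
  expect_equal(fq$retained$pos, c(2L, 3L))
})

test_that("predictor consensus counts non-missing votes with >= rule", {
  cfg <- filter_config()
  ann <- make_records(
    # 3 damaging of 3 present
    make_record(pos = 1, sift_score = 0.01, polyphen2_score = 0.93,
                cadd_phred = 27, phylop = NA, mutation_taster = NA,
                lrt = NA),
    # 0 damaging of 2 present
    make_record(pos = 2, sift_score = 0.60, polyphen2_score = NA,
                cadd_phred = 3, phylop = NA, mutation_taster = NA,
                lrt = NA),
    # exactly half damaging at consensus 0.5: boundary is damaging
    make_record(pos = 3, sift_score = 0.01, polyphen2_score = 0.9,
                cadd_phred = 3, phylop = 0, mutation_taster = NA,
                lrt = NA),
    # all predictors missing: conservatively not damaging
    make_record(pos = 4, sift_score = NA, polyphen2_score = NA,
                cadd_phred = NA, phylop = NA, mutation_taster = NA,
                lrt = NA))
  v <- predictor_consensus(ann, cfg)
  expect_equal(v$damaging, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(v$votes_total, c(3L, 2L, 4L, 0L))
  expect_error(predictor_consensus(make_record(consequence = "nonsense"),
                                   cfg),
               "missense")
})

test_that("term matching is case-insensitive on whole entries", {
  kn <- make_knowledge(c("G1", "G2"), c(FALSE, FALSE),
                       list(c("dna_repair"), character(0)),
                       list(c("Cell Adhesion"), character(0)))
  expect_equal(term_match("G1", kn, c("cell adhesion")), "cell adhesion")
  expect_equal(term_match("G1", kn, c("DNA Repair")), "DNA Repair")
  expect_length(term_match("G2", kn, default_term_list()), 0L)
  expect_length(term_match("ABSENT", kn, default_term_list()), 0L)
})

test_that("the cascade reproduces analytically known per-stage counts", {
  ref <- fixture_reference(); kn <- fixture_knowledge()
  spec <- c(n_quality_fail = 40L, n_consequence_fail = 60L,
            n_frequency_fail = 60L, n_consensus_fail = 40L,
            n_term_fail = 25L)
  sim <- generate_germline_cohort(
    ref, kn, 4L, spec,
    list(n_dominant = 2L, n_recessive = 1L, recurrent_carriers = 0L,
         n_homopolymer_decoys = 0L), seed = 77)
  res <- run_pipeline_filter(sim$cohort, kn)
  led <- as.data.frame(res$ledger)
  expect_equal(led$discarded, unname(4L * spec))
  expect_equal(nrow(res$records), 3L)   # the planted variants
  expect_length(validate_ledger(res$ledger), 0L)
  # every survivor carries the full retained trail
  expect_true(all(res$records$stage_trail ==
                    paste("quality=retained", "consequence=retained",
                          "frequency=retained",
                          "predictor_consensus=retained",
                          "term_match=retained", sep = ",")))
})

test_that("degenerate cohorts are handled", {
  kn <- fixture_knowledge()
  empty <- make_record()[0, ]
  res <- run_pipeline_filter(empty, kn)
  expect_equal(nrow(res$records), 0L)
  expect_true(all(as.data.frame(res$ledger)$input == 0L))
  syn <- make_records(make_record(pos = 1, consequence = "synonymous"),
                      make_record(pos = 2, consequence = "synonymous"))
  res2 <- run_pipeline_filter(syn, kn)
  expect_equal(nrow(res2$records), 0L)
  led <- as.data.frame(res2$ledger)
  expect_equal(led$discarded[led$stage == "consequence"], 2L)
})

test_that("membership is order-insensitive and threshold-monotone", {
  kn <- fixture_knowledge()
  cohort <- random_cohort(200L, seed = 5)
  res <- run_pipeline_filter(cohort, kn)
  set.seed(9)
  perm <- cohort[sample(nrow(cohort)), ]
  res_p <- run_pipeline_filter(perm, kn)
  expect_equal(as.data.frame(res$ledger), as.data.frame(res_p$ledger))
  key <- function(d) paste(d$patient_id, d$pos, d$ref, d$alt)
  expect_setequal(key(res$records), key(res_p$records))
  # relaxing the frequency threshold never shrinks the retained set
  loose <- run_pipeline_filter(cohort, kn, filter_config(max_pop_af = 0.5))
  expect_true(all(key(res$records) %in% key(loose$records)))
  # tightening the consensus fraction never grows it
  strict <- run_pipeline_filter(cohort, kn,
                                filter_config(consensus_fraction = 0.9))
  expect_true(all(key(strict$records) %in% key(res$records)))
})

test_that("the cascade agrees with a brute-force predicate oracle", {
  kn <- fixture_knowledge()
  for (seed in c(11, 12, 13)) {
    cohort <- random_cohort(200L, seed = seed)
    res <- run_pipeline_filter(cohort, kn)
    want <- oracle_filter_pass(cohort, kn)
    key <- function(d) paste(d$patient_id, d$pos, d$ref, d$alt)
    expect_setequal(key(res$records), key(cohort[want, ]))
  }
})
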