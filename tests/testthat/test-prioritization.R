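# Cancer-gene restriction, inheritance arms, recurrence exclusion.

.kn2 <- function() {
  make_knowledge(
    c("CANC_PR", "CANC_DOM", "CANC_ONLY", "RISK_ONLY", "NOCANC"),
    c(TRUE, TRUE, TRUE, TRUE, FALSE),
    list(c("pathogen_recognition", "innate_immunity"),
         c("gc_development"),
         character(0),
         c("alcohol_metabolism"),
         c("cell_adhesion")),
    list(c("pathogen recognition"), c("gastric cancer"), c("cancer"),
         c("alcohol metabolism"), c("cell adhesion")))
}

test_that("cancer gene restriction is a hard step-1 filter", {
  kn <- .kn2()
  r <- make_records(make_record(pos = 1, gene_symbol = "CANC_PR"),
                    make_record(pos = 2, gene_symbol = "NOCANC"))
  res <- cancer_gene_select(r, kn)
  expect_equal(res$retained$pos, 1L)
  expect_equal(res$discarded$reason, "gene_list")
  # union mode passes everything
  res_u <- cancer_gene_select(r, kn, restrict = FALSE)
  expect_equal(nrow(res_u$retained), 2L)
  # empty gene list: degenerate, warned
  kn0 <- kn; kn0$is_cancer_predisposition[] <- FALSE
  expect_warning(res0 <- cancer_gene_select(r, kn0), "empty")
  expect_equal(nrow(res0$retained), 0L)
})

test_that("recessive arm takes homozygotes on qualifying genes", {
  kn <- .kn2()
  r <- make_records(
    make_record(pos = 1, gene_symbol = "CANC_PR",
                genotype = "homozygous_alt", alt_depth = 57),
    make_record(pos = 2, gene_symbol = "CANC_PR",
                genotype = "heterozygous"),
    make_record(pos = 3, gene_symbol = "NOCANC",
                genotype = "homozygous_alt", alt_depth = 57))
  cand <- recessive_candidates(r, kn)
  # the cancer flag itself qualifies; heterozygous never does (without
  # compound-het mode); NOCANC lacks both the flag and pathogen recognition
  expect_equal(cand$pos, 1L)
  expect_equal(cand$inheritance_model, "recessive")
  expect_match(cand$matched_categories, "pathogen_recognition")
})

test_that("compound heterozygotes are admitted only behind the flag", {
  kn <- .kn2()
  r <- make_records(
    make_record(pos = 10, gene_symbol = "CANC_PR", genotype = "heterozygous"),
    make_record(pos = 20, gene_symbol = "CANC_PR", genotype = "heterozygous"),
    make_record(pos = 30, gene_symbol = "CANC_DOM", genotype = "heterozygous"))
  off <- recessive_candidates(r, kn)
  expect_equal(nrow(off), 0L)
  on <- recessive_candidates(r, kn,
                             prioritization_config(allow_compound_het = TRUE))
  expect_setequal(on$pos, c(10L, 20L))
  expect_true(all(on$compound_het))
  # brute-force check on a larger random fixture: pairs = gene/patient
  # groups with >= 2 distinct heterozygous records on qualifying genes
  set.seed(3)
  big <- do.call(rbind, lapply(1:50, function(i)
    make_record(patient_id = sample(c("PtA", "PtB"), 1),
                pos = sample(1:25, 1),
                gene_symbol = sample(c("CANC_PR", "NOCANC"), 1),
                genotype = sample(c("heterozygous", "homozygous_alt"), 1,
                                  prob = c(0.85, 0.15)))))
  big <- big[!duplicated(paste(big$patient_id, big$pos)), ]
  big$alt_depth[big$genotype == "homozygous_alt"] <- 55L
  got <- recessive_candidates(big, kn,
                              prioritization_config(allow_compound_het = TRUE))
  got_pairs <- got[got$compound_het, ]
  want <- do.call(rbind, lapply(split(big, paste(big$patient_id,
                                                 big$gene_symbol)),
                                function(d) {
    d <- d[d$genotype == "heterozygous" & d$gene_symbol == "CANC_PR", ]
    if (nrow(d) >= 2L) d else d[0, ]
  }))
  expect_equal(nrow(got_pairs), nrow(want))
  expect_setequal(paste(got_pairs$patient_id, got_pairs$pos),
                  paste(want$patient_id, want$pos))
})

test_that("dominant arm takes heterozygotes, risk factors included", {
  kn <- .kn2()
  r <- make_records(
    make_record(pos = 1, gene_symbol = "CANC_DOM", genotype = "heterozygous"),
    make_record(pos = 2, gene_symbol = "RISK_ONLY",
                genotype = "heterozygous"),
    make_record(pos = 3, gene_symbol = "CANC_DOM",
                genotype = "homozygous_alt", alt_depth = 57),
    make_record(pos = 4, gene_symbol = "CANC_ONLY",
                genotype = "heterozygous"))
  cand <- dominant_candidates(r, kn)
  # gc_development qualifies; alcohol_metabolism (risk factor) qualifies;
  # homozygotes route to the recessive arm; a bare cancer flag without a
  # dominant category does not qualify
  expect_setequal(cand$pos, c(1L, 2L))
  expect_true(all(cand$inheritance_model == "dominant"))
})

test_that("recurrence exclusion uses distinct carriers and strict >", {
  kn <- .kn2()
  cand_at <- function(patients, pos = 500L)
    do.call(rbind, lapply(patients, function(p)
      make_record(patient_id = p, pos = pos, gene_symbol = "CANC_DOM")))
  cfg <- prioritization_config()
  # 6 of 20 carriers (30%) -> excluded
  res <- recurrence_filter(cand_at(sprintf("Pt%02d", 1:6)), 20L, cfg)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(nrow(res$discarded), 6L)
  # 5 of 20 (exactly 25%) -> retained under strict >
  res <- recurrence_filter(cand_at(sprintf("Pt%02d", 1:5)), 20L, cfg)
  expect_equal(nrow(res$retained), 5L)
  # single carrier -> retained; duplicate alleles in one patient count once
  one <- rbind(cand_at("Pt01"), cand_at(rep("Pt02", 6)))
  res <- recurrence_filter(one, 20L, cfg)
  expect_equal(nrow(res$retained), 7L)
  expect_error(recurrence_filter(cand_at("Pt01"), 0L), "positive")
})

test_that("a gene can appear under both models via different variants", {
  kn <- .kn2()
  r <- make_records(
    make_record(patient_id = "PtA", pos = 100, gene_symbol = "CANC_PR",
                genotype = "homozygous_alt", alt_depth = 57),
    make_record(patient_id = "PtB", pos = 200, gene_symbol = "CANC_PR",
                genotype = "heterozygous"))
  res <- prioritize(r, kn, n_patients = 20L)
  expect_equal(nrow(res$candidates), 2L)
  expect_setequal(res$candidates$inheritance_model,
                  c("recessive", "dominant"))
  expect_equal(unique(res$candidates$gene_symbol), "CANC_PR")
})

test_that("prioritize matches a brute-force predicate oracle", {
  kn <- fixture_knowledge()
  for (seed in c(21, 22)) {
    cohort <- random_cohort(150L, seed = seed)
    res <- prioritize(cohort, kn, n_patients = 6L)
    keep <- oracle_prioritize_keep(cohort, kn, n_patients = 6L)
    key <- function(d) paste(d$patient_id, d$pos, d$ref, d$alt)
    expect_setequal(key(res$candidates), key(cohort[keep, ]))
    expect_length(validate_ledger(res$ledger), 0L)
  }
})

test_that("disabling category requirements reduces to gene-list + recurrence", {
  kn <- fixture_knowledge()
  cohort <- random_cohort(120L, seed = 31)
  all_cats <- c("is_cancer_predisposition", gene_function_categories())
  cfg <- prioritization_config(recessive_required_categories = all_cats,
                               dominant_required_categories = all_cats)
  res <- prioritize(cohort, kn, n_patients = 6L, config = cfg)
  # oracle: cancer-gene restriction, any genotype qualifies if the gene has
  # any category or the flag, then recurrence
  flagged <- kn$gene_symbol[kn$is_cancer_predisposition]
  eligible <- cohort[cohort$gene_symbol %in% flagged, ]
  has_cat <- vapply(seq_len(nrow(eligible)), function(i) {
    k <- which(kn$gene_symbol == eligible$gene_symbol[i])
    kn$is_cancer_predisposition[k] ||
      length(kn$function_categories[[k]]) > 0L
  }, logical(1))
  eligible <- eligible[has_cat, ]
  rec <- recurrence_filter(eligible, 6L)$retained
  key <- function(d) paste(d$patient_id, d$pos, d$ref, d$alt)
  expect_setequal(key(res$candidates), key(rec))
})
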