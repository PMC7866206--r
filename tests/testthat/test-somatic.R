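# Consensus merge, TMB, catalogs, refitting.

test_that("consensus thresholds are honoured at their boundaries", {
  mk <- function(pos) data.frame(chrom = rep("chr1", length(pos)), pos = pos,
                                 ref = rep("C", length(pos)),
                                 alt = rep("T", length(pos)),
                                 stringsAsFactors = FALSE)
  sets <- list(a = mk(c(1, 2)), b = mk(2), c = mk(numeric(0)),
               d = mk(numeric(0)))
  res <- consensus_merge(sets, list(), sample_id = "T")
  # pos 2 in exactly 2 of 4 callers -> retained; pos 1 in 1 caller -> dropped
  expect_equal(res$pos, 2L)
  expect_equal(res$caller_support, "a,b")
  expect_equal(res$n_callers, 2L)
  # duplicates within one caller are deduplicated with a warning
  expect_warning(res2 <- consensus_merge(list(a = mk(c(5, 5)), b = mk(5)),
                                         list(), sample_id = "T"),
                 "deduplicated")
  expect_equal(res2$pos, 5L)
})

test_that("consensus equals the brute-force intersection oracle", {
  for (seed in 1:20) {
    sets <- .rand_callsets(seed)
    snv_sets <- sets
    indel_sets <- sets[1:3]
    res <- consensus_merge(snv_sets, indel_sets, sample_id = "T")
    want <- oracle_consensus(snv_sets, indel_sets)
    got <- sort(paste(res$chrom, res$pos, res$ref, res$alt))
    expect_identical(got, want)
  }
})

test_that("TMB classification matches the published thresholds", {
  # the three printed values
  expect_equal(classify_tmb(315.4), "ultra_hypermutated")
  expect_equal(classify_tmb(43.6), "hypermutated")
  expect_equal(classify_tmb(16.8), "hypermutated")
  # strict boundaries
  expect_equal(classify_tmb(c(10, 10.0001, 100, 100.0001)),
               c("non_hypermutated", "hypermutated", "hypermutated",
                 "ultra_hypermutated"))
  rec <- compute_tmb(3154L, region_mb = 10)
  expect_equal(rec$tmb, 315.4)
  expect_equal(rec$hyper_class, "ultra_hypermutated")
  expect_error(compute_tmb(10L, region_mb = 0), "positive")
})

test_that("SBS-96 matrices count pyrimidine-normalized contexts", {
  s <- "AACGTTGCATG"
  ref <- Biostrings::DNAStringSet(s); names(ref) <- "chr1"
  # C>T at pos 3 has context ACG -> A[C>T]G
  # G>A at pos 7 has context TGC -> revcomp GCA -> G[C>T]A
  mut <- data.frame(sample_id = "T", chrom = "chr1", pos = c(3L, 7L),
                    ref = c("C", "G"), alt = c("T", "A"),
                    stringsAsFactors = FALSE)
  m <- sbs96_matrix(mut, ref)
  expect_equal(sum(m$counts), 2L)
  expect_equal(m$counts["A[C>T]G", "T"], 1L)
  expect_equal(m$counts["G[C>T]A", "T"], 1L)
  # reference mismatch is an error naming the locus
  bad <- mut; bad$ref[1] <- "G"
  expect_error(sbs96_matrix(bad, ref), "chr1:3")
  # N in context: skipped and counted
  s2 <- Biostrings::DNAStringSet("ANCGT"); names(s2) <- "chr1"
  m2 <- sbs96_matrix(data.frame(sample_id = "T", chrom = "chr1", pos = 3L,
                                ref = "C", alt = "A"), s2)
  expect_equal(sum(m2$counts), 0L)
  expect_equal(unname(m2$skipped["T"]), 1L)
})

test_that("SBS-96 matrix is invariant under global reverse complement", {
  ref <- fixture_reference()
  sim <- simulate_tumor_callsets("T1", ref,
                                 sbs_mixture = c(SBS1 = 0.6, SBS21 = 0.4),
                                 n_snvs = 400L, seed = 61,
                                 decoys_per_caller = 0L)
  snv <- sim$truth
  m <- sbs96_matrix(snv, ref)
  expect_equal(unname(colSums(m$counts)), 400L)
  L <- ref$chrom_length
  rc_seq <- Biostrings::reverseComplement(ref$sequence)
  names(rc_seq) <- "chr1"
  rc <- snv
  rc$pos <- L - snv$pos + 1L
  rc$ref <- revcomp(snv$ref)
  rc$alt <- revcomp(snv$alt)
  m_rc <- sbs96_matrix(rc, rc_seq)
  expect_identical(m$counts, m_rc$counts)
})

test_that("exposure refitting recovers exact and noisy mixtures", {
  sc <- synthetic_sbs96_catalog()
  P <- sc$probabilities
  # exact single signature
  counts <- matrix(round(P[, "SBS1"] * 0), dimnames = list(rownames(P), "S"))
  counts[, 1] <- P[, "SBS1"] * 1000
  fit <- refit_exposures(catalog_from_counts(round(counts)), sc,
                         prune = FALSE)
  expect_lt(abs(fit$S$exposures[["SBS1"]] - 1000), 20)
  expect_lt(fit$S$residual_norm, 10)
  # exact two-signature composition recovered to numerical tolerance
  d <- 600 * P[, "SBS1"] + 400 * P[, "SBS5"]
  m <- matrix(d, dimnames = list(rownames(P), "S"))
  fit2 <- refit_exposures(
    structure(list(channel_set = "SBS96", channels = rownames(P),
                   samples = "S", counts = m,
                   skipped = c(S = 0L)), class = "mutational_catalog"),
    sc, prune = FALSE)
  expect_equal(unname(fit2$S$exposures[c("SBS1", "SBS5")]), c(600, 400),
               tolerance = 1e-6)
  expect_lt(fit2$S$residual_norm, 1e-6)
  # coarse grid-search oracle on the two-signature simplex agrees
  best <- Inf; best_ab <- c(NA, NA)
  for (a in seq(0, 1000, by = 25)) for (b in seq(0, 1000, by = 25)) {
    r <- sqrt(sum((a * P[, "SBS1"] + b * P[, "SBS5"] - d)^2))
    if (r < best) { best <- r; best_ab <- c(a, b) }
  }
  expect_equal(best_ab, c(600, 400))
})

test_that("multinomial spectra refit within 0.05 of the truth", {
  sc <- synthetic_sbs96_catalog()
  P <- sc$probabilities
  mix <- c(SBS1 = 0.5, SBS5 = 0.3, SBS15 = 0.2)
  set.seed(71)
  d <- rmultinom(1, 5000, as.numeric(P[, names(mix)] %*% mix))
  rownames(d) <- rownames(P); colnames(d) <- "S"
  fit <- refit_exposures(catalog_from_counts(d), sc)
  rel <- fit$S$relative
  for (sig in names(mix))
    expect_lt(abs(rel[[sig]] - mix[[sig]]), 0.05)
  expect_lt(sum(rel[setdiff(names(rel), names(mix))]), 0.05)
})

test_that("pruning refit never beats zeroing within an iteration and keeps exposures non-negative", {
  sc <- synthetic_sbs96_catalog()
  P <- sc$probabilities
  set.seed(81)
  mix <- c(SBS1 = 0.55, SBS5 = 0.42, SBS19 = 0.03)  # one prunable signature
  d <- rmultinom(1, 3000, as.numeric(P[, names(mix)] %*% mix))
  rownames(d) <- rownames(P); colnames(d) <- "S"
  full <- refit_exposures(catalog_from_counts(d), sc, prune = FALSE)$S
  pruned <- refit_exposures(catalog_from_counts(d), sc, prune = TRUE)$S
  expect_true(all(pruned$exposures >= 0))
  expect_true(all(full$exposures >= 0))
  # zeroing the pruned signatures without refitting can only be worse
  zeroed <- full$exposures
  zeroed[pruned$exposures == 0] <- 0
  resid_zeroed <- sqrt(sum((P %*% zeroed - d)^2))
  expect_lte(pruned$residual_norm, resid_zeroed + 1e-8)
  # pruned signatures are really below threshold in the full fit
  dropped <- names(zeroed)[pruned$exposures == 0 & full$exposures > 0]
  if (length(dropped) > 0L)
    expect_true(all(full$exposures[dropped] / sum(full$exposures) < 0.05))
})

test_that("zero-mutation samples yield zero exposures and no relative", {
  sc <- synthetic_sbs96_catalog()
  d <- matrix(0L, 96, 1, dimnames = list(sbs96_channels(), "S"))
  fit <- refit_exposures(catalog_from_counts(d), sc)
  expect_true(all(fit$S$exposures == 0))
  expect_null(fit$S$relative)
  expect_equal(fit$S$residual_norm, 0)
})

test_that("ID-83 matrices classify simulated indels with conserved sums", {
  ref <- fixture_reference()
  sim <- simulate_tumor_callsets("T1", ref,
                                 id_mixture = c(ID1 = 0.4, ID2 = 0.4,
                                                ID7 = 0.2),
                                 n_indels = 150L, seed = 91,
                                 decoys_per_caller = 0L)
  m <- id83_matrix(sim$truth, ref)
  expect_equal(unname(colSums(m$counts)), 150L)
  # the simulator's intended channel equals the classifier's channel
  got <- vapply(seq_len(nrow(sim$truth)), function(i)
    id83_classify(ref, sim$truth$chrom[i], sim$truth$pos[i],
                  sim$truth$ref[i], sim$truth$alt[i]), character(1))
  expect_identical(got, sim$truth$channel)
})
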