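# Synthetic reference and germline cohort generators.

test_that("reference generation is seed-deterministic and well-formed", {
  r1 <- generate_reference(1e5, 0.41, 10L, seed = 7, gene_bp_range = c(4000L, 7000L))
  r2 <- generate_reference(1e5, 0.41, 10L, seed = 7, gene_bp_range = c(4000L, 7000L))
  expect_identical(as.character(r1$sequence), as.character(r2$sequence))
  expect_identical(as.data.frame(r1$genes), as.data.frame(r2$genes))
  r3 <- generate_reference(1e5, 0.41, 10L, seed = 8, gene_bp_range = c(4000L, 7000L))
  expect_false(identical(as.character(r1$sequence),
                         as.character(r3$sequence)))
})

test_that("observed GC content tracks the requested fraction", {
  r <- generate_reference(2e6, 0.41, 10L, seed = 7,
                          homopolymer_spec = list(n_intergenic = 0L,
                                                  n_exonic = 0L))
  s <- as.character(r$sequence[[1]])
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  # at 2 Mb the i.i.d. binomial fluctuation is far below 0.01
  expect_lt(abs(gc - 0.41), 0.01)
})

test_that("gene models nest correctly and packing limits are enforced", {
  r <- fixture_reference()
  genes <- r$genes; exons <- r$exons
  expect_true(all(GenomicRanges::start(genes) >= 1))
  expect_true(all(GenomicRanges::end(genes) <= r$chrom_length))
  # genes non-overlapping
  expect_equal(length(GenomicRanges::reduce(genes)), length(genes))
  # every exon inside its gene
  hit <- GenomicRanges::findOverlaps(exons, genes, type = "within")
  expect_equal(length(unique(S4Vectors::queryHits(hit))), length(exons))
  hitg <- genes$name[S4Vectors::subjectHits(hit)]
  expect_true(all(exons$gene[S4Vectors::queryHits(hit)] == hitg))
  expect_error(generate_reference(1e5, 0.41, 20L, seed = 1,
                                  gene_bp_range = c(9000L, 9000L)),
               "infeasible packing")
})

test_that("planted homopolymer tracts exist at their recorded loci", {
  r <- fixture_reference()
  expect_gt(length(r$homopolymers), 0L)
  s <- as.character(r$sequence[[1]])
  for (i in seq_len(min(10L, length(r$homopolymers)))) {
    t <- r$homopolymers[i]
    sub <- substring(s, GenomicRanges::start(t), GenomicRanges::end(t))
    b <- t$base
    expect_equal(sub, strrep(b, GenomicRanges::width(t)))
    expect_gte(GenomicRanges::width(t), 8L)
  }
})

test_that("cohort generation is deterministic and matches its manifest", {
  ref <- fixture_reference(); kn <- fixture_knowledge()
  spec <- c(n_quality_fail = 30L, n_consequence_fail = 50L,
            n_frequency_fail = 50L, n_consensus_fail = 30L,
            n_term_fail = 20L)
  pl <- list(n_dominant = 3L, n_recessive = 2L, recurrent_carriers = 3L,
             n_homopolymer_decoys = 1L)
  s1 <- generate_germline_cohort(ref, kn, 8L, spec, pl, seed = 42)
  s2 <- generate_germline_cohort(ref, kn, 8L, spec, pl, seed = 42)
  expect_identical(s1$cohort, s2$cohort)
  m <- s1$manifest

  # exact per-patient class counts
  expect_equal(m$background_counts, spec * 8L)
  per_patient <- table(s1$cohort$patient_id)
  expect_true(all(per_patient >= sum(spec)))

  # every planted variant exists in the cohort with the right genotype
  key <- function(d) paste(d$patient_id, d$pos, d$ref, d$alt, d$genotype)
  expect_true(all(key(m$planted_germline) %in% key(s1$cohort)))
  expect_true(all(m$planted_germline$genotype[
    m$planted_germline$inheritance_model == "recessive"] ==
      "homozygous_alt"))
  expect_true(all(m$planted_germline$genotype[
    m$planted_germline$inheritance_model == "dominant"] == "heterozygous"))

  # the artifact is carried by exactly the recorded patients
  ak <- m$artifact$key
  carriers <- s1$cohort$patient_id[s1$cohort$pos == ak$pos &
                                     s1$cohort$ref == ak$ref &
                                     s1$cohort$alt == ak$alt]
  expect_setequal(carriers, m$artifact$carriers)
  expect_length(m$artifact$carriers, 3L)

  # inclusion ages honour the recruitment bound
  expect_true(all(m$patients$age_at_diagnosis < m$inclusion_age_bound))
  expect_equal(m$inclusion_age_bound, 51L)

  # homopolymer decoys really sit in long runs
  hd <- m$homopolymer_decoys
  for (i in seq_len(nrow(hd)))
    expect_gt(homopolymer_run(ref, hd$chrom[i], hd$pos[i], hd$ref[i],
                              hd$alt[i]), 7L)
})

test_that("planting on unqualified knowledge errors before emission", {
  ref <- fixture_reference()
  kn <- fixture_knowledge()
  kn_bad <- kn
  kn_bad$role[kn_bad$role == "recessive"] <- "none"
  expect_error(generate_germline_cohort(
    ref, kn_bad, 4L, default_background_spec(),
    list(n_dominant = 1L, n_recessive = 1L, recurrent_carriers = 0L,
         n_homopolymer_decoys = 0L), seed = 1),
    "recessive")
})
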