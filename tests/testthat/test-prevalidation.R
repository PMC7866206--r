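# Read-evidence and sequence-context prevalidation.

test_that("homopolymer runs are measured exactly, including boundaries", {
  s <- paste0("AC", strrep("T", 8), "GACGT")
  ref <- Biostrings::DNAStringSet(s); names(ref) <- "chr1"
  # variant inside the 8xT run
  expect_equal(homopolymer_run(ref, "chr1", 5, "T", "A"), 8L)
  # adjacent counts too: the C at position 2 touches the run
  expect_equal(homopolymer_run(ref, "chr1", 2, "C", "G"), 8L)
  # chromosome start: no out-of-bounds access
  ref2 <- Biostrings::DNAStringSet("TTGACGT"); names(ref2) <- "chr1"
  expect_equal(homopolymer_run(ref2, "chr1", 1, "T", "C"), 2L)
  expect_error(homopolymer_run(ref2, "chr1", 99, "T", "C"), "bounds")
  # runs longer than the initial scan window are still exact
  long <- Biostrings::DNAStringSet(paste0(strrep("A", 200), "CGT"))
  names(long) <- "chr1"
  expect_equal(homopolymer_run(long, "chr1", 100, "A", "T"), 200L)
})

test_that("homopolymer_run agrees with a naive full scanner on random loci", {
  ref <- fixture_reference()
  s <- as.character(ref$sequence[[1]])
  set.seed(404)
  pos <- sample(2:(nchar(s) - 2L), 1000L)
  for (p in pos) {
    b <- substring(s, p, p)
    expect_identical(homopolymer_run(ref, "chr1", p, b, "N"),
                     naive_homopolymer(s, p, 1L))
  }
})

test_that("prevalidation discards by reason and keeps clean candidates", {
  ref <- fixture_reference()
  coding <- ref$exons
  ex1 <- GenomicRanges::start(coding)[1] + 5L
  s <- as.character(ref$sequence[[1]])
  base_at <- function(p) substring(s, p, p)
  # an intergenic position (before the first gene)
  ig <- GenomicRanges::start(ref$genes)[1] - 50L
  # inside a planted homopolymer tract that overlaps an exon
  ov <- GenomicRanges::findOverlaps(ref$homopolymers, ref$exons)
  hp <- GenomicRanges::start(ref$homopolymers[
    S4Vectors::queryHits(ov)[1]]) + 2L
  cands <- make_records(
    make_record(pos = ex1, ref = base_at(ex1), alt = "A",
                total_depth = 60, alt_depth = 28),
    make_record(pos = ig, ref = base_at(ig), alt = "A"),
    make_record(pos = hp, ref = base_at(hp), alt = "A"),
    make_record(pos = ex1 + 2L, ref = base_at(ex1 + 2L), alt = "A",
                alt_depth = 2),
    make_record(pos = ex1 + 4L, ref = base_at(ex1 + 4L), alt = "A",
                total_depth = 60, alt_depth = 5))   # VAF 0.083 het
  cands$alt[cands$alt == cands$ref] <- "G"
  res <- prevalidate(cands, ref, coding)
  expect_equal(nrow(res$passed), 1L)
  expect_equal(res$passed$pos, ex1)
  reason_of <- function(p) res$discarded$reason[res$discarded$pos == p]
  expect_match(reason_of(ig), "non_coding")
  expect_match(reason_of(hp), "repetitive")
  expect_match(reason_of(ex1 + 2L), "few_reads")
  expect_match(reason_of(ex1 + 4L), "vaf_outlier")
  expect_length(validate_ledger(res$ledger), 0L)
})

test_that("homozygous VAF gate differs from the heterozygous gate", {
  ref <- fixture_reference()
  ex1 <- GenomicRanges::start(ref$exons)[1] + 5L
  s <- as.character(ref$sequence[[1]])
  b <- substring(s, ex1, ex1)
  hom_lo <- make_record(pos = ex1, ref = b, alt = setdiff(c("A", "G"), b)[1],
                        genotype = "homozygous_alt", total_depth = 60,
                        alt_depth = 35)    # VAF 0.58: fine het, bad hom
  res <- prevalidate(hom_lo, ref, ref$exons)
  expect_equal(nrow(res$passed), 0L)
  expect_match(res$discarded$reason, "vaf_outlier")
  het <- hom_lo; het$genotype <- "heterozygous"
  expect_equal(nrow(prevalidate(het, ref, ref$exons)$passed), 1L)
})

test_that("tightening thresholds never grows the passed set", {
  ref <- fixture_reference()
  set.seed(51)
  ex <- ref$exons
  pool <- unlist(lapply(seq_len(min(20, length(ex))), function(i)
    GenomicRanges::start(ex)[i]:GenomicRanges::end(ex)[i]))
  s <- as.character(ref$sequence[[1]])
  n <- 60L
  pos <- sample(pool, n)
  cands <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- substring(s, pos[i], pos[i])
    make_record(pos = pos[i], ref = b, alt = setdiff(c("A", "C"), b)[1],
                total_depth = sample(c(8L, 20L, 60L), 1),
                alt_depth = sample(c(2L, 10L, 30L), 1))
  }))
  cands$alt_depth <- pmin(cands$alt_depth, cands$total_depth)
  base <- prevalidate(cands, ref, ref$exons)$passed
  tight <- prevalidate(cands, ref, ref$exons,
                       prevalidation_config(min_alt_reads = 8L,
                                            homopolymer_max = 5L,
                                            het_vaf_range = c(0.3, 0.7)))
  expect_true(all(paste(tight$passed$pos) %in% paste(base$pos)))
})
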