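# Prevalidation: deterministic read-evidence and sequence-context heuristics
# replacing manual genome-browser review. A candidate is discarded when it
# falls outside coding regions, sits in a long homopolymer tract, has too few
# alternate reads, or has a variant-allele fraction inconsistent with its
# genotype. This is a declared reinterpretation of visual review, not a
# reproduction of it.

#' Prevalidation configuration
#'
#' @param min_alt_reads minimum alternate-allele reads (default 4).
#' @param het_vaf_range admissible variant-allele-fraction interval for
#'   heterozygous candidates (default `[0.2, 0.8]`).
#' @param hom_vaf_min minimum VAF for homozygous candidates (default 0.8).
#' @param homopolymer_max longest tolerated single-base run at the locus;
#'   runs strictly longer are flagged repetitive (default 7, so runs >= 8
#'   are discarded).
#' @param require_coding discard candidates outside the coding regions
#'   (default `TRUE`).
#' @return list of class `prevalidation_config`.
#' @export
prevalidation_config <- function(min_alt_reads = 4L,
                                 het_vaf_range = c(0.2, 0.8),
                                 hom_vaf_min = 0.8,
                                 homopolymer_max = 7L,
                                 require_coding = TRUE) {
  stopifnot(length(het_vaf_range) == 2L, all(het_vaf_range > 0),
            all(het_vaf_range < 1), het_vaf_range[1] < het_vaf_range[2],
            hom_vaf_min > 0, hom_vaf_min < 1, homopolymer_max >= 3L)
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 het_vaf_range = het_vaf_range,
                 hom_vaf_min = hom_vaf_min,
                 homopolymer_max = as.integer(homopolymer_max),
                 require_coding = isTRUE(require_coding)),
            class = "prevalidation_config")
}

#' Longest single-base run at a variant locus
#'
#' Returns the length of the longest homopolymer run overlapping or
#' immediately adjacent to the variant locus (the reference span of `ref`,
#' extended by one base each side), scanning both directions. Runs are
#' measured on the reference sequence; the scan never reads outside the
#' chromosome.
#'
#' @param reference reference sequences.
#' @param chrom,pos,ref,alt the variant (alt participates only through the
#'   locus span convention for insertions).
#' @return integer run length.
#' @export
homopolymer_run <- function(reference, chrom, pos, ref, alt) {
  seqs <- reference_sequences(reference)
  if (!chrom %in% names(seqs)) stop("unknown sequence name: ", chrom)
  L <- Biostrings::width(seqs[chrom])
  if (pos < 1L || pos > L) stop("position out of bounds: ", pos)
  span_end <- min(L, pos + nchar(ref) - 1L)
  lo <- max(1L, pos - 1L)
  hi <- min(L, span_end + 1L)
  # adaptive window: exact run lengths without base-by-base file access
  w <- 64L
  repeat {
    win_lo <- max(1L, lo - w)
    win_hi <- min(L, hi + w)
    chars <- strsplit(ref_substr(reference, chrom, win_lo, win_hi), "")[[1]]
    best <- 0L
    truncated <- FALSE
    for (p in lo:hi) {
      i <- p - win_lo + 1L
      a <- i; b <- i
      while (a > 1L && chars[a - 1L] == chars[i]) a <- a - 1L
      while (b < length(chars) && chars[b + 1L] == chars[i]) b <- b + 1L
      if ((a == 1L && win_lo > 1L) || (b == length(chars) && win_hi < L))
        truncated <- TRUE
      best <- max(best, b - a + 1L)
    }
    if (!truncated) return(best)
    w <- w * 2L
  }
}

#' Prevalidate prioritized candidates
#'
#' Applies, in order: coding-region membership (a 1-based variant position is
#' coding iff it falls in the coding `GRanges`), homopolymer context,
#' alternate-read support, and the genotype-appropriate variant-allele
#' fraction gate. All failing reasons are recorded per candidate
#' (comma-joined); the ledger histogram counts each discard once, by its
#' first reason. Reason vocabulary: non_coding, repetitive, few_reads,
#' vaf_outlier.
#'
#' @param candidates prioritized candidate data frame.
#' @param reference reference sequences.
#' @param coding_regions `GRanges` of coding intervals
#'   ([read_bed_regions()]).
#' @param config [prevalidation_config()].
#' @param ledger ledger to extend.
#' @return list with `passed`, `discarded` (with `reason`), and `ledger`.
#' @export
prevalidate <- function(candidates, reference, coding_regions,
                        config = prevalidation_config(),
                        ledger = stage_ledger()) {
  n <- nrow(candidates)
  reasons <- vector("list", n)
  if (n > 0L) {
    loci <- GenomicRanges::GRanges(
      candidates$chrom,
      IRanges::IRanges(candidates$pos,
                       candidates$pos + nchar(candidates$ref) - 1L))
    coding <- IRanges::overlapsAny(loci, coding_regions)
    vaf <- candidates$alt_depth / candidates$total_depth
    for (i in seq_len(n)) {
      r <- character(0)
      if (config$require_coding && !coding[i]) r <- c(r, "non_coding")
      run <- homopolymer_run(reference, candidates$chrom[i],
                             candidates$pos[i], candidates$ref[i],
                             candidates$alt[i])
      if (run > config$homopolymer_max) r <- c(r, "repetitive")
      if (is.na(candidates$alt_depth[i]) ||
          candidates$alt_depth[i] < config$min_alt_reads)
        r <- c(r, "few_reads")
      else if (is.na(vaf[i])) r <- c(r, "vaf_outlier")
      else if (candidates$genotype[i] == "heterozygous" &&
               (vaf[i] < config$het_vaf_range[1] ||
                vaf[i] > config$het_vaf_range[2]))
        r <- c(r, "vaf_outlier")
      else if (candidates$genotype[i] == "homozygous_alt" &&
               vaf[i] < config$hom_vaf_min)
        r <- c(r, "vaf_outlier")
      reasons[[i]] <- r
    }
  }
  fail <- vapply(reasons, length, integer(1)) > 0L
  passed <- candidates[!fail, , drop = FALSE]
  passed <- .append_trail(passed, "prevalidation")
  discarded <- candidates[fail, , drop = FALSE]
  if (nrow(discarded) > 0L)
    discarded$reason <- vapply(reasons[fail], paste, character(1),
                               collapse = ",")
  else discarded$reason <- character(0)
  first_reason <- vapply(reasons[fail], `[`, character(1), 1L)
  ledger <- ledger_add(ledger, "prevalidation", n, nrow(passed),
                       reason_histogram(first_reason))
  rownames(passed) <- NULL
  rownames(discarded) <- NULL
  list(passed = passed, discarded = discarded, ledger = ledger)
}
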