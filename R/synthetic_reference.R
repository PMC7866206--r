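# Seeded synthetic reference: one chromosome with non-overlapping multi-exon
# gene models and deliberately planted homopolymer tracts (both intergenic and
# exonic) for prevalidation tests.

#' Generate a synthetic reference with gene models
#'
#' Produces a single chromosome of i.i.d. bases at the requested GC fraction,
#' places `n_genes` non-overlapping multi-exon genes, and overwrites planted
#' homopolymer tracts (T-rich, emulating the T-tracks that defeat visual
#' review). Deterministic for a fixed seed.
#'
#' @param length_bp chromosome length (>= 100 kb).
#' @param gc_fraction target GC content in `[0,1]` (default 0.41).
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed (`NULL`: use the current RNG stream).
#' @param gene_bp_range,min_gap gene span range and minimum intergenic gap.
#' @param n_exons_range,exon_bp_range exon count and width ranges per gene.
#' @param homopolymer_spec list with `n_intergenic`, `n_exonic` and
#'   `len_range` controlling planted tracts.
#' @return object of class `synthetic_reference`: `sequence`
#'   (`DNAStringSet`), `genes`, `exons`, `homopolymers` (`GRanges`),
#'   `chrom_length`.
#' @export
generate_reference <- function(length_bp = 2e6, gc_fraction = 0.41,
                               n_genes = 60L, seed = NULL,
                               gene_bp_range = c(6000L, 12000L),
                               min_gap = 200L,
                               n_exons_range = c(4L, 8L),
                               exon_bp_range = c(120L, 300L),
                               homopolymer_spec = list(n_intergenic = 30L,
                                                       n_exonic = 10L,
                                                       len_range = c(8L, 14L))) {
  if (length_bp < 1e5) stop("length_bp must be at least 100 kb")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  with_seed(seed, {
    widths <- sample(gene_bp_range[1]:gene_bp_range[2], n_genes,
                     replace = TRUE)
    if (sum(widths) + (n_genes + 1L) * min_gap > length_bp)
      stop("infeasible packing: ", n_genes, " genes of total span ",
           sum(widths), " bp do not fit in ", length_bp, " bp")
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    chars <- sample(names(p), length_bp, replace = TRUE, prob = p)

    # place genes left to right with random gaps from the slack budget
    slack <- length_bp - sum(widths) - (n_genes + 1L) * min_gap
    cuts <- sort(sample.int(slack + 1L, n_genes + 1L, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts))[seq_len(n_genes + 1L)]
    gaps <- min_gap + extra
    starts <- integer(n_genes)
    at <- 0L
    for (i in seq_len(n_genes)) {
      at <- at + gaps[i]
      starts[i] <- at + 1L
      at <- at + widths[i]
    }
    gene_ids <- sprintf("SYNG%03d", seq_len(n_genes))
    genes <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts, width = widths), name = gene_ids)

    # exons: ordered non-overlapping blocks inside each gene
    exon_rows <- list()
    for (i in seq_len(n_genes)) {
      k <- sample(n_exons_range[1]:n_exons_range[2], 1L)
      ew <- sample(exon_bp_range[1]:exon_bp_range[2], k, replace = TRUE)
      inner_slack <- widths[i] - sum(ew) - (k + 1L)
      if (inner_slack < 0L) { k <- 2L; ew <- rep(exon_bp_range[1], k)
        inner_slack <- widths[i] - sum(ew) - (k + 1L) }
      icuts <- sort(sample.int(inner_slack + 1L, k + 1L, replace = TRUE) - 1L)
      igaps <- 1L + diff(c(0L, icuts))[seq_len(k + 1L)]
      es <- integer(k); iat <- starts[i] - 1L
      for (j in seq_len(k)) {
        iat <- iat + igaps[j]
        es[j] <- iat + 1L
        iat <- iat + ew[j]
      }
      exon_rows[[i]] <- data.frame(start = es, width = ew, gene = gene_ids[i])
    }
    exon_df <- do.call(rbind, exon_rows)
    exons <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(exon_df$start, width = exon_df$width),
      gene = exon_df$gene)

    # planted homopolymer tracts
    hp <- list()
    n_ig <- homopolymer_spec$n_intergenic %||% 0L
    n_ex <- homopolymer_spec$n_exonic %||% 0L
    lr <- homopolymer_spec$len_range %||% c(8L, 14L)
    tract_base <- function(n) sample(c("T", "A", "C", "G"), n, replace = TRUE,
                                     prob = c(0.5, 0.2, 0.15, 0.15))
    if (n_ig > 0L) {
      # intergenic gaps before each gene
      gap_starts <- c(1L, GenomicRanges::end(genes) + 1L)
      gap_ends <- c(GenomicRanges::start(genes) - 1L, length_bp)
      ok <- gap_ends - gap_starts + 1L >= max(lr) + 4L
      pick <- sample(which(ok), min(n_ig, sum(ok)))
      for (g in pick) {
        len <- sample(lr[1]:lr[2], 1L)
        s <- sample(gap_starts[g]:(gap_ends[g] - len), 1L)
        hp[[length(hp) + 1L]] <- list(start = s, len = len,
                                      base = tract_base(1L))
      }
    }
    if (n_ex > 0L) {
      wide <- which(GenomicRanges::width(exons) >= max(lr) + 10L)
      pick <- sample(wide, min(n_ex, length(wide)))
      for (e in pick) {
        len <- sample(lr[1]:lr[2], 1L)
        lo <- GenomicRanges::start(exons)[e] + 2L
        hi <- GenomicRanges::end(exons)[e] - len - 2L
        s <- sample(lo:hi, 1L)
        hp[[length(hp) + 1L]] <- list(start = s, len = len,
                                      base = tract_base(1L))
      }
    }
    for (t in hp) chars[t$start:(t$start + t$len - 1L)] <- t$base
    homopolymers <- if (length(hp) > 0L) GenomicRanges::GRanges(
      "chr1",
      IRanges::IRanges(vapply(hp, `[[`, numeric(1), "start"),
                       width = vapply(hp, `[[`, numeric(1), "len")),
      base = vapply(hp, `[[`, character(1), "base"))
    else GenomicRanges::GRanges()

    seqs <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(seqs) <- "chr1"
    structure(list(sequence = seqs, genes = genes, exons = exons,
                   homopolymers = homopolymers, chrom_length = length_bp),
              class = "synthetic_reference")
  })
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat("synthetic_reference: chr1,", x$chrom_length, "bp,",
      length(x$genes), "genes,", length(x$exons), "exons,",
      length(x$homopolymers), "planted homopolymer tract(s)\n")
  invisible(x)
}

#' Write a synthetic reference to disk
#'
#' Emits the FASTA, a capture BED (gene spans), a coding BED (exons) and a
#' homopolymer-tract BED.
#'
#' @param reference [generate_reference()] output.
#' @param dir output directory.
#' @return named vector of file paths.
#' @export
write_synthetic_reference <- function(reference, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             capture = file.path(dir, "capture.bed"),
             coding = file.path(dir, "coding.bed"),
             homopolymers = file.path(dir, "homopolymers.bed"))
  write_reference(reference$sequence, paths["fasta"])
  write_bed_regions(reference$genes, paths["capture"])
  write_bed_regions(reference$exons, paths["coding"])
  write_bed_regions(reference$homopolymers, paths["homopolymers"])
  paths
}
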