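# VCF 4.2 IO for annotated germline cohorts and per-caller somatic callsets.
# Reading goes through VariantAnnotation; writing composes plain VCF text so
# that identical inputs give byte-identical files.
#
# Germline dialect: per-sample FORMAT GT:DP:AD and site-level INFO keys
#   GENE, CSQ, AF_MAX, SIFT, PPH2, CADD, PHYLOP, MT, LRT
# Missing predictor values are absent keys, never sentinel numbers.

.germline_cols <- c(
  "patient_id", "chrom", "pos", "ref", "alt", "genotype",
  "total_depth", "alt_depth", "call_quality",
  "gene_symbol", "consequence", "max_pop_af",
  "sift_score", "polyphen2_score", "cadd_phred", "phylop",
  "mutation_taster", "lrt"
)

#' Consequence class vocabulary
#'
#' @return character vector of the closed consequence vocabulary.
#' @export
consequence_classes <- function() {
  c("missense", "nonsense", "frameshift", "splice_site",
    "inframe_indel", "synonymous", "other")
}

.csq_aliases <- c(
  "missense" = "missense", "missense_variant" = "missense",
  "nonsense" = "nonsense", "stop_gained" = "nonsense",
  "frameshift" = "frameshift", "frameshift_variant" = "frameshift",
  "splice_site" = "splice_site", "splice" = "splice_site",
  "splicing" = "splice_site", "splice_donor_variant" = "splice_site",
  "splice_acceptor_variant" = "splice_site",
  "inframe_indel" = "inframe_indel", "inframe_insertion" = "inframe_indel",
  "inframe_deletion" = "inframe_indel",
  "synonymous" = "synonymous", "synonymous_variant" = "synonymous",
  "other" = "other"
)

normalize_consequence <- function(x) {
  key <- tolower(trimws(x))
  out <- unname(.csq_aliases[key])
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    warning("unknown consequence string(s) mapped to \"other\": ",
            paste(unique(x[bad]), collapse = ", "))
    out[bad] <- "other"
  }
  out
}

.fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         vapply(x, function(v) format(v, digits = 10, trim = TRUE,
                                      scientific = FALSE), character(1)))
}

.validate_germline <- function(df) {
  stopifnot(all(.germline_cols %in% names(df)))
  if (nrow(df) == 0L) return(df)
  bad <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt)
  if (any(bad))
    stop("alleles must be non-empty over {A,C,G,T}; offending record(s): ",
         paste(head(which(bad)), collapse = ", "))
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  if (any(df$pos < 1L)) stop("positions must be >= 1")
  if (any(!is.na(df$alt_depth) & !is.na(df$total_depth) &
          df$alt_depth > df$total_depth))
    stop("alt_depth exceeds total_depth")
  if (!all(df$genotype %in% c("heterozygous", "homozygous_alt")))
    stop("genotype must be heterozygous or homozygous_alt")
  if (!all(is.na(df$consequence) | df$consequence %in% consequence_classes()))
    stop("consequence outside the closed vocabulary")
  rng01 <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  if (!rng01(df$max_pop_af)) stop("max_pop_af outside [0,1]")
  if (!rng01(df$sift_score)) stop("sift_score outside [0,1]")
  if (!rng01(df$polyphen2_score)) stop("polyphen2_score outside [0,1]")
  if (!all(is.na(df$cadd_phred) | df$cadd_phred >= 0))
    stop("cadd_phred must be >= 0")
  if (!all(is.na(df$mutation_taster) |
           df$mutation_taster %in% c("A", "D", "N", "P")))
    stop("mutation_taster outside {A,D,N,P}")
  if (!all(is.na(df$lrt) | df$lrt %in% c("D", "N", "U")))
    stop("lrt outside {D,N,U}")
  df
}

.sort_germline <- function(df) {
  df[order(df$patient_id, df$chrom, df$pos, df$ref, df$alt,
           method = "radix"), , drop = FALSE]
}

#' Write one patient's annotated germline variants as VCF
#'
#' Deterministic, byte-identical output for identical inputs. Records are
#' sorted by (chrom, pos, ref, alt); missing annotation values are omitted
#' from INFO.
#'
#' @param records germline records data frame (one patient).
#' @param path output `.vcf` path.
#' @param reference optional reference; when given, `##contig` header lines
#'   with lengths are emitted.
#' @return `path`, invisibly.
#' @export
write_germline_vcf <- function(records, path, reference = NULL) {
  records <- .validate_germline(as.data.frame(records))
  pid <- unique(records$patient_id)
  if (length(pid) > 1L)
    stop("write_germline_vcf writes one patient per file; got ",
         length(pid), " patients")
  if (length(pid) == 0L) pid <- "SAMPLE"
  records <- records[order(records$chrom, records$pos, records$ref,
                           records$alt, method = "radix"), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gcgerm",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=AF_MAX,Number=1,Type=Float,Description=\"Maximum population allele frequency\">",
    "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score\">",
    "##INFO=<ID=PPH2,Number=1,Type=Float,Description=\"PolyPhen2 score\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD PHRED score\">",
    "##INFO=<ID=PHYLOP,Number=1,Type=Float,Description=\"PhyloP conservation score\">",
    "##INFO=<ID=MT,Number=1,Type=String,Description=\"MutationTaster call (A/D/N/P)\">",
    "##INFO=<ID=LRT,Number=1,Type=String,Description=\"LRT call (D/N/U)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
  )
  if (!is.null(reference)) {
    seqs <- reference_sequences(reference)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(seqs),
                          Biostrings::width(seqs)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", pid, sep = "\t"))
  info <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    kv <- c(GENE = r$gene_symbol,
            CSQ = r$consequence,
            AF_MAX = .fmt_num(r$max_pop_af),
            SIFT = .fmt_num(r$sift_score),
            PPH2 = .fmt_num(r$polyphen2_score),
            CADD = .fmt_num(r$cadd_phred),
            PHYLOP = .fmt_num(r$phylop),
            MT = r$mutation_taster,
            LRT = r$lrt)
    kv <- kv[!is.na(kv)]
    if (length(kv) == 0L) "." else paste(names(kv), kv, sep = "=", collapse = ";")
  }, character(1))
  gt <- ifelse(records$genotype == "homozygous_alt", "1/1", "0/1")
  ad <- paste(records$total_depth - records$alt_depth, records$alt_depth,
              sep = ",")
  body <- if (nrow(records) == 0L) character(0) else
    paste(records$chrom, records$pos, ".", records$ref, records$alt,
          .fmt_num(records$call_quality), "PASS", info, "GT:DP:AD",
          paste(gt, records$total_depth, ad, sep = ":"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a whole cohort as per-patient VCF files
#'
#' @param cohort germline records data frame (any number of patients).
#' @param dir output directory (created if needed).
#' @param reference optional reference for `##contig` lines.
#' @return named character vector of file paths, one per patient.
#' @export
write_germline_cohort <- function(cohort, dir, reference = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  pids <- sort(unique(cohort$patient_id))
  paths <- setNames(file.path(dir, paste0(pids, ".vcf")), pids)
  for (p in pids)
    write_germline_vcf(cohort[cohort$patient_id == p, , drop = FALSE],
                       paths[[p]], reference = reference)
  paths
}

.count_header_lines <- function(path) {
  n <- 0L
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

#' Read an annotated germline VCF into normalized records
#'
#' Emits one biallelic record per alternate allele per carrier sample:
#' multi-allelic sites are split, genotypes are mapped to
#' heterozygous/homozygous_alt, and homozygous-reference or missing genotypes
#' are dropped. Indel alleles are trimmed so downstream recurrence keys are
#' representation-independent. Non-diploid genotypes are rejected.
#'
#' @param path VCF file with `GT:DP:AD` sample fields and the annotation INFO
#'   keys (GENE, CSQ, AF_MAX, SIFT, PPH2, CADD, PHYLOP, MT, LRT), or bare
#'   genotype VCF when `annotation_tsv` supplies a sidecar table.
#' @param patient_id patient identifier; defaults to the single sample name in
#'   the file. For a multi-sample (joint cohort) VCF leave `NULL` to emit
#'   records for every sample, keyed by sample name.
#' @param annotation_tsv optional sidecar annotation table (TSV with columns
#'   chrom, pos, ref, alt plus the annotation fields) used instead of INFO
#'   keys.
#' @return data frame of germline records (one row per allele observation).
#' @export
read_annotated_vcf <- function(path, patient_id = NULL, annotation_tsv = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  hdr <- VariantAnnotation::header(vcf)
  sidecar <- !is.null(annotation_tsv)
  have_info <- rownames(VariantAnnotation::info(hdr))
  if (!sidecar) {
    missing_keys <- setdiff(c("GENE", "CSQ"), have_info)
    if (length(missing_keys) > 0L)
      stop("required annotation INFO key(s) missing from header: ",
           paste(missing_keys, collapse = ", "))
  }
  n <- length(vcf)
  samples <- dimnames(VariantAnnotation::geno(vcf)$GT)[[2]]
  if (is.null(samples) || length(samples) == 0L)
    stop("VCF carries no sample column")
  if (!is.null(patient_id) && length(samples) == 1L) {
    use_samples <- samples
    out_ids <- patient_id
  } else if (!is.null(patient_id)) {
    if (!patient_id %in% samples)
      stop("sample ", patient_id, " not present in ", path)
    use_samples <- patient_id
    out_ids <- patient_id
  } else {
    use_samples <- samples
    out_ids <- samples
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alts)
  qual <- VariantAnnotation::fixed(vcf)$QUAL
  n_hdr <- .count_header_lines(path)
  line_no <- n_hdr + seq_len(n)

  exp_row <- rep(seq_len(n), nalt)
  allele_idx <- unlist(lapply(nalt, seq_len), use.names = FALSE)
  alt_chr <- as.character(unlist(alts))

  inf <- VariantAnnotation::info(vcf)
  pull <- function(key, default = NA) {
    if (key %in% names(inf)) {
      v <- inf[[key]]
      if (is.list(v) || is(v, "List")) v <- as.vector(unlist(lapply(v, function(e)
        if (length(e) == 0L) NA else e[1L])))
      v
    } else rep(default, n)
  }
  ann <- data.frame(
    gene_symbol = as.character(pull("GENE", NA_character_)),
    csq_raw = as.character(pull("CSQ", NA_character_)),
    max_pop_af = as.numeric(pull("AF_MAX", NA_real_)),
    sift_score = as.numeric(pull("SIFT", NA_real_)),
    polyphen2_score = as.numeric(pull("PPH2", NA_real_)),
    cadd_phred = as.numeric(pull("CADD", NA_real_)),
    phylop = as.numeric(pull("PHYLOP", NA_real_)),
    mutation_taster = as.character(pull("MT", NA_character_)),
    lrt = as.character(pull("LRT", NA_character_)),
    stringsAsFactors = FALSE
  )

  gt_all <- VariantAnnotation::geno(vcf)$GT
  dp_all <- if ("DP" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$DP else matrix(NA_integer_, n, length(samples),
                                                dimnames = list(NULL, samples))
  ad_all <- if ("AD" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$AD else NULL

  get_ad <- function(i, s) {
    if (is.null(ad_all)) return(NULL)
    if (length(dim(ad_all)) == 3L) ad_all[i, s, ] else ad_all[[i, s]]
  }

  out <- vector("list", length(use_samples))
  for (si in seq_along(use_samples)) {
    s <- use_samples[si]
    gt <- gt_all[, s]
    miss <- gt %in% c(".", "./.", ".|.", "")
    ok_dip <- grepl("^[0-9]+[/|][0-9]+$", gt)
    bad <- !miss & !ok_dip
    if (any(bad)) {
      i <- which(bad)[1L]
      if (grepl("^[0-9.]+([/|][0-9.]+){2,}$", gt[i]) ||
          grepl("^[0-9]+$", gt[i]))
        stop("non-diploid genotype \"", gt[i], "\" at line ", line_no[i],
             " of ", path)
      stop("malformed genotype \"", gt[i], "\" at line ", line_no[i],
           " of ", path)
    }
    a1 <- suppressWarnings(as.integer(sub("[/|].*$", "", gt)))
    a2 <- suppressWarnings(as.integer(sub("^.*[/|]", "", gt)))
    dose <- (a1[exp_row] == allele_idx) + (a2[exp_row] == allele_idx)
    dose[miss[exp_row]] <- 0L
    keep <- which(!is.na(dose) & dose > 0L)
    if (length(keep) == 0L) { out[[si]] <- NULL; next }
    ri <- exp_row[keep]
    ai <- allele_idx[keep]
    alt_depth <- vapply(seq_along(keep), function(k) {
      adv <- get_ad(ri[k], s)
      if (is.null(adv) || length(adv) < ai[k] + 1L) NA_integer_
      else as.integer(adv[ai[k] + 1L])
    }, integer(1))
    total_depth <- dp_all[ri, s]
    no_dp <- is.na(total_depth)
    if (any(no_dp)) {
      total_depth[no_dp] <- vapply(which(no_dp), function(k) {
        adv <- get_ad(ri[k], s)
        if (is.null(adv)) NA_integer_ else as.integer(sum(adv))
      }, integer(1))
    }
    df <- data.frame(
      patient_id = out_ids[si],
      chrom = chrom[ri],
      pos = pos[ri],
      ref = refs[ri],
      alt = alt_chr[keep],
      genotype = ifelse(dose[keep] == 2L, "homozygous_alt", "heterozygous"),
      total_depth = as.integer(total_depth),
      alt_depth = alt_depth,
      call_quality = as.numeric(qual[ri]),
      line = line_no[ri],
      stringsAsFactors = FALSE
    )
    df <- cbind(df, ann[ri, , drop = FALSE])
    out[[si]] <- df
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) {
    res <- data.frame(matrix(nrow = 0, ncol = length(.germline_cols)))
    names(res) <- .germline_cols
    return(res)
  }

  if (sidecar) {
    side <- read.delim(annotation_tsv, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "gene_symbol", "consequence")
    if (!all(need %in% names(side)))
      stop("sidecar annotation table lacks column(s): ",
           paste(setdiff(need, names(side)), collapse = ", "))
    for (col in c("max_pop_af", "sift_score", "polyphen2_score", "cadd_phred",
                  "phylop"))
      if (!col %in% names(side)) side[[col]] <- NA_real_
    for (col in c("mutation_taster", "lrt"))
      if (!col %in% names(side)) side[[col]] <- NA_character_
    key <- variant_key(res$chrom, res$pos, res$ref, res$alt)
    skey <- variant_key(side$chrom, side$pos, side$ref, side$alt)
    idx <- match(key, skey)
    if (anyNA(idx))
      stop("sidecar annotation missing for variant(s): ",
           paste(head(key[is.na(idx)]), collapse = ", "))
    res$gene_symbol <- side$gene_symbol[idx]
    res$csq_raw <- side$consequence[idx]
    for (col in c("max_pop_af", "sift_score", "polyphen2_score", "cadd_phred",
                  "phylop", "mutation_taster", "lrt"))
      res[[col]] <- side[[col]][idx]
  }

  if (anyNA(res$gene_symbol))
    stop("missing required annotation key GENE at line ",
         res$line[which(is.na(res$gene_symbol))[1L]], " of ", path)
  if (anyNA(res$csq_raw))
    stop("missing required annotation key CSQ at line ",
         res$line[which(is.na(res$csq_raw))[1L]], " of ", path)
  res$consequence <- normalize_consequence(res$csq_raw)
  res$csq_raw <- NULL
  res$line <- NULL
  tr <- trim_alleles(res$pos, res$ref, res$alt)
  res$pos <- tr$pos; res$ref <- tr$ref; res$alt <- tr$alt
  res <- res[, .germline_cols]
  rownames(res) <- NULL
  .sort_germline(.validate_germline(res))
}

#' Read a directory (or set) of per-patient annotated VCFs
#'
#' @param paths directory containing `<patient>.vcf` files, or a character
#'   vector of VCF paths (optionally named by patient id; otherwise the file
#'   base name is used).
#' @return combined germline records data frame.
#' @export
read_germline_cohort <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.vcf$", full.names = TRUE)
    if (length(paths) == 0L) stop("no .vcf files found")
  }
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.vcf$", "", basename(paths))
  res <- do.call(rbind, lapply(seq_along(paths), function(i)
    read_annotated_vcf(paths[i], patient_id = ids[i])))
  rownames(res) <- NULL
  .sort_germline(res)
}

# ---- somatic callsets -------------------------------------------------------

#' Write a somatic callset as a minimal VCF
#'
#' @param calls data frame with chrom, pos, ref, alt.
#' @param path output path.
#' @param sample_id tumor sample identifier (header line).
#' @param caller caller name (header line).
#' @export
write_somatic_vcf <- function(calls, path, sample_id = "TUMOR",
                              caller = "caller") {
  calls <- as.data.frame(calls)
  calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt,
                       method = "radix"), , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", caller),
           paste0("##sample=", sample_id),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- if (nrow(calls) == 0L) character(0) else
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS", ".",
          sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a somatic callset VCF
#'
#' Multi-allelic records are split; alleles are trimmed; mutation class (SNV,
#' INS, DEL) is derived from allele lengths.
#'
#' @param path VCF path.
#' @return data frame with chrom, pos, ref, alt, mut_class.
#' @export
read_somatic_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alts)
  i <- rep(seq_along(vcf), nalt)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[i],
    pos = GenomicRanges::start(rr)[i],
    ref = as.character(VariantAnnotation::ref(vcf))[i],
    alt = as.character(unlist(alts)),
    stringsAsFactors = FALSE
  )
  tr <- trim_alleles(df$pos, df$ref, df$alt)
  df$pos <- tr$pos; df$ref <- tr$ref; df$alt <- tr$alt
  df$mut_class <- ifelse(is_snv(df$ref, df$alt), "SNV",
                         ifelse(nchar(df$alt) > nchar(df$ref), "INS", "DEL"))
  df <- df[order(df$chrom, df$pos, df$ref, df$alt, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
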