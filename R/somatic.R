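# Somatic mutational-profile module: multi-caller consensus, tumor mutational
# burden, SBS-96 / ID-83 catalogs and non-negative least-squares refitting of
# signature exposures against a catalog.

#' Merge per-caller somatic callsets by consensus
#'
#' A mutation is retained when its normalized key (chrom, pos, ref, alt)
#' appears in at least `min_snv` of the SNV callsets (for SNVs) or
#' `min_indel` of the indel callsets (for indels) — the 2-of-4 / 2-of-3 rule.
#' Duplicate keys within one caller are deduplicated with a warning.
#'
#' @param snv_callsets named list (by caller) of data frames with chrom, pos,
#'   ref, alt; up to 4 callers.
#' @param indel_callsets named list of indel callsets; up to 3 callers. A
#'   callset containing both classes may be passed to both arguments; rows
#'   are classified by allele lengths.
#' @param min_snv,min_indel minimum supporting callers (defaults 2 and 2).
#' @param sample_id sample identifier attached to the output.
#' @return data frame of consensus mutations with `mut_class`,
#'   `caller_support` (comma-joined) and `n_callers`.
#' @export
consensus_merge <- function(snv_callsets, indel_callsets,
                            min_snv = 2L, min_indel = 2L,
                            sample_id = NA_character_) {
  if (length(snv_callsets) > 4L) stop("at most 4 SNV callers supported")
  if (length(indel_callsets) > 3L) stop("at most 3 indel callers supported")
  collect <- function(callsets, want_snv) {
    rows <- list()
    for (caller in names(callsets)) {
      cs <- as.data.frame(callsets[[caller]])
      if (nrow(cs) == 0L) next
      tr <- trim_alleles(cs$pos, cs$ref, cs$alt)
      cs$pos <- tr$pos; cs$ref <- tr$ref; cs$alt <- tr$alt
      snv <- is_snv(cs$ref, cs$alt)
      cs <- cs[if (want_snv) snv else !snv, , drop = FALSE]
      if (nrow(cs) == 0L) next
      key <- variant_key(cs$chrom, cs$pos, cs$ref, cs$alt)
      dup <- duplicated(key)
      if (any(dup)) {
        warning("caller ", caller, ": ", sum(dup),
                " duplicate call(s) deduplicated")
        cs <- cs[!dup, , drop = FALSE]
        key <- key[!dup]
      }
      rows[[caller]] <- data.frame(key = key, chrom = cs$chrom, pos = cs$pos,
                                   ref = cs$ref, alt = cs$alt,
                                   caller = caller, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  build <- function(tab, min_support, mut_class_fun) {
    if (is.null(tab) || nrow(tab) == 0L) return(NULL)
    support <- split(tab$caller, tab$key)
    keep <- names(support)[vapply(support, length, integer(1)) >= min_support]
    if (length(keep) == 0L) return(NULL)
    first <- tab[!duplicated(tab$key), , drop = FALSE]
    first <- first[first$key %in% keep, , drop = FALSE]
    first$caller_support <- vapply(support[first$key], function(x)
      paste(sort(x), collapse = ","), character(1))
    first$n_callers <- vapply(support[first$key], length, integer(1))
    first$mut_class <- mut_class_fun(first$ref, first$alt)
    first$caller <- NULL
    first
  }
  snv_tab <- build(collect(snv_callsets, TRUE), min_snv,
                   function(r, a) rep("SNV", length(r)))
  ind_tab <- build(collect(indel_callsets, FALSE), min_indel,
                   function(r, a) ifelse(nchar(a) > nchar(r), "INS", "DEL"))
  out <- rbind(snv_tab, ind_tab)
  if (is.null(out))
    out <- data.frame(key = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), caller_support = character(0),
                      n_callers = integer(0), mut_class = character(0),
                      stringsAsFactors = FALSE)
  out$sample_id <- sample_id
  out <- out[order(out$chrom, out$pos, out$ref, out$alt, method = "radix"), ,
             drop = FALSE]
  out$key <- NULL
  rownames(out) <- NULL
  out[, c("sample_id", "chrom", "pos", "ref", "alt", "mut_class",
          "caller_support", "n_callers")]
}

#' Classify tumor mutational burden
#'
#' Strict thresholds: `tmb > 100` ultra-hypermutated, `100 >= tmb > 10`
#' hypermutated, otherwise non-hypermutated.
#'
#' @param tmb mutations per megabase (vectorized).
#' @return character vector of classes.
#' @export
classify_tmb <- function(tmb) {
  ifelse(tmb > 100, "ultra_hypermutated",
         ifelse(tmb > 10, "hypermutated", "non_hypermutated"))
}

#' Tumor mutational burden of a sample
#'
#' @param mutations consensus mutation data frame, or an integer mutation
#'   count.
#' @param region_mb size of the interrogated territory in megabases (the
#'   capture region; must be positive).
#' @param sample_id sample identifier (defaulted from `mutations` if present).
#' @return one-row data frame with `sample_id`, `n_mutations`, `region_mb`,
#'   `tmb`, `hyper_class`.
#' @export
compute_tmb <- function(mutations, region_mb, sample_id = NULL) {
  if (!is.numeric(region_mb) || region_mb <= 0)
    stop("region_mb must be positive")
  if (is.data.frame(mutations)) {
    n <- nrow(mutations)
    if (is.null(sample_id))
      sample_id <- if (n > 0L) mutations$sample_id[1L] else NA_character_
  } else {
    n <- as.integer(mutations)
    if (is.null(sample_id)) sample_id <- NA_character_
  }
  tmb <- n / region_mb
  data.frame(sample_id = sample_id, n_mutations = n, region_mb = region_mb,
             tmb = tmb, hyper_class = classify_tmb(tmb),
             stringsAsFactors = FALSE)
}

#' Build the SBS-96 mutational catalog of one or more samples
#'
#' Channels are pyrimidine-normalized trinucleotide substitutions: when the
#' reference base is a purine, the substitution and flanks are
#' reverse-complemented, so the catalog is invariant under global reverse
#' complement of genome and calls. The reference allele of every SNV is
#' checked against the reference sequence. Mutations whose context contains
#' N are skipped and counted.
#'
#' @param mutations data frame of SNVs with sample_id, chrom, pos, ref, alt.
#' @param reference reference sequences.
#' @return object of class `mutational_catalog` (fields `channel_set`,
#'   `channels`, `samples`, `counts`, `skipped`).
#' @export
sbs96_matrix <- function(mutations, reference) {
  mut <- as.data.frame(mutations)
  if (nrow(mut) > 0L && !all(is_snv(mut$ref, mut$alt)))
    stop("sbs96_matrix expects SNVs only")
  seqs <- reference_sequences(reference)
  samples <- sort(unique(mut$sample_id))
  counts <- matrix(0L, nrow = 96L, ncol = length(samples),
                   dimnames = list(sbs96_channels(), samples))
  skipped <- setNames(integer(length(samples)), samples)
  if (nrow(mut) > 0L) {
    ctx <- character(nrow(mut))
    for (chrom in unique(mut$chrom)) {
      idx <- which(mut$chrom == chrom)
      L <- Biostrings::width(seqs[chrom])
      if (any(mut$pos[idx] < 2L | mut$pos[idx] > L - 1L))
        stop("SNV context out of bounds on ", chrom)
      chars <- as.character(Biostrings::extractAt(
        seqs[[chrom]],
        IRanges::IRanges(mut$pos[idx] - 1L, mut$pos[idx] + 1L)))
      ctx[idx] <- chars
    }
    refbase <- substr(ctx, 2L, 2L)
    bad <- refbase != mut$ref
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("reference allele mismatch at ", mut$chrom[i], ":", mut$pos[i],
           " (VCF ref ", mut$ref[i], ", reference base ", refbase[i], ")")
    }
    chan <- sbs96_channel(mut$ref, mut$alt, substr(ctx, 1L, 1L),
                          substr(ctx, 3L, 3L))
    for (s in samples) {
      sel <- mut$sample_id == s
      skipped[s] <- sum(sel & is.na(chan))
      tab <- table(factor(chan[sel & !is.na(chan)],
                          levels = sbs96_channels()))
      counts[, s] <- as.integer(tab)
    }
  }
  structure(list(channel_set = "SBS96", channels = sbs96_channels(),
                 samples = samples, counts = counts, skipped = skipped),
            class = "mutational_catalog")
}

#' Build the ID-83 mutational catalog of one or more samples
#'
#' Each indel is classified with [id83_classify()].
#'
#' @param mutations data frame of indels with sample_id, chrom, pos, ref,
#'   alt.
#' @param reference reference sequences.
#' @return `mutational_catalog` with 83 channels.
#' @export
id83_matrix <- function(mutations, reference) {
  mut <- as.data.frame(mutations)
  if (nrow(mut) > 0L && any(is_snv(mut$ref, mut$alt)))
    stop("id83_matrix expects indels only")
  samples <- sort(unique(mut$sample_id))
  counts <- matrix(0L, nrow = 83L, ncol = length(samples),
                   dimnames = list(id83_channels(), samples))
  skipped <- setNames(integer(length(samples)), samples)
  if (nrow(mut) > 0L) {
    chan <- vapply(seq_len(nrow(mut)), function(i)
      id83_classify(reference, mut$chrom[i], mut$pos[i], mut$ref[i],
                    mut$alt[i]), character(1))
    for (s in samples) {
      sel <- mut$sample_id == s
      tab <- table(factor(chan[sel], levels = id83_channels()))
      counts[, s] <- as.integer(tab)
    }
  }
  structure(list(channel_set = "ID83", channels = id83_channels(),
                 samples = samples, counts = counts, skipped = skipped),
            class = "mutational_catalog")
}

#' @export
print.mutational_catalog <- function(x, ...) {
  cat("mutational_catalog:", x$channel_set, "|", length(x$samples),
      "sample(s), column sums:",
      paste(colSums(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Build a mutational catalog directly from channel counts
#'
#' Mainly for simulation and testing: wraps a channels x samples count matrix
#' in the catalog container.
#'
#' @param counts matrix with canonical SBS-96 or ID-83 rownames.
#' @return `mutational_catalog`.
#' @export
catalog_from_counts <- function(counts) {
  stopifnot(is.matrix(counts))
  if (nrow(counts) == 96L && setequal(rownames(counts), sbs96_channels())) {
    set <- "SBS96"; canon <- sbs96_channels()
  } else if (nrow(counts) == 83L && setequal(rownames(counts), id83_channels())) {
    set <- "ID83"; canon <- id83_channels()
  } else stop("counts must carry canonical SBS-96 or ID-83 rownames")
  counts <- counts[canon, , drop = FALSE]
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  structure(list(channel_set = set, channels = canon,
                 samples = colnames(counts), counts = counts,
                 skipped = setNames(integer(ncol(counts)), colnames(counts))),
            class = "mutational_catalog")
}

#' Refit signature exposures by non-negative least squares
#'
#' Per sample, exposures minimize the Euclidean distance between the observed
#' channel counts and the catalog-weighted sum, subject to non-negativity
#' (Lawson-Hanson NNLS). Signatures whose relative contribution falls below
#' `prune_threshold` are then removed and the fit repeated until the active
#' set is stable; within each pruning iteration the refit cannot have a
#' larger residual than simply zeroing the pruned exposures.
#'
#' @param catalog `mutational_catalog` of observed counts.
#' @param signatures [signature_catalog()] sharing the channel set.
#' @param prune_threshold minimum relative contribution kept (default 0.05);
#'   set `prune = FALSE` to skip pruning.
#' @param prune logical, apply pruning (default `TRUE`).
#' @return list of class `exposure_set`: one entry per sample with fields
#'   `sample_id`, `exposures` (named, all catalog signatures), `relative`
#'   (`NULL` for a zero-mutation sample), `residual_norm`, `aetiology`.
#' @export
refit_exposures <- function(catalog, signatures, prune_threshold = 0.05,
                            prune = TRUE) {
  stopifnot(inherits(catalog, "mutational_catalog"),
            inherits(signatures, "signature_catalog"))
  if (catalog$channel_set != signatures$channel_set)
    stop("catalog and signatures use different channel sets")
  P <- signatures$probabilities[catalog$channels, , drop = FALSE]
  sigs <- signatures$signatures
  out <- lapply(catalog$samples, function(s) {
    d <- as.numeric(catalog$counts[, s])
    expo <- setNames(numeric(length(sigs)), sigs)
    if (sum(d) == 0) {
      return(list(sample_id = s, exposures = expo, relative = NULL,
                  residual_norm = 0, aetiology = signatures$aetiology))
    }
    active <- sigs
    repeat {
      fit <- pracma::lsqnonneg(P[, active, drop = FALSE], d)
      x <- setNames(pmax(fit$x, 0), active)
      total <- sum(x)
      if (!prune || total == 0) break
      rel <- x / total
      keep <- names(rel)[rel >= prune_threshold]
      if (length(keep) == 0L) keep <- names(which.max(rel))
      if (setequal(keep, active)) break
      active <- keep
    }
    expo[names(x)] <- x
    resid <- sqrt(sum((P %*% expo - d)^2))
    total <- sum(expo)
    list(sample_id = s,
         exposures = expo,
         relative = if (total > 0) expo / total else NULL,
         residual_norm = resid,
         aetiology = signatures$aetiology)
  })
  names(out) <- catalog$samples
  class(out) <- "exposure_set"
  out
}

#' Tabulate an exposure set
#'
#' @param exposures `exposure_set` from [refit_exposures()].
#' @return data frame with sample_id, signature, exposure, relative,
#'   residual_norm, aetiology.
#' @export
exposure_table <- function(exposures) {
  do.call(rbind, lapply(exposures, function(e) {
    data.frame(sample_id = e$sample_id,
               signature = names(e$exposures),
               exposure = as.numeric(e$exposures),
               relative = if (is.null(e$relative)) NA_real_
               else as.numeric(e$relative),
               residual_norm = e$residual_norm,
               aetiology = as.character(e$aetiology[names(e$exposures)]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' @export
print.exposure_set <- function(x, ...) {
  tab <- exposure_table(x)
  print(tab[tab$exposure > 0, , drop = FALSE])
  invisible(x)
}
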