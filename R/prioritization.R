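# Two-step manual prioritization: restriction to cancer-predisposition genes,
# inheritance-model analyses (dominant, recessive, optional compound
# heterozygotes) with category-specific gene criteria, and the cohort
# recurrence exclusion.

#' Prioritization configuration
#'
#' @param recessive_required_categories categories (or the
#'   `is_cancer_predisposition` pseudo-category) a gene must carry for its
#'   homozygous variants to enter the recessive arm. Default: cancer
#'   predisposition or pathogen recognition.
#' @param dominant_required_categories categories qualifying a gene for the
#'   dominant arm: stomach function and gastric-cancer development plus the
#'   prioritized function list and the risk-factor functions.
#' @param allow_compound_het admit pairs of distinct heterozygous variants in
#'   the same gene and patient as recessive candidates (phase assumed trans;
#'   flagged unphased). Default `FALSE`.
#' @param max_recurrence_fraction variants carried by strictly more than this
#'   fraction of cohort patients are excluded as likely artifacts or
#'   polymorphisms. Default 0.25.
#' @param restrict_to_cancer_genes apply the step-1 cancer-gene restriction
#'   (default `TRUE`); disable for union-mode sensitivity analyses.
#' @return list of class `prioritization_config`.
#' @export
prioritization_config <- function(
    recessive_required_categories = c("is_cancer_predisposition",
                                      "pathogen_recognition"),
    dominant_required_categories = c("stomach_function", "gc_development",
                                     "tumor_suppression", "dna_repair",
                                     "apoptosis", "pathogen_recognition",
                                     "innate_immunity",
                                     "gut_epithelial_protection",
                                     "cell_adhesion", "alcohol_metabolism",
                                     "gastric_acid_secretion"),
    allow_compound_het = FALSE,
    max_recurrence_fraction = 0.25,
    restrict_to_cancer_genes = TRUE) {
  stopifnot(max_recurrence_fraction > 0, max_recurrence_fraction < 1)
  structure(list(recessive_required_categories = recessive_required_categories,
                 dominant_required_categories = dominant_required_categories,
                 allow_compound_het = isTRUE(allow_compound_het),
                 max_recurrence_fraction = max_recurrence_fraction,
                 restrict_to_cancer_genes = isTRUE(restrict_to_cancer_genes)),
            class = "prioritization_config")
}

# effective categories per record's gene, as a list
.record_categories <- function(records, knowledge) {
  cats_by_gene <- lapply(unique(records$gene_symbol), knowledge_categories,
                         knowledge = knowledge)
  names(cats_by_gene) <- unique(records$gene_symbol)
  cats_by_gene[records$gene_symbol]
}

#' Restrict records to cancer-predisposition genes
#'
#' Step 1 of the manual prioritization: only variants on genes previously
#' involved in germline predisposition to any cancer are kept. With an empty
#' gene list everything is discarded (degenerate; a warning is raised).
#'
#' @param records filtered germline records.
#' @param knowledge gene knowledge table with `is_cancer_predisposition`
#'   flags.
#' @param restrict disable to pass all records through (union mode).
#' @return list with `retained` and `discarded`.
#' @export
cancer_gene_select <- function(records, knowledge, restrict = TRUE) {
  if (!restrict)
    return(.split_records(records, rep(TRUE, nrow(records)), "gene_list"))
  flagged <- knowledge$gene_symbol[knowledge$is_cancer_predisposition]
  if (length(flagged) == 0L)
    warning("cancer gene list is empty; every record is discarded")
  keep <- records$gene_symbol %in% flagged
  .split_records(records, keep, "gene_list")
}

#' Recessive-inheritance candidates
#'
#' Homozygous-alternate records on genes whose effective categories intersect
#' the recessive requirement become recessive candidates. With
#' `allow_compound_het`, any qualifying gene carrying two or more distinct
#' heterozygous records in the same patient contributes the pair as
#' candidates (phase assumed trans, flagged unphased).
#'
#' @param patient_records germline records (any number of patients).
#' @param knowledge gene knowledge table.
#' @param config [prioritization_config()].
#' @return candidate data frame with `inheritance_model`,
#'   `matched_categories` and `compound_het` columns.
#' @export
recessive_candidates <- function(patient_records, knowledge,
                                 config = prioritization_config()) {
  cats <- .record_categories(patient_records, knowledge)
  qual <- vapply(cats, function(cc)
    length(intersect(cc, config$recessive_required_categories)) > 0L,
    logical(1))
  hom <- patient_records$genotype == "homozygous_alt" & qual
  out <- patient_records[hom, , drop = FALSE]
  if (nrow(out) > 0L) {
    out$inheritance_model <- "recessive"
    out$matched_categories <- vapply(cats[hom], function(cc)
      paste(sort(intersect(cc, config$recessive_required_categories)),
            collapse = ","), character(1))
    out$compound_het <- FALSE
  } else {
    out$inheritance_model <- character(0)
    out$matched_categories <- character(0)
    out$compound_het <- logical(0)
  }
  if (config$allow_compound_het) {
    het <- patient_records$genotype == "heterozygous" & qual
    hrec <- patient_records[het, , drop = FALSE]
    if (nrow(hrec) > 0L) {
      grp <- paste(hrec$patient_id, hrec$gene_symbol, sep = "\r")
      keys <- variant_key(hrec$chrom, hrec$pos, hrec$ref, hrec$alt)
      n_distinct <- vapply(split(keys, grp), function(k)
        length(unique(k)), integer(1))
      in_pair <- grp %in% names(n_distinct)[n_distinct >= 2L] &
        !duplicated(paste(grp, keys, sep = "\r"))
      pair <- hrec[in_pair, , drop = FALSE]
      if (nrow(pair) > 0L) {
        pcats <- .record_categories(pair, knowledge)
        pair$inheritance_model <- "recessive"
        pair$matched_categories <- vapply(pcats, function(cc)
          paste(sort(intersect(cc, config$recessive_required_categories)),
                collapse = ","), character(1))
        pair$compound_het <- TRUE
        out <- rbind(out, pair)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Dominant-inheritance candidates
#'
#' Heterozygous records on genes whose effective categories intersect the
#' dominant requirement become dominant candidates; homozygous rare variants
#' route through the recessive arm instead.
#'
#' @inheritParams recessive_candidates
#' @return candidate data frame.
#' @export
dominant_candidates <- function(patient_records, knowledge,
                                config = prioritization_config()) {
  cats <- .record_categories(patient_records, knowledge)
  qual <- vapply(cats, function(cc)
    length(intersect(cc, config$dominant_required_categories)) > 0L,
    logical(1))
  het <- patient_records$genotype == "heterozygous" & qual
  out <- patient_records[het, , drop = FALSE]
  if (nrow(out) > 0L) {
    out$inheritance_model <- "dominant"
    out$matched_categories <- vapply(cats[het], function(cc)
      paste(sort(intersect(cc, config$dominant_required_categories)),
            collapse = ","), character(1))
    out$compound_het <- FALSE
  } else {
    out$inheritance_model <- character(0)
    out$matched_categories <- character(0)
    out$compound_het <- logical(0)
  }
  rownames(out) <- NULL
  out
}

#' Cohort recurrence exclusion
#'
#' A variant key (chrom, pos, ref, alt) carried by strictly more than
#' `max_recurrence_fraction` of the cohort's patients is removed from all its
#' carriers; carriers are counted as distinct patients, not alleles.
#'
#' @param candidates candidate data frame.
#' @param n_patients cohort size (must be positive).
#' @param config [prioritization_config()].
#' @return list with `retained` and `discarded`.
#' @export
recurrence_filter <- function(candidates, n_patients,
                              config = prioritization_config()) {
  if (n_patients <= 0L) stop("n_patients must be positive")
  keys <- variant_key(candidates$chrom, candidates$pos, candidates$ref,
                      candidates$alt)
  carriers <- vapply(split(candidates$patient_id, keys), function(p)
    length(unique(p)), integer(1))
  recurrent <- names(carriers)[carriers / n_patients >
                                 config$max_recurrence_fraction]
  keep <- !(keys %in% recurrent)
  .split_records(candidates, keep, "recurrence")
}

#' Prioritize filtered germline records under both inheritance models
#'
#' Applies the cancer-gene restriction, then the recessive and dominant
#' analyses (a heterozygous record is examined by the dominant arm, a
#' homozygous one by the recessive arm; a gene may appear under both models
#' via different variants in different patients), then the recurrence
#' exclusion. The stage ledger is extended with `gene_list`, `inheritance`
#' and `recurrence` stages, counting distinct input records.
#'
#' @param filtered_cohort output records of [run_pipeline_filter()].
#' @param knowledge gene knowledge table.
#' @param n_patients cohort size for the recurrence denominator (default:
#'   number of distinct patients in `filtered_cohort`).
#' @param config [prioritization_config()].
#' @param ledger ledger to extend.
#' @return list with `candidates`, `discarded` and `ledger`.
#' @export
prioritize <- function(filtered_cohort, knowledge,
                       n_patients = length(unique(filtered_cohort$patient_id)),
                       config = prioritization_config(),
                       ledger = stage_ledger()) {
  records <- as.data.frame(filtered_cohort)
  if (is.null(records$stage_trail))
    records$stage_trail <- character(nrow(records))
  records$.rid <- seq_len(nrow(records))
  discarded_all <- list()

  res <- cancer_gene_select(records, knowledge,
                            restrict = config$restrict_to_cancer_genes)
  res$retained <- .append_trail(res$retained, "gene_list")
  ledger <- ledger_add(ledger, "gene_list", nrow(records), nrow(res$retained),
                       reason_histogram(res$discarded$reason))
  discarded_all <- c(discarded_all, list(res$discarded))
  records <- res$retained

  rec <- recessive_candidates(records, knowledge, config)
  dom <- dominant_candidates(records, knowledge, config)
  candidates <- rbind(rec, dom)
  candidates <- .append_trail(candidates, "inheritance")
  kept_rids <- unique(candidates$.rid)
  dropped <- records[!(records$.rid %in% kept_rids), , drop = FALSE]
  if (nrow(dropped) > 0L) dropped$reason <- "inheritance"
  else dropped$reason <- character(0)
  ledger <- ledger_add(ledger, "inheritance", nrow(records),
                       length(kept_rids),
                       reason_histogram(dropped$reason))
  discarded_all <- c(discarded_all, list(dropped))

  res <- recurrence_filter(candidates, n_patients, config)
  res$retained <- .append_trail(res$retained, "recurrence")
  n_in <- length(unique(candidates$.rid))
  n_out <- length(unique(res$retained$.rid))
  drop_rec <- res$discarded[!duplicated(res$discarded$.rid), , drop = FALSE]
  ledger <- ledger_add(ledger, "recurrence", n_in, n_out,
                       reason_histogram(drop_rec$reason))
  discarded_all <- c(discarded_all, list(res$discarded))
  candidates <- res$retained

  candidates <- candidates[order(candidates$patient_id, candidates$chrom,
                                 candidates$pos, candidates$ref,
                                 candidates$alt, candidates$inheritance_model,
                                 method = "radix"), , drop = FALSE]
  candidates$.rid <- NULL
  rownames(candidates) <- NULL
  discarded_all <- lapply(discarded_all, function(d) { d$.rid <- NULL; d })
  all_cols <- unique(unlist(lapply(discarded_all, names)))
  discarded <- do.call(rbind, lapply(discarded_all, function(d) {
    for (col in setdiff(all_cols, names(d))) d[[col]] <- rep(NA, nrow(d))
    d[, all_cols, drop = FALSE]
  }))
  list(candidates = candidates, discarded = discarded, ledger = ledger)
}
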