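# Final candidate selection: a transparent additive score over matched gene
# function categories, plus a tumor-concordance bonus when a patient's tumor
# exposures carry an aetiology tag mapped to the candidate's gene categories
# (the mismatch-repair <-> DNA-repair link). The expert judgment of the
# original selection is deliberately replaced by this explicit scheme.

#' Selection configuration
#'
#' @param category_weights named non-negative weights over gene function
#'   categories (plus the `is_cancer_predisposition` pseudo-category).
#' @param concordance_bonus additive bonus when tumor exposures support a
#'   candidate's gene function (default 2).
#' @param concordance_map named list mapping aetiology tags to gene
#'   categories (default: `mmr_deficiency` supports `dna_repair`).
#' @param min_signature_fraction minimum relative exposure for a signature to
#'   support concordance (default 0.05).
#' @param top_k keep only the top-scoring candidates (`Inf`: all).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(
    category_weights = c(is_cancer_predisposition = 1,
                         tumor_suppression = 2, dna_repair = 2,
                         cell_adhesion = 2, gc_development = 2,
                         pathogen_recognition = 2, innate_immunity = 1,
                         apoptosis = 1, gut_epithelial_protection = 1,
                         stomach_function = 1, alcohol_metabolism = 0.5,
                         gastric_acid_secretion = 0.5),
    concordance_bonus = 2,
    concordance_map = list(mmr_deficiency = "dna_repair"),
    min_signature_fraction = 0.05,
    top_k = Inf) {
  stopifnot(all(category_weights >= 0), all(is.finite(category_weights)),
            concordance_bonus >= 0,
            min_signature_fraction > 0, min_signature_fraction < 1)
  structure(list(category_weights = category_weights,
                 concordance_bonus = concordance_bonus,
                 concordance_map = concordance_map,
                 min_signature_fraction = min_signature_fraction,
                 top_k = top_k),
            class = "selection_config")
}

# aetiology tags supported by one patient's tumor exposures (relative
# contribution >= threshold), across any number of exposure fits
.supported_tags <- function(exposure_fits, min_fraction) {
  tags <- character(0)
  for (e in exposure_fits) {
    if (is.null(e$relative)) next
    strong <- names(e$relative)[e$relative >= min_fraction]
    tags <- c(tags, unname(e$aetiology[strong]))
  }
  unique(tags)
}

#' Score and rank prevalidated candidates
#'
#' `score = sum of category weights over the candidate gene's effective
#' categories + concordance bonus` when the patient's tumor exposures carry
#' an aetiology tag whose mapped categories intersect those gene categories
#' with relative contribution at or above the threshold. Ranking is by
#' descending score with a deterministic tie-break on (gene, chrom, pos,
#' patient).
#'
#' @param candidates prevalidated candidate data frame.
#' @param exposures_by_patient named list (by patient id) of lists of
#'   exposure fits ([refit_exposures()] entries); patients without tumor
#'   data may be absent.
#' @param knowledge gene knowledge table.
#' @param config [selection_config()].
#' @return candidates with `score`, `concordant` and `rank` columns, ranked.
#' @export
score_candidates <- function(candidates, exposures_by_patient = list(),
                             knowledge, config = selection_config()) {
  n <- nrow(candidates)
  score <- numeric(n)
  concordant <- logical(n)
  tag_cache <- lapply(exposures_by_patient, .supported_tags,
                      min_fraction = config$min_signature_fraction)
  for (i in seq_len(n)) {
    cats <- knowledge_categories(knowledge, candidates$gene_symbol[i])
    w <- config$category_weights[intersect(names(config$category_weights),
                                           cats)]
    s <- sum(w)
    tags <- tag_cache[[candidates$patient_id[i]]]
    if (!is.null(tags) && length(tags) > 0L) {
      mapped <- unique(unlist(config$concordance_map[
        intersect(names(config$concordance_map), tags)]))
      if (length(intersect(mapped, cats)) > 0L) {
        s <- s + config$concordance_bonus
        concordant[i] <- TRUE
      }
    }
    score[i] <- s
  }
  out <- candidates
  out$score <- score
  out$concordant <- concordant
  ord <- order(-out$score, out$gene_symbol, out$chrom, out$pos,
               out$patient_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  if (is.finite(config$top_k) && n > config$top_k)
    out <- out[seq_len(config$top_k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the candidate report, run summary and ledger
#'
#' Produces `candidates.tsv` (sorted by patient, chrom, pos), `tmb.tsv`,
#' `exposures.tsv`, `run_summary.json` (machine-readable: counts, ledger,
#' TMB, relative exposures) and `summary.txt` (human-readable). Output is
#' byte-identical across runs on identical inputs.
#'
#' @param candidates scored candidate data frame.
#' @param ledger [stage_ledger()].
#' @param tmb_records TMB data frame (possibly `NULL`).
#' @param exposures named list (by sample) of exposure fits (possibly
#'   empty).
#' @param out_dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_report <- function(candidates, ledger, tmb_records = NULL,
                         exposures = list(), out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot write report: unwritable directory ", out_dir)
  paths <- c(candidates = file.path(out_dir, "candidates.tsv"),
             tmb = file.path(out_dir, "tmb.tsv"),
             exposures = file.path(out_dir, "exposures.tsv"),
             summary_json = file.path(out_dir, "run_summary.json"),
             summary_txt = file.path(out_dir, "summary.txt"))

  cand_cols <- c("patient_id", "chrom", "pos", "ref", "alt", "gene_symbol",
                 "consequence", "genotype", "inheritance_model",
                 "matched_categories", "score", "concordant", "rank",
                 "stage_trail")
  cand <- candidates[, intersect(cand_cols, names(candidates)), drop = FALSE]
  cand <- cand[order(cand$patient_id, cand$chrom, cand$pos,
                     method = "radix"), , drop = FALSE]
  write.table(cand, paths["candidates"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  if (!is.null(tmb_records))
    write.table(tmb_records, paths["tmb"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  else writeLines("sample_id\tn_mutations\tregion_mb\ttmb\thyper_class",
                  paths["tmb"])

  expo_tab <- if (length(exposures) > 0L) {
    tab <- do.call(rbind, lapply(names(exposures), function(s) {
      fits <- exposures[[s]]
      do.call(rbind, lapply(fits, function(e) {
        data.frame(sample_id = s, channel_set = "",
                   signature = names(e$exposures),
                   exposure = round(as.numeric(e$exposures), 4),
                   relative = if (is.null(e$relative)) NA_real_
                   else round(as.numeric(e$relative), 6),
                   stringsAsFactors = FALSE)
      }))
    }))
    tab[tab$exposure > 0 | is.na(tab$relative), , drop = FALSE]
  } else NULL
  if (!is.null(expo_tab))
    write.table(expo_tab, paths["exposures"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  else writeLines("sample_id\tchannel_set\tsignature\texposure\trelative",
                  paths["exposures"])

  summary <- list(
    n_candidates = nrow(cand),
    n_patients_with_candidates = length(unique(cand$patient_id)),
    ledger = ledger_to_list(ledger),
    ledger_violations = validate_ledger(ledger),
    tmb = if (is.null(tmb_records)) list() else tmb_records,
    exposures = if (is.null(expo_tab)) list() else expo_tab
  )
  jsonlite::write_json(summary, paths["summary_json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  txt <- c("Germline candidate prioritization: run summary",
           "",
           sprintf("Final candidates: %d (in %d patient(s))", nrow(cand),
                   length(unique(cand$patient_id))),
           "",
           "Stage ledger (input -> retained | discarded):",
           sprintf("  %-20s %7d -> %7d | %d", ledger$stages, ledger$input,
                   ledger$retained, ledger$discarded))
  if (!is.null(tmb_records) && nrow(tmb_records) > 0L) {
    txt <- c(txt, "", "Tumor mutational burden:",
             sprintf("  %-8s %8.1f mut/Mb  %s", tmb_records$sample_id,
                     tmb_records$tmb, tmb_records$hyper_class))
  }
  writeLines(txt, paths["summary_txt"])
  invisible(paths)
}
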