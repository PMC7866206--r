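# The automated germline filtering cascade: sequence quality, functional
# consequence, population frequency, pathogenicity-predictor consensus for
# missense variants, and gene function-term matching, with per-stage ledger
# bookkeeping.

#' Default term list for gene function selection
#'
#' The study's appendix term list is not public; this default is a
#' reconstruction from the named gene functions (cancer, tumor suppression,
#' DNA repair, apoptosis, pathogen recognition, innate immunity, gut
#' epithelial protection, cell adhesion, the risk-factor functions, stomach
#' function and gastric cancer development) and is intended to be replaced by
#' users with a curated list.
#'
#' @return character vector of selection terms.
#' @export
default_term_list <- function() {
  c("cancer", "tumor suppression", "dna repair", "apoptosis",
    "pathogen recognition", "innate immunity", "gut epithelial protection",
    "cell adhesion", "alcohol metabolism", "gastric acid secretion",
    "stomach function", "gc development", "gastric cancer",
    "helicobacter pylori")
}

#' Germline filter configuration
#'
#' The study states the filter intents (functional effect, sequence quality,
#' rarity, predictor panel, term selection) without numeric thresholds; the
#' defaults here are declared conventions, all configurable.
#'
#' @param allowed_consequences consequence classes retained by the functional
#'   filter (default: missense plus the loss-of-function classes).
#' @param max_pop_af rarity threshold on the maximum population allele
#'   frequency; records with frequency `< max_pop_af`, or with no frequency
#'   record (novel variants), are retained. Default 0.01.
#' @param min_depth,min_alt_reads,min_quality sequence-quality gates
#'   (total depth, alternate-allele reads, call quality). Defaults 10, 4, 30.
#' @param predictor_rules named list of per-tool damaging rules (predicate
#'   functions of the score); defaults use the tools' published cutoffs:
#'   SIFT < 0.05, PolyPhen2 >= 0.446, CADD >= 20, PhyloP >= 2,
#'   MutationTaster in {A,D}, LRT = D.
#' @param consensus_fraction fraction of non-missing predictors that must
#'   vote damaging for a missense variant (default 0.5; a variant with no
#'   non-missing predictor is not damaging).
#' @param term_list selection terms matched against gene terms and category
#'   names (default [default_term_list()]).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(allowed_consequences = c("missense", "nonsense",
                                                   "frameshift", "splice_site"),
                          max_pop_af = 0.01,
                          min_depth = 10L,
                          min_alt_reads = 4L,
                          min_quality = 30,
                          predictor_rules = default_predictor_rules(),
                          consensus_fraction = 0.5,
                          term_list = default_term_list()) {
  stopifnot(max_pop_af >= 0, min_depth >= 0, min_alt_reads >= 0,
            min_quality >= 0,
            consensus_fraction > 0, consensus_fraction <= 1)
  structure(list(allowed_consequences = allowed_consequences,
                 max_pop_af = max_pop_af,
                 min_depth = as.integer(min_depth),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_quality = min_quality,
                 predictor_rules = predictor_rules,
                 consensus_fraction = consensus_fraction,
                 term_list = term_list),
            class = "filter_config")
}

#' Default per-tool damaging rules
#'
#' @return named list of predicate functions over predictor values.
#' @export
default_predictor_rules <- function() {
  list(
    sift_score = function(x) x < 0.05,
    polyphen2_score = function(x) x >= 0.446,
    cadd_phred = function(x) x >= 20,
    phylop = function(x) x >= 2.0,
    mutation_taster = function(x) x %in% c("A", "D"),
    lrt = function(x) x == "D"
  )
}

.split_records <- function(records, keep, reason) {
  discarded <- records[!keep, , drop = FALSE]
  if (nrow(discarded) > 0L) discarded$reason <- reason
  else discarded$reason <- character(0)
  list(retained = records[keep, , drop = FALSE], discarded = discarded)
}

#' Sequence-quality filter
#'
#' Retains records with `total_depth >= min_depth`,
#' `alt_depth >= min_alt_reads` and `call_quality >= min_quality`.
#'
#' @param records germline records data frame.
#' @param config [filter_config()].
#' @return list with `retained` and `discarded` (with a `reason` column).
#' @export
quality_filter <- function(records, config = filter_config()) {
  keep <- !is.na(records$total_depth) & records$total_depth >= config$min_depth &
    !is.na(records$alt_depth) & records$alt_depth >= config$min_alt_reads &
    !is.na(records$call_quality) & records$call_quality >= config$min_quality
  .split_records(records, keep, "quality")
}

#' Functional-consequence filter
#'
#' Retains records whose consequence class is in the allowed set; synonymous
#' and "other" are discarded by default.
#'
#' @inheritParams quality_filter
#' @return list with `retained` and `discarded`.
#' @export
consequence_filter <- function(records, config = filter_config()) {
  keep <- records$consequence %in% config$allowed_consequences
  .split_records(records, keep, "consequence")
}

#' Population-frequency filter
#'
#' Retains records with maximum population allele frequency strictly below the
#' threshold; a missing frequency is treated as rare (novel variants are the
#' object of the analysis).
#'
#' @inheritParams quality_filter
#' @return list with `retained` and `discarded`.
#' @export
frequency_filter <- function(records, config = filter_config()) {
  keep <- is.na(records$max_pop_af) | records$max_pop_af < config$max_pop_af
  .split_records(records, keep, "frequency")
}

#' Pathogenicity-predictor consensus for missense variants
#'
#' Each non-missing predictor votes damaging according to the per-tool rules;
#' the variant is damaging when the damaging fraction of non-missing votes is
#' at least `consensus_fraction`. A variant with no non-missing predictor is
#' conservatively not damaging. The predictors score amino-acid substitutions,
#' so calling this on non-missense records is a contract violation.
#'
#' @param annotation data frame of missense records (the predictor columns
#'   are used: sift_score, polyphen2_score, cadd_phred, phylop,
#'   mutation_taster, lrt).
#' @param config [filter_config()].
#' @return data frame with `damaging` (logical), `votes_damaging`,
#'   `votes_total` per input row.
#' @export
predictor_consensus <- function(annotation, config = filter_config()) {
  if (nrow(annotation) > 0L && any(annotation$consequence != "missense"))
    stop("predictor_consensus is defined for missense variants only")
  n <- nrow(annotation)
  votes_damaging <- integer(n)
  votes_total <- integer(n)
  for (tool in names(config$predictor_rules)) {
    x <- annotation[[tool]]
    present <- !is.na(x)
    vote <- rep(FALSE, n)
    if (any(present)) vote[present] <- config$predictor_rules[[tool]](x[present])
    votes_total <- votes_total + as.integer(present)
    votes_damaging <- votes_damaging + as.integer(present & vote)
  }
  damaging <- votes_total > 0L &
    votes_damaging / pmax(votes_total, 1L) >= config$consensus_fraction
  data.frame(damaging = damaging, votes_damaging = votes_damaging,
             votes_total = votes_total)
}

#' Match selection terms against one gene's terms and categories
#'
#' Case-insensitive whole-entry matching of the term list against the gene's
#' free-text terms and its category names (underscores read as spaces). A
#' gene absent from the knowledge table yields no match (not an error).
#'
#' @param gene_symbol gene symbol.
#' @param knowledge gene knowledge table ([read_gene_knowledge()]).
#' @param term_list character vector of selection terms.
#' @return character vector of matched terms (possibly empty).
#' @export
term_match <- function(gene_symbol, knowledge, term_list = default_term_list()) {
  i <- match(gene_symbol, knowledge$gene_symbol)
  if (is.na(i)) return(character(0))
  norm <- function(x) tolower(gsub("_", " ", trimws(x), fixed = TRUE))
  gene_tokens <- norm(c(knowledge$terms[[i]], knowledge$function_categories[[i]]))
  hits <- norm(term_list) %in% gene_tokens
  term_list[hits]
}

.append_trail <- function(records, stage) {
  if (is.null(records$stage_trail))
    records$stage_trail <- character(nrow(records))
  if (nrow(records) == 0L) return(records)
  records$stage_trail <- ifelse(
    nzchar(records$stage_trail),
    paste(records$stage_trail, paste0(stage, "=retained"), sep = ","),
    paste0(stage, "=retained"))
  records
}

#' Run the automated germline filtering cascade
#'
#' Stages are applied in fixed order: quality, consequence, frequency,
#' predictor consensus (missense records only; loss-of-function classes
#' bypass the predictors), term match. The stage order affects discard
#' attribution but not final membership. A stage ledger with discard-reason
#' histograms is maintained and checked for conservation.
#'
#' @param cohort germline records data frame (parsed and annotated).
#' @param knowledge gene knowledge table.
#' @param config [filter_config()].
#' @param ledger ledger to extend (default: a fresh one).
#' @return list with `records` (retained, with `stage_trail`), `discarded`
#'   (all stages, with `reason`), and `ledger`.
#' @export
run_pipeline_filter <- function(cohort, knowledge, config = filter_config(),
                                ledger = stage_ledger()) {
  records <- as.data.frame(cohort)
  if (is.null(records$stage_trail))
    records$stage_trail <- character(nrow(records))
  discarded_all <- list()

  # quality
  res <- quality_filter(records, config)
  res$retained <- .append_trail(res$retained, "quality")
  ledger <- ledger_add(ledger, "quality", nrow(records), nrow(res$retained),
                       reason_histogram(res$discarded$reason))
  discarded_all <- c(discarded_all, list(res$discarded))
  records <- res$retained

  # consequence
  res <- consequence_filter(records, config)
  res$retained <- .append_trail(res$retained, "consequence")
  ledger <- ledger_add(ledger, "consequence", nrow(records),
                       nrow(res$retained),
                       reason_histogram(res$discarded$reason))
  discarded_all <- c(discarded_all, list(res$discarded))
  records <- res$retained

  # frequency
  res <- frequency_filter(records, config)
  res$retained <- .append_trail(res$retained, "frequency")
  ledger <- ledger_add(ledger, "frequency", nrow(records), nrow(res$retained),
                       reason_histogram(res$discarded$reason))
  discarded_all <- c(discarded_all, list(res$discarded))
  records <- res$retained

  # predictor consensus: missense must pass; other allowed classes bypass
  is_mis <- records$consequence == "missense"
  keep <- !is_mis
  if (any(is_mis)) {
    cons <- predictor_consensus(records[is_mis, , drop = FALSE], config)
    keep[is_mis] <- cons$damaging
  }
  res <- .split_records(records, keep, "predictor_consensus")
  res$retained <- .append_trail(res$retained, "predictor_consensus")
  ledger <- ledger_add(ledger, "predictor_consensus", nrow(records),
                       nrow(res$retained),
                       reason_histogram(res$discarded$reason))
  discarded_all <- c(discarded_all, list(res$discarded))
  records <- res$retained

  # term match
  genes <- unique(records$gene_symbol)
  gene_ok <- vapply(genes, function(g)
    length(term_match(g, knowledge, config$term_list)) > 0L, logical(1))
  unknown <- setdiff(genes, knowledge$gene_symbol)
  if (length(unknown) > 0L)
    message("term_match: ", length(unknown),
            " gene(s) absent from the knowledge table")
  keep <- records$gene_symbol %in% genes[gene_ok]
  res <- .split_records(records, keep, "term_match")
  res$retained <- .append_trail(res$retained, "term_match")
  ledger <- ledger_add(ledger, "term_match", nrow(records),
                       nrow(res$retained),
                       reason_histogram(res$discarded$reason))
  discarded_all <- c(discarded_all, list(res$discarded))
  records <- res$retained

  viol <- validate_ledger(ledger)
  if (length(viol) > 0L)
    stop("ledger conservation violated:\n", paste(viol, collapse = "\n"))

  discarded <- do.call(rbind, discarded_all)
  rownames(records) <- NULL
  if (!is.null(discarded)) rownames(discarded) <- NULL
  list(records = .sort_germline_keep(records), discarded = discarded,
       ledger = ledger)
}

# sort helper preserving extra columns
.sort_germline_keep <- function(df) {
  df[order(df$patient_id, df$chrom, df$pos, df$ref, df$alt,
           method = "radix"), , drop = FALSE]
}
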