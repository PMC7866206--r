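# End-to-end orchestration on synthetic inputs: simulate -> filter ->
# prioritize -> prevalidate -> somatic profiling -> score -> report, with a
# single ledger across the germline stages and a hard stop on any ledger
# violation.

#' Default end-to-end configuration
#'
#' Study-shaped defaults: a 2 Mb single-chromosome reference with 60 genes, a
#' 20-patient cohort with 5,000 background variants per patient, 12 planted
#' causal variants (9 dominant, 3 recessive), one recurrent artifact in 6
#' patients and 2 repetitive-context decoys; nine tumors whose burden targets
#' mirror an ultra-hypermutated MMR-deficient sample, two hypermutated
#' samples and six low-burden clock-like samples. Tumor mutation counts are
#' derived as `round(tmb_target x capture megabases)`.
#'
#' @param seed integer master seed.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    reference = list(length_bp = 2e6, gc_fraction = 0.41, n_genes = 60L),
    knowledge = list(n_recessive = 5L, n_dominant = 12L, n_decoy = 20L),
    cohort = list(n_patients = 20L,
                  background_spec = default_background_spec(),
                  planted_spec = default_planted_spec()),
    filter = filter_config(),
    prioritization = prioritization_config(),
    prevalidation = prevalidation_config(),
    somatic = list(
      enabled = TRUE,
      decoys_per_caller = 25L,
      indel_fraction = 0.08,
      tumors = list(
        list(patient = "Pt11", tmb_target = 315.4,
             sbs_mixture = c(SBS1 = 0.10, SBS5 = 0.15, SBS15 = 0.45,
                             SBS21 = 0.30),
             id_mixture = c(ID1 = 0.3, ID2 = 0.3, ID7 = 0.4)),
        list(patient = "Pt03", tmb_target = 43.6,
             sbs_mixture = c(SBS1 = 0.3, SBS5 = 0.4, SBS19 = 0.3),
             id_mixture = c(ID1 = 0.6, ID2 = 0.4)),
        list(patient = "Pt05", tmb_target = 16.8,
             sbs_mixture = c(SBS1 = 0.35, SBS5 = 0.45, SBS19 = 0.2),
             id_mixture = c(ID1 = 0.6, ID2 = 0.4)),
        list(patient = "Pt01", tmb_target = 6.2,
             sbs_mixture = c(SBS1 = 0.5, SBS5 = 0.5),
             id_mixture = c(ID1 = 0.7, ID2 = 0.3)),
        list(patient = "Pt02", tmb_target = 5.1,
             sbs_mixture = c(SBS1 = 0.5, SBS5 = 0.5),
             id_mixture = c(ID1 = 0.7, ID2 = 0.3)),
        list(patient = "Pt04", tmb_target = 4.4,
             sbs_mixture = c(SBS1 = 0.5, SBS5 = 0.5),
             id_mixture = c(ID1 = 0.7, ID2 = 0.3)),
        list(patient = "Pt06", tmb_target = 3.8,
             sbs_mixture = c(SBS1 = 0.5, SBS5 = 0.5),
             id_mixture = c(ID1 = 0.7, ID2 = 0.3)),
        list(patient = "Pt09", tmb_target = 2.9,
             sbs_mixture = c(SBS1 = 0.5, SBS5 = 0.5),
             id_mixture = c(ID1 = 0.7, ID2 = 0.3)),
        list(patient = "Pt14", tmb_target = 2.4,
             sbs_mixture = c(SBS1 = 0.5, SBS5 = 0.5),
             id_mixture = c(ID1 = 0.7, ID2 = 0.3))
      )
    ),
    selection = selection_config()
  )
}

#' Run the whole pipeline on synthetic inputs
#'
#' Executes simulate, filter, prioritize, prevalidate, somatic profiling,
#' score and report. Idempotent for a fixed seed and configuration; any
#' ledger violation aborts with an error of class `gcgerm_ledger_violation`.
#'
#' @param config configuration list ([default_run_config()]).
#' @param out_dir report directory, or `NULL` to skip writing.
#' @param quiet suppress progress messages.
#' @return list with `candidates`, `ledger`, `tmb`, `exposures` (by
#'   patient), `manifest`, `knowledge`, `reference`, `region_mb`.
#' @export
run_all <- function(config = default_run_config(), out_dir = NULL,
                    quiet = FALSE) {
  say <- function(...) if (!quiet) message("[gcgerm] ", ...)
  with_seed(config$seed, {
    say("simulating reference (", config$reference$length_bp, " bp, ",
        config$reference$n_genes, " genes)")
    reference <- generate_reference(
      length_bp = config$reference$length_bp,
      gc_fraction = config$reference$gc_fraction,
      n_genes = config$reference$n_genes, seed = NULL)
    knowledge <- simulate_gene_knowledge(
      reference, n_recessive = config$knowledge$n_recessive,
      n_dominant = config$knowledge$n_dominant,
      n_decoy = config$knowledge$n_decoy, seed = NULL)

    say("simulating germline cohort (", config$cohort$n_patients,
        " patients)")
    sim <- generate_germline_cohort(
      reference, knowledge, n_patients = config$cohort$n_patients,
      background_spec = config$cohort$background_spec,
      planted_spec = config$cohort$planted_spec, seed = NULL)
    cohort <- sim$cohort
    manifest <- sim$manifest

    say("germline filter cascade on ", nrow(cohort), " records")
    filt <- run_pipeline_filter(cohort, knowledge, config$filter)
    say("prioritization (", nrow(filt$records), " records in)")
    prio <- prioritize(filt$records, knowledge,
                       n_patients = config$cohort$n_patients,
                       config = config$prioritization, ledger = filt$ledger)
    say("prevalidation (", nrow(prio$candidates), " candidates in)")
    prev <- prevalidate(prio$candidates, reference, reference$exons,
                        config = config$prevalidation, ledger = prio$ledger)
    ledger <- prev$ledger

    # ---- somatic profiling -------------------------------------------
    tmb <- NULL
    exposures <- list()
    region_mb <- region_megabases(reference$genes)
    if (isTRUE(config$somatic$enabled)) {
      sbs_cat <- synthetic_sbs96_catalog()
      id_cat <- synthetic_id83_catalog()
      ctx_index <- build_context_index(reference)
      tmb_rows <- list()
      for (spec in config$somatic$tumors) {
        n_total <- max(1L, round(spec$tmb_target * region_mb))
        n_ind <- round(config$somatic$indel_fraction * n_total)
        n_snv <- n_total - n_ind
        say("simulating tumor ", spec$patient, " (", n_total, " mutations)")
        tsim <- simulate_tumor_callsets(
          sample_id = spec$patient, reference = reference,
          sbs_mixture = spec$sbs_mixture, n_snvs = n_snv,
          id_mixture = spec$id_mixture, n_indels = n_ind,
          sbs_catalog = sbs_cat, id_catalog = id_cat,
          decoys_per_caller = config$somatic$decoys_per_caller,
          context_index = ctx_index, seed = NULL)
        panel <- default_caller_panel()
        cons <- consensus_merge(
          tsim$callsets[panel$snv], tsim$callsets[panel$indel],
          sample_id = spec$patient)
        tmb_rows[[spec$patient]] <- compute_tmb(cons, region_mb)
        snvs <- cons[cons$mut_class == "SNV", , drop = FALSE]
        indels <- cons[cons$mut_class != "SNV", , drop = FALSE]
        fits <- list()
        if (nrow(snvs) > 0L)
          fits$sbs <- refit_exposures(sbs96_matrix(snvs, reference),
                                      sbs_cat)[[1L]]
        if (nrow(indels) > 0L)
          fits$id <- refit_exposures(id83_matrix(indels, reference),
                                     id_cat)[[1L]]
        exposures[[spec$patient]] <- fits
      }
      tmb <- do.call(rbind, tmb_rows)
      rownames(tmb) <- NULL
    }

    say("scoring ", nrow(prev$passed), " prevalidated candidates")
    candidates <- score_candidates(prev$passed, exposures, knowledge,
                                   config$selection)

    viol <- validate_ledger(ledger)
    if (length(viol) > 0L)
      stop(structure(class = c("gcgerm_ledger_violation", "error",
                               "condition"),
                     list(message = paste("ledger violation:",
                                          paste(viol, collapse = "; ")),
                          call = sys.call())))

    if (!is.null(out_dir)) {
      say("writing report to ", out_dir)
      write_report(candidates, ledger, tmb, exposures, out_dir)
    }
    list(candidates = candidates, ledger = ledger, tmb = tmb,
         exposures = exposures, manifest = manifest, knowledge = knowledge,
         reference = reference, region_mb = region_mb)
  })
}
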