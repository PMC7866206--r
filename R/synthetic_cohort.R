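# Seeded synthetic germline cohort with a ground-truth manifest. Background
# variants are constructed to fail exactly one designated cascade stage;
# planted causal variants are rare, damaging-by-consensus, on qualifying
# genes, with genotypes matching their inheritance model; one recurrent
# artifact exercises the cohort recurrence exclusion; optional decoys inside
# planted exonic homopolymer tracts exercise prevalidation.

#' Simulate a gene knowledge table for a synthetic reference
#'
#' Assigns gene roles: recessive-qualifying cancer genes (pathogen
#' recognition / innate immunity), dominant-qualifying cancer genes (always
#' including at least one DNA-repair gene, for tumor-concordance scenarios),
#' non-cancer decoy genes whose terms match the selection list (they survive
#' the automated filter and die at the cancer-gene step), and genes with no
#' matching terms. Genes containing exonic homopolymer tracts are placed in
#' the dominant group so repetitive-context decoys can be planted on
#' qualifying genes.
#'
#' @param reference [generate_reference()] output.
#' @param n_recessive,n_dominant,n_decoy group sizes; remaining genes get no
#'   matching terms.
#' @param seed integer seed (`NULL`: current stream).
#' @return gene knowledge data frame (as from [read_gene_knowledge()]) with a
#'   `role` column.
#' @export
simulate_gene_knowledge <- function(reference, n_recessive = 5L,
                                    n_dominant = 12L, n_decoy = 20L,
                                    seed = NULL) {
  genes <- reference$genes$name
  n <- length(genes)
  if (n_recessive + n_dominant + n_decoy > n)
    stop("gene groups exceed the number of genes")
  with_seed(seed, {
    # genes carrying an exonic homopolymer tract go to the dominant group
    hp_genes <- character(0)
    if (length(reference$homopolymers) > 0L) {
      ov <- GenomicRanges::findOverlaps(reference$homopolymers,
                                        reference$exons)
      hp_genes <- unique(reference$exons$gene[S4Vectors::subjectHits(ov)])
    }
    dominant <- head(hp_genes, n_dominant)
    pool <- setdiff(genes, dominant)
    dominant <- c(dominant, sample(pool, n_dominant - length(dominant)))
    pool <- setdiff(pool, dominant)
    recessive <- sample(pool, n_recessive)
    pool <- setdiff(pool, recessive)
    decoy <- sample(pool, n_decoy)
    none <- setdiff(pool, decoy)

    dom_cat_sets <- list(c("dna_repair"),
                         c("tumor_suppression", "cell_adhesion"),
                         c("gc_development"),
                         c("stomach_function", "gastric_acid_secretion"),
                         c("apoptosis", "tumor_suppression"),
                         c("gut_epithelial_protection"),
                         c("alcohol_metabolism"),
                         c("cell_adhesion"))
    role <- setNames(rep("none", n), genes)
    role[recessive] <- "recessive"
    role[dominant] <- "dominant"
    role[decoy] <- "decoy"
    cats <- setNames(vector("list", n), genes)
    terms <- setNames(vector("list", n), genes)
    for (g in recessive) {
      cats[[g]] <- c("pathogen_recognition", "innate_immunity")
      terms[[g]] <- c("pathogen recognition", "helicobacter pylori")
    }
    # first dominant gene is guaranteed DNA repair
    for (i in seq_along(dominant)) {
      g <- dominant[i]
      cats[[g]] <- dom_cat_sets[[(i - 1L) %% length(dom_cat_sets) + 1L]]
      terms[[g]] <- gsub("_", " ", cats[[g]], fixed = TRUE)
    }
    for (g in decoy) {
      cats[[g]] <- sample(c("cell_adhesion", "apoptosis", "dna_repair"), 1L)
      terms[[g]] <- gsub("_", " ", cats[[g]], fixed = TRUE)
    }
    for (g in none) {
      cats[[g]] <- character(0)
      terms[[g]] <- sample(c("ribosome biogenesis", "axon guidance",
                             "photoreceptor maintenance"), 1L)
    }
    out <- data.frame(gene_symbol = genes,
                      is_cancer_predisposition =
                        genes %in% c(recessive, dominant),
                      stringsAsFactors = FALSE)
    out$function_categories <- unname(cats[genes])
    out$terms <- unname(terms[genes])
    out$role <- unname(role[genes])
    out
  })
}

.benign_profile <- function(n) {
  data.frame(sift_score = runif(n, 0.3, 0.95),
             polyphen2_score = runif(n, 0, 0.2),
             cadd_phred = runif(n, 0, 8),
             phylop = runif(n, -2, 1),
             mutation_taster = sample(c("N", "P"), n, replace = TRUE),
             lrt = sample(c("N", "U"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

.damaging_profile <- function(n) {
  data.frame(sift_score = runif(n, 0, 0.02),
             polyphen2_score = runif(n, 0.9, 1),
             cadd_phred = runif(n, 25, 35),
             phylop = runif(n, 2.5, 6),
             mutation_taster = sample(c("A", "D"), n, replace = TRUE),
             lrt = rep("D", n),
             stringsAsFactors = FALSE)
}

.na_profile <- function(n) {
  data.frame(sift_score = rep(NA_real_, n),
             polyphen2_score = rep(NA_real_, n),
             cadd_phred = rep(NA_real_, n),
             phylop = rep(NA_real_, n),
             mutation_taster = rep(NA_character_, n),
             lrt = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

# good read support: depth, alt reads, quality; het VAF well inside [0.2,0.8]
.good_support <- function(n, genotype) {
  dp <- sample(40:90, n, replace = TRUE)
  ad <- integer(n)
  het <- genotype == "heterozygous"
  if (any(het)) {
    ad[het] <- rbinom(sum(het), dp[het], 0.5)
    lo <- ceiling(0.3 * dp[het]); hi <- floor(0.7 * dp[het])
    ad[het] <- pmin(pmax(ad[het], lo), hi)
  }
  if (any(!het)) {
    ad[!het] <- dp[!het] - rbinom(sum(!het), dp[!het], 0.02)
    ad[!het] <- pmax(ad[!het], ceiling(0.9 * dp[!het]))
  }
  data.frame(total_depth = dp, alt_depth = ad,
             call_quality = round(runif(n, 60, 1500), 2))
}

# ref base and a random different alt base at each position
.snv_at <- function(chrom_string, pos) {
  refb <- substring(chrom_string, pos, pos)
  alt <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
    USE.NAMES = FALSE)
  list(ref = refb, alt = alt)
}

# sample a clean exonic SNV position on one gene (homopolymer run <= max_run)
.clean_exon_pos <- function(reference, gene, n = 1L, max_run = 4L) {
  ex <- reference$exons[reference$exons$gene == gene]
  pool <- unlist(lapply(seq_along(ex), function(i)
    (GenomicRanges::start(ex)[i] + 1L):(GenomicRanges::end(ex)[i] - 1L)))
  out <- integer(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 500L) stop("cannot find clean exonic position on ", gene)
    p <- sample(pool, 1L)
    if (homopolymer_run(reference, "chr1", p, "N", "N") <= max_run &&
        !(p %in% out))
      out <- c(out, p)
  }
  out
}

#' Default background composition of the synthetic cohort
#'
#' Each class is constructed to fail exactly one cascade stage (quality,
#' consequence, frequency, predictor consensus, or term match), so every
#' per-stage discard count is analytically known. 5,000 variants per patient
#' by default.
#'
#' @return named integer vector of per-patient class sizes.
#' @export
default_background_spec <- function() {
  c(n_quality_fail = 600L, n_consequence_fail = 1600L,
    n_frequency_fail = 1600L, n_consensus_fail = 900L, n_term_fail = 300L)
}

#' Default planted-truth composition
#'
#' @return list with dominant/recessive planted counts, recurrent-artifact
#'   carrier count and homopolymer-decoy count.
#' @export
default_planted_spec <- function() {
  list(n_dominant = 9L, n_recessive = 3L, recurrent_carriers = 6L,
       n_homopolymer_decoys = 2L)
}

#' Generate an annotated synthetic germline cohort with ground truth
#'
#' Background records are placed at unique per-patient positions inside gene
#' spans (classes sized exactly as specified); planted causal variants sit at
#' clean exonic positions with strong read support; the recurrent artifact is
#' an identical damaging variant shared by the configured number of patients.
#'
#' @param reference [generate_reference()] output.
#' @param knowledge [simulate_gene_knowledge()] output (must carry the
#'   `role` column; planted variants require qualifying genes).
#' @param n_patients cohort size (default 20).
#' @param background_spec named vector of per-patient background class sizes
#'   ([default_background_spec()]).
#' @param planted_spec list from [default_planted_spec()].
#' @param seed integer seed (`NULL`: current stream).
#' @return list with `cohort` (germline records data frame) and `manifest`
#'   (class `truth_manifest`).
#' @export
generate_germline_cohort <- function(reference, knowledge, n_patients = 20L,
                                     background_spec = default_background_spec(),
                                     planted_spec = default_planted_spec(),
                                     seed = NULL) {
  stopifnot(n_patients >= 1L)
  if (is.null(knowledge$role))
    stop("knowledge must come from simulate_gene_knowledge (role column)")
  rec_genes <- knowledge$gene_symbol[knowledge$role == "recessive"]
  dom_genes <- knowledge$gene_symbol[knowledge$role == "dominant"]
  none_genes <- knowledge$gene_symbol[knowledge$role == "none"]
  if (planted_spec$n_recessive > 0L && length(rec_genes) == 0L)
    stop("no recessive-qualifying genes in knowledge")
  if ((planted_spec$n_dominant > 0L || planted_spec$recurrent_carriers > 0L) &&
      length(dom_genes) == 0L)
    stop("no dominant-qualifying genes in knowledge")
  if (background_spec[["n_term_fail"]] > 0L && length(none_genes) == 0L)
    stop("no term-free genes for the term-fail background class")

  with_seed(seed, {
    pids <- sprintf("Pt%02d", seq_len(n_patients))
    ages <- sample(26:50, n_patients, replace = TRUE)
    chrom_string <- as.character(reference$sequence[[1]])
    genes_gr <- reference$genes
    gene_ids <- genes_gr$name
    g_start <- GenomicRanges::start(genes_gr)
    g_end <- GenomicRanges::end(genes_gr)
    # genes are ordered and non-overlapping: map position -> containing gene
    gene_of_pos <- function(pos) {
      i <- findInterval(pos, g_start)
      gene_ids[i]
    }
    pool_all <- unlist(lapply(seq_along(gene_ids), function(i)
      g_start[i]:g_end[i]))
    none_idx <- which(gene_ids %in% none_genes)
    pool_none <- unlist(lapply(none_idx, function(i) g_start[i]:g_end[i]))

    # ---- planted causal variants -------------------------------------
    n_pl <- planted_spec$n_dominant + planted_spec$n_recessive
    planted <- NULL
    if (n_pl > 0L) {
      carriers <- sample(pids, min(n_pl, n_patients))
      if (length(carriers) < n_pl)
        carriers <- c(carriers, sample(pids, n_pl - length(carriers),
                                       replace = TRUE))
      dom_csq <- rep(c("missense", "nonsense", "frameshift", "splice_site"),
                     length.out = planted_spec$n_dominant)
      pl_gene <- c(sample(dom_genes, planted_spec$n_dominant, replace =
                            length(dom_genes) < planted_spec$n_dominant),
                   sample(rec_genes, planted_spec$n_recessive, replace =
                            length(rec_genes) < planted_spec$n_recessive))
      pl_model <- c(rep("dominant", planted_spec$n_dominant),
                    rep("recessive", planted_spec$n_recessive))
      pl_csq <- c(dom_csq, rep("missense", planted_spec$n_recessive))
      rows <- vector("list", n_pl)
      for (i in seq_len(n_pl)) {
        g <- pl_gene[i]
        p <- .clean_exon_pos(reference, g, 1L)
        genotype <- if (pl_model[i] == "recessive") "homozygous_alt"
        else "heterozygous"
        if (pl_csq[i] == "frameshift") {
          refa <- substring(chrom_string, p, p + 1L)   # 1-bp anchored deletion
          alta <- substr(refa, 1L, 1L)
        } else {
          al <- .snv_at(chrom_string, p)
          refa <- al$ref; alta <- al$alt
        }
        prof <- if (pl_csq[i] == "missense") .damaging_profile(1L)
        else .na_profile(1L)
        sup <- .good_support(1L, genotype)
        rows[[i]] <- data.frame(
          patient_id = carriers[i], chrom = "chr1", pos = p, ref = refa,
          alt = alta, genotype = genotype, sup, gene_symbol = g,
          consequence = pl_csq[i],
          max_pop_af = if (runif(1) < 0.5) NA_real_ else runif(1, 0, 0.002),
          prof, truth_class = "planted", stringsAsFactors = FALSE)
      }
      planted <- do.call(rbind, rows)
    }

    # ---- recurrent artifact ------------------------------------------
    artifact <- NULL
    if (planted_spec$recurrent_carriers > 0L) {
      g <- sample(dom_genes, 1L)
      p <- .clean_exon_pos(reference, g, 1L)
      al <- .snv_at(chrom_string, p)
      who <- sample(pids, planted_spec$recurrent_carriers)
      sup <- .good_support(length(who), rep("heterozygous", length(who)))
      artifact <- data.frame(
        patient_id = who, chrom = "chr1", pos = p, ref = al$ref,
        alt = al$alt, genotype = "heterozygous", sup, gene_symbol = g,
        consequence = "missense", max_pop_af = NA_real_,
        .damaging_profile(length(who)), truth_class = "artifact",
        stringsAsFactors = FALSE)
    }

    # ---- homopolymer decoys ------------------------------------------
    decoys <- NULL
    n_hd <- planted_spec$n_homopolymer_decoys
    if (n_hd > 0L) {
      ov <- GenomicRanges::findOverlaps(reference$homopolymers,
                                        reference$exons)
      tr_i <- S4Vectors::queryHits(ov)
      tr_gene <- reference$exons$gene[S4Vectors::subjectHits(ov)]
      ok <- tr_gene %in% dom_genes
      if (sum(ok) == 0L) {
        warning("no exonic homopolymer tract on a dominant gene; ",
                "no decoys planted")
        n_hd <- 0L
      } else {
        pick <- sample(rep(which(ok), 2L), n_hd)
        who <- sample(pids, n_hd, replace = n_hd > n_patients)
        rows <- list()
        for (j in seq_len(n_hd)) {
          t <- reference$homopolymers[tr_i[pick[j]]]
          p <- GenomicRanges::start(t) + 2L
          al <- .snv_at(chrom_string, p)
          sup <- .good_support(1L, "heterozygous")
          rows[[j]] <- data.frame(
            patient_id = who[j], chrom = "chr1", pos = p, ref = al$ref,
            alt = al$alt, genotype = "heterozygous", sup,
            gene_symbol = tr_gene[pick[j]], consequence = "missense",
            max_pop_af = NA_real_, .damaging_profile(1L),
            truth_class = "homopolymer_decoy", stringsAsFactors = FALSE)
        }
        decoys <- do.call(rbind, rows)
        decoys <- decoys[!duplicated(paste(decoys$patient_id, decoys$pos)), ,
                         drop = FALSE]
      }
    }

    special <- rbind(planted, artifact, decoys)

    # ---- background ---------------------------------------------------
    bg_rows <- vector("list", n_patients)
    for (pi in seq_len(n_patients)) {
      counts <- background_spec
      n_bg <- sum(counts)
      if (n_bg == 0L) next
      special_p <- if (is.null(special)) integer(0)
      else special$pos[special$patient_id == pids[pi]]
      n_term <- counts[["n_term_fail"]]
      pos_term <- if (n_term > 0L)
        sample(setdiff(pool_none, special_p), n_term) else integer(0)
      pos_rest <- sample(setdiff(pool_all, c(special_p, pos_term)),
                         n_bg - n_term)
      cls <- rep(setdiff(names(counts), "n_term_fail"),
                 counts[setdiff(names(counts), "n_term_fail")])
      pos <- c(pos_rest, pos_term)
      cls <- c(cls, rep("n_term_fail", n_term))
      gene <- gene_of_pos(pos)
      al <- .snv_at(chrom_string, pos)
      genotype <- sample(c("heterozygous", "homozygous_alt"), n_bg,
                         replace = TRUE, prob = c(0.9, 0.1))
      sup <- .good_support(n_bg, genotype)
      consequence <- rep("missense", n_bg)
      af <- runif(n_bg, 0, 0.004)
      af[runif(n_bg) < 0.3] <- NA
      prof <- .damaging_profile(n_bg)

      qf <- cls == "n_quality_fail"
      if (any(qf)) {
        mode <- sample(c("dp", "alt", "qual"), sum(qf), replace = TRUE)
        i <- which(qf)
        dp_i <- i[mode == "dp"]
        sup$total_depth[dp_i] <- sample(3:9, length(dp_i), replace = TRUE)
        sup$alt_depth[dp_i] <- pmax(1L, sup$total_depth[dp_i] - 2L)
        alt_i <- i[mode == "alt"]
        sup$alt_depth[alt_i] <- sample(0:3, length(alt_i), replace = TRUE)
        qual_i <- i[mode == "qual"]
        sup$call_quality[qual_i] <- round(runif(length(qual_i), 1, 29), 2)
        consequence[qf] <- sample(c("missense", "synonymous", "nonsense"),
                                  sum(qf), replace = TRUE)
      }
      cf <- cls == "n_consequence_fail"
      consequence[cf] <- sample(c("synonymous", "other"), sum(cf),
                                replace = TRUE, prob = c(0.8, 0.2))
      ff <- cls == "n_frequency_fail"
      af[ff] <- runif(sum(ff), 0.05, 0.5)
      bf <- cls == "n_consensus_fail"
      if (any(bf)) prof[bf, ] <- .benign_profile(sum(bf))
      # term-fail: damaging rare missense on term-free genes (already set)

      bg_rows[[pi]] <- data.frame(
        patient_id = pids[pi], chrom = "chr1", pos = pos, ref = al$ref,
        alt = al$alt, genotype = genotype, sup, gene_symbol = gene,
        consequence = consequence, max_pop_af = af, prof,
        truth_class = cls, stringsAsFactors = FALSE)
    }
    bg <- do.call(rbind, bg_rows)

    cohort <- rbind(bg, special)
    truth_class <- cohort$truth_class
    cohort$truth_class <- NULL
    cohort <- cohort[, .germline_cols]
    ord <- order(cohort$patient_id, cohort$chrom, cohort$pos, cohort$ref,
                 cohort$alt, method = "radix")
    cohort <- cohort[ord, , drop = FALSE]
    truth_class <- truth_class[ord]
    rownames(cohort) <- NULL
    .validate_germline(cohort)

    key_cols <- c("patient_id", "chrom", "pos", "ref", "alt", "gene_symbol",
                  "genotype", "consequence")
    manifest <- structure(list(
      seed = seed,
      n_patients = n_patients,
      patients = data.frame(patient_id = pids, age_at_diagnosis = ages,
                            stringsAsFactors = FALSE),
      inclusion_age_bound = 51L,
      planted_germline = if (is.null(planted)) NULL else
        cbind(planted[, key_cols],
              inheritance_model = pl_model,
              category = vapply(pl_gene, function(g)
                paste(knowledge_categories(knowledge, g), collapse = ","),
                character(1))),
      artifact = if (is.null(artifact)) NULL else
        list(key = artifact[1L, c("chrom", "pos", "ref", "alt")],
             carriers = artifact$patient_id),
      homopolymer_decoys = if (is.null(decoys)) NULL else decoys[, key_cols],
      background_counts = {
        bgc <- table(factor(truth_class[truth_class %in%
                                          names(background_spec)],
                            levels = names(background_spec)))
        setNames(as.integer(bgc), names(bgc))
      },
      truth_class = truth_class
    ), class = "truth_manifest")
    list(cohort = cohort, manifest = manifest)
  })
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat("truth_manifest:", x$n_patients, "patients;",
      if (is.null(x$planted_germline)) 0L else nrow(x$planted_germline),
      "planted causal variant(s);",
      if (!is.null(x$artifact)) paste0("artifact in ",
                                       length(x$artifact$carriers),
                                       " patient(s); ") else "",
      sum(x$background_counts), "background records/patient design\n")
  invisible(x)
}
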