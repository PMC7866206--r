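# Shared fixtures (built once per test run) and independent brute-force
# oracles used to cross-check the vectorized implementations.

.fx <- new.env(parent = emptyenv())

fixture_reference <- function() {
  if (is.null(.fx$ref))
    .fx$ref <- generate_reference(1e5, 0.41, 12L, seed = 101,
                                  gene_bp_range = c(4000L, 7000L))
  .fx$ref
}

fixture_knowledge <- function() {
  if (is.null(.fx$kn))
    .fx$kn <- simulate_gene_knowledge(fixture_reference(), n_recessive = 3L,
                                      n_dominant = 5L, n_decoy = 3L,
                                      seed = 102)
  .fx$kn
}

# one germline record with sensible defaults: rare damaging missense with
# strong support on a heterozygous genotype
make_record <- function(patient_id = "Pt01", chrom = "chr1", pos = 1000L,
                        ref = "C", alt = "T", genotype = "heterozygous",
                        total_depth = 60L, alt_depth = 28L,
                        call_quality = 200, gene_symbol = "G1",
                        consequence = "missense", max_pop_af = NA_real_,
                        sift_score = 0.01, polyphen2_score = 0.95,
                        cadd_phred = 28, phylop = 3.5,
                        mutation_taster = "D", lrt = "D") {
  data.frame(patient_id = patient_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, genotype = genotype,
             total_depth = as.integer(total_depth),
             alt_depth = as.integer(alt_depth), call_quality = call_quality,
             gene_symbol = gene_symbol, consequence = consequence,
             max_pop_af = max_pop_af, sift_score = sift_score,
             polyphen2_score = polyphen2_score, cadd_phred = cadd_phred,
             phylop = phylop, mutation_taster = mutation_taster, lrt = lrt,
             stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

# a small knowledge table built by hand
make_knowledge <- function(genes, cancer, cats, terms) {
  out <- data.frame(gene_symbol = genes, is_cancer_predisposition = cancer,
                    stringsAsFactors = FALSE)
  out$function_categories <- cats
  out$terms <- terms
  out
}

# --- independent oracle: the five filter predicates composed in order -----
# (record-by-record if-chains with the default predictor cutoffs hardcoded)
oracle_filter_pass <- function(records, knowledge, config = filter_config()) {
  pass <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (is.na(r$total_depth) || r$total_depth < config$min_depth) next
    if (is.na(r$alt_depth) || r$alt_depth < config$min_alt_reads) next
    if (is.na(r$call_quality) || r$call_quality < config$min_quality) next
    if (!(r$consequence %in% config$allowed_consequences)) next
    if (!is.na(r$max_pop_af) && r$max_pop_af >= config$max_pop_af) next
    if (r$consequence == "missense") {
      votes <- 0L; tot <- 0L
      if (!is.na(r$sift_score)) { tot <- tot + 1L
        if (r$sift_score < 0.05) votes <- votes + 1L }
      if (!is.na(r$polyphen2_score)) { tot <- tot + 1L
        if (r$polyphen2_score >= 0.446) votes <- votes + 1L }
      if (!is.na(r$cadd_phred)) { tot <- tot + 1L
        if (r$cadd_phred >= 20) votes <- votes + 1L }
      if (!is.na(r$phylop)) { tot <- tot + 1L
        if (r$phylop >= 2.0) votes <- votes + 1L }
      if (!is.na(r$mutation_taster)) { tot <- tot + 1L
        if (r$mutation_taster %in% c("A", "D")) votes <- votes + 1L }
      if (!is.na(r$lrt)) { tot <- tot + 1L
        if (r$lrt == "D") votes <- votes + 1L }
      if (tot == 0L || votes / tot < config$consensus_fraction) next
    }
    k <- which(knowledge$gene_symbol == r$gene_symbol)
    if (length(k) == 0L) next
    toks <- tolower(gsub("_", " ", c(knowledge$terms[[k]],
                                     knowledge$function_categories[[k]])))
    if (!any(tolower(gsub("_", " ", config$term_list)) %in% toks)) next
    pass[i] <- TRUE
  }
  pass
}

# --- independent oracle: prioritization predicates ------------------------
oracle_prioritize_keep <- function(records, knowledge,
                                   n_patients,
                                   config = prioritization_config()) {
  keep <- logical(nrow(records))
  eff_cats <- function(g) {
    k <- which(knowledge$gene_symbol == g)
    if (length(k) == 0L) return(character(0))
    cc <- knowledge$function_categories[[k]]
    if (knowledge$is_cancer_predisposition[k])
      cc <- c("is_cancer_predisposition", cc)
    cc
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (config$restrict_to_cancer_genes) {
      k <- which(knowledge$gene_symbol == r$gene_symbol)
      if (length(k) == 0L || !knowledge$is_cancer_predisposition[k]) next
    }
    cc <- eff_cats(r$gene_symbol)
    ok <- if (r$genotype == "homozygous_alt")
      length(intersect(cc, config$recessive_required_categories)) > 0L
    else
      length(intersect(cc, config$dominant_required_categories)) > 0L
    if (!ok) next
    keep[i] <- TRUE
  }
  # recurrence on the kept set
  keys <- paste(records$chrom, records$pos, records$ref, records$alt)
  for (key in unique(keys[keep])) {
    sel <- keep & keys == key
    carriers <- length(unique(records$patient_id[sel]))
    if (carriers / n_patients > config$max_recurrence_fraction)
      keep[sel] <- FALSE
  }
  keep
}

# --- independent oracle: consensus merge ----------------------------------
oracle_consensus <- function(snv_sets, indel_sets, min_snv = 2L,
                             min_indel = 2L) {
  tally <- function(sets, want_snv) {
    keys <- list()
    for (nm in names(sets)) {
      cs <- sets[[nm]]
      if (nrow(cs) == 0L) next
      snv <- nchar(cs$ref) == 1L & nchar(cs$alt) == 1L
      cs <- cs[if (want_snv) snv else !snv, , drop = FALSE]
      keys[[nm]] <- unique(paste(cs$chrom, cs$pos, cs$ref, cs$alt))
    }
    all_keys <- unique(unlist(keys))
    cnt <- vapply(all_keys, function(k)
      sum(vapply(keys, function(kk) k %in% kk, logical(1))), integer(1))
    names(cnt) <- all_keys
    cnt
  }
  snv_cnt <- tally(snv_sets, TRUE)
  ind_cnt <- tally(indel_sets, FALSE)
  sort(c(names(snv_cnt)[snv_cnt >= min_snv],
         names(ind_cnt)[ind_cnt >= min_indel]))
}

# --- naive homopolymer scanner (full-sequence character walk) -------------
naive_homopolymer <- function(chrom_string, pos, ref_len = 1L) {
  chars <- strsplit(chrom_string, "", fixed = TRUE)[[1]]
  L <- length(chars)
  lo <- max(1L, pos - 1L)
  hi <- min(L, pos + ref_len - 1L + 1L)
  best <- 0L
  for (p in lo:hi) {
    b <- chars[p]
    a <- p; z <- p
    while (a > 1L && chars[a - 1L] == b) a <- a - 1L
    while (z < L && chars[z + 1L] == b) z <- z + 1L
    best <- max(best, z - a + 1L)
  }
  best
}

# random small per-caller callsets for consensus-oracle tests
.rand_callsets <- function(seed, n_callers = 4L, max_var = 60L) {
  set.seed(seed)
  keys <- data.frame(chrom = "chr1", pos = sample(1:300, max_var),
                     stringsAsFactors = FALSE)
  keys$ref <- sample(c("A", "C", "G", "T"), max_var, replace = TRUE)
  is_ind <- runif(max_var) < 0.3
  keys$alt <- ifelse(is_ind, paste0(keys$ref, "A"),
                     vapply(keys$ref, function(b)
                       sample(setdiff(c("A", "C", "G", "T"), b), 1),
                       character(1)))
  lapply(setNames(seq_len(n_callers), paste0("caller", seq_len(n_callers))),
         function(i) keys[runif(max_var) < 0.5, , drop = FALSE])
}

# random small cohort over the fixture genes for oracle-equivalence tests
random_cohort <- function(n, seed, knowledge = fixture_knowledge()) {
  set.seed(seed)
  genes <- c(knowledge$gene_symbol, "UNKNOWN1")
  consequences <- consequence_classes()
  df <- data.frame(
    patient_id = sample(sprintf("Pt%02d", 1:6), n, replace = TRUE),
    chrom = "chr1",
    pos = sample(1000:2000, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = NA_character_,
    genotype = sample(c("heterozygous", "homozygous_alt"), n, replace = TRUE,
                      prob = c(0.8, 0.2)),
    total_depth = sample(c(5L, 15L, 60L), n, replace = TRUE,
                         prob = c(0.15, 0.25, 0.6)),
    alt_depth = NA_integer_,
    call_quality = sample(c(10, 40, 500), n, replace = TRUE,
                          prob = c(0.15, 0.25, 0.6)),
    gene_symbol = sample(genes, n, replace = TRUE),
    consequence = sample(consequences, n, replace = TRUE),
    max_pop_af = ifelse(runif(n) < 0.3, NA_real_,
                        sample(c(0.0005, 0.005, 0.2), n, replace = TRUE)),
    sift_score = ifelse(runif(n) < 0.3, NA_real_, runif(n)),
    polyphen2_score = ifelse(runif(n) < 0.3, NA_real_, runif(n)),
    cadd_phred = ifelse(runif(n) < 0.3, NA_real_, runif(n, 0, 40)),
    phylop = ifelse(runif(n) < 0.3, NA_real_, runif(n, -3, 7)),
    mutation_taster = ifelse(runif(n) < 0.3, NA_character_,
                             sample(c("A", "D", "N", "P"), n,
                                    replace = TRUE)),
    lrt = ifelse(runif(n) < 0.3, NA_character_,
                 sample(c("D", "N", "U"), n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  df$alt <- vapply(df$ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
    USE.NAMES = FALSE)
  df$alt_depth <- pmin(df$total_depth,
                       sample(c(2L, 6L, 30L), n, replace = TRUE))
  df
}
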