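# Gene-knowledge tables and COSMIC-layout signature catalogs.

#' Closed vocabulary of gene function categories
#'
#' The category scheme used for inheritance-model gene criteria and candidate
#' scoring: tumor suppression, DNA repair, apoptosis, pathogen recognition,
#' innate immunity activation, gut epithelial protection, cell adhesion, the
#' gastric-cancer risk-factor functions (alcohol metabolism, gastric acid
#' secretion), stomach function and gastric cancer development.
#'
#' @return character vector of valid category tokens.
#' @export
gene_function_categories <- function() {
  c("tumor_suppression", "dna_repair", "apoptosis", "pathogen_recognition",
    "innate_immunity", "gut_epithelial_protection", "cell_adhesion",
    "alcohol_metabolism", "gastric_acid_secretion", "stomach_function",
    "gc_development")
}

#' Read a gene knowledge table
#'
#' Tab-separated with header columns `gene_symbol`,
#' `is_cancer_predisposition` (0/1), `function_categories` (comma-joined
#' subset of [gene_function_categories()]; may be empty) and `terms`
#' (semicolon-joined free-text term list; may be empty).
#'
#' @param path TSV path.
#' @return data frame keyed by gene symbol with list-columns
#'   `function_categories` and `terms`.
#' @export
read_gene_knowledge <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_symbol", "is_cancer_predisposition", "function_categories",
            "terms")
  if (!all(need %in% names(df)))
    stop("gene knowledge table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  dup <- duplicated(df$gene_symbol)
  if (any(dup))
    stop("duplicate gene symbol(s): ",
         paste(unique(df$gene_symbol[dup]), collapse = ", "))
  cats <- strsplit(df$function_categories, ",", fixed = TRUE)
  cats <- lapply(cats, function(x) trimws(x[nzchar(trimws(x))]))
  vocab <- gene_function_categories()
  for (i in seq_along(cats)) {
    bad <- setdiff(cats[[i]], vocab)
    if (length(bad) > 0L)
      stop("unknown function category \"", bad[1L], "\" on line ", i + 1L,
           " (gene ", df$gene_symbol[i], ")")
  }
  terms <- strsplit(df$terms, ";", fixed = TRUE)
  terms <- lapply(terms, function(x) trimws(x[nzchar(trimws(x))]))
  flag <- df$is_cancer_predisposition
  if (!all(flag %in% c("0", "1", "TRUE", "FALSE")))
    stop("is_cancer_predisposition must be 0/1")
  out <- data.frame(gene_symbol = df$gene_symbol,
                    is_cancer_predisposition = flag %in% c("1", "TRUE"),
                    stringsAsFactors = FALSE)
  out$function_categories <- cats
  out$terms <- terms
  out
}

#' Write a gene knowledge table
#'
#' @param knowledge knowledge data frame as returned by
#'   [read_gene_knowledge()].
#' @param path output TSV path.
#' @export
write_gene_knowledge <- function(knowledge, path) {
  df <- data.frame(
    gene_symbol = knowledge$gene_symbol,
    is_cancer_predisposition = as.integer(knowledge$is_cancer_predisposition),
    function_categories = vapply(knowledge$function_categories, paste,
                                 character(1), collapse = ","),
    terms = vapply(knowledge$terms, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# effective categories of one gene: function categories plus the pseudo
# category "is_cancer_predisposition" when flagged; empty for unknown genes
knowledge_categories <- function(knowledge, gene) {
  i <- match(gene, knowledge$gene_symbol)
  if (is.na(i)) return(character(0))
  cats <- knowledge$function_categories[[i]]
  if (knowledge$is_cancer_predisposition[i])
    cats <- c("is_cancer_predisposition", cats)
  cats
}

# ---- signature catalogs -----------------------------------------------------

#' Construct a signature catalog
#'
#' @param probabilities channels x signatures matrix; rownames are channel
#'   labels matching the SBS-96 or ID-83 canonical set, colnames are signature
#'   identifiers. Columns must sum to 1 within `tol` and are renormalized
#'   exactly.
#' @param aetiology named character vector of per-signature aetiology tags
#'   (e.g. `mmr_deficiency`, `clock_like`); missing signatures get
#'   `"unknown"`.
#' @param tol column-sum tolerance (default 1e-4).
#' @return object of class `signature_catalog` with fields `channel_set`,
#'   `channels`, `signatures`, `probabilities`, `aetiology`.
#' @export
signature_catalog <- function(probabilities, aetiology = NULL, tol = 1e-4) {
  stopifnot(is.matrix(probabilities))
  if (any(probabilities < 0))
    stop("signature probabilities must be non-negative")
  chan <- rownames(probabilities)
  if (nrow(probabilities) == 96L && setequal(chan, sbs96_channels())) {
    set <- "SBS96"; canon <- sbs96_channels()
  } else if (nrow(probabilities) == 83L && setequal(chan, id83_channels())) {
    set <- "ID83"; canon <- id83_channels()
  } else {
    stop("expected 96 SBS or 83 ID channel rows with canonical labels, got ",
         nrow(probabilities), " rows")
  }
  probabilities <- probabilities[canon, , drop = FALSE]
  cs <- colSums(probabilities)
  off <- abs(cs - 1) > tol
  if (any(off))
    stop("signature column(s) do not sum to 1 within ", tol, ": ",
         paste(colnames(probabilities)[off], collapse = ", "))
  probabilities <- sweep(probabilities, 2L, cs, "/")
  sigs <- colnames(probabilities)
  aet <- setNames(rep("unknown", length(sigs)), sigs)
  if (!is.null(aetiology)) {
    known <- intersect(names(aetiology), sigs)
    aet[known] <- aetiology[known]
  }
  structure(list(channel_set = set, channels = canon, signatures = sigs,
                 probabilities = probabilities, aetiology = aet),
            class = "signature_catalog")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("signature_catalog:", x$channel_set, "|", length(x$signatures),
      "signatures:", paste(x$signatures, collapse = ", "), "\n")
  invisible(x)
}

#' Read a signature catalog in COSMIC matrix layout
#'
#' First column (`Type` or `MutationType`) holds channel labels; each further
#' column is one signature. Columns must sum to 1 within 1e-4 (then
#' renormalized exactly); channel order is canonicalized.
#'
#' @param path TSV path.
#' @param aetiology optional named character vector of aetiology tags, or path
#'   to a two-column TSV (`signature`, `aetiology`).
#' @return [signature_catalog()] object.
#' @export
read_signature_catalog <- function(path, aetiology = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("signature catalog needs a channel column plus at least one signature column")
  chan <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- chan
  if (!nrow(m) %in% c(96L, 83L))
    stop("expected 96 (SBS) or 83 (ID) channel rows, got ", nrow(m))
  if (is.character(aetiology) && length(aetiology) == 1L &&
      file.exists(aetiology) && is.null(names(aetiology))) {
    at <- read.delim(aetiology, stringsAsFactors = FALSE)
    aetiology <- setNames(at$aetiology, at$signature)
  }
  signature_catalog(m, aetiology = aetiology)
}

#' Write a signature catalog in COSMIC matrix layout
#'
#' @param catalog [signature_catalog()] object.
#' @param path output TSV path.
#' @export
write_signature_catalog <- function(catalog, path) {
  lab <- if (catalog$channel_set == "SBS96") "Type" else "MutationType"
  df <- data.frame(catalog$channels, catalog$probabilities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- lab
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
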