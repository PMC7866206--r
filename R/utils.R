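#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats runif rbinom rmultinom setNames
#' @importFrom utils read.delim write.table head
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# seed = NULL means "use the current stream" (callers composing several
# generators under one outer seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorized helper over plain character vectors (alleles, contexts).
#'
#' @param x character vector of DNA strings over A,C,G,T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable key for a variant record, comparable across patients/callers
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

is_snv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L

# Trim shared suffix then shared prefix from allele pairs (keeping >= 1 base
# each), adjusting pos for prefix trimming. Makes recurrence keys independent
# of padded representations.
trim_alleles <- function(pos, ref, alt) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]
    # suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # prefix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

# extract reference bases [start, end] of one chromosome as a single string
ref_substr <- function(reference, chrom, start, end) {
  seqs <- reference_sequences(reference)
  if (!chrom %in% names(seqs))
    stop("unknown sequence name: ", chrom)
  L <- Biostrings::width(seqs[chrom])
  if (start < 1L || end > L)
    stop("position out of bounds on ", chrom, ": ", start, "-", end)
  as.character(Biostrings::subseq(seqs[[chrom]], start, end))
}

# Accept either a DNAStringSet or a synthetic_reference object everywhere a
# reference sequence is needed.
reference_sequences <- function(reference) {
  if (is(reference, "DNAStringSet")) return(reference)
  if (inherits(reference, "synthetic_reference")) return(reference$sequence)
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    return(read_reference(reference))
  stop("not a usable reference (DNAStringSet, synthetic_reference or FASTA path)")
}
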