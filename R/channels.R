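# Mutation classification channels: SBS-96 single-base substitutions in
# pyrimidine-normalized trinucleotide context, and the 83-channel COSMIC-style
# small insertion/deletion scheme.

#' Canonical SBS-96 channel labels
#'
#' The 96 channels are the 6 pyrimidine-centered substitutions (C>A, C>G, C>T,
#' T>A, T>C, T>G) crossed with the 16 flanking-base contexts, in COSMIC order
#' (substitution major, then 5' base, then 3' base).
#'
#' @return character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(r3 = bases, r5 = bases, sub = subs,
                      stringsAsFactors = FALSE)[, c("sub", "r5", "r3")]
  grid <- grid[order(match(grid$sub, subs), match(grid$r5, bases),
                     match(grid$r3, bases)), ]
  paste0(grid$r5, "[", grid$sub, "]", grid$r3)
}

#' Canonical ID-83 channel labels
#'
#' Labels follow the SigProfiler/COSMIC v3 indel scheme
#' (`length:type:context:count`), read from the bundled channel-list fixture so
#' that channel naming is bit-exact. 1-bp events are pyrimidine-normalized
#' (C/T); longer events use `R` (repeat) or `M` (microhomology) context; the
#' final field counts repeat units (deletions: additional copies present;
#' insertions: copies already present) or microhomology length, capped at the
#' class maximum.
#'
#' @return character vector of length 83, e.g. `"1:Del:T:5"`.
#' @export
id83_channels <- function() {
  path <- system.file("extdata", "id83_channels.txt", package = "gcgerm")
  if (path == "") path <- file.path("inst", "extdata", "id83_channels.txt")
  ch <- readLines(path)
  stopifnot(length(ch) == 83L)
  ch
}

#' Pyrimidine-normalized SBS-96 channel for one substitution
#'
#' @param ref,alt single reference/alternate bases.
#' @param fl5,fl3 flanking bases 5' and 3' of the variant (genomic strand).
#' @return channel label, or `NA` if the context contains non-ACGT characters.
#' @export
sbs96_channel <- function(ref, alt, fl5, fl3) {
  n <- length(ref)
  out <- rep(NA_character_, n)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    fl5 %in% c("A", "C", "G", "T") & fl3 %in% c("A", "C", "G", "T") & ref != alt
  pur <- ok & ref %in% c("A", "G")
  # purine reference: flip to the pyrimidine strand
  r <- ref; a <- alt; l <- fl5; r3 <- fl3
  r[pur] <- comp_base(ref[pur])
  a[pur] <- comp_base(alt[pur])
  l[pur] <- comp_base(fl3[pur])
  r3[pur] <- comp_base(fl5[pur])
  out[ok] <- paste0(l[ok], "[", r[ok], ">", a[ok], "]", r3[ok])
  out
}

# longest run of `base` in `chars` covering index i (1 if chars[i] != base)
.run_at <- function(chars, i, base) {
  if (chars[i] != base) return(0L)
  lo <- i; hi <- i
  while (lo > 1L && chars[lo - 1L] == base) lo <- lo - 1L
  while (hi < length(chars) && chars[hi + 1L] == base) hi <- hi + 1L
  hi - lo + 1L
}

#' Classify one small indel into its ID-83 channel
#'
#' Input must be a normalized, anchored indel (`ref` and `alt` share their
#' first base and exactly one of them has length 1), left-aligned against the
#' reference. Classification follows the COSMIC convention: type and length
#' class (1, 2, 3, 4, 5+); for 1-bp events the pyrimidine-normalized base and
#' the homopolymer repeat count at the locus; for longer events the number of
#' additional exact copies of the inserted/deleted unit flanking the site, and
#' for non-repeat deletions the longest microhomology shared between the
#' deleted sequence and its immediate flanks.
#'
#' @param reference reference sequences ([synthetic_reference] or
#'   `DNAStringSet`).
#' @param chrom,pos,ref,alt the indel in VCF-style anchored representation.
#' @return one label from [id83_channels()].
#' @export
id83_classify <- function(reference, chrom, pos, ref, alt) {
  if (nchar(ref) == nchar(alt)) stop("not an indel: ", ref, ">", alt)
  if (substr(ref, 1, 1) != substr(alt, 1, 1) ||
      (nchar(ref) > 1L && nchar(alt) > 1L))
    stop("indel must be anchored and normalized: ", ref, ">", alt)
  del <- nchar(ref) > nchar(alt)
  seq_ <- if (del) substr(ref, 2L, nchar(ref)) else substr(alt, 2L, nchar(alt))
  len <- nchar(seq_)
  seqs <- reference_sequences(reference)
  L <- Biostrings::width(seqs[chrom])
  if (del && pos + nchar(ref) - 1L > L)
    stop("indel spans the end of ", chrom)
  if (pos < 1L || pos > L) stop("position out of bounds: ", pos)
  obs <- ref_substr(reference, chrom, pos, pos + nchar(ref) - 1L)
  if (obs != ref)
    stop("reference allele mismatch at ", chrom, ":", pos, " (VCF ref ",
         ref, ", reference ", obs, ")")
  size_cls <- if (len >= 5L) "5" else as.character(len)

  # window of reference around the event, generous enough for repeat counting
  win_lo <- max(1L, pos - 6L * len - 12L)
  win_hi <- min(L, pos + nchar(ref) - 1L + 6L * len + 12L)
  win <- strsplit(ref_substr(reference, chrom, win_lo, win_hi), "")[[1]]
  # index of the anchor base within the window
  a <- pos - win_lo + 1L

  if (len == 1L) {
    base <- seq_
    norm <- if (base %in% c("A", "G")) comp_base(base) else base
    if (del) {
      # homopolymer length including the deleted base, minus one, capped at 5
      run <- .run_at(win, a + 1L, base)
      cnt <- min(run - 1L, 5L)
    } else {
      # existing homopolymer length at the insertion point, capped at 5
      run_right <- if (a + 1L <= length(win)) .run_at(win, a + 1L, base) else 0L
      run_left <- .run_at(win, a, base)
      run <- max(run_right, run_left)
      cnt <- min(run, 5L)
    }
    return(paste("1", if (del) "Del" else "Ins", norm, cnt, sep = ":"))
  }

  # >= 2 bp: count additional exact repeat units flanking the event
  n_rep <- 0L
  if (del) {
    i <- a + len + 1L           # first base after the deleted unit
    while (i + len - 1L <= length(win) &&
           paste(win[i:(i + len - 1L)], collapse = "") == seq_) {
      n_rep <- n_rep + 1L; i <- i + len
    }
    # also count copies immediately before (defensively; left-aligned input
    # normally carries none)
    j <- a - len + 1L
    while (j >= 1L && paste(win[j:(j + len - 1L)], collapse = "") == seq_) {
      n_rep <- n_rep + 1L; j <- j - len
    }
  } else {
    i <- a + 1L
    while (i + len - 1L <= length(win) &&
           paste(win[i:(i + len - 1L)], collapse = "") == seq_) {
      n_rep <- n_rep + 1L; i <- i + len
    }
    j <- a - len + 1L
    while (j >= 1L && paste(win[j:(j + len - 1L)], collapse = "") == seq_) {
      n_rep <- n_rep + 1L; j <- j - len
    }
  }
  if (n_rep > 0L || !del) {
    cnt <- min(n_rep, 5L)
    return(paste(size_cls, if (del) "Del" else "Ins", "R", cnt, sep = ":"))
  }

  # non-repeat deletion: microhomology between the deleted sequence and flanks
  mh <- 0L
  after <- win[(a + len + 1L):length(win)]
  for (m in seq_len(len - 1L)) {
    if (m <= length(after) &&
        paste(after[seq_len(m)], collapse = "") == substr(seq_, 1L, m))
      mh <- max(mh, m)
  }
  before <- win[seq_len(a)]
  for (m in seq_len(len - 1L)) {
    if (m <= length(before) &&
        paste(before[(length(before) - m + 1L):length(before)], collapse = "") ==
        substr(seq_, len - m + 1L, len))
      mh <- max(mh, m)
  }
  if (mh >= 1L) {
    mh_cap <- if (len >= 5L) 5L else len - 1L
    return(paste(size_cls, "Del", "M", min(mh, mh_cap), sep = ":"))
  }
  paste(size_cls, "Del", "R", "0", sep = ":")
}
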