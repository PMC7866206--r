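# Seeded synthetic tumor callsets: SNVs drawn from an SBS-96 signature
# mixture and placed at reference positions with the matching
# pyrimidine-normalized trinucleotide context; indels drawn from
# homopolymer-compatible ID channels (plus one microhomology deletion class)
# and placed at suitable tracts. Every true mutation is written to at least
# two callers; caller-private decoys exercise the consensus merge.

#' Index reference positions by normalized trinucleotide context
#'
#' @param reference reference sequences (single chromosome supported).
#' @return list mapping the 32 pyrimidine-centered trinucleotide contexts to
#'   integer position vectors.
#' @export
build_context_index <- function(reference) {
  seqs <- reference_sequences(reference)
  if (length(seqs) != 1L)
    stop("context index supports a single-chromosome reference")
  s <- as.character(seqs[[1]])
  L <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  center <- chars[2:(L - 1L)]
  tri <- paste0(chars[1:(L - 2L)], center, chars[3:L])
  pur <- center %in% c("A", "G")
  tri[pur] <- revcomp(tri[pur])
  split(2:(L - 1L), tri)
}

# draw a per-mutation channel from a signature mixture
.mixture_channel_probs <- function(mixture, catalog) {
  if (abs(sum(mixture) - 1) > 1e-6)
    stop("mixture fractions must sum to 1")
  missing <- setdiff(names(mixture), catalog$signatures)
  if (length(missing) > 0L)
    stop("mixture names absent from catalog: ",
         paste(missing, collapse = ", "))
  p <- as.numeric(catalog$probabilities[, names(mixture), drop = FALSE] %*%
                    mixture)
  setNames(p, catalog$channels)
}

# run-length index of the reference: start, length, base per run
.run_index <- function(chrom_string) {
  r <- rle(strsplit(chrom_string, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, len = r$lengths,
             base = r$values, stringsAsFactors = FALSE)
}

#' Default caller panel
#'
#' Four SNV callers and three indel callers, mirroring a
#' MuTect/Strelka/VarScan/MuSe setup where one caller reports SNVs only.
#'
#' @return list with `snv` and `indel` caller name vectors.
#' @export
default_caller_panel <- function() {
  list(snv = c("mutect", "strelka", "varscan", "muse"),
       indel = c("strelka", "varscan", "muse"))
}

#' Simulate per-caller somatic callsets from a signature mixture
#'
#' SNV channels are drawn from the SBS mixture and placed uniformly among
#' unused reference positions whose normalized trinucleotide context matches
#' (without replacement, so no site mutates twice). Indel channels are drawn
#' from the ID mixture and placed at homopolymer tracts (or, for the
#' microhomology class, at sites verified by the ID-83 classifier). Each true
#' mutation is assigned to >= 2 SNV callers (>= 2 of 3 for indels); decoys
#' are private to a single caller.
#'
#' @param sample_id tumor sample name.
#' @param reference [generate_reference()] output or `DNAStringSet`.
#' @param sbs_mixture named fractions over SBS signatures (sum 1), or `NULL`.
#' @param n_snvs number of true SNVs.
#' @param id_mixture named fractions over ID signatures, or `NULL`.
#' @param n_indels number of true indels.
#' @param sbs_catalog,id_catalog signature catalogs covering the mixtures.
#' @param callers caller panel ([default_caller_panel()]).
#' @param decoys_per_caller caller-private false calls added per caller
#'   (default 25).
#' @param context_index optional precomputed [build_context_index()].
#' @param seed integer seed (`NULL`: current stream).
#' @param max_attempts placement attempts per mutation before erroring.
#' @return list with `truth` (true mutation data frame with channels and
#'   caller support), `callsets` (named list of per-caller data frames),
#'   `decoys`, `true_exposures` (the mixtures), `sample_id`.
#' @export
simulate_tumor_callsets <- function(sample_id, reference,
                                    sbs_mixture = NULL, n_snvs = 0L,
                                    id_mixture = NULL, n_indels = 0L,
                                    sbs_catalog = synthetic_sbs96_catalog(),
                                    id_catalog = synthetic_id83_catalog(),
                                    callers = default_caller_panel(),
                                    decoys_per_caller = 25L,
                                    context_index = NULL,
                                    seed = NULL,
                                    max_attempts = 200L) {
  seqs <- reference_sequences(reference)
  chrom <- names(seqs)[1L]
  chrom_string <- as.character(seqs[[1L]])
  L <- nchar(chrom_string)
  with_seed(seed, {
    if (is.null(context_index) && n_snvs > 0L)
      context_index <- build_context_index(reference)
    used <- new.env(parent = emptyenv())
    mark_used <- function(lo, hi) for (p in lo:hi)
      assign(as.character(p), TRUE, envir = used)
    is_used <- function(lo, hi) any(vapply(lo:hi, function(p)
      exists(as.character(p), envir = used), logical(1)))

    truth <- list()

    # ---- SNVs --------------------------------------------------------
    if (n_snvs > 0L) {
      probs <- .mixture_channel_probs(sbs_mixture, sbs_catalog)
      drawn <- sample(names(probs), n_snvs, replace = TRUE, prob = probs)
      for (k in seq_len(n_snvs)) {
        chanlab <- drawn[k]
        ctx <- paste0(substr(chanlab, 1L, 1L), substr(chanlab, 3L, 3L),
                      substr(chanlab, 7L, 7L))
        target <- substr(chanlab, 5L, 5L)
        pool <- context_index[[ctx]]
        if (is.null(pool) || length(pool) == 0L)
          stop("no reference context matches channel ", chanlab)
        placed <- FALSE
        for (a in seq_len(max_attempts)) {
          p <- pool[sample.int(length(pool), 1L)]
          if (is_used(p, p)) next
          refb <- substring(chrom_string, p, p)
          altb <- if (refb %in% c("C", "T")) target else comp_base(target)
          mark_used(p, p)
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = sample_id, chrom = chrom, pos = p, ref = refb,
            alt = altb, mut_class = "SNV", channel = chanlab,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place SNV for channel ", chanlab, " after ",
               max_attempts, " attempts")
      }
    }

    # ---- indels ------------------------------------------------------
    if (n_indels > 0L) {
      runs <- .run_index(chrom_string)
      probs <- .mixture_channel_probs(id_mixture, id_catalog)
      drawn <- sample(names(probs), n_indels, replace = TRUE, prob = probs)
      cand_cache <- new.env(parent = emptyenv())
      place_1bp <- function(chanlab) {
        f <- strsplit(chanlab, ":", fixed = TRUE)[[1]]
        del <- f[2] == "Del"
        base <- f[3]
        cnt <- as.integer(f[4])
        # run length required on the reference for this channel
        need <- if (del) cnt + 1L else cnt
        cand <- if (exists(chanlab, envir = cand_cache))
          get(chanlab, envir = cand_cache)
        else {
          cc <- unlist(lapply(c(base, comp_base(base)), function(b) {
            sel <- runs$base == b &
              (if (cnt == 5L) runs$len >= need else runs$len == need) &
              runs$start > 1L & runs$start + runs$len <= L
            which(sel)
          }))
          assign(chanlab, cc, envir = cand_cache)
          cc
        }
        if (length(cand) == 0L) return(NULL)
        for (a in seq_len(max_attempts)) {
          ri <- cand[sample.int(length(cand), 1L)]
          st <- runs$start[ri]; b <- runs$base[ri]
          anchor <- st - 1L
          if (del) {
            if (is_used(anchor, st + runs$len[ri] - 1L)) next
            refa <- substring(chrom_string, anchor, st)
            alta <- substring(chrom_string, anchor, anchor)
            mark_used(anchor, st + runs$len[ri] - 1L)
          } else {
            if (cnt == 0L) next  # no-run insertions handled below
            if (is_used(anchor, st + runs$len[ri] - 1L)) next
            refa <- substring(chrom_string, anchor, anchor)
            alta <- paste0(refa, b)
            mark_used(anchor, st + runs$len[ri] - 1L)
          }
          return(data.frame(sample_id = sample_id, chrom = chrom,
                            pos = anchor, ref = refa, alt = alta,
                            mut_class = if (del) "DEL" else "INS",
                            channel = chanlab, stringsAsFactors = FALSE))
        }
        NULL
      }
      place_ins0 <- function(chanlab) {
        # insertion of one base between non-matching neighbors
        f <- strsplit(chanlab, ":", fixed = TRUE)[[1]]
        base <- f[3]
        for (a in seq_len(max_attempts)) {
          p <- sample.int(L - 2L, 1L) + 1L
          bb <- sample(c(base, comp_base(base)), 1L)
          if (substring(chrom_string, p, p) == bb ||
              substring(chrom_string, p + 1L, p + 1L) == bb) next
          if (is_used(p, p + 1L)) next
          refa <- substring(chrom_string, p, p)
          mark_used(p, p + 1L)
          return(data.frame(sample_id = sample_id, chrom = chrom, pos = p,
                            ref = refa, alt = paste0(refa, bb),
                            mut_class = "INS", channel = chanlab,
                            stringsAsFactors = FALSE))
        }
        NULL
      }
      place_mh <- function(chanlab) {
        f <- strsplit(chanlab, ":", fixed = TRUE)[[1]]
        dlen <- as.integer(f[1])
        for (a in seq_len(max_attempts * 10L)) {
          p <- sample.int(L - dlen - 8L, 1L) + 1L
          if (is_used(p, p + dlen + 2L)) next
          refa <- substring(chrom_string, p, p + dlen)
          alta <- substring(chrom_string, p, p)
          got <- tryCatch(id83_classify(reference, chrom, p, refa, alta),
                          error = function(e) NA_character_)
          if (identical(got, chanlab)) {
            mark_used(p, p + dlen + 2L)
            return(data.frame(sample_id = sample_id, chrom = chrom, pos = p,
                              ref = refa, alt = alta, mut_class = "DEL",
                              channel = chanlab, stringsAsFactors = FALSE))
          }
        }
        NULL
      }
      for (k in seq_len(n_indels)) {
        chanlab <- drawn[k]
        f <- strsplit(chanlab, ":", fixed = TRUE)[[1]]
        row <- if (f[1] == "1" && !(f[2] == "Ins" && f[4] == "0"))
          place_1bp(chanlab)
        else if (f[1] == "1") place_ins0(chanlab)
        else if (f[3] == "M") place_mh(chanlab)
        else stop("simulator does not place channel ", chanlab)
        if (is.null(row))
          stop("could not place indel for channel ", chanlab)
        truth[[length(truth) + 1L]] <- row
      }
    }

    truth <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(sample_id = character(0), chrom = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 mut_class = character(0), channel = character(0),
                 stringsAsFactors = FALSE)

    # ---- caller assignment -------------------------------------------
    assign_support <- function(panel, n) {
      if (n == 0L) return(character(0))
      vapply(seq_len(n), function(i) {
        size <- sample(2L:length(panel), 1L,
                       prob = rev(seq_len(length(panel) - 1L)))
        paste(sort(sample(panel, size)), collapse = ",")
      }, character(1))
    }
    snv_rows <- truth$mut_class == "SNV"
    truth$caller_support <- ""
    truth$caller_support[snv_rows] <- assign_support(callers$snv,
                                                     sum(snv_rows))
    truth$caller_support[!snv_rows] <- assign_support(callers$indel,
                                                      sum(!snv_rows))

    # caller-private decoys at unused positions
    decoys <- NULL
    all_callers <- union(callers$snv, callers$indel)
    if (decoys_per_caller > 0L) {
      rows <- list()
      for (caller in all_callers) {
        for (i in seq_len(decoys_per_caller)) {
          repeat {
            p <- sample.int(L - 2L, 1L) + 1L
            if (!is_used(p, p)) break
          }
          refb <- substring(chrom_string, p, p)
          altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
          mark_used(p, p)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, chrom = chrom, pos = p, ref = refb,
            alt = altb, mut_class = "SNV", caller = caller,
            stringsAsFactors = FALSE)
        }
      }
      decoys <- do.call(rbind, rows)
      # a decoy assigned to an indel-only caller must still be a class that
      # caller reports; SNV decoys on SNV callers, 1-bp insertions otherwise
      only_indel <- setdiff(callers$indel, callers$snv)
      fix <- decoys$caller %in% only_indel
      if (any(fix)) {
        decoys$alt[fix] <- paste0(decoys$ref[fix], "A")
        decoys$mut_class[fix] <- "INS"
      }
    }

    callsets <- setNames(vector("list", length(all_callers)), all_callers)
    for (caller in all_callers) {
      has <- grepl(paste0("(^|,)", caller, "(,|$)"), truth$caller_support)
      cs <- truth[has, c("chrom", "pos", "ref", "alt"), drop = FALSE]
      if (!is.null(decoys)) {
        dd <- decoys[decoys$caller == caller,
                     c("chrom", "pos", "ref", "alt"), drop = FALSE]
        cs <- rbind(cs, dd)
      }
      cs <- cs[order(cs$chrom, cs$pos, cs$ref, cs$alt, method = "radix"), ,
               drop = FALSE]
      rownames(cs) <- NULL
      callsets[[caller]] <- cs
    }

    rownames(truth) <- NULL
    list(sample_id = sample_id, truth = truth, callsets = callsets,
         decoys = decoys,
         true_exposures = list(sbs = sbs_mixture, id = id_mixture))
  })
}

#' Write simulated callsets as per-caller VCF files
#'
#' @param sim [simulate_tumor_callsets()] output.
#' @param dir output directory.
#' @return named vector of paths.
#' @export
write_tumor_callsets <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- setNames(file.path(dir, paste0(sim$sample_id, "_",
                                          names(sim$callsets), ".vcf")),
                    names(sim$callsets))
  for (caller in names(sim$callsets))
    write_somatic_vcf(sim$callsets[[caller]], paths[[caller]],
                      sample_id = sim$sample_id, caller = caller)
  paths
}
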