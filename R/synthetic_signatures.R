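# Deterministic synthetic stand-in signature catalogs. The published COSMIC
# v3 matrices are not redistributed here; these catalogs are constructed in
# code with the qualitative shapes and aetiology tags the analysis needs
# (CpG-deamination-like and flat clock-like SBS patterns, mismatch-repair-
# deficiency-like patterns, homopolymer indel patterns), and are clearly
# synthetic. Signature identifiers reuse the familiar COSMIC names so that
# aetiology-driven logic reads naturally, but the probability values are not
# COSMIC's.

#' Synthetic SBS-96 signature catalog (stand-in)
#'
#' Five deterministic, well-separated signatures: SBS1-like (C>T at CpG),
#' SBS5-like (flat), SBS15-like and SBS21-like (MMR-deficiency patterns:
#' C>T-heavy at G-5' contexts and T>C-heavy respectively) and SBS19-like
#' (C>A/C>T mix, unknown aetiology).
#'
#' @return [signature_catalog()] with aetiology tags.
#' @export
synthetic_sbs96_catalog <- function() {
  ch <- sbs96_channels()
  sub <- sub("^.\\[(.+)\\].$", "\\1", ch)
  fl5 <- substr(ch, 1L, 1L)
  fl3 <- substr(ch, nchar(ch), nchar(ch))
  w <- function(x) x / sum(x)

  sbs1 <- rep(0.2, 96)
  sbs1[sub == "C>T" & fl3 == "G"] <- 18
  sbs1 <- w(sbs1)

  # flat with a mild deterministic tilt
  sbs5 <- w(1 + 0.25 * sin(seq_len(96) / 7))

  sbs15 <- rep(0.12, 96)
  sbs15[sub == "C>T" & fl5 == "G"] <- 14
  sbs15[sub == "C>G" & fl5 == "G"] <- 3
  sbs15 <- w(sbs15)

  sbs19 <- rep(0.15, 96)
  sbs19[sub == "C>A" & fl3 == "T"] <- 8
  sbs19[sub == "C>T" & fl5 == "A"] <- 6
  sbs19 <- w(sbs19)

  sbs21 <- rep(0.1, 96)
  sbs21[sub == "T>C"] <- 10
  sbs21[sub == "T>C" & fl5 == "G"] <- 20
  sbs21 <- w(sbs21)

  m <- cbind(SBS1 = sbs1, SBS5 = sbs5, SBS15 = sbs15, SBS19 = sbs19,
             SBS21 = sbs21)
  rownames(m) <- ch
  signature_catalog(m, aetiology = c(SBS1 = "clock_like",
                                     SBS5 = "clock_like",
                                     SBS15 = "mmr_deficiency",
                                     SBS19 = "unknown",
                                     SBS21 = "mmr_deficiency"))
}

#' Synthetic ID-83 signature catalog (stand-in)
#'
#' Three deterministic indel signatures supported on channels the tumor
#' simulator can place: ID1-like (1-bp T insertions in long homopolymers),
#' ID2-like (1-bp T deletions in long homopolymers) and ID7-like
#' (MMR-deficiency pattern: 1-bp deletions at short repeats plus a
#' microhomology deletion class).
#'
#' @return [signature_catalog()] with aetiology tags.
#' @export
synthetic_id83_catalog <- function() {
  ch <- id83_channels()
  w <- function(x) x / sum(x)
  z <- setNames(numeric(83), ch)

  id1 <- z
  id1["1:Ins:T:5"] <- 0.55
  id1["1:Ins:T:4"] <- 0.3
  id1["1:Ins:C:4"] <- 0.05
  id1["1:Ins:T:3"] <- 0.1
  id1 <- w(id1)

  id2 <- z
  id2["1:Del:T:5"] <- 0.6
  id2["1:Del:T:4"] <- 0.3
  id2["1:Del:C:4"] <- 0.1
  id2 <- w(id2)

  id7 <- z
  id7["1:Del:T:1"] <- 0.25
  id7["1:Del:T:2"] <- 0.25
  id7["1:Del:C:1"] <- 0.15
  id7["1:Del:C:2"] <- 0.15
  id7["5:Del:M:2"] <- 0.2
  id7 <- w(id7)

  m <- cbind(ID1 = id1, ID2 = id2, ID7 = id7)
  rownames(m) <- ch
  signature_catalog(m, aetiology = c(ID1 = "clock_like", ID2 = "clock_like",
                                     ID7 = "mmr_deficiency"))
}
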