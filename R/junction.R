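# Breakpoint microhomology reconstruction.
#
# Microhomology is defined as the total junction ambiguity: the maximal
# perfect-identity tract shared by the two junction flanks, extending in
# both directions from the reported breakpoints, so that every breakpoint
# pair inside the ambiguity range reconstructs the same alternate allele.
# Only perfect identity counts; near-perfect ("homeology") tracts are
# reported separately.

char_at <- function(x, i) substr(x, i + 1L, i + 1L)   # 0-based

#' Compute breakpoint microhomology from reference sequence
#'
#' For deletions and duplications, the right extension is the maximal k
#' with `ref[bp5 .. bp5+k) == ref[bp3 .. bp3+k)` and the left extension
#' the maximal j with `ref[bp5-j .. bp5) == ref[bp3-j .. bp3)`. For
#' inversions the comparison runs against the complement of the partner
#' flank read in the opposite direction; by strand symmetry the two
#' inversion junctions carry the same ambiguity, and both are reported.
#'
#' @param refseq reference chromosome string
#' @param bp5,bp3 0-based breakpoints, `bp5 < bp3`
#' @param sv_type DEL, DUP, mCNV or INV
#' @param alt_insertion junction insertion from the alternate allele, when
#'   known (synthetic truth or assembly sequence); never contributes to
#'   microhomology
#' @param max_scan cap on the scanned tract length
#' @return list: `mh_sequence`, `mh_length`, `left_extension`,
#'   `right_extension`, `junction_insertion`, `ambiguity` (half-open range
#'   of equivalent 5' breakpoints, length `mh_length + 1`), and
#'   `homeology_length` (longest window with >= 90% identity)
#' @export
compute_microhomology <- function(refseq, bp5, bp3,
                                  sv_type = "DEL", alt_insertion = "",
                                  max_scan = 400L) {
  L <- nchar(refseq)
  if (!(bp5 >= 0 && bp5 < bp3 && bp3 <= L))
    stop("require 0 <= bp5 < bp3 <= len(refseq)")
  inv <- sv_type == "INV"
  right_at <- function(t) {
    a <- char_at(refseq, bp5 + t)
    b <- if (inv) dna_complement(char_at(refseq, bp3 - 1L - t))
         else char_at(refseq, bp3 + t)
    nzchar(a) && nzchar(b) && a == b
  }
  left_at <- function(t) {
    a <- char_at(refseq, bp5 - 1L - t)
    b <- if (inv) dna_complement(char_at(refseq, bp3 + t))
         else char_at(refseq, bp3 - 1L - t)
    nzchar(a) && nzchar(b) && a == b
  }
  r <- 0L
  while (r < max_scan && bp5 + r < bp3 && right_at(r)) r <- r + 1L
  l <- 0L
  while (l < max_scan && bp5 - l > 0 && left_at(l)) l <- l + 1L
  mh <- l + r
  mh_seq <- if (mh > 0) seq_slice(refseq, bp5 - l, bp5 + r) else ""
  # homeology: longest window starting at the left ambiguity edge with
  # >= 90% identity between the two flanks (auxiliary annotation)
  hom <- mh
  mism <- 0L
  t <- r
  while (bp5 + t < bp3 && t < max_scan) {
    if (!right_at(t)) mism <- mism + 1L
    t <- t + 1L
    if (mism > 0 && mism / t > 0.1) break
    if (mism / t <= 0.1) hom <- l + t
  }
  list(mh_sequence = mh_seq, mh_length = mh,
       left_extension = l, right_extension = r,
       junction_insertion = alt_insertion,
       ambiguity = c(bp5 - l, bp5 + r + 1L),
       homeology_length = hom)
}

#' Render a human-readable junction reconstruction
#'
#' Three aligned lines: the 5' reference flank, the alternate allele, and
#' the 3' reference flank, with the microhomology tract delimited by
#' brackets. Purely presentational and byte-stable.
#'
#' @param refseq reference chromosome string
#' @param altseq alternate allele around the junction, or NULL
#' @param bp5,bp3 breakpoints
#' @param call junction call from [compute_microhomology()]
#' @param context flank bp shown on either side (clipped at bounds)
#' @return character vector of three lines
#' @export
reconstruct_junction_text <- function(refseq, altseq = NULL, bp5, bp3, call,
                                      context = 60L) {
  if (!is.null(altseq) && identical(altseq, refseq))
    stop("reference and alternate are identical: no junction to render")
  l <- call$left_extension; r <- call$right_extension
  mh <- call$mh_sequence
  ins <- call$junction_insertion
  ctx5 <- seq_slice(refseq, max(0, bp5 - l - context), bp5 - l)
  ctx3 <- seq_slice(refseq, bp3 + r, min(nchar(refseq), bp3 + r + context))
  into5 <- seq_slice(refseq, bp5 + r, min(bp3, bp5 + r + 20L))
  outof3 <- seq_slice(refseq, max(bp5, bp3 - l - 20L), bp3 - l)
  hl <- if (nzchar(mh)) paste0("[", mh, "]") else ""
  insl <- if (nzchar(ins)) paste0("{", ins, "}") else ""
  c(paste0("REF5 ", ctx5, hl, into5, "..."),
    paste0("ALT  ", ctx5, hl, insl, ctx3),
    paste0("REF3 ", "...", outof3, hl, ctx3))
}

#' Detect secondary events at rearrangement junctions
#'
#' Globally aligns the observed alternate segment against the clean
#' expected alternate (the TruthRecord edit applied to the reference
#' window) and reports insertions/deletions of at least `min_size` bp as
#' secondary events — the complex-breakpoint signature seen at
#' Alu-mediated inversions.
#'
#' @param refseq reference chromosome string
#' @param alt_segment observed alternate sequence over
#'   `[window_start, window_end)` of the reference
#' @param sv one-row TruthRecord-like data.frame (start, end, sv_type,
#'   window_start, window_end, junction_insertion, copy_number)
#' @param min_size minimum indel size reported
#' @return data.frame with `type` (DEL/INS) and `size`; zero rows for a
#'   clean junction. NULL (with a message) when no alternate is available.
#' @export
detect_complex_breakpoints <- function(refseq, alt_segment, sv,
                                       min_size = 5L) {
  if (is.null(alt_segment) || is.na(alt_segment) || !nzchar(alt_segment)) {
    message("alternate sequence missing: complex breakpoints not evaluable")
    return(NULL)
  }
  clean <- sv
  for (col in c("cdel5", "cdel3")) clean[[col]] <- 0L
  for (col in c("cins5", "cins3")) clean[[col]] <- ""
  full <- apply_truth_edit(refseq, clean)
  delta <- nchar(refseq) - nchar(full)
  expected <- seq_slice(full, sv$window_start,
                        max(sv$window_start, sv$window_end - delta))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(alt_segment), Biostrings::DNAString(expected),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 5, mismatch = -4, baseOnly = TRUE),
    gapOpening = 10, gapExtension = 0.5)
  dels <- IRanges::width(Biostrings::indel(Biostrings::pattern(aln))[[1]])
  inss <- IRanges::width(Biostrings::indel(Biostrings::subject(aln))[[1]])
  out <- rbind(
    if (length(dels)) data.frame(type = "DEL", size = dels) else NULL,
    if (length(inss)) data.frame(type = "INS", size = inss) else NULL)
  if (is.null(out)) out <- data.frame(type = character(0), size = integer(0))
  out <- out[out$size >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}
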