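# HR vs NHE mechanism inference by local alignment of junction flanks
# against TE consensus sequences.
#
# The chimeric TE left behind by an HR event must reconstruct a full
# consensus-length element with the microhomology at the junction: the
# 5'-flank alignment (consensus end e1) and 3'-flank alignment (consensus
# start s2) then overlap by exactly the microhomology, overlap = e1 - s2.
# Flanks that fail to overlap along the consensus indicate non-homologous
# repair. Alu events that fail the full-consensus test but retain
# microhomology are retried monomer-by-monomer to catch chimeras that
# recombined between homologous positions of different monomers.

#' Smith-Waterman local alignment against a consensus
#'
#' EDNAFULL-equivalent scoring: match +5, mismatch -4, gap open 10, gap
#' extend 0.5 (a length-L gap costs 10 + 0.5 L). Identity is computed over
#' alignment columns including gaps.
#'
#' @param query flank sequence (consensus orientation)
#' @param consensus consensus sequence (character or [te_consensus])
#' @param match,mismatch,gap_open,gap_ext scoring constants
#' @return list: `score`, `identity_percent`, `query_span` and
#'   `consensus_span` (0-based half-open), `nmatch`, `columns`
#' @export
local_align <- function(query, consensus, match = 5, mismatch = -4,
                        gap_open = 10, gap_ext = 0.5) {
  if (inherits(consensus, "te_consensus")) consensus <- consensus$sequence
  if (!nzchar(query)) stop("local_align: empty query")
  if (!nzchar(consensus)) stop("local_align: empty consensus")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(consensus),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE),
    gapOpening = gap_open, gapExtension = gap_ext)
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score = Biostrings::score(aln),
       identity_percent = 100 * Biostrings::nmatch(aln) / cols,
       query_span = c(IRanges::start(p) - 1L, IRanges::end(p)),
       consensus_span = c(IRanges::start(s) - 1L, IRanges::end(s)),
       nmatch = Biostrings::nmatch(aln), columns = cols)
}

#' Percent similarity of two TE sequences
#'
#' 100 x (identical aligned positions / alignment columns) of the best
#' local alignment under the same scoring as [local_align()]. Both
#' sequences must be in consensus orientation.
#'
#' @param te1_seq,te2_seq DNA strings
#' @return percent in \[0, 100\]
#' @export
percent_similarity <- function(te1_seq, te2_seq) {
  if (!nzchar(te1_seq) || !nzchar(te2_seq))
    stop("percent_similarity: empty sequence")
  local_align(te1_seq, te2_seq)$identity_percent
}

# Consensus-oriented subsequence of a TE copy between two genomic
# positions; returns the sequence plus its consensus span.
te_consensus_slice <- function(refseq, te, gfrom, gto) {
  stopifnot(gfrom >= te$te_start, gto <= te$te_end, gfrom <= gto)
  raw <- seq_slice(refseq, gfrom, gto)
  t0 <- te$truncate_5p
  if (te$strand == "+") {
    list(seq = raw,
         span = c(gfrom - te$te_start + t0, gto - te$te_start + t0))
  } else {
    list(seq = revcomp(raw),
         span = c(te$te_end - gto + t0, te$te_end - gfrom + t0))
  }
}

#' Extract consensus-oriented junction flanks of a TEMR
#'
#' Breakpoints are first moved to their outer representation (the 5'
#' junction to the right edge of the microhomology ambiguity, the 3'
#' junction to the left edge) so each flank includes the microhomology
#' tract; minus-strand TEs are reverse-complemented into consensus
#' orientation. The flank covering the consensus prefix is returned as
#' `flank5` regardless of which genomic side contributed it.
#'
#' @param refseq reference chromosome string
#' @param temr one-row classified TEMR (start, end, sv_type, te5/te3
#'   fields from [classify_temr()])
#' @param te_annotation TE annotation table
#' @param jc junction call from [compute_microhomology()]
#' @return list: `flank5`, `flank3`, their consensus spans
#'   (`span5`, `span3`), and `swapped`
#' @export
extract_flanks <- function(refseq, temr, te_annotation, jc) {
  te5 <- assign_breakpoint_te(temr$chrom, temr$start, te_annotation)
  te3 <- assign_breakpoint_te(temr$chrom, temr$end, te_annotation)
  if (is.null(te5) || is.null(te3))
    stop("breakpoint outside the assigned TE annotation")
  l <- jc$left_extension; r <- jc$right_extension
  inv <- temr$sv_type == "INV"
  bp5o <- temr$start + r
  bp3o <- if (inv) temr$end + l else temr$end - l
  f5 <- te_consensus_slice(refseq, te5, te5$te_start, bp5o)
  f3 <- if (inv) {
    # minus-strand partner: its consensus-suffix flank is the genomic
    # slice from the TE start up to the (outer) breakpoint, RC'd
    te_consensus_slice(refseq, te3, te3$te_start, bp3o)
  } else {
    te_consensus_slice(refseq, te3, bp3o, te3$te_end)
  }
  swapped <- FALSE
  if (f5$span[1] > f3$span[1]) {
    # both copies on the minus strand: genomic left retains the consensus
    # suffix, so the roles swap
    tmp <- f5; f5 <- f3; f3 <- tmp
    swapped <- TRUE
  }
  list(flank5 = f5$seq, flank3 = f3$seq,
       span5 = f5$span, span3 = f3$span, swapped = swapped)
}

#' Infer the repair mechanism of one TEMR
#'
#' Decision sequence: (1) a microhomology of 5 bp or more that is >= 90%
#' A (or T) sits in a poly-A tract and goes to manual review; (2) both
#' flanks are aligned to the family consensus and `overlap_bp =
#' e1 - s2`; the call is HR when the overlap is at least 1 bp and equals
#' the microhomology length (within `tolerance`); (3) Alu events that
#' fail but retain microhomology are realigned monomer-by-monomer,
#' detecting chimeras that crossed monomers; (4) flanks that fail to
#' overlap along the consensus are NHE; (5) a LINE-1 flank aligning over
#' less than half its length (truncated element) or an overlap discordant
#' with the microhomology goes to manual review.
#'
#' @param flanks output of [extract_flanks()]
#' @param mh_length,mh_sequence junction call fields
#' @param family TE class ("Alu" enables the monomer retry)
#' @param consensus the family's [te_consensus]
#' @param tolerance allowed |overlap - microhomology| for an HR call
#' @param polya_frac A (or T) fraction that triggers the poly-A flag
#' @param polya_min_mh minimum microhomology length for the poly-A flag
#' @param trunc_cov LINE-1 flank coverage below which the truncated flag
#'   triggers
#' @return list: `label` (HR / NHE / MANUAL_REVIEW), `overlap_bp`,
#'   `consensus_junction_position` (HR only), `monomer_cross`,
#'   `review_reason`, and the two flank alignments
#' @export
infer_mechanism <- function(flanks, mh_length, mh_sequence, family,
                            consensus, tolerance = 0L,
                            polya_frac = 0.9, polya_min_mh = 5L,
                            trunc_cov = 0.5) {
  res <- list(label = "MANUAL_REVIEW", overlap_bp = NA_integer_,
              consensus_junction_position = NA_integer_,
              monomer_cross = "none", review_reason = "none",
              aln5 = NULL, aln3 = NULL)
  if (mh_length >= polya_min_mh) {
    b <- strsplit(toupper(mh_sequence), "")[[1]]
    if (mean(b == "A") >= polya_frac || mean(b == "T") >= polya_frac) {
      res$review_reason <- "polyA"
      return(res)
    }
  }
  a5 <- local_align(flanks$flank5, consensus)
  a3 <- local_align(flanks$flank3, consensus)
  res$aln5 <- a5; res$aln3 <- a3
  if (family == "LINE-1") {
    # the EMBOSS-style cheap gap extension lets any sequence align over
    # its full span, so coverage is measured on an effectively gapless
    # local alignment
    cov <- function(fl) {
      a <- local_align(fl, consensus, gap_open = 25, gap_ext = 10)
      diff(a$query_span) / nchar(fl)
    }
    if (cov(flanks$flank5) < trunc_cov || cov(flanks$flank3) < trunc_cov) {
      res$review_reason <- "truncated"
      return(res)
    }
  }
  ov <- a5$consensus_span[2] - a3$consensus_span[1]
  res$overlap_bp <- ov
  if (ov >= 1 && abs(ov - mh_length) <= tolerance && mh_length >= 1) {
    res$label <- "HR"
    res$consensus_junction_position <- a3$consensus_span[1]
    stopifnot(res$overlap_bp == mh_length || tolerance > 0)
    return(res)
  }
  if (family == "Alu" && mh_length >= 1 &&
      !is.null(consensus$monomer_bounds)) {
    mb <- consensus$monomer_bounds
    # first read the cross direction off the full-consensus alignments:
    # the 5' flank ends in one monomer, the 3' flank starts in the other,
    # and the overlap is re-tested in monomer-local coordinates
    mono_of <- function(pos) {
      if (pos >= mb$left[1] && pos <= mb$left[2]) "left"
      else if (pos >= mb$right[1] && pos <= mb$right[2]) "right"
      else NA_character_
    }
    m5 <- mono_of(a5$consensus_span[2])
    m3 <- mono_of(a3$consensus_span[1])
    if (!is.na(m5) && !is.na(m3) && m5 != m3) {
      ovm <- (a5$consensus_span[2] - mb[[m5]][1]) -
        (a3$consensus_span[1] - mb[[m3]][1])
      if (ovm >= 1 && abs(ovm - mh_length) <= tolerance) {
        res$label <- "HR"
        res$overlap_bp <- ovm
        res$monomer_cross <- paste0(m5, "-to-", m3)
        res$consensus_junction_position <- a3$consensus_span[1]
        return(res)
      }
    }
    # fallback: realign each flank against each monomer separately
    mono <- lapply(mb[c("left", "right")], function(iv)
      seq_slice(consensus$sequence, iv[1], iv[2]))
    for (cb in list(c("left", "right"), c("right", "left"))) {
      a5m <- local_align(flanks$flank5, mono[[cb[1]]])
      a3m <- local_align(flanks$flank3, mono[[cb[2]]])
      ovm <- a5m$consensus_span[2] - a3m$consensus_span[1]
      if (ovm >= 1 && abs(ovm - mh_length) <= tolerance) {
        res$label <- "HR"
        res$overlap_bp <- ovm
        res$monomer_cross <- paste(cb, collapse = "-to-")
        res$consensus_junction_position <-
          mb[[cb[2]]][1] + a3m$consensus_span[1]
        res$aln5 <- a5m; res$aln3 <- a3m
        return(res)
      }
    }
  }
  if (ov <= 0) {
    res$label <- "NHE"
    return(res)
  }
  res$review_reason <- "discordant"
  res
}

#' Map a microhomology onto the consensus
#'
#' For an HR call the microhomology occupies `[s2, s2 + mh)` on the
#' consensus, where s2 is the 3'-flank alignment start. Also reports which
#' annotated promoter boxes (A-box / B-box / A'-box) the tract touches.
#'
#' @param call a [infer_mechanism()] result with label HR
#' @param mh_length microhomology length
#' @param consensus the family's [te_consensus]
#' @return list: `interval` (half-open on consensus), `boxes_touched`
#' @export
map_mh_to_consensus <- function(call, mh_length, consensus) {
  if (call$label != "HR") stop("consensus mapping applies to HR calls only")
  s2 <- call$consensus_junction_position
  iv <- c(s2, s2 + mh_length)
  touched <- character(0)
  if (!is.null(consensus$boxes)) {
    for (nm in names(consensus$boxes)) {
      b <- consensus$boxes[[nm]]
      if (overlap_bp(iv[1], iv[2], b[1], b[2]) > 0)
        touched <- c(touched, nm)
    }
  }
  list(interval = iv, boxes_touched = touched)
}

#' Tabulate mechanism calls across a cohort
#'
#' @param temrs data.frame with `mechanism_label`, `family`,
#'   `monomer_cross`, `review_reason` columns (see
#'   [run_temr_pipeline()]'s `temr` table)
#' @return list: label x family table, percent systematically categorized,
#'   manual-review fraction, monomer-cross tallies (single- vs
#'   three-monomer chimeras), and the Alu HR share under both reported
#'   denominators (all HR events; all Alu events)
#' @export
classify_cohort <- function(temrs) {
  tab <- table(label = temrs$mechanism_label, family = temrs$family)
  n <- nrow(temrs)
  n_manual <- sum(temrs$mechanism_label == "MANUAL_REVIEW")
  hr <- temrs$mechanism_label == "HR"
  alu <- temrs$family == "Alu"
  # left-to-right crosses leave a single-monomer chimera; right-to-left
  # crosses leave a three-monomer chimera
  single <- sum(temrs$monomer_cross == "left-to-right", na.rm = TRUE)
  triple <- sum(temrs$monomer_cross == "right-to-left", na.rm = TRUE)
  pct <- function(a, b) if (b == 0) NA_real_ else round(100 * a / b, 1)
  list(table = tab,
       n = n,
       percent_systematic = pct(n - n_manual, n),
       percent_manual = pct(n_manual, n),
       monomer_chimeras = c(single_monomer = single,
                            three_monomer = triple),
       hr_alu_of_hr_percent = pct(sum(hr & alu), sum(hr)),
       hr_alu_of_alu_percent = pct(sum(hr & alu), sum(alu)))
}
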