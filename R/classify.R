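# TEMR categorization: intersect merged SV breakpoints with the TE
# annotation; an SV whose two breakpoints fall in distinct TE copies of
# the same element class is a TEMR.

#' Assign the TE containing a breakpoint
#'
#' Returns the unique TE whose half-open interval contains the position,
#' or NULL. Nested/overlapping annotations resolve to the smallest
#' containing element, with a warning flag.
#'
#' @param chrom chromosome name
#' @param pos 0-based position
#' @param te_annotation annotation table ([build_reference()] layout)
#' @return list(copy_id, family, subfamily, strand, offset, te_start,
#'   te_end, multiple) or NULL when unannotated
#' @export
assign_breakpoint_te <- function(chrom, pos, te_annotation) {
  hit <- which(te_annotation$chrom == chrom &
               te_annotation$start <= pos & pos < te_annotation$end)
  if (length(hit) == 0) return(NULL)
  multiple <- length(hit) > 1
  if (multiple) {
    w <- te_annotation$end[hit] - te_annotation$start[hit]
    hit <- hit[which.min(w)]
  }
  r <- te_annotation[hit, ]
  list(copy_id = r$copy_id, family = r$family, subfamily = r$subfamily,
       strand = r$strand, offset = pos - r$start,
       te_start = r$start, te_end = r$end,
       truncate_5p = if (!is.null(r$truncate_5p)) r$truncate_5p else 0L,
       multiple = multiple)
}

#' Classify a merged callset into TEMRs and non-TEMRs
#'
#' For each SV the 5' breakpoint (`start`) and 3' breakpoint (`end`) are
#' intersected with the TE annotation. TEMR: both breakpoints in distinct
#' TE copies of the same class; orientation is `direct` when the two TE
#' strands agree and `inverted` otherwise. Both breakpoints in one and the
#' same copy is non-TEMR.
#'
#' @param merged consensus callset (chrom/start/end/sv_type, ...)
#' @param te_annotation TE annotation table
#' @return `merged` with columns `is_temr`, `family`, `orientation`,
#'   `te5_id`, `te3_id`, `te5_offset`, `te3_offset`, `te5_strand`,
#'   `te3_strand`, `te5_subfamily`, `te3_subfamily`
#' @export
classify_temr <- function(merged, te_annotation) {
  n <- nrow(merged)
  out <- merged
  out$is_temr <- FALSE
  out$family <- NA_character_
  out$orientation <- NA_character_
  for (col in c("te5_id", "te3_id", "te5_strand", "te3_strand",
                "te5_subfamily", "te3_subfamily"))
    out[[col]] <- NA_character_
  out$te5_offset <- out$te3_offset <- NA_integer_
  for (i in seq_len(n)) {
    a <- assign_breakpoint_te(merged$chrom[i], merged$start[i], te_annotation)
    b <- assign_breakpoint_te(merged$chrom[i], merged$end[i], te_annotation)
    if (is.null(a) || is.null(b)) next
    out$te5_id[i] <- a$copy_id; out$te3_id[i] <- b$copy_id
    out$te5_offset[i] <- a$offset; out$te3_offset[i] <- b$offset
    out$te5_strand[i] <- a$strand; out$te3_strand[i] <- b$strand
    out$te5_subfamily[i] <- a$subfamily; out$te3_subfamily[i] <- b$subfamily
    if (a$copy_id != b$copy_id && a$family == b$family) {
      out$is_temr[i] <- TRUE
      out$family[i] <- a$family
      out$orientation[i] <- if (a$strand == b$strand) "direct" else "inverted"
    }
  }
  out
}

#' Summarize a classified callset
#'
#' Counts by family x SV type x orientation, the TEMR fraction of the
#' callset, and per-class size medians.
#'
#' @param classified output of [classify_temr()]
#' @return list: `n_sv`, `n_temr`, `temr_percent` (two decimals),
#'   `by_class` (count table), `size_medians`
#' @export
summarize_callset <- function(classified) {
  temr <- classified[classified$is_temr, , drop = FALSE]
  n_sv <- nrow(classified); n_temr <- nrow(temr)
  pct <- if (n_sv == 0) 0 else round(100 * n_temr / n_sv, 2)
  by_class <- if (n_temr > 0)
    as.data.frame(table(family = temr$family, sv_type = temr$sv_type,
                        orientation = temr$orientation),
                  stringsAsFactors = FALSE)
  else data.frame(family = character(0), sv_type = character(0),
                  orientation = character(0), Freq = integer(0))
  by_class <- by_class[by_class$Freq > 0, , drop = FALSE]
  by_class <- by_class[order(by_class$family, by_class$sv_type), ,
                       drop = FALSE]
  rownames(by_class) <- NULL
  med <- function(d) if (nrow(d) == 0) NA_real_ else
    stats::median(d$end - d$start)
  size_medians <- c(
    temr = med(temr),
    non_temr = med(classified[!classified$is_temr, , drop = FALSE]))
  if (n_temr > 0) {
    fams <- sort(unique(temr$family))
    fam_med <- vapply(fams, function(f)
      med(temr[temr$family == f, , drop = FALSE]), 0)
    size_medians <- c(size_medians, stats::setNames(fam_med, fams))
  }
  list(n_sv = n_sv, n_temr = n_temr, temr_percent = pct,
       by_class = by_class, size_medians = size_medians)
}
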