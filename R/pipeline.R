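# End-to-end orchestration: simulate -> filter -> merge -> classify ->
# junction -> mechanism -> summary, with per-stage record counts and
# deterministic seeding. The analysis/ scripts and the acceptance script
# are thin drivers over this function.

#' Run the full TEMR discovery pipeline on a synthetic cohort
#'
#' Generates a cohort ([simulate_temr_cohort()]), simulates multi-caller
#' callsets, filters and merges them, classifies TEMRs against the planted
#' annotation, reconstructs every junction, infers mechanisms against the
#' consensus set, and summarizes. The truth table doubles as the
#' assembly-derived junction resource: matched records supply the junction
#' insertion sequence, exactly as an assembly callset would.
#'
#' @param seed master seed; all stages derive from it
#' @param n_events planted TEMRs
#' @param background_length chromosome length
#' @param jitter_sd caller breakpoint jitter (bp)
#' @param fp_rate false positives per Mbp per caller
#' @param cfg a [filter_config]
#' @param cohort optionally, a pre-built cohort (from
#'   [simulate_temr_cohort()]); when supplied the generator arguments are
#'   ignored
#' @param ... passed to [simulate_temr_cohort()]
#' @return list: `cohort`, `callsets`, `filtered`, `merged`, `classified`,
#'   `temr` (per-event junction + mechanism table), `summary`,
#'   `mechanism_summary`, `manifest`
#' @export
run_temr_pipeline <- function(seed = 1L, n_events = 120L,
                              background_length = 5e6,
                              jitter_sd = 0, fp_rate = 0,
                              cfg = filter_config(), cohort = NULL, ...) {
  if (is.null(cohort))
    cohort <- simulate_temr_cohort(n_events = n_events,
                                   background_length = background_length,
                                   seed = derive_seed(seed, "cohort"), ...)
  refseq <- cohort$reference$sequence
  callsets <- simulate_callsets(cohort$truth, nchar(refseq),
                                jitter_sd = jitter_sd, fp_rate = fp_rate,
                                seed = derive_seed(seed, "callers"))
  flt <- filter_calls(do.call(rbind, callsets), cfg = cfg)
  merged <- merge_by_rank(flt$kept, cfg)
  classified <- classify_temr(merged, cohort$annotation)
  temr <- classified[classified$is_temr, , drop = FALSE]
  temr <- annotate_junctions(temr, refseq, cohort$annotation,
                             cohort$consensus_set,
                             assembly = cohort$truth)
  summary <- summarize_callset(classified)
  mech_summary <- if (nrow(temr) > 0) classify_cohort(temr) else NULL
  manifest <- list(
    seed = seed,
    stages = c(simulate = nrow(cohort$truth),
               calls = sum(vapply(callsets, nrow, 0L)),
               filtered = nrow(flt$kept),
               merged = nrow(merged),
               temr = nrow(temr)),
    filter_counts = flt$counts)
  list(cohort = cohort, callsets = callsets, filtered = flt,
       merged = merged, classified = classified, temr = temr,
       summary = summary, mechanism_summary = mech_summary,
       manifest = manifest)
}

#' Annotate junctions and mechanisms for a classified TEMR table
#'
#' For each TEMR: reconstruct the breakpoint microhomology from the
#' reference, pick up the junction insertion from a matched assembly
#' record when one overlaps reciprocally at 80%, extract consensus-
#' oriented flanks, infer the mechanism, and compute the percent
#' similarity of the two TE copies.
#'
#' @param temr classified TEMR rows ([classify_temr()])
#' @param refseq reference chromosome string
#' @param te_annotation TE annotation
#' @param consensus_set named list of [te_consensus]
#' @param assembly optional table with chrom/start/end and
#'   `junction_insertion` (an assembly-derived junction resource)
#' @return `temr` with junction and mechanism columns appended
#' @export
annotate_junctions <- function(temr, refseq, te_annotation, consensus_set,
                               assembly = NULL) {
  n <- nrow(temr)
  temr$mh_length <- NA_integer_
  temr$mh_sequence <- NA_character_
  temr$junction_insertion <- ""
  temr$homeology_length <- NA_integer_
  temr$similarity_percent <- NA_real_
  temr$mechanism_label <- NA_character_
  temr$overlap_bp <- NA_integer_
  temr$consensus_junction_position <- NA_integer_
  temr$monomer_cross <- NA_character_
  temr$review_reason <- NA_character_
  if (n == 0) return(temr)
  for (i in seq_len(n)) {
    ins <- ""
    if (!is.null(assembly) && nrow(assembly) > 0) {
      same <- assembly$chrom == temr$chrom[i]
      if (any(same)) {
        ro <- reciprocal_overlap(temr$start[i], temr$end[i],
                                 assembly$start[same], assembly$end[same])
        j <- which(same)[ro >= 0.8]
        if (length(j) > 0) ins <- assembly$junction_insertion[j[1]]
      }
    }
    jc <- compute_microhomology(refseq, temr$start[i], temr$end[i],
                                sv_type = temr$sv_type[i],
                                alt_insertion = ins)
    temr$mh_length[i] <- jc$mh_length
    temr$mh_sequence[i] <- jc$mh_sequence
    temr$junction_insertion[i] <- jc$junction_insertion
    temr$homeology_length[i] <- jc$homeology_length
    fam <- temr$family[i]
    cons <- consensus_set[[fam]]
    if (is.null(cons)) stop("no consensus for family ", fam)
    fl <- extract_flanks(refseq, temr[i, ], te_annotation, jc)
    mc <- infer_mechanism(fl, jc$mh_length, jc$mh_sequence, fam, cons)
    temr$mechanism_label[i] <- mc$label
    temr$overlap_bp[i] <- mc$overlap_bp
    temr$consensus_junction_position[i] <- mc$consensus_junction_position
    temr$monomer_cross[i] <- mc$monomer_cross
    temr$review_reason[i] <- mc$review_reason
    te5 <- assign_breakpoint_te(temr$chrom[i], temr$start[i], te_annotation)
    te3 <- assign_breakpoint_te(temr$chrom[i], temr$end[i], te_annotation)
    s5 <- te_consensus_slice(refseq, te5, te5$te_start, te5$te_end)$seq
    s3 <- te_consensus_slice(refseq, te3, te3$te_start, te3$te_end)$seq
    temr$similarity_percent[i] <- percent_similarity(s5, s3)
  }
  temr
}

#' Cohort-level TEMR summary statistics
#'
#' The medians and fractions conventionally reported for a TEMR callset:
#' microhomology medians (overall among events with microhomology, and by
#' mechanism), TEMR length median, the HR fraction among mechanism-typed
#' events, TE similarity medians, and the GC median of Alu microhomologies
#' of 5 bp and longer.
#'
#' @param temr table with mh_length, mh_sequence, mechanism_label,
#'   family, similarity_percent, start, end columns
#' @return named list of summary values
#' @export
summarize_temr_callset <- function(temr) {
  has_mh <- temr$mh_length >= 1
  hr <- temr$mechanism_label == "HR"
  nhe <- temr$mechanism_label == "NHE"
  alu <- temr$family == "Alu"
  l1 <- temr$family == "LINE-1"
  med <- function(x) if (length(x) == 0) NA_real_ else stats::median(x)
  gc5 <- vapply(temr$mh_sequence[alu & has_mh & temr$mh_length >= 5],
                gc_content, 0)
  list(
    n = nrow(temr),
    median_mh = med(temr$mh_length[has_mh]),
    median_mh_hr = med(temr$mh_length[hr & has_mh]),
    median_mh_nhe = med(temr$mh_length[nhe & has_mh]),
    median_length = med(temr$end - temr$start),
    hr_percent = if (sum(hr | nhe) == 0) NA_real_ else
      round(100 * sum(hr) / sum(hr | nhe), 1),
    median_similarity_hr = med(temr$similarity_percent[hr]),
    median_similarity_nhe = med(temr$similarity_percent[nhe]),
    median_similarity_l1_hr = med(temr$similarity_percent[hr & l1]),
    median_gc_alu_mh5 = med(gc5))
}

#' Evaluate pipeline output against the planted truth
#'
#' Matches merged records to truth intervals (same type class, reciprocal
#' overlap >= 0.8 at jitter, exact at jitter 0) and scores recovery, false
#' positives, classification, microhomology and mechanism agreement.
#'
#' @param result output of [run_temr_pipeline()]
#' @param ro_min reciprocal overlap required for a truth match
#' @return list of scores (percentages and counts)
#' @export
score_against_truth <- function(result, ro_min = 0.8) {
  truth <- result$cohort$truth
  merged <- result$merged
  svt <- ifelse(truth$sv_type == "mCNV", "DUP", truth$sv_type)
  match_of <- rep(NA_integer_, nrow(truth))
  used <- logical(nrow(merged))
  for (i in seq_len(nrow(truth))) {
    cand <- which(!used & merged$chrom == truth$chrom[i] &
                  merged$sv_type == svt[i])
    if (length(cand) == 0) next
    ro <- reciprocal_overlap(truth$start[i], truth$end[i],
                             merged$start[cand], merged$end[cand])
    j <- cand[which.max(ro)]
    if (max(ro) >= ro_min) { match_of[i] <- j; used[j] <- TRUE }
  }
  recovered <- !is.na(match_of)
  fp <- sum(!used) - 0L  # merged records not matching any truth event
  cls <- result$classified
  correct_class <- vapply(which(recovered), function(i) {
    j <- match_of[i]
    isTRUE(cls$is_temr[j]) && cls$family[j] == truth$family[i] &&
      cls$orientation[j] == truth$orientation[i]
  }, TRUE)
  temr <- result$temr
  key <- paste(temr$chrom, temr$start, temr$end, temr$sv_type)
  mh_ok <- mech_ok <- logical(0)
  for (i in which(recovered)) {
    j <- match_of[i]
    k <- match(paste(cls$chrom[j], cls$start[j], cls$end[j],
                     cls$sv_type[j]), key)
    if (is.na(k)) next
    mh_ok <- c(mh_ok, temr$mh_length[k] == truth$mh_length[i])
    mech_ok <- c(mech_ok,
                 temr$mechanism_label[k] == truth$mechanism[i])
  }
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  list(n_truth = nrow(truth), n_merged = nrow(merged),
       recovery_percent = 100 * mean(recovered),
       false_positives = fp,
       classification_percent = pct(correct_class),
       mh_exact_percent = pct(mh_ok),
       mechanism_accuracy_percent = pct(mech_ok))
}
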