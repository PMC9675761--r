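# Ensemble filtering and rank-based merging of multi-caller SV callsets.

#' Filtering and merging configuration
#'
#' Defaults follow the standard short/long-read ensemble thresholds:
#' 50 bp - 50 kbp size range, 500 bp exclusion buffer around gaps and
#' centromeres, 50% simple-repeat overlap, SR >= 5 or PR >= 10 (short
#' reads) / RS >= 5 (long reads) support, RD < 0.7 for deletions and
#' RD > 1.3 for duplications, 80% reciprocal overlap for merging, and the
#' caller ranks Manta > DELLY > LUMPY and pbsv > Sniffles > SVIM.
#'
#' @param min_size,max_size retained SV size range in bp
#' @param exclusion_buffer bp around exclusion regions within which a
#'   breakpoint disqualifies the call
#' @param simple_repeat_overlap rejected when this fraction or more of the
#'   SV is covered by simple repeats
#' @param sr_min,pr_min,rs_min read-support thresholds
#' @param rd_del_max,rd_dup_min depth-ratio thresholds
#' @param ro_threshold reciprocal-overlap threshold for merging
#' @param caller_rank named list of rank-ordered caller vectors per
#'   technology
#' @param tech_priority which technology's coordinates win when a call is
#'   supported by both
#' @return a `filter_config` list
#' @export
filter_config <- function(min_size = 50L, max_size = 50000L,
                          exclusion_buffer = 500L,
                          simple_repeat_overlap = 0.5,
                          sr_min = 5L, pr_min = 10L, rs_min = 5L,
                          rd_del_max = 0.7, rd_dup_min = 1.3,
                          ro_threshold = 0.8,
                          caller_rank = list(
                            SRS = c("Manta", "DELLY", "LUMPY"),
                            LRS = c("pbsv", "Sniffles", "SVIM")),
                          tech_priority = c("SRS", "LRS")) {
  stopifnot(ro_threshold > 0, ro_threshold <= 1, min_size <= max_size)
  structure(list(min_size = min_size, max_size = max_size,
                 exclusion_buffer = exclusion_buffer,
                 simple_repeat_overlap = simple_repeat_overlap,
                 sr_min = sr_min, pr_min = pr_min, rs_min = rs_min,
                 rd_del_max = rd_del_max, rd_dup_min = rd_dup_min,
                 ro_threshold = ro_threshold, caller_rank = caller_rank,
                 tech_priority = tech_priority),
            class = "filter_config")
}

#' Reciprocal overlap of two half-open intervals
#'
#' `min(overlap/len(a), overlap/len(b))`; 0 when disjoint. Vectorized.
#'
#' @param s1,e1 first interval (0-based half-open)
#' @param s2,e2 second interval
#' @return fraction in \[0, 1\]
#' @export
reciprocal_overlap <- function(s1, e1, s2, e2) {
  if (any(e1 <= s1) || any(e2 <= s2))
    stop("reciprocal_overlap: zero-length interval")
  ov <- overlap_bp(s1, e1, s2, e2)
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

# distance from a point to a half-open interval set (0 if inside)
point_dist <- function(p, s, e) {
  pmax(0, pmax(s - p, p - (e - 1L)))
}

#' Filter per-caller SV calls
#'
#' Applies, in order: SV-type whitelist (DEL/DUP/INV), size range,
#' exclusion-region buffer (gaps/centromeres), simple-repeat coverage,
#' read support, and depth ratio (deletions and duplications only).
#' Every rejected call carries the first reason that disqualified it.
#'
#' @param calls data.frame with chrom, start, end, sv_type, caller,
#'   technology, PR, SR, RS, RD
#' @param exclusion_regions BED-like data.frame (chrom/start/end) or NULL
#' @param simple_repeats BED-like data.frame or NULL
#' @param cfg a [filter_config]
#' @return list with `kept` (calls passing all filters) and `rejected`
#'   (calls plus a `reason` column); `counts` tabulates reasons
#' @export
filter_calls <- function(calls, exclusion_regions = NULL,
                         simple_repeats = NULL, cfg = filter_config()) {
  n <- nrow(calls)
  reason <- rep(NA_character_, n)
  sz <- calls$end - calls$start
  bad_type <- !(calls$sv_type %in% c("DEL", "DUP", "INV"))
  reason[bad_type] <- "type"
  bad_size <- is.na(reason) & (sz < cfg$min_size | sz > cfg$max_size)
  reason[bad_size] <- "size"
  if (!is.null(exclusion_regions) && nrow(exclusion_regions) > 0) {
    for (i in which(is.na(reason))) {
      ex <- exclusion_regions[exclusion_regions$chrom == calls$chrom[i], ]
      if (nrow(ex) == 0) next
      d5 <- min(point_dist(calls$start[i], ex$start, ex$end))
      d3 <- min(point_dist(calls$end[i] - 1L, ex$start, ex$end))
      if (min(d5, d3) <= cfg$exclusion_buffer) reason[i] <- "exclusion"
    }
  }
  if (!is.null(simple_repeats) && nrow(simple_repeats) > 0) {
    for (i in which(is.na(reason))) {
      sr <- simple_repeats[simple_repeats$chrom == calls$chrom[i], ]
      if (nrow(sr) == 0) next
      cov <- covered_bp(calls$start[i], calls$end[i], sr$start, sr$end)
      if (cov / sz[i] >= cfg$simple_repeat_overlap)
        reason[i] <- "simple_repeat"
    }
  }
  num0 <- function(x) ifelse(is.na(x), 0, x)
  srs <- calls$technology == "SRS"
  ok_sup <- ifelse(srs,
                   num0(calls$SR) >= cfg$sr_min | num0(calls$PR) >= cfg$pr_min,
                   num0(calls$RS) >= cfg$rs_min)
  reason[is.na(reason) & !ok_sup] <- "support"
  rd <- calls$RD
  ok_rd <- rep(TRUE, n)
  ok_rd[calls$sv_type == "DEL" & !is.na(rd) & rd >= cfg$rd_del_max] <- FALSE
  ok_rd[calls$sv_type == "DUP" & !is.na(rd) & rd <= cfg$rd_dup_min] <- FALSE
  reason[is.na(reason) & !ok_rd] <- "depth"
  kept <- calls[is.na(reason), , drop = FALSE]
  rej <- calls[!is.na(reason), , drop = FALSE]
  rej$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rej) <- NULL
  list(kept = kept, rejected = rej,
       counts = c(table(factor(rej$reason,
                               levels = c("type", "size", "exclusion",
                                          "simple_repeat", "support",
                                          "depth")))))
}

# single-linkage clustering of same-type calls at RO >= thr; returns an
# integer cluster id per row (O(n^2) within chrom x type groups)
cluster_ro <- function(calls, thr) {
  n <- nrow(calls)
  id <- seq_len(n)
  find <- function(i) { while (id[i] != i) { id[i] <<- id[id[i]]; i <- id[i] }; i }
  grp <- split(seq_len(n), paste(calls$chrom, calls$sv_type))
  for (ix in grp) {
    if (length(ix) < 2) next
    for (a in seq_along(ix)[-length(ix)]) {
      for (b in (a + 1):length(ix)) {
        i <- ix[a]; j <- ix[b]
        if (reciprocal_overlap(calls$start[i], calls$end[i],
                               calls$start[j], calls$end[j]) >= thr) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) id[ri] <- rj
        }
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

# pick the representative row of a cluster: highest-ranked caller, ties
# broken by smaller start then smaller end (deterministic)
cluster_rep <- function(rows, rank_order) {
  rk <- match(rows$caller, rank_order)
  rk[is.na(rk)] <- length(rank_order) + 1L
  rows[order(rk, rows$start, rows$end), , drop = FALSE][1, , drop = FALSE]
}

#' Merge per-caller calls into a high-confidence consensus callset
#'
#' Calls of the same type with pairwise reciprocal overlap at or above the
#' threshold are clustered (single linkage) within each technology; each
#' cluster keeps the highest-ranked caller's exact coordinates (no
#' averaging) and the full supporter list. Within-technology consensus
#' requires support from two or more callers; the final set keeps a record
#' when it has consensus in either technology, or cross-technology support
#' (RO >= threshold between a short-read and a long-read record).
#' Records confirmed in both technologies collapse to one, keeping the
#' coordinates of the higher-priority technology.
#'
#' @param calls either one combined data.frame or a list of per-caller
#'   data.frames (as from [simulate_callsets()]); all rows need `caller`
#'   and `technology`
#' @param cfg a [filter_config]
#' @return consensus data.frame with `supporters` (comma-joined callers),
#'   `n_callers`, and `technologies`
#' @export
merge_by_rank <- function(calls, cfg = filter_config()) {
  if (is.list(calls) && !is.data.frame(calls))
    calls <- do.call(rbind, calls)
  empty <- calls[0, c("chrom", "start", "end", "sv_type", "caller",
                      "technology", "sample")]
  empty$supporters <- character(0); empty$n_callers <- integer(0)
  empty$technologies <- character(0)
  if (nrow(calls) == 0) return(empty)
  # prior supporter / technology lists survive re-merging (idempotence)
  if (is.null(calls$supporters)) calls$supporters <- calls$caller
  if (is.null(calls$technologies)) calls$technologies <- calls$technology
  reps <- list()
  for (tech in unique(calls$technology)) {
    sub <- calls[calls$technology == tech, , drop = FALSE]
    cl <- cluster_ro(sub, cfg$ro_threshold)
    for (k in unique(cl)) {
      rows <- sub[cl == k, , drop = FALSE]
      rep1 <- cluster_rep(rows, cfg$caller_rank[[tech]])
      sup <- sort(unique(unlist(strsplit(rows$supporters, ","))))
      rep1$supporters <- paste(sup, collapse = ",")
      rep1$n_callers <- length(sup)
      rep1$technologies <-
        paste(sort(unique(unlist(strsplit(rows$technologies, ",")))),
              collapse = ",")
      reps[[length(reps) + 1L]] <- rep1
    }
  }
  reps <- do.call(rbind, reps)
  consensus <- reps$n_callers >= 2L
  # cross-technology rescue for single-caller records
  cross <- grepl(",", reps$technologies)
  for (i in seq_len(nrow(reps))) {
    if (cross[i]) next
    other <- reps$technology != reps$technology[i] &
      reps$chrom == reps$chrom[i] & reps$sv_type == reps$sv_type[i]
    if (!any(other)) next
    ro <- reciprocal_overlap(reps$start[i], reps$end[i],
                             reps$start[other], reps$end[other])
    cross[i] <- any(ro >= cfg$ro_threshold)
  }
  final <- reps[consensus | cross, , drop = FALSE]
  if (nrow(final) == 0) return(empty)
  # collapse records representing the same event across technologies
  cl <- cluster_ro(final, cfg$ro_threshold)
  out <- list()
  for (k in unique(cl)) {
    rows <- final[cl == k, , drop = FALSE]
    pr <- match(rows$technology, cfg$tech_priority)
    rep1 <- rows[order(pr, rows$start, rows$end), , drop = FALSE][1, , drop = FALSE]
    sup <- sort(unique(unlist(strsplit(rows$supporters, ","))))
    rep1$supporters <- paste(sup, collapse = ",")
    rep1$n_callers <- length(sup)
    rep1$technologies <-
      paste(sort(unique(unlist(strsplit(rows$technologies, ",")))),
            collapse = ",")
    out[[length(out) + 1L]] <- rep1
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-sample consensus callsets into a nonredundant union
#'
#' Records clustered at the reciprocal-overlap threshold across samples
#' collapse to one, retaining the coordinates of the first sample in
#' lexicographic order; per-sample carrier flags are preserved.
#'
#' @param per_sample named list of consensus callsets ([merge_by_rank()])
#' @param cfg a [filter_config]
#' @return nonredundant data.frame with a `carriers` column
#' @export
merge_across_samples <- function(per_sample, cfg = filter_config()) {
  samples <- sort(names(per_sample))
  all <- do.call(rbind, lapply(samples, function(s) {
    d <- per_sample[[s]]
    if (nrow(d) > 0) d$sample <- s
    d
  }))
  if (is.null(all) || nrow(all) == 0) {
    out <- per_sample[[1]][0, , drop = FALSE]
    out$carriers <- character(0)
    return(out)
  }
  cl <- cluster_ro(all, cfg$ro_threshold)
  out <- list()
  for (k in unique(cl)) {
    rows <- all[cl == k, , drop = FALSE]
    rows <- rows[order(rows$sample, rows$start, rows$end), , drop = FALSE]
    rep1 <- rows[1, , drop = FALSE]
    rep1$carriers <- paste(sort(unique(rows$sample)), collapse = ",")
    out[[length(out) + 1L]] <- rep1
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate duplications against assembly insertions
#'
#' A duplication is validated when an insertion call falls within the
#' duplication (plus a window on either side) and the two sizes agree to
#' the `size_match` fraction: `min(dupLen, insLen) / max(...) >= 0.9` by
#' default.
#'
#' @param duplications data.frame (chrom/start/end)
#' @param insertions data.frame with chrom, pos (insertion point) and
#'   `ins_length`
#' @param window bp around the duplication searched for the insertion
#' @param size_match minimum size ratio
#' @return the duplications with a logical `validated` column
#' @export
curate_duplications <- function(duplications, insertions, window = 500L,
                                size_match = 0.9) {
  ok <- logical(nrow(duplications))
  for (i in seq_len(nrow(duplications))) {
    d <- duplications[i, ]
    dl <- d$end - d$start
    cand <- insertions[insertions$chrom == d$chrom &
                       insertions$pos >= d$start - window &
                       insertions$pos <= d$end + window, , drop = FALSE]
    if (nrow(cand) == 0) next
    r <- pmin(dl, cand$ins_length) / pmax(dl, cand$ins_length)
    ok[i] <- any(r >= size_match)
  }
  duplications$validated <- ok
  duplications
}
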