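# Synthetic genome / TEMR generator.
#
# The generator builds a background genome, seeds it with consensus-derived
# TE copies at controlled divergence, and plants TEMRs (DEL / DUP / INV /
# mCNV) whose repair mechanism is known by construction:
#   * HR events get a substitution-free window of exactly `mh_length` bp at
#     the same consensus offset in both copies, with forced mismatches at
#     both window edges so the realized microhomology equals the request;
#     the junction is placed uniformly within the window.
#   * NHE events get junction offsets at disjoint consensus positions, a
#     forced 0-4 bp identical tract, and optional 1-23 bp insertions.
# Mutation is substitution-only by default, which keeps microhomology
# tracts analytically controllable.

BASES <- c("A", "C", "G", "T")

#' Mutate a TE consensus into a diverged copy
#'
#' Applies i.i.d. substitutions at the given rate (no indels), optionally
#' 5'-truncates (emulating truncated LINE-1 copies) and reverse-complements
#' for minus-strand placement. Selected consensus positions can be
#' protected from substitution or forced to carry one; the substitution
#' log permits exact reconstruction.
#'
#' @param consensus a [te_consensus]
#' @param divergence substitution rate in \[0, 1)
#' @param strand "+" or "-"
#' @param truncate_5p number of consensus bases removed from the 5' end
#' @param seed RNG seed (NULL = current stream)
#' @param protect integer vector of 0-based consensus positions kept equal
#'   to the consensus
#' @param force_mismatch 0-based consensus positions forced to differ from
#'   the consensus
#' @return list with `sequence` (genomic orientation), `substitutions`
#'   (data.frame pos0 / ref / alt in consensus coordinates), and
#'   `realized_divergence`
#' @export
mutate_from_consensus <- function(consensus, divergence, strand = "+",
                                  truncate_5p = 0L, seed = NULL,
                                  protect = integer(0),
                                  force_mismatch = integer(0)) {
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  stopifnot(strand %in% c("+", "-"), truncate_5p < consensus$length)
  with_seed(seed, {
    b <- strsplit(consensus$sequence, "")[[1]]
    keep <- seq.int(truncate_5p + 1L, consensus$length)
    cand <- setdiff(keep - 1L, protect)          # 0-based positions
    hit <- cand[stats::runif(length(cand)) < divergence]
    hit <- sort(union(hit, intersect(force_mismatch, keep - 1L)))
    ref <- b[hit + 1L]
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
    b2 <- b
    b2[hit + 1L] <- alt
    seq_c <- paste(b2[keep], collapse = "")
    list(sequence = if (strand == "-") revcomp(seq_c) else seq_c,
         substitutions = data.frame(pos0 = hit, ref = ref, alt = alt,
                                    stringsAsFactors = FALSE),
         realized_divergence = length(hit) / length(keep))
  })
}

#' Hamming distance between equal-length strings
#' @param a,b character scalars of equal length
#' @return number of differing positions
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Build a synthetic reference chromosome with planted TE copies
#'
#' @param background_length chromosome length in bp
#' @param placements data.frame with columns `position` (0-based),
#'   `family` (consensus set key), `divergence`, `strand`, `truncate_5p`;
#'   an optional character column `sequence` supplies a pre-realized copy
#'   (its `divergence` is then taken as given). Extra columns are carried
#'   into the annotation.
#' @param consensus_set named list of [te_consensus] (see
#'   [synthetic_consensus_set()])
#' @param chrom chromosome name
#' @param gc background GC fraction
#' @param seed RNG seed
#' @return list with `chrom`, `sequence`, `annotation` (8-column BED-like
#'   table plus any extra placement columns) and `mutation_log`
#' @export
build_reference <- function(background_length, placements,
                            consensus_set = synthetic_consensus_set(),
                            chrom = "chrS", gc = 0.41, seed = NULL) {
  with_seed(seed, {
    geno <- random_dna(background_length, gc)
    n <- if (is.null(placements)) 0L else nrow(placements)
    ann <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), subfamily = character(0),
                      divergence = numeric(0), strand = character(0),
                      family = character(0), copy_id = character(0),
                      truncate_5p = integer(0))
    logs <- list()
    if (n > 0L) {
      seqs <- character(n); divs <- numeric(n); trunc <- integer(n)
      for (i in seq_len(n)) {
        p <- placements[i, , drop = FALSE]
        trunc[i] <- if (!is.null(p$truncate_5p)) p$truncate_5p else 0L
        if (!is.null(placements$sequence) && !is.na(p$sequence) &&
            nzchar(p$sequence)) {
          seqs[i] <- p$sequence
          divs[i] <- p$divergence
        } else {
          cs <- consensus_set[[p$family]]
          if (is.null(cs)) stop("no consensus for family ", p$family)
          m <- mutate_from_consensus(cs, p$divergence, p$strand, trunc[i])
          seqs[i] <- m$sequence
          divs[i] <- m$realized_divergence
          logs[[sprintf("te%04d", i)]] <- m$substitutions
        }
      }
      st <- placements$position
      en <- st + nchar(seqs)
      o <- order(st)
      if (any(st[o][-1] < en[o][-n]))
        stop("overlapping TE placements")
      if (any(en > background_length))
        stop("placement extends past chromosome end")
      for (i in seq_len(n)) geno <- seq_overwrite(geno, st[i], seqs[i])
      cons_names <- vapply(placements$family,
                           function(f) consensus_set[[f]]$name, "")
      ann <- data.frame(chrom = chrom, start = st, end = en,
                        subfamily = cons_names,
                        divergence = round(100 * divs, 2),
                        strand = placements$strand,
                        family = placements$family,
                        copy_id = sprintf("te%04d", seq_len(n)),
                        truncate_5p = trunc,
                        stringsAsFactors = FALSE)
      extra <- setdiff(names(placements),
                       c("position", "family", "divergence", "strand",
                         "truncate_5p", "sequence"))
      for (e in extra) ann[[e]] <- placements[[e]]
      ann <- ann[order(ann$start), , drop = FALSE]
      rownames(ann) <- NULL
    }
    list(chrom = chrom, sequence = geno, annotation = ann,
         mutation_log = logs)
  })
}

#' Specification for one planted TEMR
#'
#' Validates the mechanism contract: HR events require `mh_length >= 5`
#' and no junction insertion; NHE events require `mh_length <= 4`.
#'
#' @param sv_type one of DEL, DUP, INV, mCNV
#' @param mechanism HR or NHE
#' @param te_family TE class (must exist in the consensus set)
#' @param te_orientation direct or inverted
#' @param mh_length intended microhomology in bp
#' @param junction_insertion DNA string inserted at the junction (NHE only)
#' @param divergence_5p,divergence_3p per-copy substitution rates
#' @param copy_number total copies of the segment on the alternate
#'   haplotype (mCNV only; DUP is 2)
#' @param pair_id annotation pair to use (optional; otherwise the first
#'   eligible pair is taken)
#' @return a `plant_spec` list
#' @export
plant_spec <- function(sv_type, mechanism, te_family = "Alu",
                       te_orientation = if (sv_type == "INV") "inverted" else "direct",
                       mh_length = if (mechanism == "HR") 15L else 0L,
                       junction_insertion = "",
                       divergence_5p = 0.05, divergence_3p = 0.05,
                       copy_number = if (sv_type == "mCNV") 3L else 2L,
                       pair_id = NULL) {
  stopifnot(sv_type %in% c("DEL", "DUP", "INV", "mCNV"),
            mechanism %in% c("HR", "NHE"), mh_length >= 0)
  if (mechanism == "HR" && (mh_length < 5 || nzchar(junction_insertion)))
    stop("HR events need mh_length >= 5 and no junction insertion")
  if (mechanism == "NHE" && mh_length > 4)
    stop("NHE events need mh_length <= 4")
  if (sv_type == "INV" && te_orientation != "inverted")
    stop("inversions are mediated by TEs in opposite orientation")
  if (sv_type %in% c("DEL", "DUP", "mCNV") && te_orientation != "direct")
    stop(sv_type, " planting requires TEs in direct orientation")
  structure(list(sv_type = sv_type, mechanism = mechanism,
                 te_family = te_family, te_orientation = te_orientation,
                 mh_length = as.integer(mh_length),
                 junction_insertion = toupper(junction_insertion),
                 divergence_5p = divergence_5p, divergence_3p = divergence_3p,
                 copy_number = as.integer(copy_number), pair_id = pair_id),
            class = "plant_spec")
}

# Junction geometry: genomic breakpoint from a consensus junction offset.
# te row has start/end/strand/truncate_5p; `side` is "5p" (left TE) or
# "3p" (right TE); for inversions the right TE is on the minus strand and
# the breakpoint runs from its far end.
bp_from_offset <- function(te, j, sv_type, side) {
  t0 <- te$truncate_5p
  if (side == "5p" || sv_type != "INV") te$start + (j - t0)
  else te$end - (j - t0)
}

#' Plant one TEMR between an eligible TE pair
#'
#' The pair must carry forced-window metadata (`jwin_start`, `jwin_len`,
#' `pair_id` annotation columns) as produced by [simulate_temr_cohort()]'s
#' builder or by [make_te_pair()]. The junction is placed uniformly within
#' the shared window.
#'
#' @param reference list as returned by [build_reference()]
#' @param spec a [plant_spec]
#' @param seed RNG seed
#' @param flank_window context kept around the event in `alt_segment`
#' @return one-row data.frame (a TruthRecord): interval, sv_type,
#'   mechanism, mh_sequence, junction_insertion, TE ids, consensus
#'   junction position, plus the local alternate segment and its window
#' @export
plant_temr <- function(reference, spec, seed = NULL, flank_window = 600L) {
  ann <- reference$annotation
  if (is.null(ann$pair_id))
    stop("annotation carries no plantable TE pairs")
  cand <- ann[!is.na(ann$pair_id), , drop = FALSE]
  if (!is.null(spec$pair_id)) {
    cand <- cand[cand$pair_id == spec$pair_id, , drop = FALSE]
  } else {
    cand <- cand[cand$family == spec$te_family, , drop = FALSE]
  }
  pid <- unique(cand$pair_id)
  pair <- NULL
  for (p in pid) {
    rows <- cand[cand$pair_id == p, , drop = FALSE]
    if (nrow(rows) != 2L) next
    rows <- rows[order(rows$start), , drop = FALSE]
    ori <- if (rows$strand[1] == rows$strand[2]) "direct" else "inverted"
    if (ori != spec$te_orientation) next
    if (rows$jwin_len[1] < spec$mh_length) next
    pair <- rows
    break
  }
  if (is.null(pair))
    stop("no eligible TE pair for requested planting")
  te5 <- pair[1, ]; te3 <- pair[2, ]
  m <- spec$mh_length
  with_seed(seed, {
    # junction uniform within the ambiguity range [ws, ws + m]
    jrel <- sample.int(m + 1L, 1L) - 1L
    ws5 <- te5$jwin_start
    ws3 <- te3$jwin_start
    j5 <- ws5 + jrel
    j3 <- ws3 + jrel
    bp5 <- bp_from_offset(te5, j5, spec$sv_type, "5p")
    bp3 <- bp_from_offset(te3, j3, spec$sv_type, "3p")
    if (bp3 <= bp5) stop("degenerate planting: bp3 <= bp5")
    refseq <- reference$sequence
    mh_seq <- if (m > 0)
      seq_slice(refseq, te5$start + (ws5 - te5$truncate_5p),
                te5$start + (ws5 - te5$truncate_5p) + m) else ""
    truth <- data.frame(
      chrom = reference$chrom, start = bp5, end = bp3,
      sv_type = spec$sv_type, mechanism = spec$mechanism,
      family = spec$te_family, orientation = spec$te_orientation,
      mh_length = m, mh_sequence = mh_seq,
      junction_insertion = spec$junction_insertion,
      copy_number = spec$copy_number,
      te5_id = te5$copy_id, te3_id = te3$copy_id,
      consensus_junction_position =
        if (spec$mechanism == "HR") ws5 else NA_integer_,
      stringsAsFactors = FALSE)
    win_s <- max(0, te5$start - flank_window)
    win_e <- min(nchar(refseq), te3$end + flank_window)
    full_alt <- apply_truth_edit(refseq, truth)
    delta <- nchar(refseq) - nchar(full_alt)
    truth$window_start <- win_s
    truth$window_end <- win_e
    truth$alt_segment <- seq_slice(full_alt, win_s, win_e - delta)
    truth
  })
}

#' Apply a TruthRecord edit to a reference sequence
#'
#' Reconstructs the full alternate haplotype byte-for-byte: deletion with
#' optional junction insertion, tandem amplification to `copy_number`
#' copies, or inversion with optional planted junction complexities
#' (columns `cdel5`, `cdel3`, `cins5`, `cins3`).
#'
#' @param refseq reference chromosome string
#' @param truth one-row TruthRecord data.frame
#' @return alternate haplotype string
#' @export
apply_truth_edit <- function(refseq, truth) {
  g <- function(nm, def) {
    v <- truth[[nm]]
    if (is.null(v) || is.na(v)) def else v
  }
  bp5 <- truth$start; bp3 <- truth$end
  ins <- g("junction_insertion", "")
  left <- seq_slice(refseq, 0, bp5)
  right <- seq_slice(refseq, bp3, nchar(refseq))
  seg <- seq_slice(refseq, bp5, bp3)
  switch(truth$sv_type,
    DEL = paste0(left, ins, right),
    DUP = ,
    mCNV = {
      cn <- g("copy_number", 2L)
      paste0(left, seg, strrep(paste0(ins, seg), cn - 1L), right)
    },
    INV = {
      d5 <- g("cdel5", 0L); d3 <- g("cdel3", 0L)
      inner <- seq_slice(refseq, bp5 + d5, bp3 - d3)
      paste0(left, g("cins5", ""), revcomp(inner), g("cins3", ""), right)
    },
    stop("unknown sv_type ", truth$sv_type))
}

# ---- TE pair construction with forced junction windows -------------------

# Realize a TE pair (consensus-oriented surgery before strand flip):
# identical window content at the junction offsets, mismatches forced at
# both edges so the recomputed microhomology is exactly mh bp.
make_te_pair_seqs <- function(cons, mech, mh, ws5, ws3, div5, div3,
                              strand3 = "+") {
  L <- cons$length
  prot5 <- intersect((ws5 - 1L):(ws5 + mh), 0:(L - 1L))
  prot3 <- intersect((ws3 - 1L):(ws3 + mh), 0:(L - 1L))
  m5 <- mutate_from_consensus(cons, div5, "+", protect = prot5)
  m3 <- mutate_from_consensus(cons, div3, "+", protect = prot3)
  s5 <- m5$sequence
  s3 <- m3$sequence
  if (mh > 0) {
    s3 <- seq_overwrite(s3, ws3, seq_slice(s5, ws5, ws5 + mh))
  }
  force_diff <- function(s, pos, avoid) {
    cur <- seq_slice(s, pos, pos + 1L)
    if (cur != avoid) return(s)
    seq_overwrite(s, pos, sample(setdiff(BASES, avoid), 1L))
  }
  if (ws3 - 1L >= 0 && ws5 - 1L >= 0)
    s3 <- force_diff(s3, ws3 - 1L, seq_slice(s5, ws5 - 1L, ws5))
  if (ws3 + mh < L && ws5 + mh < L)
    s3 <- force_diff(s3, ws3 + mh, seq_slice(s5, ws5 + mh, ws5 + mh + 1L))
  list(seq5 = s5,
       seq3 = if (strand3 == "-") revcomp(s3) else s3,
       div5 = hamming(s5, cons$sequence) / L,
       div3 = hamming(s3, cons$sequence) / L)
}

#' Build a two-copy placement table for one plantable TE pair
#'
#' Convenience for unit tests: realizes both copies with the forced
#' window, and returns a `placements` data.frame for [build_reference()].
#'
#' @param cons a [te_consensus]
#' @param spec a [plant_spec]
#' @param at0 genomic position of the 5' copy
#' @param gap bp between the two copies
#' @param ws5,ws3 consensus window starts (NHE needs `ws5 + margin < ws3`;
#'   HR forces `ws3 == ws5`)
#' @param pair_id identifier stored in the annotation
#' @param seed RNG seed
#' @return placements data.frame with window metadata columns
#' @export
make_te_pair <- function(cons, spec, at0 = 1000L, gap = 1200L,
                         ws5 = 60L, ws3 = if (spec$mechanism == "HR") ws5 else ws5 + 80L,
                         pair_id = "p1", seed = NULL) {
  if (spec$mechanism == "HR" && ws3 != ws5)
    stop("HR windows sit at the same consensus offset")
  with_seed(seed, {
    strand3 <- if (spec$te_orientation == "inverted") "-" else "+"
    ps <- make_te_pair_seqs(cons, spec$mechanism, spec$mh_length, ws5, ws3,
                            spec$divergence_5p, spec$divergence_3p, strand3)
    data.frame(position = c(at0, at0 + cons$length + gap),
               family = spec$te_family,
               divergence = c(ps$div5, ps$div3),
               strand = c("+", strand3),
               truncate_5p = 0L,
               sequence = c(ps$seq5, ps$seq3),
               jwin_start = c(ws5, ws3),
               jwin_len = spec$mh_length,
               pair_id = pair_id,
               stringsAsFactors = FALSE)
  })
}

# ---- cohort generator ----------------------------------------------------

#' Simulate a genome-scale TEMR cohort with known truth
#'
#' Lays out one TE-pair cassette per event across a synthetic chromosome,
#' interleaves decoy TE copies, plants every event, and returns the
#' reference, annotation, per-event truth and the consensus set. Default
#' class mixture mirrors the observed callset composition: ~80% Alu /
#' 20% LINE-1, ~79% HR / 21% NHE, SV types dominated by deletions, all
#' inversions between inverted-orientation TEs.
#'
#' @param n_events number of planted TEMRs
#' @param background_length chromosome length (default 5 Mbp)
#' @param seed master seed; every downstream draw derives from it
#' @param p_family named probabilities for TE family
#' @param p_svtype named probabilities for SV type
#' @param p_hr probability an event is HR (inversions use `p_hr_inv`)
#' @param p_hr_inv HR fraction among inversions
#' @param divergence_range per-copy substitution-rate range for HR pairs
#' @param divergence_range_nhe substitution-rate range for NHE pairs
#'   (non-homologous repair acts between more diverged repeats)
#' @param n_decoys extra TE copies not involved in any event
#' @param p_insertion probability a blunt NHE junction carries an
#'   insertion (1-23 bp)
#' @param consensus_set consensus sequences to plant from
#' @return list: `reference` (chrom/sequence), `annotation`, `truth`,
#'   `consensus_set`
#' @export
simulate_temr_cohort <- function(n_events = 120L,
                                 background_length = 5e6,
                                 seed = 1L,
                                 p_family = c(Alu = 0.8, `LINE-1` = 0.2),
                                 p_svtype = c(DEL = 0.88, DUP = 0.06,
                                              INV = 0.04, mCNV = 0.02),
                                 p_hr = 0.79, p_hr_inv = 0.73,
                                 divergence_range = c(0.02, 0.10),
                                 divergence_range_nhe = c(0.08, 0.15),
                                 n_decoys = 80L,
                                 p_insertion = 0.35,
                                 consensus_set = synthetic_consensus_set()) {
  specs <- with_seed(derive_seed(seed, "specs"), {
    fam <- sample(names(p_family), n_events, TRUE, p_family)
    svt <- sample(names(p_svtype), n_events, TRUE, p_svtype)
    lapply(seq_len(n_events), function(i) {
      hrp <- if (svt[i] == "INV") p_hr_inv else p_hr
      mech <- if (stats::runif(1) < hrp) "HR" else "NHE"
      mh <- if (mech == "HR") 5L + stats::rpois(1, 12)
            else sample(0:4, 1L, prob = c(0.40, 0.30, 0.15, 0.10, 0.05))
      ins <- ""
      if (mech == "NHE" && mh == 0L && stats::runif(1) < p_insertion)
        ins <- random_dna(sample(1:23, 1L), gc = 0.5)
      dr <- if (mech == "HR") divergence_range else divergence_range_nhe
      dv <- stats::runif(2, dr[1], dr[2])
      plant_spec(svt[i], mech, te_family = fam[i],
                 mh_length = mh, junction_insertion = ins,
                 divergence_5p = dv[1], divergence_3p = dv[2],
                 pair_id = sprintf("ev%03d", i))
    })
  })
  placements <- with_seed(derive_seed(seed, "layout"), {
    rows <- list()
    widths <- numeric(0)
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      cons <- consensus_set[[sp$te_family]]
      L <- cons$length
      m <- sp$mh_length
      # junction windows clear of the poly-A tract and of TE edges
      lo <- if (sp$te_family == "Alu") 40L else 100L
      hi <- cons$polyA_span[1] - 40L - m
      ws5 <- sample(lo:hi, 1L)
      if (sp$mechanism == "HR") {
        # keep HR windows out of A/T homopolymer runs (linker A-tracts)
        for (try in 1:25) {
          b <- strsplit(seq_slice(cons$sequence, ws5, ws5 + m), "")[[1]]
          if (mean(b == "A") < 0.9 && mean(b == "T") < 0.9) break
          ws5 <- sample(lo:hi, 1L)
        }
      }
      ws3 <- if (sp$mechanism == "HR") ws5 else {
        pick <- (ws5 + m + 25L):hi
        if (length(pick) < 5L) { ws5 <- lo; pick <- (lo + m + 25L):hi }
        sample(pick, 1L)
      }
      strand3 <- if (sp$te_orientation == "inverted") "-" else "+"
      ps <- make_te_pair_seqs(cons, sp$mechanism, m, ws5, ws3,
                              sp$divergence_5p, sp$divergence_3p, strand3)
      target <- if (sp$te_family == "Alu")
        round(stats::runif(1, 400, 3500)) else round(stats::runif(1, 1800, 9000))
      gap <- max(60L, target - L)
      rows[[i]] <- data.frame(
        position = c(0, L + gap),           # cassette-local; shifted below
        family = sp$te_family,
        divergence = c(ps$div5, ps$div3),
        strand = c("+", strand3), truncate_5p = 0L,
        sequence = c(ps$seq5, ps$seq3),
        jwin_start = c(ws5, ws3), jwin_len = m,
        pair_id = sp$pair_id, stringsAsFactors = FALSE)
      widths[i] <- 2 * L + gap
    }
    # decoy copies, placed in their own slots between cassettes
    dec <- lapply(seq_len(n_decoys), function(k) {
      fam <- sample(names(p_family), 1L, prob = p_family)
      cons <- consensus_set[[fam]]
      data.frame(position = 0, family = fam,
                 divergence = stats::runif(1, divergence_range[1], 0.2),
                 strand = sample(c("+", "-"), 1L), truncate_5p = 0L,
                 sequence = NA_character_,
                 jwin_start = NA_integer_, jwin_len = NA_integer_,
                 pair_id = NA_character_, stringsAsFactors = FALSE)
    })
    dec_w <- vapply(dec, function(d) consensus_set[[d$family]]$length, 0)
    blocks <- c(rows, dec)
    bw <- c(widths, dec_w)
    ord <- sample(length(blocks))           # interleave decoys
    free <- background_length - sum(bw) - 200
    if (free < length(blocks) + 1)
      stop("background too short for requested cohort")
    g <- stats::runif(length(blocks) + 1L)
    gaps <- floor(free * g / sum(g))
    cur <- 100
    out <- list()
    for (k in seq_along(ord)) {
      cur <- cur + gaps[k]
      b <- blocks[[ord[k]]]
      b$position <- b$position + cur
      out[[k]] <- b
      cur <- cur + bw[ord[k]]
    }
    do.call(rbind, out)
  })
  ref <- build_reference(background_length, placements, consensus_set,
                         seed = derive_seed(seed, "background"))
  truth <- do.call(rbind, lapply(seq_along(specs), function(i) {
    plant_temr(ref, specs[[i]], seed = derive_seed(seed, specs[[i]]$pair_id))
  }))
  rownames(truth) <- NULL
  list(reference = list(chrom = ref$chrom, sequence = ref$sequence),
       annotation = ref$annotation, truth = truth,
       consensus_set = consensus_set)
}

# ---- simulated caller output --------------------------------------------

#' Default caller panel
#'
#' Three short-read and three long-read callers with the rank order used
#' for rank-based merging.
#' @return data.frame with caller, technology, rank
#' @export
default_callers <- function() {
  data.frame(caller = c("Manta", "DELLY", "LUMPY", "pbsv", "Sniffles", "SVIM"),
             technology = c("SRS", "SRS", "SRS", "LRS", "LRS", "LRS"),
             rank = c(1L, 2L, 3L, 1L, 2L, 3L),
             stringsAsFactors = FALSE)
}

#' Simulate per-caller SV call tables from a truth set
#'
#' Each true event appears in each caller's table with Gaussian breakpoint
#' jitter (rounded, caller-specific sd), Poisson support counts, and a
#' depth ratio consistent with the SV type (DEL ~0.5, DUP ~1.5, INV ~1.0,
#' mCNV above, Gaussian noise sd `rd_sd`). False positives are random
#' intervals not overlapping truth, private to one caller.
#'
#' @param truth TruthRecord table ([simulate_temr_cohort()] or
#'   [plant_temr()])
#' @param genome_length chromosome length (for false-positive placement)
#' @param callers caller panel ([default_callers()]); an optional
#'   `jitter_sd` column overrides `jitter_sd`
#' @param jitter_sd breakpoint jitter sd in bp (scalar)
#' @param fp_rate false positives per Mbp per caller
#' @param support list: `sr_mean`, `pr_mean`, `rs_mean`, `rd_sd`,
#'   `detect_p`, and optionally `fixed` (named list of support values
#'   forced for every event of every caller, e.g. `list(SR=4, PR=9)`)
#' @param sample_id sample name
#' @param seed RNG seed
#' @return named list of per-caller data.frames (chrom, start, end,
#'   sv_type, caller, technology, PR, SR, RS, RD, sample)
#' @export
simulate_callsets <- function(truth, genome_length,
                              callers = default_callers(),
                              jitter_sd = 0, fp_rate = 0,
                              support = list(), sample_id = "S1",
                              seed = NULL) {
  stopifnot(jitter_sd >= 0, fp_rate >= 0)
  sup <- utils::modifyList(list(sr_mean = 12, pr_mean = 20, rs_mean = 12,
                                rd_sd = 0.05, detect_p = 1, fixed = NULL),
                           support)
  rd_base <- function(svt, cn) {
    switch(svt, DEL = 0.5, DUP = 1.5, INV = 1.0,
           mCNV = 1 + 0.5 * (cn - 1), 1.0)
  }
  with_seed(seed, {
    out <- list()
    for (ci in seq_len(nrow(callers))) {
      cl <- callers[ci, ]
      sd_c <- if (!is.null(callers$jitter_sd)) cl$jitter_sd else jitter_sd
      n <- nrow(truth)
      keep <- stats::runif(n) < sup$detect_p
      st <- truth$start + round(stats::rnorm(n, 0, sd_c))
      en <- truth$end + round(stats::rnorm(n, 0, sd_c))
      bad <- en <= st
      en[bad] <- st[bad] + 1
      svt <- ifelse(truth$sv_type == "mCNV", "DUP", truth$sv_type)
      is_srs <- cl$technology == "SRS"
      SR <- if (is_srs) stats::rpois(n, sup$sr_mean) else NA_integer_
      PR <- if (is_srs) stats::rpois(n, sup$pr_mean) else NA_integer_
      RS <- if (!is_srs) stats::rpois(n, sup$rs_mean) else NA_integer_
      if (!is.null(sup$fixed)) {
        for (nm in names(sup$fixed)) assign(nm, rep(sup$fixed[[nm]], n))
      }
      RD <- mapply(rd_base, truth$sv_type, truth$copy_number) +
        stats::rnorm(n, 0, sup$rd_sd)
      df <- data.frame(chrom = truth$chrom, start = st, end = en,
                       sv_type = svt, caller = cl$caller,
                       technology = cl$technology,
                       PR = PR, SR = SR, RS = RS, RD = round(RD, 3),
                       sample = sample_id, stringsAsFactors = FALSE)[keep, ]
      n_fp <- stats::rpois(1, fp_rate * genome_length / 1e6)
      if (n_fp > 0) {
        fps <- list()
        tries <- 0
        while (length(fps) < n_fp && tries < 50 * n_fp) {
          tries <- tries + 1
          len <- sample(100:5000, 1L)
          s <- sample.int(genome_length - len, 1L)
          if (any(overlap_bp(s, s + len, truth$start, truth$end) > 0))
            next
          t <- sample(c("DEL", "DUP", "INV"), 1L)
          fps[[length(fps) + 1L]] <- data.frame(
            chrom = truth$chrom[1], start = s, end = s + len, sv_type = t,
            caller = cl$caller, technology = cl$technology,
            PR = if (is_srs) stats::rpois(1, sup$pr_mean) else NA_integer_,
            SR = if (is_srs) stats::rpois(1, sup$sr_mean) else NA_integer_,
            RS = if (!is_srs) stats::rpois(1, sup$rs_mean) else NA_integer_,
            RD = round(rd_base(t, 2) + stats::rnorm(1, 0, sup$rd_sd), 3),
            sample = sample_id, stringsAsFactors = FALSE)
        }
        df <- rbind(df, do.call(rbind, fps))
      }
      rownames(df) <- NULL
      out[[cl$caller]] <- df
    }
    out
  })
}
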