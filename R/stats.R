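# Enrichment and association statistics: TE density with random-window
# controls, callable-region density, read-depth copy number, ancestral
# deletion matching, genic annotation, and the classical tests.

#' TE density around an SV
#'
#' Percentage of the window (default 50 kbp: 25 kbp on either side of the
#' SV midpoint) covered by TEs of the given family. Windows clipped at
#' chromosome ends renormalize the denominator to the bases actually
#' evaluated.
#'
#' @param sv one-row data.frame (chrom/start/end)
#' @param te_annotation TE annotation table
#' @param family TE class to measure
#' @param window total window size in bp
#' @param chrom_length chromosome length for clipping (NULL = no right
#'   clip)
#' @return percent in \[0, 100\]
#' @export
te_density <- function(sv, te_annotation, family, window = 50000L,
                       chrom_length = NULL) {
  mid <- floor((sv$start + sv$end) / 2)
  if (!is.null(chrom_length) && (mid < 0 || mid > chrom_length))
    stop("SV midpoint off chromosome")
  ws <- max(0, mid - window / 2)
  we <- mid + window / 2
  if (!is.null(chrom_length)) we <- min(chrom_length, we)
  ann <- te_annotation[te_annotation$chrom == sv$chrom &
                       te_annotation$family == family, , drop = FALSE]
  cov <- covered_bp(ws, we, ann$start, ann$end)
  100 * cov / (we - ws)
}

#' Sample random control windows with a minimum TE count
#'
#' Rejection-samples fixed-size windows uniformly over the genome until
#' `n` windows each fully contain at least `min_te_count` TEs of the
#' family, and returns their densities.
#'
#' @param n number of control windows
#' @param genome_sizes named numeric vector of chromosome lengths
#' @param te_annotation TE annotation table
#' @param family TE class
#' @param min_te_count minimum TEs per window
#' @param window window size in bp
#' @param seed RNG seed
#' @param max_iter sampling cap (default 1000 n)
#' @return numeric vector of `n` densities (percent)
#' @export
sample_control_windows <- function(n, genome_sizes, te_annotation, family,
                                   min_te_count = 2L, window = 50000L,
                                   seed = NULL, max_iter = 1000L * n) {
  stopifnot(n >= 1)
  ann <- te_annotation[te_annotation$family == family, , drop = FALSE]
  if (nrow(ann) < min_te_count)
    stop("family too rare for control sampling: ", family)
  with_seed(seed, {
    dens <- numeric(0)
    it <- 0L
    while (length(dens) < n && it < max_iter) {
      it <- it + 1L
      chr <- sample(names(genome_sizes), 1L,
                    prob = genome_sizes / sum(genome_sizes))
      if (genome_sizes[[chr]] <= window) next
      ws <- sample.int(genome_sizes[[chr]] - window, 1L)
      we <- ws + window
      a <- ann[ann$chrom == chr, , drop = FALSE]
      inside <- sum(a$start >= ws & a$end <= we)
      if (inside < min_te_count) next
      dens <- c(dens, 100 * covered_bp(ws, we, a$start, a$end) / window)
    }
    if (length(dens) < n)
      stop(sprintf("control sampling failed: %d/%d windows after %d draws",
                   length(dens), n, it))
    dens
  })
}

#' Welch's unequal-variance t test
#'
#' @param x,y numeric samples (length >= 2 each)
#' @return list: `t`, `df` (Welch-Satterthwaite), `p` (two-sided),
#'   `degenerate` (TRUE when both samples are constant and equal, in
#'   which case t = 0 and p = 1)
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    stop("welch_t: zero variance with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Exact two-tailed binomial test
#'
#' Small-point-probability method: the p-value sums the probabilities of
#' all outcomes no more likely than the observed count.
#'
#' @param k observed successes
#' @param n trials (> 0)
#' @param p0 null success probability
#' @return two-tailed p-value
#' @export
binom_two_tailed <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("binom_two_tailed: n must be positive")
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  stats::binom.test(k, n, p0, alternative = "two.sided")$p.value
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' @param a,b,c,d cell counts, table rows (a, b) / (c, d)
#' @return two-tailed p-value
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("fisher_exact_2x2: all-zero table")
  stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
}

#' Spearman rank correlation
#'
#' Average ranks for ties; p-value from the t approximation.
#'
#' @param x,y numeric vectors, length >= 3
#' @return list: `rho`, `p`, `degenerate` flag for constant input
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Event density over callable regions
#'
#' Events per `per` bp (default 10 Mbp) of callable sequence, per
#' chromosome and genome-wide; only events whose midpoint falls in
#' callable space are counted.
#'
#' @param events data.frame (chrom/start/end)
#' @param callable data.frame of disjoint callable intervals
#'   (chrom/start/end)
#' @param per denominator unit in bp
#' @return list: `per_chrom` data.frame (chrom, n, callable_bp, density),
#'   `genome` density
#' @export
callable_density <- function(events, callable, per = 1e7) {
  if (nrow(callable) == 0) stop("empty callable set")
  mid <- floor((events$start + events$end) / 2)
  in_call <- vapply(seq_len(nrow(events)), function(i) {
    cc <- callable[callable$chrom == events$chrom[i], , drop = FALSE]
    any(cc$start <= mid[i] & mid[i] < cc$end)
  }, TRUE)
  chroms <- unique(callable$chrom)
  per_chrom <- do.call(rbind, lapply(chroms, function(ch) {
    bp <- sum(callable$end[callable$chrom == ch] -
              callable$start[callable$chrom == ch])
    n <- sum(in_call & events$chrom == ch)
    data.frame(chrom = ch, n = n, callable_bp = bp,
               density = n / bp * per)
  }))
  tot_bp <- sum(per_chrom$callable_bp)
  list(per_chrom = per_chrom,
       genome = sum(per_chrom$n) / tot_bp * per)
}

#' Copy number from read depth
#'
#' Divides the mean per-base depth over the locus by the genome-wide mean
#' depth; integer copy number is `round(2 * ratio)`. Loci with less than
#' `min_unique` of their length outside TE annotation are flagged
#' `low_unique` (read-depth estimates there are unreliable).
#'
#' @param depth numeric vector of per-base depths over the locus
#' @param genome_mean genome-wide mean depth (> 0)
#' @param locus optional c(start, end) of the locus (for the unique-
#'   sequence check)
#' @param te_annotation optional annotation to compute the unique fraction
#' @param chrom chromosome of the locus
#' @param min_unique minimum unique-sequence fraction
#' @return list: `ratio`, `copy_number`, `unique_fraction`, `low_unique`
#' @export
depth_copy_number <- function(depth, genome_mean, locus = NULL,
                              te_annotation = NULL, chrom = NULL,
                              min_unique = 0.07) {
  if (genome_mean <= 0) stop("genome mean depth must be positive")
  stopifnot(all(depth >= 0))
  ratio <- mean(depth) / genome_mean
  uf <- NA_real_
  if (!is.null(locus) && !is.null(te_annotation)) {
    ann <- te_annotation
    if (!is.null(chrom)) ann <- ann[ann$chrom == chrom, , drop = FALSE]
    cov <- covered_bp(locus[1], locus[2], ann$start, ann$end)
    uf <- 1 - cov / (locus[2] - locus[1])
  }
  list(ratio = ratio, copy_number = as.integer(round(2 * ratio)),
       unique_fraction = uf,
       low_unique = !is.na(uf) && uf < min_unique)
}

#' Match ancestral deletions to present-day insertions
#'
#' Pairs a deletion (relative to an outgroup genome) with an insertion
#' (relative to the reference) when the insertion point falls within
#' `window` bp of the deletion interval and the two sizes agree to the
#' `size_match` fraction.
#'
#' @param deletions data.frame: chrom, start, end, size
#' @param insertions data.frame: chrom, pos, size
#' @param window search window in bp (the consensus length is the
#'   conventional choice)
#' @param size_match minimum min(size)/max(size) ratio
#' @return data.frame of matched pairs with the size ratio
#' @export
match_ancestral <- function(deletions, insertions, window,
                            size_match = 0.9) {
  out <- list()
  for (i in seq_len(nrow(deletions))) {
    d <- deletions[i, ]
    cand <- insertions[insertions$chrom == d$chrom &
                       insertions$pos >= d$start - window &
                       insertions$pos <= d$end + window, , drop = FALSE]
    if (nrow(cand) == 0) next
    r <- pmin(d$size, cand$size) / pmax(d$size, cand$size)
    ok <- which(r >= size_match)
    for (j in ok) {
      out[[length(out) + 1L]] <- data.frame(
        del_chrom = d$chrom, del_start = d$start, del_end = d$end,
        del_size = d$size, ins_pos = cand$pos[j], ins_size = cand$size[j],
        size_ratio = r[j])
    }
  }
  if (length(out) == 0)
    return(data.frame(del_chrom = character(0), del_start = numeric(0),
                      del_end = numeric(0), del_size = numeric(0),
                      ins_pos = numeric(0), ins_size = numeric(0),
                      size_ratio = numeric(0)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genic annotation of SVs
#'
#' Assigns each SV one of four categories with precedence exonic >
#' intronic > proximal > intergenic: exonic overlaps any exon; intronic
#' overlaps a gene body without touching an exon; proximal lies within
#' `proximal` bp of a gene; intergenic otherwise. Categories partition
#' the callset.
#'
#' @param svs data.frame (chrom/start/end)
#' @param genes data.frame of gene spans (chrom/start/end/gene)
#' @param exons data.frame of exon spans (chrom/start/end/gene)
#' @param proximal distance in bp defining gene-proximal
#' @return `svs` with a `genic_category` factor column
#' @export
annotate_genic <- function(svs, genes, exons, proximal = 5000L) {
  lv <- c("exonic", "intronic", "proximal", "intergenic")
  cat <- character(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    s <- svs$start[i]; e <- svs$end[i]; ch <- svs$chrom[i]
    ex <- exons[exons$chrom == ch, , drop = FALSE]
    gn <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(ex) > 0 && any(overlap_bp(s, e, ex$start, ex$end) > 0))
      cat[i] <- "exonic"
    else if (nrow(gn) > 0 && any(overlap_bp(s, e, gn$start, gn$end) > 0))
      cat[i] <- "intronic"
    else if (nrow(gn) > 0 &&
             any(overlap_bp(s - proximal, e + proximal,
                            gn$start, gn$end) > 0))
      cat[i] <- "proximal"
    else cat[i] <- "intergenic"
  }
  svs$genic_category <- factor(cat, levels = lv)
  svs
}

#' Genic enrichment of TEMRs versus non-TEMRs
#'
#' Two-tailed Fisher's exact test on the 2x2 table of genic (any category
#' other than intergenic) versus intergenic counts.
#'
#' @param temr_categories,nontemr_categories factors from
#'   [annotate_genic()]
#' @return list: `table`, `p`
#' @export
genic_enrichment <- function(temr_categories, nontemr_categories) {
  g1 <- sum(temr_categories != "intergenic")
  i1 <- sum(temr_categories == "intergenic")
  g2 <- sum(nontemr_categories != "intergenic")
  i2 <- sum(nontemr_categories == "intergenic")
  list(table = matrix(c(g1, i1, g2, i2), 2, 2, byrow = TRUE,
                      dimnames = list(c("TEMR", "non-TEMR"),
                                      c("genic", "intergenic"))),
       p = fisher_exact_2x2(g1, i1, g2, i2))
}
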