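# Independent oracles used to check the package's own implementations.
# These deliberately take the slow, exhaustive route.

# Affine-gap Smith-Waterman by full dynamic programming (Gotoh).
# A gap of length L costs open + L * ext.
sw_oracle <- function(q, s, match = 5, mismatch = -4, open = 10, ext = 0.5) {
  qb <- strsplit(q, "")[[1]]; sb <- strsplit(s, "")[[1]]
  n <- length(qb); m <- length(sb)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (qb[i - 1] == sb[j - 1]) match else mismatch
      prev <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1], 0)
      M[i, j] <- prev + sub
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Microhomology by exhaustive breakpoint-shift enumeration: the number of
# equivalent breakpoint pairs (k such that the shifted edit reconstructs
# the identical alternate allele) minus one. Independent of the package's
# character-comparison route.
mh_oracle <- function(refseq, bp5, bp3, sv_type = "DEL", max_shift = 60L) {
  edit <- function(b5, b3) {
    tr <- data.frame(start = b5, end = b3, sv_type = sv_type,
                     junction_insertion = "", copy_number = 2L)
    apply_truth_edit(refseq, tr)
  }
  alt0 <- edit(bp5, bp3)
  eq <- function(k) {
    b5 <- bp5 + k
    b3 <- if (sv_type == "INV") bp3 - k else bp3 + k
    if (b5 < 0 || b3 <= b5 || b3 > nchar(refseq)) return(FALSE)
    identical(edit(b5, b3), alt0)
  }
  r <- 0L
  while (r < max_shift && eq(r + 1L)) r <- r + 1L
  l <- 0L
  while (l < max_shift && eq(-(l + 1L))) l <- l + 1L
  l + r
}

# Exact two-tailed Fisher p for a 2x2 table by full hypergeometric
# enumeration (small-point-probability rule).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - r2):min(r1, c1)
  p <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p0 <- p[xs == a]
  sum(p[p <= p0 * (1 + 1e-7)])
}

# Exact two-tailed binomial p by direct enumeration.
binom_oracle <- function(k, n, p0 = 0.5) {
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

# Welch statistic and df from the textbook formulas.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  c(t = t, df = df)
}

# O(n^2) single-linkage clustering of intervals at a reciprocal-overlap
# threshold, by explicit connected components.
ro_cluster_oracle <- function(df, thr) {
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || df$chrom[i] != df$chrom[j] ||
        df$sv_type[i] != df$sv_type[j]) next
    ov <- max(0, min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]))
    ro <- min(ov / (df$end[i] - df$start[i]), ov / (df$end[j] - df$start[j]))
    adj[i, j] <- ro >= thr
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}
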