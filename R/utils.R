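# Shared low-level helpers: DNA strings, intervals, seeded RNG.
# Coordinates are 0-based half-open everywhere inside the package;
# conversion to 1-based happens only at FASTA/VCF I/O boundaries.

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over the alphabet A/C/G/T (case preserved
#'   as upper case).
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Complement (without reversal) of a DNA string
#' @param x character scalar
#' @return complemented string
#' @keywords internal
dna_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Random DNA of a given length and GC fraction
#'
#' Draws i.i.d. bases with P(G) = P(C) = gc/2. Uses the current RNG
#' stream; wrap in [with_seed()] for reproducibility.
#'
#' @param n number of bases
#' @param gc GC fraction in \[0, 1\] (default 0.41, roughly genomic)
#' @return character scalar of length `n`
#' @export
random_dna <- function(n, gc = 0.41) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code does not disturb the
#' caller's stream. `seed = NULL` runs on the current stream.
#'
#' @param seed integer seed or NULL
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a parent seed and a stage label, staying
# well below .Machine$integer.max.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147480000)
}

#' Substring by 0-based half-open coordinates
#' @param x character scalar
#' @param start0,end0 0-based half-open bounds
#' @return the slice as a character scalar
#' @export
seq_slice <- function(x, start0, end0) {
  stopifnot(start0 >= 0, end0 >= start0, end0 <= nchar(x))
  if (end0 == start0) return("")
  substr(x, start0 + 1L, end0)
}

# Replace x[start0, end0) with `value` (same length required).
seq_overwrite <- function(x, start0, value) {
  n <- nchar(value)
  if (n == 0L) return(x)
  paste0(seq_slice(x, 0L, start0), value, seq_slice(x, start0 + n, nchar(x)))
}

#' Pairwise overlap in bp of two half-open intervals
#' @keywords internal
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Merge a set of half-open intervals (two-column matrix or df with
# start/end) into disjoint sorted intervals.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      k <- length(out_s)
      if (start[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], end[i])
      } else {
        out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
      }
    }
  }
  data.frame(start = out_s, end = out_e)
}

# Total bp of [s,e) covered by the interval set (start/end vectors),
# after merging overlaps.
covered_bp <- function(s, e, set_start, set_end) {
  if (length(set_start) == 0L) return(0)
  m <- merge_intervals(set_start, set_end)
  sum(overlap_bp(s, e, m$start, m$end))
}

#' GC content of a DNA string, in percent
#'
#' @param seq non-empty character scalar
#' @return 100 * (#G + #C) / length
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("gc_content: empty sequence")
  b <- strsplit(toupper(seq), "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}
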