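# TE consensus containers and the bundled synthetic consensus set.

#' Construct a TE consensus object
#'
#' A consensus carries the sequence plus structural metadata used by the
#' mechanism classifier: monomer boundaries (for dimeric Alu-like
#' elements), the 3' adenosine-rich tract, and optional RNA-pol-III
#' box annotations. All intervals are 0-based half-open on the consensus.
#'
#' @param name identifier (e.g. "AluY-syn")
#' @param sequence DNA string over A/C/G/T
#' @param family TE class label: "Alu", "LINE-1", or other
#' @param monomer_bounds named list of half-open intervals
#'   (`left`, `linker`, `right`) or NULL for monomeric elements
#' @param polyA_span half-open interval of the poly-A tract, or NULL
#' @param boxes named list of half-open intervals (A_box, B_box,
#'   Aprime_box, ...) or NULL
#' @return an object of class `te_consensus`
#' @export
te_consensus <- function(name, sequence, family,
                         monomer_bounds = NULL, polyA_span = NULL,
                         boxes = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  if (grepl("[^ACGT]", toupper(sequence)))
    stop("consensus sequence must be over {A,C,G,T}")
  L <- nchar(sequence)
  chk <- function(iv) {
    stopifnot(length(iv) == 2L, iv[1] >= 0, iv[2] <= L, iv[1] < iv[2])
  }
  if (!is.null(monomer_bounds)) {
    lapply(monomer_bounds, chk)
    b <- do.call(rbind, monomer_bounds)
    o <- order(b[, 1])
    if (any(b[o, 1][-1] < b[o, 2][-nrow(b)]))
      stop("monomer_bounds must be disjoint and ordered")
  }
  if (!is.null(polyA_span)) chk(polyA_span)
  if (!is.null(boxes)) lapply(boxes, chk)
  structure(list(name = name, sequence = toupper(sequence),
                 family = family, length = L,
                 monomer_bounds = monomer_bounds,
                 polyA_span = polyA_span, boxes = boxes),
            class = "te_consensus")
}

#' @export
print.te_consensus <- function(x, ...) {
  cat(sprintf("<te_consensus> %s (%s), %d bp\n", x$name, x$family, x$length))
  if (!is.null(x$monomer_bounds))
    cat("  monomers:",
        paste(names(x$monomer_bounds),
              vapply(x$monomer_bounds,
                     function(i) sprintf("[%d,%d)", i[1], i[2]), ""),
              collapse = " "), "\n")
  if (!is.null(x$polyA_span))
    cat(sprintf("  polyA: [%d,%d)\n", x$polyA_span[1], x$polyA_span[2]))
  invisible(x)
}

#' Bundled synthetic TE consensus set
#'
#' Generates, deterministically, a synthetic stand-in for the real Alu and
#' LINE-1 consensus sequences (which are third-party data and are not
#' bundled). The Alu-like element is a 311 bp dimer: a 132 bp left monomer,
#' a 38 bp A-rich linker, a right monomer derived from the left one at ~12%
#' divergence (mirroring the homology between real Alu arms), and a 30 bp
#' poly-A tail. A-box/B-box-like intervals are annotated in the left
#' monomer with an A'-box at the homologous right-monomer offset. The
#' LINE-1-like element is monomeric with a 3' poly-A tract; its 1,500 bp
#' default length is a scaled-down stand-in for the ~6 kbp element.
#'
#' @param seed integer seed; the default yields the package's reference set
#' @param l1_length length of the LINE-1-like consensus
#' @return named list of [te_consensus] objects (`Alu`, `LINE-1`)
#' @export
synthetic_consensus_set <- function(seed = 7L, l1_length = 1500L) {
  with_seed(seed, {
    left <- random_dna(132, gc = 0.55)
    # left monomer carries the box-like motifs; fix their content so the
    # consensus is stable across monomer mutation draws
    linker <- paste0(strrep("A", 8), random_dna(22, gc = 0.5), strrep("A", 8))
    right_core <- mutate_string(seq_slice(left, 0, 111), 0.12)
    alu_seq <- paste0(left, linker, right_core, strrep("A", 30))
    alu <- te_consensus(
      name = "AluY-syn", sequence = alu_seq, family = "Alu",
      monomer_bounds = list(left = c(0L, 132L), linker = c(132L, 170L),
                            right = c(170L, 281L)),
      polyA_span = c(281L, 311L),
      boxes = list(A_box = c(34L, 55L), B_box = c(77L, 98L),
                   Aprime_box = c(204L, 225L)))
    body <- random_dna(l1_length - 30L, gc = 0.42)
    l1 <- te_consensus(
      name = "L1-syn", sequence = paste0(body, strrep("A", 30)),
      family = "LINE-1",
      polyA_span = c(l1_length - 30L, l1_length))
    list("Alu" = alu, "LINE-1" = l1)
  })
}

# Substitute each position independently with probability `rate`
# (helper for consensus construction; uses current RNG stream).
mutate_string <- function(x, rate) {
  b <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) {
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  }
  paste(b, collapse = "")
}

#' Write a consensus set to FASTA with metadata headers
#'
#' Structural metadata is serialized as `key=a-b` tokens on the header
#' line so a set round-trips through plain FASTA.
#' @param set named list of [te_consensus]
#' @param path output file
#' @export
write_consensus_fasta <- function(set, path) {
  lines <- character(0)
  for (fam in names(set)) {
    cs <- set[[fam]]
    meta <- c(sprintf("family=%s", cs$family))
    f <- function(nm, iv) sprintf("%s=%d-%d", nm, iv[1], iv[2])
    if (!is.null(cs$monomer_bounds))
      meta <- c(meta, mapply(f, names(cs$monomer_bounds), cs$monomer_bounds))
    if (!is.null(cs$polyA_span)) meta <- c(meta, f("polyA", cs$polyA_span))
    if (!is.null(cs$boxes))
      meta <- c(meta, mapply(f, names(cs$boxes), cs$boxes))
    lines <- c(lines, paste0(">", cs$name, " ", paste(meta, collapse = " ")),
               cs$sequence)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a consensus set written by [write_consensus_fasta()]
#' @param path FASTA file with metadata headers
#' @return named list of [te_consensus] (names are families)
#' @export
read_consensus_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(xs)) {
    hdr <- strsplit(names(xs)[i], "\\s+")[[1]]
    nm <- hdr[1]
    kv <- hdr[-1]
    vals <- sub("^[^=]+=", "", kv)
    keys <- sub("=.*$", "", kv)
    pick <- function(k) {
      j <- match(k, keys)
      if (is.na(j)) return(NULL)
      as.integer(strsplit(vals[j], "-")[[1]])
    }
    mb <- Filter(Negate(is.null),
                 list(left = pick("left"), linker = pick("linker"),
                      right = pick("right")))
    if (length(mb) == 0L) mb <- NULL
    bx <- Filter(Negate(is.null),
                 list(A_box = pick("A_box"), B_box = pick("B_box"),
                      Aprime_box = pick("Aprime_box")))
    if (length(bx) == 0L) bx <- NULL
    fam <- if ("family" %in% keys) vals[match("family", keys)] else nm
    out[[fam]] <- te_consensus(nm, as.character(xs[[i]]), fam,
                               monomer_bounds = mb, polyA_span = pick("polyA"),
                               boxes = bx)
  }
  out
}
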