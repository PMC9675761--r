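---
title: "Discovering and typing transposable element-mediated rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and typing transposable element-mediated rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temrkit)
```

## The problem

Transposable elements (TEs) — above all the ~300 bp dimeric *Alu* element
and the ~6 kbp LINE-1 — pepper mammalian genomes with hundreds of
thousands of near-identical copies. Two copies of the same class can act
as substrates for ectopic DNA repair, and the resulting structural
variants (deletions, duplications, inversions, and higher-order
amplifications) are called transposable element-mediated rearrangements
(TEMRs): SVs whose two breakpoints fall in *distinct* TE copies of the
*same* element class.

`temrkit` implements the full discovery-and-characterization chain for
such events, and ships a synthetic-genome generator that plants TEMRs of
known mechanism so that every stage can be scored against ground truth:

1. **ensemble merging** — filter per-caller SV calls and merge them by
   reciprocal overlap with rank-based breakpoint retention;
2. **TEMR categorization** — intersect breakpoints with a
   RepeatMasker-style annotation;
3. **junction reconstruction** — compute breakpoint microhomology from
   reference sequence;
4. **mechanism inference** — align junction flanks to a TE consensus and
   label each event homologous recombination (HR) or non-homologous
   repair (NHE);
5. **statistics** — density enrichment, GC content, copy number from read
   depth, genic intersection, and the classical exact tests.

## Microhomology as junction ambiguity

For a deletion with breakpoints $b_5 < b_3$ on the reference $R$, the
junction is *ambiguous* wherever the two flanks share sequence: the right
extension is the maximal $k$ with $R[b_5 .. b_5+k) = R[b_3 .. b_3+k)$ and
the left extension the maximal $j$ with $R[b_5-j .. b_5) = R[b_3-j ..
b_3)$. The microhomology is the union of the two, every breakpoint pair
inside the ambiguity range reconstructs a byte-identical alternate
allele, and the range has length $\mathrm{mh}+1$. Only perfect identity
counts; a separate "homeology" scan reports the longest window that stays
at or above 90% identity, as an auxiliary annotation. For inversions the
comparison runs against the complement of the partner flank read in the
opposite direction; by strand symmetry both inversion junctions carry the
same ambiguity. Junction insertions (taken from the alternate allele when
one is available) never contribute to microhomology.

The test suite checks this definition against an independent oracle that
*enumerates* breakpoint shifts and compares reconstructed alleles by
string equality, on a thousand random instances.

## The HR/NHE classifier

Junction flanks are extracted in consensus orientation — the flank
covering the consensus prefix up to the junction, and the flank covering
the suffix from the junction on — after moving the breakpoints to their
outer representation (5' junction at the right edge of the ambiguity
range, 3' at the left edge) so that *each flank contains the
microhomology tract*. Both flanks are locally aligned to the family
consensus. Writing $e_1$ for the consensus end of the 5'-flank alignment
and $s_2$ for the consensus start of the 3'-flank alignment, the
*consensus overlap* is $e_1 - s_2$, and:

* **HR** — overlap at least 1 bp **and** exactly equal to the
  microhomology length: the chimeric TE left behind reconstructs one
  full-length element with the microhomology at the junction.
* **Alu monomer retry** — *Alu* elements are dimers of two homologous
  monomers, so a chimera can recombine between homologous positions of
  *different* monomers. Events that fail the full-consensus test but
  retain microhomology are re-tested in monomer-local coordinates: the
  monomer containing $e_1$ and the monomer containing $s_2$ are read off
  the full-consensus alignments, and, if that fails, each flank is
  realigned against each monomer separately. A left-to-right cross leaves
  a single-monomer (~150 bp) chimera; a right-to-left cross leaves a
  three-monomer (~450 bp) chimera.
* **NHE** — flanks that fail to overlap along the consensus
  ($e_1 - s_2 \le 0$). Note this deliberately includes events with short
  (1–4 bp) microhomology: restricting NHE to zero-microhomology events
  would push most end-joining junctions into manual review, which
  contradicts both the observed NHE microhomology distribution and the
  fraction of events that can be typed systematically.
* **MANUAL_REVIEW** — with a machine-readable reason instead of a silent
  guess: `polyA` when a microhomology of 5 bp or more is at least 90%
  A (or T) — such junctions sit in the adenosine-rich tract where
  alignment offsets are meaningless; `truncated` when a LINE-1 flank's
  effectively-gapless local alignment covers less than half the flank;
  `discordant` when an overlap exists but differs from the
  microhomology.

The hard invariant `label == HR implies overlap == mh_length` is asserted
on every call.

Two numerical choices deserve a note. First, alignment scoring is
EDNAFULL-equivalent (match +5, mismatch −4, gap open 10, gap extension
0.5), with a length-$L$ gap costing $10 + 0.5L$ and identity computed
over alignment columns including gaps; percent similarity between two TE
copies uses the same scoring. Second, because that gap extension is so
cheap, *any* sequence tends to align over its full span, so the
truncation-coverage check is measured on a secondary, effectively
gapless alignment (gap open 25, extension 10); the mechanism decision
itself always uses the standard scoring.

## Ensemble merging

Per-caller calls are first filtered: DEL/DUP/INV only, 50 bp–50 kbp,
breakpoints more than 500 bp from gaps/centromeres, less than 50% of the
span in simple repeats, read support SR ≥ 5 or PR ≥ 10 (short reads) or
RS ≥ 5 (long reads), and depth ratio RD < 0.7 for deletions and RD > 1.3
for duplications (inversions are copy-neutral and exempt). Every
rejected call carries the first reason that disqualified it, so the
filter funnel is auditable.

Calls of the same type with pairwise reciprocal overlap
$\min(o/|a|, o/|b|) \ge 0.8$ are clustered by single linkage within each
technology. Each cluster keeps the *exact* coordinates of its
highest-ranked caller (Manta > DELLY > LUMPY; pbsv > Sniffles > SVIM) —
never an average — with ties broken by smaller start, then smaller end.
A cluster is within-technology consensus when two or more distinct
callers support it; the final callset keeps records with consensus in
either technology or cross-technology support at the same overlap
threshold. When both technologies confirm an event the short-read
representative's coordinates win (short-read callers had the best
junction precision in our hands); this priority is configurable. Prior
supporter lists survive re-merging, which makes merging idempotent.
Cross-sample merging collapses clusters to the record of the first
sample in lexicographic order, keeping carrier flags.

Duplications are validated against an assembly insertion resource: an
insertion within the duplication ± 500 bp whose length matches the
duplication to 90%.

## What the generator emulates — and what it does not

`simulate_temr_cohort()` builds one synthetic chromosome (default 5 Mbp)
from cassettes of two TE copies, each derived from a bundled *synthetic*
consensus: an Alu-like 311 bp dimer (left monomer [0,132), A-rich linker,
right monomer derived from the left at ~12% divergence, 30 bp poly-A
tail, with A-box/B-box-like metadata) and a LINE-1-like element of
1,500 bp — a deliberately scaled-down stand-in for the ~6 kbp element
that keeps consensus alignments cheap while preserving the length
contrast between families. Real consensus sequences can be supplied as
FASTA with metadata headers.

Copies mutate from the consensus by i.i.d. substitutions only (indels
off by default), which keeps microhomology tracts analytically
controllable:

* **HR events** force a substitution-free window of exactly the intended
  microhomology length at the *same* consensus offset in both copies,
  with mismatches forced at both window edges, so the realized
  microhomology equals the request; the junction is placed uniformly
  inside the window. Windows avoid the poly-A tract, A/T homopolymer
  runs, and the outer 40 bp of the element.
* **NHE events** take junction offsets at *disjoint* consensus positions
  (separated by at least 25 bp), with an identical 0–4 bp tract copied
  between the copies and optional 1–23 bp junction insertions (35% of
  blunt junctions).
* Deletions, duplications, and mCNVs use direct-orientation pairs;
  inversions use opposite-orientation pairs — matching the observed
  orientation geometry. Default mixture: 80% Alu / 20% LINE-1, 79% HR
  (73% among inversions), HR copies at 2–10% divergence and NHE copies
  at 8–15% (non-homologous repair acts between more diverged repeats).

Caller simulation draws Poisson support counts (SR ~12, PR ~20, RS ~12),
depth ratios centered at 0.5/1.5/1.0 for DEL/DUP/INV (mCNV above) with
Gaussian noise sd 0.05, optional rounded-Gaussian breakpoint jitter per
caller, and uniformly placed false positives private to one caller.

The generator does *not* emulate read-level data (FASTQ/BAM), SNV/indel
background, diploidy and phasing, nested or overlapping real-genome TE
architecture, transductions, or reference errors. Passing the end-to-end
benchmark therefore demonstrates that the *logic* of every stage is
correct under controlled conditions; it does not certify caller behavior
on real reads. The headline benchmark runs the characterization at zero
breakpoint jitter, because exact microhomology recovery is only defined
for junction-precise calls — on real data those come from the
highest-precision caller or assemblies, which is exactly what the
rank-based merge retains; merging under jitter is exercised separately.

## Problem sizes and parameters

The study conditions used by the analysis scripts and the acceptance
script are: one 5 Mbp chromosome, 120 planted TEMRs, 80 decoy TE copies,
six callers, jitter 0, false-positive rate 0. The mechanism-recovery
benchmark uses at least 100 events per class at divergence ≤ 15%. Null
calibration of Welch's *t* and the exact binomial uses 10,000
simulations at *n* = 20 per arm. These sizes keep a full run around a
minute on one core while leaving every class populated.

Other defaults, all configurable: reciprocal-overlap threshold 0.8;
HR overlap tolerance 0 bp (a tolerance is exposed because SNVs near
junctions can shift alignment ends by a base or two in real data);
poly-A flag at ≥ 90% A or T over ≥ 5 bp; LINE-1 truncation flag below
50% flank coverage; TE-density windows of 50 kbp centered on the SV
midpoint, clipped at chromosome ends with the denominator renormalized;
control windows rejection-sampled until they contain ≥ 2 family members,
capped at 1000 draws per window; copy number as `round(2 * depth
ratio)`, flagged when less than 7% of the locus is unique sequence;
ancestral-deletion matching at 90% size agreement within a
consensus-length window; genic categories with precedence exonic >
intronic > proximal (5 kbp) > intergenic. Two-tailed exact tests use the
small-point-probability rule; no multiple-testing correction is applied
by default.

## Known limitations

* Mechanism sub-typing (SSA vs MMEJ vs MMBIR) is out of scope: the
  classifier separates homology-driven from non-homologous repair, which
  is as far as junction geometry alone can go.
* Breakend (BND) translocations and multi-allelic records are not
  merged.
* The minus/minus direct-orientation flank geometry is handled by
  consensus-role swapping; mixed exotic geometries (e.g. an inversion
  whose 5' TE is on the minus strand) are not planted by the generator
  and are untested against truth.
* Manual-review events are emitted with reasons, not resolved: on real
  cohorts a reviewer still owns the ~10% tail of poly-A and truncated
  junctions.

## A minimal run

```{r, eval = FALSE}
res <- run_temr_pipeline(seed = 11, n_events = 12,
                         background_length = 6e5)
score_against_truth(res)       # recovery / classification / mechanism
summarize_temr_callset(res$temr)
```

The `analysis/` directory of the source repository chains the same calls
as six narrative stage scripts (simulate, merge, classify, characterize,
stats, report), writing plain-text tables under `results/`.
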