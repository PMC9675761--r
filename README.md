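# temrkit

Discovery and mechanistic characterization of **transposable
element-mediated rearrangements (TEMRs)** — structural variants whose two
breakpoints fall in distinct transposable element copies of the same
class (Alu–Alu, LINE-1–LINE-1, ...). Such events arise when two
homologous TE copies serve as substrates for ectopic DNA repair, and they
account for a sizable slice of deletions, duplications, inversions and
higher-order amplifications in human genomes.

`temrkit` is aimed at structural-variant analysts who have per-caller SV
callsets, a reference genome and a RepeatMasker-style TE annotation, and
want to (1) reduce multi-caller output to a high-confidence ensemble
callset, (2) pull out the TEMRs, (3) reconstruct each breakpoint junction
at base resolution, and (4) type the repair mechanism behind each event.
A synthetic-genome generator with planted ground truth makes the whole
chain testable without any external data.

## The core computations

* **Ensemble merging.** Calls of the same SV type merge at reciprocal
  overlap `RO(a,b) = min(o/|a|, o/|b|) >= 0.8` (single linkage); each
  cluster keeps the exact breakpoints of its highest-ranked caller
  (Manta > DELLY > LUMPY for short reads; pbsv > Sniffles > SVIM for
  long reads). Consensus needs two callers within a technology, or
  cross-technology support. Filters: 50 bp–50 kbp, 500 bp
  exclusion-region buffer, <50% simple-repeat overlap, SR >= 5 | PR >= 10
  (SRS) / RS >= 5 (LRS), RD < 0.7 (DEL) / RD > 1.3 (DUP).
* **Microhomology.** For breakpoints `b5 < b3`, the junction ambiguity:
  the maximal tract with `ref[b5..b5+k) == ref[b3..b3+k)` extended in
  both directions; every breakpoint pair inside the ambiguity range
  rebuilds an identical alternate allele.
* **Mechanism.** Junction flanks are aligned to the family consensus
  (Smith–Waterman, match +5 / mismatch −4 / gap open 10 / extend 0.5).
  With `e1` the consensus end of the 5' flank and `s2` the consensus
  start of the 3' flank, an event is **HR** when the overlap `e1 - s2`
  is >= 1 bp and equals the microhomology length (the chimera rebuilds
  one full TE); *Alu* events are retried monomer-by-monomer to catch
  chimeras that crossed monomers; flanks that fail to overlap are
  **NHE**; poly-A, truncated-LINE-1 and discordant cases go to
  **MANUAL_REVIEW** with machine-readable reasons.
* **Statistics.** TE density in 50 kbp windows against rejection-sampled
  control windows (Welch's *t*), microhomology GC content, read-depth
  copy number (`CN = round(2 * ratio)`), ancestral-deletion matching
  (90% size rule), genic intersection, exact two-tailed binomial and
  Fisher tests, Spearman correlation.

## Worked example

```r
library(temrkit)
res <- run_temr_pipeline(seed = 11, n_events = 12, background_length = 6e5)
res$manifest$stages
#> simulate    calls filtered   merged     temr
#>       12       72       72       12       12
table(mechanism = res$temr$mechanism_label, family = res$temr$family)
#>          family
#> mechanism Alu LINE-1
#>       HR    5      2
#>       NHE   4      1
str(summarize_temr_callset(res$temr)[c("median_mh_hr", "median_mh_nhe",
                                       "median_similarity_hr")])
#> List of 3
#>  $ median_mh_hr        : int 15
#>  $ median_mh_nhe       : num 1.5
#>  $ median_similarity_hr: num 90.2
```

Twelve events are planted, every caller reports all twelve, all twelve
survive filtering and merge into exactly twelve nonredundant records,
and all are classified as TEMRs. HR junctions carry long microhomologies
(median 15 bp here) between highly similar TE copies; NHE junctions are
near-blunt — the two mechanistic signatures the classifier keys on.

The `analysis/` directory runs the same pipeline as six narrative
stages with plain-text outputs under `results/`:

```sh
Rscript analysis/01_simulate.R      # genome + annotation + callsets
Rscript analysis/02_merge.R         # filter funnel + ensemble merge
Rscript analysis/03_classify.R      # TEMR categorization
Rscript analysis/04_characterize.R  # junctions + mechanisms
Rscript analysis/05_stats.R         # enrichment statistics
Rscript analysis/06_report.R        # consolidated report
```

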