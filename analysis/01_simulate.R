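#!/usr/bin/env Rscript
# Stage 1 — simulate the study genome.
#
# Builds a 5 Mbp synthetic chromosome carrying 120 planted TEMRs (deletions,
# duplications, inversions and mCNVs between Alu-like and LINE-1-like
# copies of known repair mechanism) plus decoy TE copies, then simulates
# the six-caller (3 short-read + 3 long-read) callsets. Everything
# downstream works from the files written here.

suppressMessages(library(temrkit))

seed <- 20231L
out <- "results"
dir.create(out, showWarnings = FALSE)

co <- simulate_temr_cohort(n_events = 120L, background_length = 5e6,
                           seed = seed)
cs <- simulate_callsets(co$truth, nchar(co$reference$sequence),
                        jitter_sd = 0, fp_rate = 0, seed = seed + 1L)

write_fasta(setNames(co$reference$sequence, co$reference$chrom),
            file.path(out, "reference.fa"))
write_consensus_fasta(co$consensus_set, file.path(out, "consensus.fa"))
write_tsv(co$annotation, file.path(out, "te_annotation.tsv"))
write_tsv(co$truth, file.path(out, "truth.tsv"))
write_sv_vcf(co$truth, file.path(out, "truth.vcf"))
for (cl in names(cs))
  write_tsv(cs[[cl]], file.path(out, sprintf("calls_%s.tsv", cl)))

cat(sprintf("simulated %d TEMRs (%s) on a %.1f Mbp chromosome\n",
            nrow(co$truth),
            paste(names(table(co$truth$sv_type)),
                  table(co$truth$sv_type), collapse = ", "),
            nchar(co$reference$sequence) / 1e6))
cat(sprintf("TE annotation: %d copies (%d decoys); callsets: %s\n",
            nrow(co$annotation),
            sum(is.na(co$annotation$pair_id)),
            paste(names(cs), collapse = ", ")))
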