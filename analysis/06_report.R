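#!/usr/bin/env Rscript
# Stage 6 — consolidated report: recovery against the planted truth plus
# the headline callset numbers, rendered from the stage outputs without
# recomputation.

suppressMessages(library(temrkit))

out <- "results"
truth <- read_tsv(file.path(out, "truth.tsv"))
merged <- read_tsv(file.path(out, "merged.tsv"))
temr <- read_tsv(file.path(out, "temr.tsv"))
cls_sum <- jsonlite::read_json(file.path(out, "classify_summary.json"))
mech_sum <- jsonlite::read_json(file.path(out, "mechanism_summary.json"))

s <- summarize_temr_callset(temr)

lines <- c(
  sprintf("planted events: %d; ensemble records: %d; TEMRs: %d (%.2f%%)",
          nrow(truth), nrow(merged), cls_sum$n_temr, cls_sum$temr_percent),
  sprintf("families: %s",
          paste(names(table(temr$family)), table(temr$family),
                sep = "=", collapse = ", ")),
  sprintf("mechanisms: %s (systematic %.1f%%)",
          paste(names(table(temr$mechanism_label)),
                table(temr$mechanism_label), sep = "=", collapse = ", "),
          mech_sum$percent_systematic),
  sprintf("median microhomology: %d bp overall; %d bp HR; %d bp NHE",
          s$median_mh, s$median_mh_hr, s$median_mh_nhe),
  sprintf("median TEMR length: %d bp; HR fraction: %.1f%%",
          s$median_length, s$hr_percent),
  sprintf("median TE similarity: %.1f%% (HR) vs %.1f%% (NHE)",
          s$median_similarity_hr, s$median_similarity_nhe))

writeLines(lines)
writeLines(lines, file.path(out, "report.txt"))
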