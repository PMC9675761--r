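#!/usr/bin/env Rscript
# Stage 3 — TEMR categorization: intersect ensemble breakpoints with the
# TE annotation; SVs with both breakpoints in distinct same-class TEs are
# TEMRs, with family and orientation class recorded.

suppressMessages(library(temrkit))

out <- "results"
merged <- read_tsv(file.path(out, "merged.tsv"))
ann <- read_tsv(file.path(out, "te_annotation.tsv"))

cls <- classify_temr(merged, ann)
s <- summarize_callset(cls)

write_tsv(cls, file.path(out, "classified.tsv"))
jsonlite::write_json(s[c("n_sv", "n_temr", "temr_percent")],
                     file.path(out, "classify_summary.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("%d of %d SVs are TEMRs (%.2f%%)\n",
            s$n_temr, s$n_sv, s$temr_percent))
print(s$by_class)
cat("size medians (bp):\n"); print(s$size_medians)
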