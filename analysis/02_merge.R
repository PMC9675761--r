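#!/usr/bin/env Rscript
# Stage 2 — filter per-caller calls and merge them into the
# high-confidence ensemble callset (80% reciprocal overlap, rank-based
# breakpoint retention, two-caller within-technology consensus or
# cross-technology support).

suppressMessages(library(temrkit))

out <- "results"
files <- list.files(out, pattern = "^calls_.*\\.tsv$", full.names = TRUE)
stopifnot(length(files) > 0)
calls <- do.call(rbind, lapply(files, read_tsv))

cfg <- filter_config()
flt <- filter_calls(calls, cfg = cfg)
merged <- merge_by_rank(flt$kept, cfg)

write_tsv(merged, file.path(out, "merged.tsv"))
write_sv_vcf(merged, file.path(out, "merged.vcf"))
write_tsv(flt$rejected, file.path(out, "rejected_calls.tsv"))

cat(sprintf("input calls: %d; passed filters: %d; rejected: %d\n",
            nrow(calls), nrow(flt$kept), nrow(flt$rejected)))
print(flt$counts)
cat(sprintf("ensemble callset: %d nonredundant records\n", nrow(merged)))
cat(sprintf("  supported by both technologies: %d\n",
            sum(grepl(",", merged$technologies))))
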