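#!/usr/bin/env Rscript
# Reproduce the reported per-domain, per-class CaM-binding motif counts by
# exhaustive strict-alphabet enumeration over the packaged CaMBD corpus,
# and write the full concordance table.

suppressPackageStartupMessages(library(cambscan))
dir.create("results", showWarnings = FALSE)

report <- concordance_report(alphabet = "strict")
print(report)

write_concordance_tsv(report, "results/concordance.tsv")

conc <- report$concordance
message(sprintf(
  "Of the %d stated counts, %d are reproduced exactly by the strict ",
  nrow(conc), sum(conc$match)))
message(sprintf(
  "alphabet {F,I,L,V,W}; the %d disagreements are visual-scan counts not ",
  sum(!conc$match)))
message("attainable under any single uniform anchor set (see results/concordance.tsv).")
message("Wrote results/concordance.tsv")
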