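#!/usr/bin/env Rscript
# Arithmetic on the packaged clinical tables: per-subtype pCR rates of
# the 317-sample cohort fixture and the subtype split of the 22-patient
# paired cohort fixture.

library(neostrat)

out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

t1 <- cohort_summary(read_annotation(neostrat_fixture("table1_cohort.tsv")))
print(t1)
t2 <- cohort_summary(read_annotation(neostrat_fixture("table2_annotation.tsv")))
print(t2)

summary_df <- data.frame(
  quantity = c("pcr_pct_erpos", "pcr_pct_tn", "paired_erpos", "paired_tn"),
  value = c(t1$subtypes$ERpos$pcr_pct, t1$subtypes$TN$pcr_pct,
            t2$paired$ERpos, t2$paired$TN))
write.table(summary_df, file.path(out, "cohort_tables.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", file.path(out, "cohort_tables.tsv"), "\n")
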