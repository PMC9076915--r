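#!/usr/bin/env Rscript
# Generate the synthetic study cohort every later step consumes: a
# treatment-naive expression cohort of 120 TN + 80 ER+ samples with three
# latent processes (proliferation, immune, ECM) coupled to NRI, plus one
# paired pre/post-treatment genome with a planted pre-only copy-number
# loss and planted shared / pre-only / post-only somatic variants.

library(neostrat)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

cfg <- sim_config(seed = seed)
sim <- simulate_cohort(cfg)
write_expression(sim$expression, file.path(out, "expression.tsv"))
write_annotation(sim$annotation, file.path(out, "annotation.tsv"))
write.table(sim$assignment, file.path(out, "true_assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$latents, file.path(out, "latents.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pg <- simulate_paired_genomics(sim_config(seed = seed + 3000L))
write.table(cbind(pg$pre[, c("chrom", "pos", "logr")]),
            file.path(out, "pre.cn.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(pg$post[, c("chrom", "pos", "logr")]),
            file.path(out, "post.cn.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_paired_vcf(pg$variants, file.path(out, "somatic.vcf"))
jsonlite::write_json(
  list(seed = seed, purity_pre = pg$truth$purity_pre,
       purity_post = pg$truth$purity_post,
       loss_region = pg$truth$loss_region,
       variant_sharing = pg$truth$variant_sharing),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cs <- cohort_summary(sim$annotation)
cat(sprintf("cohort: %d samples (%d TN, %d ER+), %d genes\n",
            ncol(sim$expression), cfg$n_tn, cfg$n_er,
            nrow(sim$expression)))
cat(sprintf("median NRI: TN %.2f, ER+ %.2f\n",
            cs$subtypes$TN$median_nri, cs$subtypes$ERpos$median_nri))
cat(sprintf("paired genome: %d probes, purity pre/post %.2f/%.2f\n",
            nrow(pg$pre), pg$truth$purity_pre, pg$truth$purity_post))
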