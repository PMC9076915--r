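#!/usr/bin/env Rscript
# Compare the paired pre/post-treatment genome: purity-adjust the probe
# log ratios, segment the pre-minus-post delta, filter and classify the
# somatic variants, build the combined per-gene aberration table, and
# test the planted loss gene's pre-treatment frequency against a
# reference-cohort frequency.

library(neostrat)

cohort_dir <- "results/cohort"
if (!file.exists(file.path(cohort_dir, "somatic.vcf")))
  stop("run analysis/01_simulate_cohort.R first")
out <- "results/paired"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

truth <- jsonlite::read_json(file.path(cohort_dir, "truth.json"),
                             simplifyVector = TRUE)
pre_tab <- read.delim(file.path(cohort_dir, "pre.cn.tsv"))
post_tab <- read.delim(file.path(cohort_dir, "post.cn.tsv"))
pre <- cn_profile(pre_tab$chrom, pre_tab$pos, pre_tab$logr,
                  truth$purity_pre)
post <- cn_profile(post_tab$chrom, post_tab$pos, post_tab$logr,
                   truth$purity_post)

delta <- paired_delta(pre, post)
segs <- segment_delta(delta, min_probes = 10, t_threshold = 4)
write_seg(segs, file.path(out, "delta.seg"))
cat(sprintf("delta segmentation: %d segments over %d probes\n",
            nrow(segs), nrow(delta)))
big <- segs[abs(segs$mean_delta) > 0.5, ]
cat(sprintf("segments with |mean delta| > 0.5: %d (planted loss at %s:%d-%d)\n",
            nrow(big), truth$loss_region$chrom, truth$loss_region$start,
            truth$loss_region$end))

variants <- read_paired_vcf(file.path(cohort_dir, "somatic.vcf"))
retained <- filter_somatic_variants(variants)
classified <- classify_variant_sharing(retained)
write.table(classified, file.path(out, "variants.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("variants: %d called, %d retained (>10%% AF, coding)\n",
            nrow(variants), nrow(retained)))
print(table(classified$sharing))

seg_of <- function(profile, tp) {
  adj <- data.frame(chrom = profile$chrom, pos = profile$pos,
                    delta = as.numeric(
                      purity_adjust_logr(profile$logr,
                                         attr(profile, "purity"))))
  s <- segment_delta(adj, min_probes = 10, t_threshold = 4, sample = tp)
  data.frame(timepoint = tp, chrom = s$chrom, start = s$start,
             end = s$end, mean_logr = s$mean_delta)
}
segments_tp <- rbind(seg_of(pre, "pre"), seg_of(post, "post"))
regions <- data.frame(gene = truth$loss_region$gene,
                      chrom = truth$loss_region$chrom,
                      start = truth$loss_region$start,
                      end = truth$loss_region$end)
gene_tab <- recurrent_gene_table(classified, segments_tp, regions)
write.table(gene_tab, file.path(out, "gene_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("planted loss gene aberrated pre/post: %d/%d\n",
            gene_tab$pre, gene_tab$post))

# frequency comparison in the style of the CCND1-vs-reference test:
# 7 amplified of 16 patients against a 19% reference frequency
p <- aberration_frequency_test(7, 16, 0.19)
cat(sprintf("frequency test 7/16 vs 19%% reference: one-sided p = %.3f\n", p))
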