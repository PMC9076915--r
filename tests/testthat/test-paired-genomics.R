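test_that("purity adjustment inverts forward mixing on a grid", {
  # identity at full purity
  r <- seq(-3, 3, by = 0.5)
  expect_equal(as.numeric(purity_adjust_logr(r, 1)), r, tolerance = 1e-12)
  # worked example: true logR 1 at purity 0.5 observes log2(1.5)
  obs <- mix_logr(1, 0.5)
  expect_equal(obs, log2(1.5), tolerance = 1e-12)
  expect_equal(as.numeric(purity_adjust_logr(obs, 0.5)), 1,
               tolerance = 1e-9)
  # full round-trip grid
  for (p in seq(0.2, 1, by = 0.1)) {
    rt <- seq(-2, 2, by = 0.25)
    back <- purity_adjust_logr(mix_logr(rt, p), p)
    expect_lt(max(abs(as.numeric(back) - rt)), 1e-9)
    expect_false(any(attr(back, "clipped")))
  }
  expect_error(purity_adjust_logr(0, 0), "purity")
})

test_that("deep observed losses clip at the floor and are flagged", {
  out <- purity_adjust_logr(-6, 0.5)
  expect_equal(as.numeric(out), log2(0.01))
  expect_true(attr(out, "clipped"))
  # monotone in the observed value
  v <- as.numeric(purity_adjust_logr(seq(-4, 2, by = 0.1), 0.7))
  expect_true(!is.unsorted(v))
})

test_that("VAF adjustment scales linearly and caps at one", {
  expect_equal(as.numeric(purity_adjust_vaf(0.3, 1)), 0.3)
  expect_equal(as.numeric(purity_adjust_vaf(0.2, 0.5)), 0.4)
  capped <- purity_adjust_vaf(0.8, 0.5)
  expect_equal(as.numeric(capped), 1)
  expect_true(attr(capped, "capped"))
  expect_error(purity_adjust_vaf(0.2, 0), "purity")
})

test_that("paired delta is zero on identical profiles and flags grid mismatch", {
  p <- cn_profile(rep("chr1", 5), 1:5 * 100L, c(0, 0.5, -0.3, 1, 0), 0.8)
  d <- paired_delta(p, p)
  expect_true(all(d$delta == 0))
  q <- cn_profile(rep("chr1", 5), c(100L, 250L, 300L, 400L, 500L),
                  rep(0, 5), 0.8)
  expect_error(paired_delta(p, q), "index 2")
})

test_that("the planted pre-only loss appears as a -1 delta block", {
  cfg <- sim_config(n_probes = 800, n_chrom = 2, cn_sigma = 0,
                    purity_range = c(0.55, 0.55), seed = 29)
  g <- simulate_paired_genomics(cfg)
  d <- paired_delta(g$pre, g$post)
  loss <- g$truth$loss_region
  in_loss <- d$chrom == loss$chrom & d$pos >= loss$start &
    d$pos <= loss$end
  expect_equal(unique(round(d$delta[in_loss], 9)), -1)
  expect_true(all(abs(d$delta[!in_loss]) < 1e-9))
})

test_that("segmentation recovers a planted step and respects degenerate settings", {
  # all-zero delta: one segment per chromosome with mean zero
  flat <- data.frame(chrom = rep(c("chr1", "chr2"), each = 50),
                     pos = rep(1:50 * 10L, 2), delta = 0)
  s0 <- segment_delta(flat)
  expect_equal(nrow(s0), 2L)
  expect_equal(s0$mean_delta, c(0, 0))
  expect_equal(s0$n_probes, c(50L, 50L))

  # planted step: 100 probes at 0 then 100 at -1, noise SD 0.1
  set.seed(41)
  step <- data.frame(chrom = "chr1", pos = 1:200 * 10L,
                     delta = c(rep(0, 100), rep(-1, 100)) + rnorm(200, 0, 0.1))
  s1 <- segment_delta(step, min_probes = 10, t_threshold = 4)
  expect_equal(nrow(s1), 2L)
  boundary <- s1$end[1] / 10
  expect_lte(abs(boundary - 100), 3)
  expect_lt(abs(s1$mean_delta[1] - 0), 0.1)
  expect_lt(abs(s1$mean_delta[2] - (-1)), 0.1)

  # infinite threshold never splits
  s2 <- segment_delta(step, t_threshold = Inf)
  expect_equal(nrow(s2), 1L)
})

test_that("segments tile the probes and carry exact arithmetic means", {
  set.seed(53)
  d <- data.frame(chrom = rep("chr1", 300), pos = 1:300 * 7L,
                  delta = rnorm(300) + rep(c(0, 2, -1), each = 100))
  segs <- segment_delta(d, min_probes = 5, t_threshold = 4)
  expect_equal(sum(segs$n_probes), 300L)
  expect_equal(segs$start[1], d$pos[1])
  expect_equal(segs$end[nrow(segs)], d$pos[300])
  expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
  for (i in seq_len(nrow(segs))) {
    members <- d$pos >= segs$start[i] & d$pos <= segs$end[i]
    expect_identical(segs$mean_delta[i], mean(d$delta[members]))
  }
})

test_that("the >10%/coding retention rule keeps exactly the right variants", {
  v <- toy_variants()
  kept <- filter_somatic_variants(v)
  expect_equal(nrow(kept), 3L)
  expect_setequal(kept$gene, c("G01", "G02", "G05"))
  # monotone: raising the cutoff never increases the retained count
  counts <- vapply(seq(0, 0.5, by = 0.05), function(cut)
    nrow(filter_somatic_variants(v, af_cutoff = cut)), numeric(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("sharing classification follows the three-state rule", {
  v <- data.frame(vaf_pre = c(0.4, 0.3, 0.0, 0.3, 0.05, NA),
                  vaf_post = c(0.4, 0.0, 0.3, 0.05, 0.3, 0.3),
                  dp_pre = c(100, 100, 100, 100, 100, 0),
                  dp_post = c(100, 100, 100, 100, 100, 100))
  cl <- classify_variant_sharing(v)
  expect_equal(cl$sharing,
               c("shared", "pre_only", "post_only", "indeterminate",
                 "indeterminate", "indeterminate"))
  # shallow depth blocks absence calls
  v2 <- data.frame(vaf_pre = 0.3, vaf_post = 0.0, dp_pre = 100, dp_post = 10)
  expect_equal(classify_variant_sharing(v2)$sharing, "indeterminate")
  expect_error(classify_variant_sharing(v, present_af = 0.1,
                                        absent_af = 0.1), "below")
})

test_that("swapping timepoints mirrors pre_only and post_only", {
  set.seed(61)
  v <- data.frame(vaf_pre = runif(50, 0, 0.5), vaf_post = runif(50, 0, 0.5),
                  dp_pre = sample(5:200, 50, TRUE),
                  dp_post = sample(5:200, 50, TRUE))
  cl <- classify_variant_sharing(v)
  v_swap <- data.frame(vaf_pre = v$vaf_post, vaf_post = v$vaf_pre,
                       dp_pre = v$dp_post, dp_post = v$dp_pre)
  cl_swap <- classify_variant_sharing(v_swap)
  map <- c(shared = "shared", pre_only = "post_only",
           post_only = "pre_only", indeterminate = "indeterminate")
  expect_equal(cl_swap$sharing, unname(map[cl$sharing]))
})

test_that("frequency tests agree with brute-force tail sums", {
  expect_equal(aberration_frequency_test(0, 16, 0.19), 1)
  expect_equal(aberration_frequency_test(10, 10, 0.5), 2^-10,
               tolerance = 1e-12)
  # exhaustive binomial tail oracle
  oracle <- sum(choose(16, 7:16) * 0.19^(7:16) * 0.81^(16 - 7:16))
  expect_equal(aberration_frequency_test(7, 16, 0.19), oracle,
               tolerance = 1e-12)
  expect_error(aberration_frequency_test(5, 4, 0.1), "k <= n")
  # reference cohort size switches to a one-sided Fisher test
  p_fisher <- fisher.test(matrix(c(7, 9, 20, 80), 2),
                          alternative = "greater")$p.value
  expect_equal(aberration_frequency_test(7, 16, 0.2, ref_n = 100),
               p_fisher, tolerance = 1e-12)
})

test_that("the combined gene table integrates variants and segments", {
  regions <- data.frame(gene = c("LOSS01", "MUTG", "QUIET"),
                        chrom = c("chr1", "chr2", "chr2"),
                        start = c(1000L, 100L, 5000L),
                        end = c(2000L, 200L, 6000L),
                        stringsAsFactors = FALSE)
  segments <- data.frame(
    timepoint = rep(c("pre", "post"), each = 2),
    chrom = rep(c("chr1", "chr2"), 2),
    start = c(1L, 1L, 1L, 1L), end = c(10000L, 10000L, 10000L, 10000L),
    mean_logr = c(-1, 0, 0, 0),
    stringsAsFactors = FALSE)
  variants <- data.frame(gene = "MUTG", chrom = "chr2", pos = 150L,
                         vaf_pre = 0.4, vaf_post = 0.35,
                         stringsAsFactors = FALSE)
  tab <- recurrent_gene_table(variants, segments, regions)
  expect_equal(tab$pre[tab$gene == "LOSS01"], 1L)   # pre-only loss
  expect_equal(tab$post[tab$gene == "LOSS01"], 0L)
  expect_equal(tab$pre[tab$gene == "MUTG"], 1L)     # shared variant
  expect_equal(tab$post[tab$gene == "MUTG"], 1L)
  expect_equal(tab$pre[tab$gene == "QUIET"] + tab$post[tab$gene == "QUIET"],
               0L)
  # uncovered region warns and counts as not aberrated
  regions2 <- rbind(regions,
                    data.frame(gene = "OFFGRID", chrom = "chr9",
                               start = 1L, end = 10L))
  expect_warning(tab2 <- recurrent_gene_table(variants, segments, regions2),
                 "OFFGRID")
  expect_equal(tab2$pre[tab2$gene == "OFFGRID"], 0L)
})

test_that("the simulator's planted loss lands in the gene table", {
  cfg <- sim_config(n_probes = 800, n_chrom = 2, cn_sigma = 0,
                    purity_range = c(0.6, 0.6), seed = 67)
  g <- simulate_paired_genomics(cfg)
  seg_of <- function(profile, tp) {
    adj <- data.frame(chrom = profile$chrom, pos = profile$pos,
                      delta = as.numeric(
                        purity_adjust_logr(profile$logr,
                                           attr(profile, "purity"))))
    s <- segment_delta(adj, min_probes = 10, t_threshold = 4)
    data.frame(timepoint = tp, chrom = s$chrom, start = s$start,
               end = s$end, mean_logr = s$mean_delta,
               stringsAsFactors = FALSE)
  }
  segments <- rbind(seg_of(g$pre, "pre"), seg_of(g$post, "post"))
  tab <- recurrent_gene_table(
    filter_somatic_variants(g$variants), segments, g$truth$loss_region)
  expect_equal(tab$pre, 1L)
  expect_equal(tab$post, 0L)
})
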