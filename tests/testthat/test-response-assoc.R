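make_null_matrix <- function(n_genes, n, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n), n_genes, n,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n))))
}

test_that("negating the response exactly negates d and fixes q", {
  expr <- make_null_matrix(80, 30, seed = 1)
  y <- runif(30)
  a <- sam_quantitative(expr, y, n_perm = 200, seed = 9)
  b <- sam_quantitative(expr, -y, n_perm = 200, seed = 9)
  expect_equal(b$table$d, -a$table$d, tolerance = 1e-12)
  expect_identical(b$table$q, a$table$q)
  expect_identical(b$s0, a$s0)
})

test_that("a planted gene dominates the statistic and clears FDR 5%", {
  set.seed(4)
  n <- 60
  y <- runif(n)
  expr <- make_null_matrix(499, n, seed = 5)
  planted <- 2 * y + rnorm(n, sd = 0.01)
  expr <- rbind(expr, PLANTED = planted)
  sam <- sam_quantitative(expr, y, n_perm = 500, seed = 3)
  tab <- sam$table
  expect_equal(tab$gene[which.max(abs(tab$d))], "PLANTED")
  expect_lt(tab$q[tab$gene == "PLANTED"], 0.05)
  core <- select_core_set(sam, 0.05)
  # the planted gene heads the core set; median-count FDR granularity can
  # admit a stray extreme null gene, but never more than a handful
  expect_identical(core$gene[1], "PLANTED")
  expect_identical(core$direction[1], "positive")
  expect_lte(nrow(core), 5L)
})

test_that("core-set selection behaves at the FDR extremes", {
  expr <- make_null_matrix(50, 20, seed = 2)
  sam <- sam_quantitative(expr, seq_len(20) / 20, n_perm = 100, seed = 1)
  expect_equal(nrow(select_core_set(sam, 0)), 0L)
  all_genes <- select_core_set(sam, 1)
  expect_equal(nrow(all_genes), sum(is.finite(sam$table$q) &
                                      sam$table$q < 1))
  expect_true(!is.unsorted(rev(abs(all_genes$d))))
})

test_that("q is non-increasing in |d| and deterministic under a seed", {
  expr <- make_null_matrix(120, 25, seed = 6)
  y <- rnorm(25)
  a <- sam_quantitative(expr, y, n_perm = 150, seed = 42)
  ord <- order(abs(a$table$d), decreasing = TRUE)
  expect_true(!is.unsorted(a$table$q[ord]))
  b <- sam_quantitative(expr, y, n_perm = 150, seed = 42)
  expect_identical(a$table$q, b$table$q)
})

test_that("small cohorts switch to exhaustive permutation enumeration", {
  expr <- make_null_matrix(30, 5, seed = 8)
  sam <- sam_quantitative(expr, c(0.1, 0.3, 0.5, 0.7, 0.9),
                          n_perm = 1000, seed = 1)
  expect_equal(sam$n_perm, factorial(5))
})

test_that("zero-variance genes and positive scaling are handled sanely", {
  expr <- make_null_matrix(40, 20, seed = 3)
  expr[1, ] <- 5  # constant gene
  y <- rnorm(20)
  sam <- sam_quantitative(expr, y, n_perm = 100, seed = 2)
  expect_equal(sam$table$d[1], 0)
  expect_equal(sam$table$q[1], 1)
  # positive scaling of one gene cannot flip the sign of its statistic
  expr2 <- expr
  expr2[2, ] <- expr2[2, ] * 7
  sam2 <- sam_quantitative(expr2, y, n_perm = 100, seed = 2)
  expect_equal(sign(sam2$table$d[2]), sign(sam$table$d[2]))
})

test_that("constant response is rejected", {
  expr <- make_null_matrix(10, 12, seed = 7)
  expect_error(sam_quantitative(expr, rep(1, 12), n_perm = 100),
               "distinct")
})

test_that("clustering recovers the latent gene blocks", {
  cfg <- sim_config(n_tn = 80, n_er = 0, n_genes_per_process = 30,
                    n_null_genes = 10, beta_expr = 2, sigma_expr = 1,
                    seed = 19)
  sim <- simulate_cohort(cfg)
  markers <- split(sim$assignment$gene, sim$assignment$process)
  got <- assign_processes(sim$expression, sim$assignment$gene,
                          markers = markers)
  truth <- sim$assignment$process[match(got$gene, sim$assignment$gene)]
  ari <- mclust::adjustedRandIndex(got$process, truth)
  expect_gt(ari, 0.9)
  # with these markers the labels themselves must agree almost everywhere
  expect_gt(mean(got$process == truth), 0.95)
})

test_that("identical genes always land in the same cluster", {
  expr <- make_null_matrix(20, 30, seed = 10)
  expr[2, ] <- expr[1, ]
  got <- assign_processes(expr, rownames(expr))
  expect_equal(got$process[1], got$process[2])
})

test_that("marker ties and oversized k are errors", {
  expr <- make_null_matrix(9, 25, seed = 11)
  genes <- rownames(expr)
  got <- assign_processes(expr, genes)
  cl1 <- got$gene[got$process == got$process[1]]
  tie_markers <- list(a = cl1[1], b = cl1[1])  # same single gene twice
  expect_error(assign_processes(expr, genes, markers = tie_markers),
               "tie")
  expect_error(assign_processes(expr, genes[1:3], k = 4), "k exceeds")
})

test_that("hypergeometric overlap matches exact combinatorics", {
  # all five draws marked: p = 1 / C(10, 5)
  r <- geneset_overlap_test(letters[1:5], letters[1:5], 10)
  expect_equal(r$p, 1 / choose(10, 5), tolerance = 1e-12)
  # disjoint sets: overlap 0 has p = 1
  expect_equal(geneset_overlap_test(c("a", "b"), c("x", "y"), 1000)$p, 1)
  # a = b = universe: p = 1
  expect_equal(geneset_overlap_test(letters[1:4], letters[1:4], 4)$p, 1)
  # exceeding the universe is impossible
  expect_error(geneset_overlap_test(letters[1:5], letters[1:2], 3),
               "universe")
  # batch adjustment is Benjamini-Hochberg
  batch <- geneset_overlap_tests(
    list(hit = letters[1:5], miss = letters[22:26]),
    letters[1:5], 26)
  expect_equal(batch$p_adj, p.adjust(batch$p, "BH"))
})
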