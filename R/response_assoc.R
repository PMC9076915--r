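#' Permutation-based association of gene expression with a quantitative
#' response
#'
#' For each gene, the least-squares slope `r` of log2 expression on the
#' response `y` (with intercept) and its standard error `s` are moderated
#' into `d = r / (s + s0)`, where the fudge factor `s0` stabilizes the
#' variance of `d` across the range of `s`. The null distribution of `d` is
#' built by permuting `y`; per-gene q-values estimate, for the symmetric
#' cutoff at each observed `|d|`, the median number of null exceedances
#' over the observed number (pi0 fixed at 1, conservative), monotonized so
#' q never decreases as `|d|` decreases, and capped at 1.
#'
#' Samples with missing `y` are dropped for all genes alike. When the number
#' of distinct orderings `n!` does not exceed 1000 the permutation null is
#' enumerated exactly; otherwise `n_perm` random permutations are drawn.
#' Genes with zero expression variance get `d = 0`, `q = 1`.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param y Quantitative response (e.g. NRI), one value per sample; at
#'   least three distinct values after dropping missing.
#' @param n_perm Number of random permutations (at least 100).
#' @param seed Integer seed for the permutation draw.
#' @return List of class `sam_result`: `table` (data frame `gene`, `r`,
#'   `s`, `d`, `q`), scalar `s0`, and the realized permutation count
#'   `n_perm`.
#' @export
sam_quantitative <- function(expr, y, n_perm = 1000L, seed = 1L) {
  stopifnot(is.matrix(expr), length(y) == ncol(expr))
  keep <- !is.na(y)
  y <- y[keep]
  expr <- expr[, keep, drop = FALSE]
  n <- length(y)
  if (any(!is.finite(y))) stop("sam_quantitative: y must be finite")
  if (length(unique(y)) < 3L)
    stop("sam_quantitative: y needs at least 3 distinct values")
  if (n_perm < 100L) stop("sam_quantitative: n_perm must be >= 100")

  yc <- y - mean(y)
  syy <- sum(yc^2)
  ec <- expr - rowMeans(expr)
  sxx <- rowSums(ec^2)
  reg <- slope_stats(ec, yc, syy, sxx, n)

  zero_var <- sxx == 0
  s0 <- fudge_factor(reg$r[!zero_var], reg$s[!zero_var])
  d <- ifelse(zero_var, 0, reg$r / (reg$s + s0))

  # permutation null (s0 held fixed)
  set.seed(as.integer(seed))
  if (factorial(n) <= 1000) {
    perm_idx <- all_permutations(n)
  } else {
    perm_idx <- replicate(n_perm, sample.int(n))
  }
  b_perm <- ncol(perm_idx)
  yp <- matrix(yc[perm_idx], nrow = n)
  sxy_p <- ec %*% yp                              # genes x perms
  r_p <- sxy_p / syy
  rss_p <- pmax(sxx - sxy_p^2 / syy, 0)
  s_p <- sqrt(rss_p / ((n - 2) * syy))
  d_p <- r_p / (s_p + s0)
  d_p[zero_var, ] <- 0

  abs_d <- abs(d)
  obs_count <- vapply(abs_d, function(x) sum(abs_d >= x), numeric(1L))
  null_counts <- matrix(0, nrow(expr), b_perm)
  for (b in seq_len(b_perm)) {
    v <- sort(abs(d_p[, b]))
    # number of null |d*| >= x  ==  total minus number strictly below x
    null_counts[, b] <- length(v) - findInterval(abs_d, v, left.open = TRUE)
  }
  med_null <- apply(null_counts, 1L, stats::median)
  q <- pmin(med_null / obs_count, 1)
  q[zero_var] <- 1

  # monotonize: q non-increasing in |d|
  ord <- order(abs_d, decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  q <- pmin(q, 1)

  tab <- data.frame(gene = rownames(expr), r = reg$r, s = reg$s, d = d,
                    q = q, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, s0 = s0, n_perm = b_perm), class = "sam_result")
}

slope_stats <- function(ec, yc, syy, sxx, n) {
  sxy <- as.numeric(ec %*% yc)
  r <- sxy / syy
  rss <- pmax(sxx - sxy^2 / syy, 0)
  s <- sqrt(rss / ((n - 2) * syy))
  list(r = r, s = s)
}

# Tusher-style fudge factor: percentile of {s_j} (grid 0, 5, ..., 100)
# minimizing the coefficient of variation of the MAD of d across
# s-quantile windows; falls back to median(s) below 100 genes.
fudge_factor <- function(r, s) {
  if (length(s) == 0) return(0)
  if (length(s) < 100L) return(stats::median(s))
  alphas <- seq(0, 1, by = 0.05)
  qs <- stats::quantile(s, probs = seq(0, 1, by = 0.01), names = FALSE)
  windows <- cut(s, breaks = unique(qs), include.lowest = TRUE)
  cv <- vapply(alphas, function(a) {
    s0a <- stats::quantile(s, a, names = FALSE)
    da <- r / (s + s0a)
    mads <- tapply(da, windows, stats::mad)
    mads <- mads[is.finite(mads)]
    if (length(mads) < 2L || mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1L))
  stats::quantile(s, alphas[which.min(cv)], names = FALSE)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (j in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- c(k, rest[sub[, j]])
    }
  }
  out
}

#' Select the FDR-controlled core gene set
#'
#' Genes with `q < fdr`, split by the sign of their moderated statistic and
#' ordered by `|d|` descending (stable).
#'
#' @param sam A `sam_result` from [sam_quantitative()].
#' @param fdr FDR threshold in (0, 1); `fdr = 0` selects nothing.
#' @return Data frame `gene`, `d`, `q`, `direction`
#'   (`positive`/`negative`).
#' @export
select_core_set <- function(sam, fdr) {
  stopifnot(inherits(sam, "sam_result"), fdr >= 0, fdr <= 1)
  tab <- sam$table
  sel <- tab[is.finite(tab$q) & tab$q < fdr, , drop = FALSE]
  sel <- sel[order(-abs(sel$d)), , drop = FALSE]
  data.frame(gene = sel$gene, d = sel$d, q = sel$q,
             direction = ifelse(sel$d >= 0, "positive", "negative"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign core genes to biological processes by clustering
#'
#' Average-linkage hierarchical clustering of the core genes on correlation
#' distance (1 - Pearson across samples), cut at three clusters. Each
#' cluster is labelled by majority overlap with the supplied marker gene
#' lists; a tie between marker labels, or two clusters claiming the same
#' label, is an error. Without markers (or for clusters matching no
#' marker), clusters are named `cluster_1`, `cluster_2`, ... by decreasing
#' size.
#'
#' @param expr Genes x samples expression matrix.
#' @param core_genes Character vector of at least three genes present in
#'   `expr`.
#' @param markers Optional named list of marker gene vectors, one per
#'   process label.
#' @param k Number of clusters (default 3).
#' @return Data frame `gene`, `process`.
#' @export
assign_processes <- function(expr, core_genes, markers = NULL, k = 3L) {
  core_genes <- intersect(core_genes, rownames(expr))
  if (length(core_genes) < 3L)
    stop("assign_processes: need at least 3 core genes present in expr")
  if (k > length(core_genes))
    stop("assign_processes: k exceeds the number of core genes")
  x <- expr[core_genes, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[!is.finite(cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  cl <- stats::cutree(hc, k = k)

  sizes <- sort(table(cl), decreasing = TRUE)
  labels <- stats::setNames(paste0("cluster_", seq_len(k)),
                            names(sizes))
  if (!is.null(markers)) {
    if (length(markers) == 0)
      stop("assign_processes: empty marker list")
    for (ci in names(sizes)) {
      genes_ci <- core_genes[cl == as.integer(ci)]
      ov <- vapply(markers, function(m) length(intersect(genes_ci, m)),
                   numeric(1L))
      if (max(ov) == 0) next
      top <- names(ov)[ov == max(ov)]
      if (length(top) > 1L)
        stop("assign_processes: marker-label tie for a cluster (",
             paste(top, collapse = " vs "), ")")
      if (top %in% labels[names(labels) != ci])
        stop("assign_processes: two clusters claim marker label ", top)
      labels[ci] <- top
    }
  }
  data.frame(gene = core_genes,
             process = unname(labels[as.character(cl)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability `P(X >= |a intersect b|)` of drawing at least the
#' observed overlap when `|b|` genes are sampled from a universe containing
#' `|a|` marked genes. Zero overlap gives p = 1.
#'
#' @param set_a,set_b Character vectors (de-duplicated internally).
#' @param universe_size Size of the gene universe; both sets must fit.
#' @return List with `overlap` and `p`.
#' @export
geneset_overlap_test <- function(set_a, set_b, universe_size) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) > universe_size || length(b) > universe_size)
    stop("geneset_overlap_test: set larger than universe")
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), universe_size - length(a),
                     length(b), lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Batch gene-set overlap tests with Benjamini-Hochberg adjustment
#'
#' @param sets_a Named list of gene sets tested against `set_b`.
#' @param set_b Reference gene set.
#' @param universe_size Size of the gene universe.
#' @return Data frame `set`, `overlap`, `p`, `p_adj` (BH across the batch).
#' @export
geneset_overlap_tests <- function(sets_a, set_b, universe_size) {
  res <- lapply(sets_a, geneset_overlap_test, set_b = set_b,
                universe_size = universe_size)
  data.frame(
    set = names(sets_a),
    overlap = vapply(res, `[[`, numeric(1L), "overlap"),
    p = vapply(res, `[[`, numeric(1L), "p"),
    p_adj = stats::p.adjust(vapply(res, `[[`, numeric(1L), "p"), "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
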