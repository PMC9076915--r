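#' Ordered probe-level copy-number profile
#'
#' A data frame of probes ordered by (chromosome, position) carrying log2
#' tumor/normal ratios, with the sample's tumor purity attached as an
#' attribute.
#'
#' @param chrom Chromosome per probe.
#' @param pos 1-based probe position, strictly increasing within chromosome.
#' @param logr Finite log2 ratio per probe.
#' @param purity Tumor cell fraction in (0, 1].
#' @return Data frame of class `cn_profile` with attribute `purity`.
#' @export
cn_profile <- function(chrom, pos, logr, purity) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(logr))
  if (!is.numeric(purity) || length(purity) != 1L || purity <= 0 || purity > 1)
    stop("cn_profile: purity must be a single value in (0, 1]")
  if (any(!is.finite(logr))) stop("cn_profile: logr must be finite")
  bad <- unlist(tapply(pos, chrom, function(p) any(diff(p) <= 0)))
  if (any(bad))
    stop("cn_profile: positions must be strictly increasing within ",
         paste(names(bad)[bad], collapse = ", "))
  structure(
    data.frame(chrom = as.character(chrom), pos = as.integer(pos),
               logr = as.numeric(logr), stringsAsFactors = FALSE),
    purity = purity, class = c("cn_profile", "data.frame")
  )
}

#' Purity-adjust copy-number log ratios
#'
#' Inverts the two-component tumor/normal mixture: the observed bulk copy
#' ratio is `purity * 2^logr_true + (1 - purity)`, so
#' `logr_adj = log2(max((2^logr_obs - (1 - purity)) / purity, eps))`. Deep
#' observed losses whose inverted ratio would drop below `eps` are floored
#' at `log2(eps)` and flagged via the `clipped` attribute.
#'
#' @param logr_obs Observed log2 ratio(s).
#' @param purity Tumor cell fraction in (0, 1].
#' @param eps Floor for the inverted copy ratio (default 0.01).
#' @return Adjusted log2 ratio(s), with a logical `clipped` attribute.
#' @export
purity_adjust_logr <- function(logr_obs, purity, eps = 0.01) {
  if (!is.numeric(purity) || any(purity <= 0) || any(purity > 1))
    stop("purity_adjust_logr: purity must lie in (0, 1]")
  arg <- (2^logr_obs - (1 - purity)) / purity
  clipped <- arg < eps
  out <- log2(pmax(arg, eps))
  attr(out, "clipped") <- clipped
  out
}

#' Purity-adjust variant allele frequencies
#'
#' Under the copy-neutral heterozygous assumption a clonal variant at
#' cellular VAF `v` is observed at `purity * v`, so the adjustment is the
#' linear rescaling `min(vaf_obs / purity, 1)`; values driven above 1 are
#' capped and flagged via the `capped` attribute.
#'
#' @param vaf_obs Observed allele frequency in \[0, 1\] (NA passed through).
#' @param purity Tumor cell fraction in (0, 1].
#' @return Adjusted VAF(s) with a logical `capped` attribute.
#' @export
purity_adjust_vaf <- function(vaf_obs, purity) {
  if (!is.numeric(purity) || any(purity <= 0) || any(purity > 1))
    stop("purity_adjust_vaf: purity must lie in (0, 1]")
  raw <- vaf_obs / purity
  capped <- !is.na(raw) & raw > 1
  out <- pmin(raw, 1)
  attr(out, "capped") <- capped
  out
}

#' Probe-wise pre-minus-post purity-adjusted copy-number delta
#'
#' Adjusts each profile for its own purity, then subtracts the
#' post-treatment (surgery) log ratio from the pre-treatment (biopsy) log
#' ratio per probe. Restoration of a pre-only loss therefore shows up as a
#' negative delta over the affected block.
#'
#' @param pre,post [cn_profile()] objects on identical probe grids.
#' @return Data frame `chrom`, `pos`, `delta`.
#' @export
paired_delta <- function(pre, post) {
  stopifnot(inherits(pre, "cn_profile"), inherits(post, "cn_profile"))
  same <- nrow(pre) == nrow(post) &&
    all(pre$chrom == post$chrom) && all(pre$pos == post$pos)
  if (!same) {
    if (nrow(pre) != nrow(post))
      stop("paired_delta: probe grids differ in length (",
           nrow(pre), " vs ", nrow(post), ")")
    i <- which(pre$chrom != post$chrom | pre$pos != post$pos)[1]
    stop("paired_delta: probe grids disagree first at index ", i, " (",
         pre$chrom[i], ":", pre$pos[i], " vs ",
         post$chrom[i], ":", post$pos[i], ")")
  }
  adj_pre <- purity_adjust_logr(pre$logr, attr(pre, "purity"))
  adj_post <- purity_adjust_logr(post$logr, attr(post, "purity"))
  data.frame(chrom = pre$chrom, pos = pre$pos,
             delta = as.numeric(adj_pre) - as.numeric(adj_post),
             stringsAsFactors = FALSE)
}

# best binary split of x maximizing the two-sample t statistic; returns
# list(split, t) or NULL when no admissible split exists
best_split <- function(x, min_probes) {
  n <- length(x)
  if (n < 2L * min_probes) return(NULL)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- min_probes:(n - min_probes)      # size of the left side
  n1 <- k
  n2 <- n - k
  s1 <- cs[k]
  s2 <- cs[n] - s1
  m1 <- s1 / n1
  m2 <- s2 / n2
  ss1 <- cs2[k] - s1^2 / n1
  ss2 <- (cs2[n] - cs2[k]) - s2^2 / n2
  sp2 <- pmax(ss1 + ss2, 0) / pmax(n1 + n2 - 2L, 1L)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- ifelse(denom > 0, abs(m1 - m2) / denom,
                 ifelse(abs(m1 - m2) > 0, Inf, 0))
  best <- which.max(tval)
  list(split = k[best], t = tval[best])
}

segment_one <- function(x, min_probes, t_threshold) {
  rec <- function(lo, hi) {
    bs <- best_split(x[lo:hi], min_probes)
    if (!is.null(bs) && is.finite(t_threshold) && bs$t > t_threshold) {
      mid <- lo + bs$split - 1L
      return(rbind(rec(lo, mid), rec(mid + 1L, hi)))
    }
    cbind(lo, hi)
  }
  rec(1L, length(x))
}

#' Segment a copy-number delta track by recursive binary splitting
#'
#' Within each chromosome, repeatedly places the split that maximizes the
#' two-sample t statistic between the left and right means; a split is
#' accepted when `|t| > t_threshold` and both sides hold at least
#' `min_probes` probes, and segmentation recurses into both sides. The
#' emitted segments tile the probe set, and each segment mean is the exact
#' arithmetic mean of its member deltas.
#'
#' @param delta Data frame `chrom`, `pos`, `delta` (as from
#'   [paired_delta()]).
#' @param min_probes Minimum probes per side of an accepted split
#'   (default 10, must be at least 2).
#' @param t_threshold t-statistic acceptance threshold (default 4);
#'   `Inf` never splits.
#' @param sample Sample label written into the segment table.
#' @return Data frame `sample`, `chrom`, `start`, `end` (1-based inclusive
#'   probe positions), `n_probes`, `mean_delta`.
#' @export
segment_delta <- function(delta, min_probes = 10L, t_threshold = 4,
                          sample = "delta") {
  stopifnot(min_probes >= 2L)
  out <- lapply(unique(delta$chrom), function(ch) {
    d <- delta[delta$chrom == ch, ]
    bounds <- segment_one(d$delta, min_probes, t_threshold)
    data.frame(
      sample = sample, chrom = ch,
      start = d$pos[bounds[, 1]], end = d$pos[bounds[, 2]],
      n_probes = bounds[, 2] - bounds[, 1] + 1L,
      mean_delta = vapply(seq_len(nrow(bounds)), function(i)
        mean(d$delta[bounds[i, 1]:bounds[i, 2]]), numeric(1L)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Filter somatic variants on allele frequency and coding effect
#'
#' Retains variants with an allele frequency strictly above `af_cutoff` in
#' either the pre- or the post-treatment sample and an effect on the
#' protein-coding sequence. Missing VAFs (zero depth) never satisfy the
#' frequency condition.
#'
#' @param variants Variant data frame with `vaf_pre`, `vaf_post`,
#'   `effect_class` columns.
#' @param af_cutoff Allele-frequency cutoff (default 0.10, strict).
#' @return The retained subset, row order preserved.
#' @export
filter_somatic_variants <- function(variants, af_cutoff = 0.10) {
  above <- function(v) !is.na(v) & v > af_cutoff
  keep <- (above(variants$vaf_pre) | above(variants$vaf_post)) &
    variants$effect_class == "coding"
  variants[keep, , drop = FALSE]
}

#' Classify pre/post sharing of somatic variants
#'
#' Per sample a variant is `present` when its VAF reaches `present_af`,
#' `absent` when its VAF is at most `absent_af` with depth at least
#' `absent_min_depth` (absence is never called from shallow data), and
#' `uncertain` otherwise. Sharing is `shared` (present, present),
#' `pre_only` (present, absent), `post_only` (absent, present), and
#' `indeterminate` for every other combination.
#'
#' @param variants Variant data frame with `vaf_pre`, `vaf_post`,
#'   `dp_pre`, `dp_post`.
#' @param present_af Presence threshold (default 0.10).
#' @param absent_af Absence threshold (default 0.02); must be below
#'   `present_af`.
#' @param absent_min_depth Minimum depth to call absence (default 20).
#' @return `variants` with a `sharing` column filled in.
#' @export
classify_variant_sharing <- function(variants, present_af = 0.10,
                                     absent_af = 0.02,
                                     absent_min_depth = 20L) {
  if (absent_af >= present_af)
    stop("classify_variant_sharing: absent_af must be below present_af")
  state <- function(vaf, dp) {
    ifelse(!is.na(vaf) & vaf >= present_af, "present",
           ifelse(!is.na(vaf) & vaf <= absent_af & dp >= absent_min_depth,
                  "absent", "uncertain"))
  }
  s_pre <- state(variants$vaf_pre, variants$dp_pre)
  s_post <- state(variants$vaf_post, variants$dp_post)
  variants$sharing <- ifelse(
    s_pre == "present" & s_post == "present", "shared",
    ifelse(s_pre == "present" & s_post == "absent", "pre_only",
           ifelse(s_pre == "absent" & s_post == "present", "post_only",
                  "indeterminate")))
  variants
}

#' Test an aberration frequency against a reference cohort
#'
#' With a reference cohort size, builds the 2x2 table of aberrated versus
#' non-aberrated cases in this cohort against `round(ref_freq * ref_n)`
#' aberrated reference cases and applies a one-sided (greater) Fisher exact
#' test. Without `ref_n`, computes the exact binomial upper tail
#' `P(X >= k | n, ref_freq)`.
#'
#' @param k Aberrated cases observed, `0 <= k <= n`.
#' @param n Cohort size.
#' @param ref_freq Reference aberration frequency in \[0, 1\].
#' @param ref_n Optional reference cohort size.
#' @return One-sided p-value.
#' @export
aberration_frequency_test <- function(k, n, ref_freq, ref_n = NULL) {
  stopifnot(ref_freq >= 0, ref_freq <= 1)
  if (k < 0 || k > n) stop("aberration_frequency_test: need 0 <= k <= n")
  if (is.null(ref_n)) {
    stats::pbinom(k - 1, n, ref_freq, lower.tail = FALSE)
  } else {
    k_ref <- round(ref_freq * ref_n)
    tab <- matrix(c(k, n - k, k_ref, ref_n - k_ref), nrow = 2L)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }
}

#' Combined per-gene aberration table across timepoints
#'
#' A gene counts as aberrated at a timepoint when it carries a retained
#' variant present there (VAF at or above `present_af`) or its region
#' overlaps a copy-number segment of that timepoint whose mean adjusted log
#' ratio reaches the amplification or loss threshold. Gene regions outside
#' the probed span overlap no segment and are counted as not covered, with
#' a warning.
#'
#' @param variants Retained variant data frame (`gene`, `chrom`, `pos`,
#'   `vaf_pre`, `vaf_post`).
#' @param segments Segment table with `timepoint` (`pre`/`post`), `chrom`,
#'   `start`, `end`, `mean_logr` of the purity-adjusted per-timepoint
#'   profile.
#' @param gene_regions Data frame `gene`, `chrom`, `start`, `end`.
#' @param amp_threshold,del_threshold Mean adjusted log-ratio cutoffs for
#'   amplification (default +0.8) and loss (default -0.8).
#' @param present_af Variant presence threshold (default 0.10).
#' @return Data frame `gene`, `pre`, `post` with 0/1 aberration indicators
#'   per timepoint.
#' @export
recurrent_gene_table <- function(variants, segments, gene_regions,
                                 amp_threshold = 0.8, del_threshold = -0.8,
                                 present_af = 0.10) {
  seg_hit <- function(tp, g) {
    s <- segments[segments$timepoint == tp & segments$chrom == g$chrom, ,
                  drop = FALSE]
    ov <- s$start <= g$end & s$end >= g$start
    if (!any(ov)) return(NA)  # region not covered by this timepoint
    any(s$mean_logr[ov] >= amp_threshold | s$mean_logr[ov] <= del_threshold)
  }
  var_hit <- function(vaf_col, g) {
    v <- variants[variants$gene == g$gene, , drop = FALSE]
    nrow(v) > 0 && any(!is.na(v[[vaf_col]]) & v[[vaf_col]] >= present_af)
  }
  res <- lapply(seq_len(nrow(gene_regions)), function(i) {
    g <- gene_regions[i, ]
    hits <- c(pre = seg_hit("pre", g), post = seg_hit("post", g))
    if (anyNA(hits)) {
      warning("recurrent_gene_table: region of ", g$gene,
              " not covered by segments; counted as not aberrated")
      hits[is.na(hits)] <- FALSE
    }
    data.frame(gene = g$gene,
               pre = as.integer(hits["pre"] | var_hit("vaf_pre", g)),
               post = as.integer(hits["post"] | var_hit("vaf_post", g)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
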