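#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator into one validated list. The defaults
#' describe a desk-scale HER2-negative neoadjuvant cohort: expression for
#' three latent biological processes (proliferation, immune response, ECM
#' organization) coupled to a semi-continuous response index (NRI) with
#' subtype-specific coefficients, survival with a planted hazard ratio
#' between stratification profiles, and paired pre/post-treatment genomes
#' observed through a tumor/normal purity mixture.
#'
#' @param n_tn,n_er Number of triple-negative and ER-positive samples.
#' @param n_genes_per_process Genes driven by each latent process.
#' @param n_null_genes Genes with no association to any latent.
#' @param beta_expr Expression effect size (log2 units per latent SD).
#' @param sigma_expr Per-gene expression noise SD (log2 units).
#' @param response_coefs Named list (`TN`, `ERpos`) of length-3 numeric
#'   vectors `(b_prolif, b_immune, b_ecm)` linking latents to NRI. The ECM
#'   coefficient enters with a negative sign: high ECM lowers response.
#' @param nri_intercepts Named numeric (`TN`, `ERpos`): baseline NRI per
#'   subtype. Defaults equal the printed cohort medians (0.67 TN, 0.29 ER+).
#' @param nri_sigma SD of the NRI noise added before clamping to \[0, 1\].
#' @param pcr_threshold NRI cutoff above which a sample is labelled pCR.
#' @param planted_log_hr Log hazard ratio of HHL relative to the LLH
#'   reference used by [simulate_survival()].
#' @param censor_rate Expected fraction of censored samples.
#' @param n_probes Total copy-number probes across the synthetic genome.
#' @param n_chrom Number of synthetic chromosomes the probes tile.
#' @param cn_sigma Probe-level log-ratio noise SD.
#' @param purity_range Interval within (0, 1\] from which tumor purity is
#'   drawn; default 0.4--0.9 matches the tumor percentages of the paired
#'   cohort fixture.
#' @param depth_mean Mean sequencing depth for somatic variants.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_tn = 120L, n_er = 80L,
                       n_genes_per_process = 100L, n_null_genes = 300L,
                       beta_expr = 1, sigma_expr = 1,
                       response_coefs = list(
                         TN    = c(b_prolif = 0.15, b_immune = 0.10, b_ecm = 0.12),
                         ERpos = c(b_prolif = 0.05, b_immune = 0.02, b_ecm = 0.03)
                       ),
                       nri_intercepts = c(TN = 0.67, ERpos = 0.29),
                       nri_sigma = 0.1, pcr_threshold = 0.95,
                       planted_log_hr = log(0.29), censor_rate = 0.3,
                       n_probes = 2000L, n_chrom = 4L, cn_sigma = 0.1,
                       purity_range = c(0.4, 0.9), depth_mean = 150,
                       seed = 1L) {
  cfg <- list(
    n_tn = as.integer(n_tn), n_er = as.integer(n_er),
    n_genes_per_process = as.integer(n_genes_per_process),
    n_null_genes = as.integer(n_null_genes),
    beta_expr = beta_expr, sigma_expr = sigma_expr,
    response_coefs = response_coefs, nri_intercepts = nri_intercepts,
    nri_sigma = nri_sigma, pcr_threshold = pcr_threshold,
    planted_log_hr = planted_log_hr, censor_rate = censor_rate,
    n_probes = as.integer(n_probes), n_chrom = as.integer(n_chrom),
    cn_sigma = cn_sigma, purity_range = as.numeric(purity_range),
    depth_mean = depth_mean, seed = as.integer(seed)
  )
  num <- unlist(cfg[c("n_tn", "n_er", "n_genes_per_process", "n_null_genes",
                      "beta_expr", "sigma_expr", "nri_sigma", "pcr_threshold",
                      "planted_log_hr", "censor_rate", "n_probes", "n_chrom",
                      "cn_sigma", "purity_range", "depth_mean", "seed")])
  if (any(!is.finite(num)))
    stop("sim_config: all numeric fields must be finite")
  if (any(unlist(cfg[c("n_tn", "n_genes_per_process", "n_null_genes",
                       "n_probes", "n_chrom")]) <= 0L) || cfg$n_er < 0L)
    stop("sim_config: counts must be positive")
  pr <- cfg$purity_range
  if (length(pr) != 2L || pr[1] > pr[2] || pr[1] <= 0 || pr[2] > 1)
    stop("sim_config: purity_range must be an interval within (0, 1]")
  if (cfg$pcr_threshold <= 0 || cfg$pcr_threshold >= 1)
    stop("sim_config: pcr_threshold must lie in (0, 1)")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("sim_config: censor_rate must lie in [0, 1)")
  for (st in c("TN", "ERpos")) {
    if (is.null(cfg$response_coefs[[st]]) ||
        length(cfg$response_coefs[[st]]) != 3L ||
        any(!is.finite(cfg$response_coefs[[st]])))
      stop("sim_config: response_coefs$", st,
           " must be a finite numeric triple")
  }
  structure(cfg, class = "sim_config")
}

process_names <- function() c("proliferation", "immune", "ECM")

latent_profile <- function(z) {
  # Ground truth follows the sign pattern of the latents: HHL needs high
  # proliferation and immune activity with low ECM; LLH is the mirror image.
  ifelse(z[, 1] > 0 & z[, 2] > 0 & z[, 3] < 0, "HHL",
         ifelse(z[, 1] < 0 & z[, 2] < 0 & z[, 3] > 0, "LLH", "other"))
}

#' Simulate a treatment-naive expression cohort
#'
#' Draws per-sample standard-normal latent activities for proliferation,
#' immune response and ECM organization; expression of a process gene g in
#' sample j is `mu_g + beta_expr * z_proc(g),j + N(0, sigma_expr)` on the
#' log2 scale (null genes omit the latent term). NRI is a clamped linear
#' response `intercept + b_p z_p + b_i z_i - b_e z_e + noise`, and pCR is
#' called when NRI reaches `pcr_threshold`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `expression` (genes x samples log2 matrix),
#'   `annotation` (sample annotation data frame), `assignment` (data frame
#'   mapping process genes to their generating process), and `latents`
#'   (per-sample latent activities with the sign-derived `true_profile`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_tn + config$n_er
  subtype <- rep(c("TN", "ERpos"), c(config$n_tn, config$n_er))
  sample_id <- sprintf("S%04d", seq_len(n))

  z <- matrix(stats::rnorm(n * 3L), n, 3L,
              dimnames = list(sample_id, c("z_prolif", "z_immune", "z_ecm")))

  gpp <- config$n_genes_per_process
  procs <- process_names()
  gene_proc <- rep(procs, each = gpp)
  gene_ids <- c(sprintf("PRO%04d", seq_len(gpp)),
                sprintf("IMM%04d", seq_len(gpp)),
                sprintf("ECM%04d", seq_len(gpp)),
                sprintf("NUL%04d", seq_len(config$n_null_genes)))
  n_genes <- length(gene_ids)
  mu <- stats::rnorm(n_genes, mean = 8, sd = 1)

  expr <- matrix(mu, n_genes, n) +
    matrix(stats::rnorm(n_genes * n, sd = config$sigma_expr), n_genes, n)
  for (k in seq_along(procs)) {
    rows <- seq_len(gpp) + (k - 1L) * gpp
    expr[rows, ] <- expr[rows, ] +
      config$beta_expr * matrix(z[, k], gpp, n, byrow = TRUE)
  }
  dimnames(expr) <- list(gene_ids, sample_id)

  b <- t(vapply(subtype, function(st) config$response_coefs[[st]],
                numeric(3L)))
  intercept <- config$nri_intercepts[subtype]
  nri_raw <- intercept + b[, 1] * z[, 1] + b[, 2] * z[, 2] - b[, 3] * z[, 3] +
    stats::rnorm(n, sd = config$nri_sigma)
  nri <- pmin(pmax(nri_raw, 0), 1)
  pcr <- ifelse(nri >= config$pcr_threshold, "yes", "no")

  annotation <- data.frame(
    sample_id = sample_id, patient_id = sample_id, subtype = subtype,
    timepoint = "pre", nri = nri, pcr = pcr,
    rfs_time = NA_real_, rfs_event = NA_integer_, purity = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  latents <- data.frame(sample_id = sample_id, z,
                        true_profile = latent_profile(z),
                        stringsAsFactors = FALSE, row.names = NULL)
  assignment <- data.frame(gene = gene_ids[seq_len(3L * gpp)],
                           process = gene_proc, stringsAsFactors = FALSE)
  list(expression = expr, annotation = annotation,
       assignment = assignment, latents = latents)
}

#' Simulate recurrence-free survival with a planted profile hazard ratio
#'
#' Event times are exponential with rate `lambda0 * exp(planted_log_hr)` for
#' HHL samples and `lambda0` otherwise (LLH is the reference; `other`
#' samples sit at the reference hazard). A fraction `censor_rate` of samples
#' is censored at a uniform point before their event time, so `censor_rate
#' = 0` leaves every event observed.
#'
#' @param annotation Sample annotation data frame (must carry `sample_id`).
#' @param profiles Data frame with `sample_id` and `profile` columns, or a
#'   character vector of profiles named by sample id; every annotation
#'   sample must be covered.
#' @param planted_log_hr Log hazard ratio, HHL versus the LLH reference.
#' @param censor_rate Expected fraction censored, in \[0, 1).
#' @param seed Integer seed.
#' @param lambda0 Baseline exponential hazard.
#' @return The annotation with `rfs_time` and `rfs_event` filled in.
#' @export
simulate_survival <- function(annotation, profiles, planted_log_hr,
                              censor_rate = 0.3, seed = 1L, lambda0 = 0.1) {
  if (is.data.frame(profiles)) {
    prof <- profiles$profile
    names(prof) <- profiles$sample_id
  } else prof <- profiles
  missing_ids <- setdiff(annotation$sample_id, names(prof))
  if (length(missing_ids) > 0)
    stop("simulate_survival: no profile for sample(s) ",
         paste(utils::head(missing_ids, 3L), collapse = ", "))
  p <- prof[annotation$sample_id]
  if (anyNA(p)) stop("simulate_survival: missing profile values")
  set.seed(as.integer(seed))
  n <- nrow(annotation)
  rate <- lambda0 * exp(planted_log_hr * (p == "HHL"))
  t_event <- stats::rexp(n, rate = rate)
  censored <- stats::rbinom(n, 1L, censor_rate) == 1L
  annotation$rfs_time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  annotation$rfs_event <- as.integer(!censored)
  annotation
}

#' Forward purity mixing of a copy-number log ratio
#'
#' Observed bulk signal is a two-component mixture of tumor (copy ratio
#' `2^logr_true`) and normal (ratio 1) tissue:
#' `log2(purity * 2^logr_true + (1 - purity))`.
#'
#' @param logr_true True tumor log2 copy ratio.
#' @param purity Tumor cell fraction in (0, 1].
#' @return Observed (mixed) log2 ratio.
#' @export
mix_logr <- function(logr_true, purity) {
  stopifnot(all(purity > 0), all(purity <= 1))
  log2(purity * 2^logr_true + (1 - purity))
}

#' Simulate paired pre/post-treatment copy-number and variant data
#'
#' Builds a blockwise integer copy-number genome shared by the pre- and
#' post-treatment samples, plants one block lost in the pre-treatment sample
#' only (single-copy loss restored after therapy, the CDKN1B-like event),
#' observes probe log ratios through [mix_logr()] at per-sample purities
#' plus Gaussian noise, and draws somatic variants with binomial read
#' sampling at clonal VAF 0.5 diluted by purity, planting shared, pre-only
#' and post-only events.
#'
#' @param config A [sim_config()] object.
#' @return List with `pre` and `post` [cn_profile()] objects, `variants`
#'   (data frame with per-sample depths, alt counts and VAFs), and `truth`
#'   (latent states: true per-probe log ratios, purities, the planted loss
#'   region and gene, and true variant sharing).
#' @export
simulate_paired_genomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  per_chrom <- rep(config$n_probes %/% config$n_chrom, config$n_chrom)
  per_chrom[config$n_chrom] <- config$n_probes - sum(per_chrom[-config$n_chrom])
  chrom <- rep(sprintf("chr%d", seq_len(config$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(m) seq_len(m) * 1000L),
                use.names = FALSE)

  # blockwise true copy-number states (diploid baseline), geometric blocks
  cn_states <- c(1L, 2L, 3L, 4L)
  cn_probs <- c(0.10, 0.70, 0.12, 0.08)
  cn <- integer(config$n_probes)
  block_id <- integer(config$n_probes)
  nb <- 0L
  offset <- 0L
  for (m in per_chrom) {
    i <- 1L
    while (i <= m) {
      len <- min(stats::rgeom(1L, 1 / 50) + 10L, m - i + 1L)
      nb <- nb + 1L
      idx <- offset + i:(i + len - 1L)
      cn[idx] <- sample(cn_states, 1L, prob = cn_probs)
      block_id[idx] <- nb
      i <- i + len
    }
    offset <- offset + m
  }

  cn_pre <- cn
  cn_post <- cn
  # planted pre-only single-copy loss: pick a chr1 block (preferring one of
  # at least 30 probes), force it diploid post-treatment, lost pre-treatment
  cand <- unique(block_id[chrom == "chr1"])
  sizes <- vapply(cand, function(bid) sum(block_id == bid), integer(1L))
  big <- cand[sizes >= 30L]
  loss_block <- if (length(big) > 0) big[ceiling(length(big) / 2)]
                else cand[which.max(sizes)]
  cn_pre[block_id == loss_block] <- 1L
  cn_post[block_id == loss_block] <- 2L
  loss_idx <- which(block_id == loss_block)
  loss_region <- data.frame(
    gene = "LOSS01", chrom = "chr1",
    start = pos[min(loss_idx)], end = pos[max(loss_idx)],
    stringsAsFactors = FALSE
  )

  purity_pre <- stats::runif(1L, config$purity_range[1], config$purity_range[2])
  purity_post <- stats::runif(1L, config$purity_range[1], config$purity_range[2])
  r_true_pre <- log2(cn_pre / 2)
  r_true_post <- log2(cn_post / 2)
  logr_pre <- mix_logr(r_true_pre, purity_pre) +
    stats::rnorm(config$n_probes, sd = config$cn_sigma)
  logr_post <- mix_logr(r_true_post, purity_post) +
    stats::rnorm(config$n_probes, sd = config$cn_sigma)

  pre <- cn_profile(chrom, pos, logr_pre, purity_pre)
  post <- cn_profile(chrom, pos, logr_post, purity_post)

  # somatic variants: shared, pre-only, post-only; clonal het VAF 0.5
  n_sh <- 20L; n_pre <- 5L; n_post <- 5L
  n_var <- n_sh + n_pre + n_post
  truth_sharing <- rep(c("shared", "pre_only", "post_only"),
                       c(n_sh, n_pre, n_post))
  vidx <- sort(sample.int(config$n_probes, n_var))
  effect <- rep("coding", n_var)
  effect[seq_len(min(4L, n_sh))] <- "non_coding"
  vaf_clonal <- 0.5
  dp_pre <- pmax(stats::rpois(n_var, config$depth_mean), 1L)
  dp_post <- pmax(stats::rpois(n_var, config$depth_mean), 1L)
  p_pre <- ifelse(truth_sharing %in% c("shared", "pre_only"),
                  purity_pre * vaf_clonal, 0.001)
  p_post <- ifelse(truth_sharing %in% c("shared", "post_only"),
                   purity_post * vaf_clonal, 0.001)
  alt_pre <- stats::rbinom(n_var, dp_pre, p_pre)
  alt_post <- stats::rbinom(n_var, dp_post, p_post)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  variants <- data.frame(
    chrom = chrom[vidx], pos = pos[vidx], ref = ref, alt = alt,
    gene = sprintf("MUT%03d", seq_len(n_var)), effect_class = effect,
    dp_pre = dp_pre, dp_post = dp_post,
    alt_pre = alt_pre, alt_post = alt_post,
    vaf_pre = ifelse(dp_pre > 0, alt_pre / dp_pre, NA_real_),
    vaf_post = ifelse(dp_post > 0, alt_post / dp_post, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )

  truth <- list(
    seed = config$seed,
    purity_pre = purity_pre, purity_post = purity_post,
    logr_true_pre = r_true_pre, logr_true_post = r_true_post,
    loss_region = loss_region, variant_sharing = truth_sharing,
    vaf_clonal = vaf_clonal
  )
  list(pre = pre, post = post, variants = variants, truth = truth)
}
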