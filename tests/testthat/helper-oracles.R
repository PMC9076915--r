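# Shared oracles and tiny fixtures, built in code.

# Six-variant toy table exercising the >10%/coding retention rule;
# exactly rows 1, 2 and 5 survive it.
toy_variants <- function() {
  data.frame(
    chrom = "chr1", pos = 1:6 * 100L,
    ref = "A", alt = "T",
    gene = sprintf("G%02d", 1:6),
    effect_class = c("coding", "coding", "coding", "non_coding",
                     "coding", "coding"),
    dp_pre = 100L, dp_post = 100L,
    vaf_pre = c(0.20, 0.00, 0.05, 0.50, 0.11, 0.10),
    vaf_post = c(0.00, 0.20, 0.05, 0.50, 0.00, 0.10),
    stringsAsFactors = FALSE
  )
}

# Breslow partial log-likelihood for a single binary covariate, written
# directly from its definition (each tied event keeps the full risk set).
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Pure grid maximization of the Breslow partial likelihood with three
# refinement passes; independent of any model-fitting routine.
grid_max_loglik <- function(time, event, x,
                            lo = -5, hi = 5, n_grid = 2001L, passes = 4L) {
  for (p in seq_len(passes)) {
    grid <- seq(lo, hi, length.out = n_grid)
    ll <- vapply(grid, breslow_loglik, numeric(1L),
                 time = time, event = event, x = x)
    best <- which.max(ll)
    step <- grid[2] - grid[1]
    lo <- grid[best] - 2 * step
    hi <- grid[best] + 2 * step
  }
  grid[best]
}
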