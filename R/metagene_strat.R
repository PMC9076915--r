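#' Per-sample metagene scores
#'
#' The metagene score of a process in a sample is the median log2
#' expression of the genes assigned to that process. Processes must map to
#' at least one gene present in the matrix.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param assignment Data frame `gene`, `process` with processes
#'   `proliferation`, `immune`, `ECM`.
#' @return Data frame of class `metagene_scores`: `sample_id`,
#'   `score_prolif`, `score_immune`, `score_ecm`.
#' @export
metagene_scores <- function(expr, assignment) {
  cols <- c(proliferation = "score_prolif", immune = "score_immune",
            ECM = "score_ecm")
  out <- data.frame(sample_id = colnames(expr), stringsAsFactors = FALSE)
  for (proc in names(cols)) {
    genes <- intersect(assignment$gene[assignment$process == proc],
                       rownames(expr))
    if (length(genes) == 0)
      stop("metagene_scores: no genes in matrix for process ", proc)
    out[[cols[[proc]]]] <-
      apply(expr[genes, , drop = FALSE], 2L, stats::median)
  }
  structure(out, class = c("metagene_scores", "data.frame"))
}

#' Dichotomize metagene scores into HHL/LLH/other profiles
#'
#' Per process, the threshold is the median of that metagene over the
#' cohort samples (`cohort_mask`); a sample is called H when its score lies
#' strictly above the threshold and L otherwise, so a single-sample cohort
#' is all L. The profile is `HHL` for calls (H, H, L) in (proliferation,
#' immune, ECM) order, `LLH` for (L, L, H), and `other` otherwise.
#' Thresholds are meant to be recomputed within each cohort being
#' stratified (e.g. per subtype).
#'
#' @param scores A [metagene_scores()] data frame.
#' @param cohort_mask Logical vector over rows of `scores`, or character
#'   vector of sample ids, defining the cohort whose medians set the
#'   thresholds; default all samples.
#' @return `scores` with `call_prolif`, `call_immune`, `call_ecm` and
#'   `profile` columns added; thresholds attached as attribute
#'   `thresholds`.
#' @export
stratify <- function(scores, cohort_mask = NULL) {
  if (is.null(cohort_mask)) cohort_mask <- rep(TRUE, nrow(scores))
  if (is.character(cohort_mask))
    cohort_mask <- scores$sample_id %in% cohort_mask
  if (!any(cohort_mask)) stop("stratify: empty cohort_mask")
  score_cols <- c("score_prolif", "score_immune", "score_ecm")
  call_cols <- c("call_prolif", "call_immune", "call_ecm")
  thr <- numeric(3L)
  for (i in seq_len(3L)) {
    v <- scores[[score_cols[i]]][cohort_mask]
    thr[i] <- stats::median(v)
    if (length(unique(v)) == 1L)
      warning("stratify: degenerate metagene ", score_cols[i],
              " (all scores identical); every call is L")
    scores[[call_cols[i]]] <-
      ifelse(scores[[score_cols[i]]] > thr[i], "H", "L")
  }
  scores$profile <- ifelse(
    scores$call_prolif == "H" & scores$call_immune == "H" &
      scores$call_ecm == "L", "HHL",
    ifelse(scores$call_prolif == "L" & scores$call_immune == "L" &
             scores$call_ecm == "H", "LLH", "other"))
  attr(scores, "thresholds") <- stats::setNames(thr, score_cols)
  scores
}

#' Compare response between the HHL and LLH profiles
#'
#' Two-sided Wilcoxon rank-sum test of NRI between the HHL and LLH groups
#' (normal approximation without continuity correction, robust to ties)
#' and a two-sided Fisher exact test of the 2x2 responder table. The
#' responder definition uses a `npcr` column (pCR or near-pCR) when the
#' annotation provides one, otherwise `pcr == "yes"`. A test whose groups
#' are empty or whose inputs are all missing is reported as skipped with a
#' reason rather than an error.
#'
#' @param profiles Data frame with `sample_id` and `profile`.
#' @param annotation Sample annotation with `nri` and `pcr` (optionally
#'   `npcr`).
#' @return List with `n_hhl`, `n_llh`, `wilcoxon` (list `p`, `statistic`
#'   or `skipped` reason) and `fisher` (list `p`, `table` or `skipped`
#'   reason).
#' @export
profile_response_tests <- function(profiles, annotation) {
  m <- merge(profiles[, c("sample_id", "profile")], annotation,
             by = "sample_id")
  m <- m[m$profile %in% c("HHL", "LLH"), , drop = FALSE]
  grp <- factor(m$profile, levels = c("HHL", "LLH"))
  out <- list(n_hhl = sum(grp == "HHL"), n_llh = sum(grp == "LLH"))

  nri_ok <- !is.na(m$nri)
  if (out$n_hhl == 0 || out$n_llh == 0) {
    out$wilcoxon <- list(skipped = "empty HHL or LLH group")
  } else if (sum(nri_ok & grp == "HHL") == 0 ||
             sum(nri_ok & grp == "LLH") == 0) {
    out$wilcoxon <- list(skipped = "no non-missing NRI in a group")
  } else {
    wt <- stats::wilcox.test(m$nri[nri_ok] ~ droplevels(grp[nri_ok]),
                             exact = FALSE, correct = FALSE)
    out$wilcoxon <- list(p = wt$p.value, statistic = unname(wt$statistic))
  }

  responder <- if ("npcr" %in% colnames(m)) m$npcr == "yes"
               else m$pcr == "yes"
  resp_ok <- !is.na(responder)
  if (out$n_hhl == 0 || out$n_llh == 0 ||
      sum(resp_ok & grp == "HHL") == 0 || sum(resp_ok & grp == "LLH") == 0) {
    out$fisher <- list(skipped = "empty or all-missing responder group")
  } else {
    tab <- table(grp[resp_ok],
                 factor(ifelse(responder[resp_ok], "responder",
                               "non_responder"),
                        levels = c("responder", "non_responder")))
    out$fisher <- list(p = stats::fisher.test(tab)$p.value,
                       table = tab)
  }
  out
}
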