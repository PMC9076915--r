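#' Run the full stratification and paired-genomics pipeline
#'
#' Orchestrates simulate (or load) -> response association -> metagene
#' stratification -> survival comparison -> paired pre/post genomics and
#' writes every stage product plus a machine-readable `report.json` into
#' `out_dir`. The run is driven by a single seed from which each stage's
#' seed is derived by a fixed offset, so stages are individually
#' reproducible and an identical config yields a byte-identical report.
#'
#' The config is a list with exactly one of:
#' \describe{
#'   \item{`simulation`}{arguments for [sim_config()];}
#'   \item{`inputs`}{paths `expression`, `annotation` (and optionally
#'     `markers`, a TSV with `gene`, `process`).}
#' }
#' plus optional `params` (`n_perm`, `fdr`, `t_threshold`, `min_probes`,
#' `present_af`, `absent_af`, `absent_min_depth`) and `seed`.
#'
#' @param config Run configuration list (or path to a YAML file encoding
#'   it, when the yaml package is available).
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress stage logging to stderr.
#' @return The report, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("run_pipeline: reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs)
    stop("run_pipeline: exactly one of 'simulation' or 'inputs' ",
         "must be present in the config")
  seed <- as.integer(config$seed %||% 1L)
  params <- utils::modifyList(
    list(n_perm = 1000L, fdr = 0.05, t_threshold = 4, min_probes = 10L,
         present_af = 0.10, absent_af = 0.02, absent_min_depth = 20L),
    config$params %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(...) if (!quiet) message("[neostrat] ", ...)
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    written <<- c(written, p)
    p
  }

  report <- list(seed = seed, params = params,
                 package_version = as.character(
                   utils::packageVersion("neostrat")))
  tryCatch({
    # ---- stage 1: cohort ------------------------------------------------
    note("stage cohort")
    if (has_sim) {
      sc <- do.call(sim_config, utils::modifyList(config$simulation,
                                                  list(seed = seed)))
      cohort <- simulate_cohort(sc)
      expr <- cohort$expression
      ann <- cohort$annotation
      markers <- split(cohort$assignment$gene, cohort$assignment$process)
      emit("expression.tsv", function(p) write_expression(expr, p))
      emit("annotation.tsv", function(p) write_annotation(ann, p))
    } else {
      expr <- read_expression(config$inputs$expression)
      ann <- read_annotation(config$inputs$annotation)
      markers <- if (!is.null(config$inputs$markers)) {
        mk <- utils::read.delim(config$inputs$markers,
                                stringsAsFactors = FALSE)
        split(mk$gene, mk$process)
      } else NULL
    }
    report$cohort <- list(
      n_samples = ncol(expr), n_genes = nrow(expr),
      n_tn = sum(ann$subtype == "TN"), n_er = sum(ann$subtype == "ERpos"))

    # ---- stage 2: response association (core set learned on TN) --------
    note("stage associate")
    tn <- ann$subtype == "TN"
    sam <- sam_quantitative(expr[, tn, drop = FALSE], ann$nri[tn],
                            n_perm = params$n_perm, seed = seed + 1000L)
    emit("sam.tsv", function(p)
      utils::write.table(sam$table, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    core <- select_core_set(sam, params$fdr)
    report$associate <- list(n_genes_tested = nrow(sam$table),
                             s0 = sam$s0, n_perm = sam$n_perm,
                             n_core = nrow(core),
                             n_positive = sum(core$direction == "positive"),
                             n_negative = sum(core$direction == "negative"))

    # ---- stage 3: process assignment + stratification -------------------
    note("stage stratify")
    if (nrow(core) >= 3L) {
      assignment <- assign_processes(expr, core$gene, markers = markers)
      # a weak core set can miss a process entirely; marker genes then
      # stand in for the missing metagene so scoring stays defined
      lost <- setdiff(names(markers), unique(assignment$process))
      if (length(lost) > 0) {
        extra <- do.call(rbind, lapply(lost, function(pn)
          data.frame(gene = setdiff(markers[[pn]], assignment$gene),
                     process = pn, stringsAsFactors = FALSE)))
        assignment <- rbind(assignment, extra)
        report$stratify_note <- paste(
          "marker fallback for process(es):", paste(lost, collapse = ", "))
      }
    } else {
      # too little signal to cluster: fall back to the marker lists
      assignment <- do.call(rbind, lapply(names(markers), function(pn)
        data.frame(gene = markers[[pn]], process = pn,
                   stringsAsFactors = FALSE)))
      report$stratify_note <- "core set below 3 genes; markers used directly"
    }
    emit("assignment.tsv", function(p)
      utils::write.table(assignment, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    scores <- metagene_scores(expr, assignment)
    # thresholds recomputed within each cohort being stratified
    prof_list <- lapply(c("TN", "ERpos"), function(st) {
      idx <- ann$subtype[match(scores$sample_id, ann$sample_id)] == st
      if (!any(idx)) return(NULL)
      stratify(scores[idx, , drop = FALSE])
    })
    profiles <- do.call(rbind, prof_list)
    profiles <- profiles[match(scores$sample_id, profiles$sample_id), ,
                         drop = FALSE]
    emit("profiles.tsv", function(p)
      utils::write.table(profiles, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    counts <- table(factor(profiles$profile,
                           levels = c("HHL", "LLH", "other")))
    report$stratify <- list(n_hhl = unname(counts["HHL"]),
                            n_llh = unname(counts["LLH"]),
                            n_other = unname(counts["other"]))
    resp <- profile_response_tests(profiles, ann)
    report$response_tests <- list(
      n_hhl = resp$n_hhl, n_llh = resp$n_llh,
      wilcoxon_p = resp$wilcoxon$p %||% NA_real_,
      fisher_p = resp$fisher$p %||% NA_real_)

    # ---- stage 4: survival ----------------------------------------------
    note("stage survive")
    if (has_sim) {
      ann <- simulate_survival(ann, profiles, sc$planted_log_hr,
                               censor_rate = sc$censor_rate,
                               seed = seed + 2000L)
    }
    two <- profiles$profile %in% c("HHL", "LLH") &
      !is.na(ann$rfs_time[match(profiles$sample_id, ann$sample_id)])
    if (sum(two) >= 2L) {
      ids <- profiles$sample_id[two]
      ai <- match(ids, ann$sample_id)
      grp <- factor(profiles$profile[two], levels = c("LLH", "HHL"))
      lr <- logrank_test(ann$rfs_time[ai], ann$rfs_event[ai], grp)
      cx <- cox_two_group(ann$rfs_time[ai], ann$rfs_event[ai], grp)
      report$survival <- list(
        n = length(ids), logrank_chi2 = lr$chi2, logrank_p = lr$p,
        log_hr = cx$log_hr, hr = cx$hr, ci95 = cx$ci95, cox_p = cx$p,
        diverged = cx$diverged)
    } else {
      report$survival <- list(skipped = "fewer than 2 profiled samples with survival data")
    }

    # ---- stage 5: paired genomics ---------------------------------------
    note("stage paired-genomics")
    if (has_sim) {
      pg_cfg <- do.call(sim_config, utils::modifyList(
        config$simulation, list(seed = seed + 3000L)))
      pg <- simulate_paired_genomics(pg_cfg)
      delta <- paired_delta(pg$pre, pg$post)
      segs <- segment_delta(delta, min_probes = params$min_probes,
                            t_threshold = params$t_threshold)
      emit("delta.seg", function(p) write_seg(segs, p))
      emit("somatic.vcf", function(p) write_paired_vcf(pg$variants, p))
      retained <- filter_somatic_variants(pg$variants,
                                          af_cutoff = params$present_af)
      classified <- classify_variant_sharing(
        retained, present_af = params$present_af,
        absent_af = params$absent_af,
        absent_min_depth = params$absent_min_depth)
      emit("variants.tsv", function(p)
        utils::write.table(classified, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      report$paired_genomics <- list(
        n_probes = nrow(delta), n_segments = nrow(segs),
        purity_pre = pg$truth$purity_pre,
        purity_post = pg$truth$purity_post,
        n_variants = nrow(pg$variants), n_retained = nrow(retained),
        sharing = as.list(table(factor(
          classified$sharing,
          levels = c("shared", "pre_only", "post_only", "indeterminate")))))
    } else {
      report$paired_genomics <- list(skipped = "no paired data in input mode")
    }

    # ---- report ----------------------------------------------------------
    make_report(report, file.path(out_dir, "report.json"))
    note("done")
    invisible(report)
  }, error = function(e) {
    unlink(written)
    stop("run_pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Write the pipeline report as canonical JSON
#'
#' @param report Named list of stage summaries.
#' @param path Output JSON path.
#' @return The report, invisibly.
#' @export
make_report <- function(report, path) {
  stopifnot(length(report) > 0)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
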