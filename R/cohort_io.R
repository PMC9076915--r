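#' Read a gene x sample log2 expression matrix from TSV
#'
#' First column holds gene identifiers, the header row sample identifiers.
#' Row and column order are preserved; duplicate identifiers, non-numeric
#' cells and non-finite values are rejected.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0)
    stop("read_expression: duplicated gene id(s): ",
         paste(unique(dup), collapse = ", "))
  samples <- colnames(df)[-1]
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s) > 0)
    stop("read_expression: duplicated sample id(s): ",
         paste(unique(dup_s), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, samples))
  if (any(is.na(vals) | !is.finite(vals)))
    stop("read_expression: non-numeric or non-finite cell in ", path)
  vals
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ann_columns <- function() {
  c("sample_id", "patient_id", "subtype", "timepoint", "nri", "pcr",
    "rfs_time", "rfs_event", "purity")
}

#' Read a sample annotation table from TSV
#'
#' Expects the columns `sample_id`, `patient_id`, `subtype` (`ERpos`/`TN`),
#' `timepoint` (`pre`/`post`), `nri`, `pcr` (`yes`/`no`), `rfs_time`,
#' `rfs_event`, `purity`, with `NA` as missing-value token. Bounds and code
#' sets are enforced: NRI in \[0, 1\], purity in (0, 1\], `rfs_event`
#' present exactly when `rfs_time` is.
#'
#' @param path Path to a tab-separated file.
#' @return Typed data frame of sample annotations.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  missing_cols <- setdiff(c("sample_id", "subtype"), colnames(df))
  if (length(missing_cols) > 0)
    stop("read_annotation: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(ann_columns(), colnames(df))) df[[col]] <- NA
  df <- df[, ann_columns()]
  df$nri <- as.numeric(df$nri)
  df$rfs_time <- as.numeric(df$rfs_time)
  df$rfs_event <- as.integer(df$rfs_event)
  df$purity <- as.numeric(df$purity)
  validate_annotation(df)
  df
}

validate_annotation <- function(df) {
  bad_sub <- setdiff(unique(df$subtype[!is.na(df$subtype)]), c("ERpos", "TN"))
  if (length(bad_sub) > 0)
    stop("annotation: unknown subtype code(s): ",
         paste(bad_sub, collapse = ", "))
  if (any(!is.na(df$nri) & (df$nri < 0 | df$nri > 1)))
    stop("annotation: nri outside [0, 1]")
  if (any(!is.na(df$purity) & (df$purity <= 0 | df$purity > 1)))
    stop("annotation: purity outside (0, 1]")
  if (any(is.na(df$rfs_time) != is.na(df$rfs_event)))
    stop("annotation: rfs_event must be present exactly when rfs_time is")
  if (any(!is.na(df$rfs_time) & df$rfs_time < 0))
    stop("annotation: negative rfs_time")
  invisible(df)
}

#' Write a sample annotation table to TSV
#'
#' @param annotation Annotation data frame.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read paired pre/post somatic variant calls from a two-sample VCF
#'
#' Expects a VCF 4.2 file with exactly two sample columns (pre then post),
#' per-sample `AD` (ref,alt depths) and `DP` FORMAT fields, and `GENE` and
#' `EFFECT` keys in INFO. VAF is alt depth over DP; zero depth yields a
#' missing VAF.
#'
#' @param path Path to the VCF file.
#' @return Variant data frame with `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `effect_class`, depths, alt counts and VAFs per sample.
#' @export
read_paired_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (length(samples) != 2L)
    stop("read_paired_vcf: expected exactly 2 sample columns, found ",
         length(samples))
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if (!all(c("AD", "DP") %in% fmt))
    stop("read_paired_vcf: AD and DP FORMAT fields are required")
  ad <- vcfR::extract.gt(v, "AD")
  dp <- suppressWarnings(
    apply(vcfR::extract.gt(v, "DP"), 2, as.numeric))
  dp <- matrix(dp, ncol = 2L)
  alt_of <- function(x) as.numeric(vapply(strsplit(x, ","), `[`, "", 2L))
  alt <- matrix(c(alt_of(ad[, 1]), alt_of(ad[, 2])), ncol = 2L)
  vaf <- ifelse(dp > 0, alt / dp, NA_real_)
  gene <- vcfR::extract.info(v, "GENE")
  effect <- vcfR::extract.info(v, "EFFECT")
  data.frame(
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    ref = as.character(v@fix[, "REF"]),
    alt = as.character(v@fix[, "ALT"]),
    gene = gene, effect_class = effect,
    dp_pre = dp[, 1], dp_post = dp[, 2],
    alt_pre = alt[, 1], alt_post = alt[, 2],
    vaf_pre = vaf[, 1], vaf_post = vaf[, 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write paired somatic variants as a two-sample VCF 4.2
#'
#' Counterpart of [read_paired_vcf()]; used to serialize simulated variant
#' tables. Gene and effect annotations go into INFO (`GENE`, `EFFECT`),
#' depths and alt counts into per-sample `AD`/`DP`.
#'
#' @param variants Variant data frame (as from
#'   [simulate_paired_genomics()]).
#' @param path Output path.
#' @param sample_names Names of the two sample columns.
#' @export
write_paired_vcf <- function(variants, path,
                             sample_names = c("PRE", "POST")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  gt <- function(alt, dp) sprintf("./.:%d,%d:%d", dp - alt, alt, dp)
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s;EFFECT=%s\tGT:AD:DP\t%s\t%s",
    variants$chrom, variants$pos, variants$ref, variants$alt,
    variants$gene, variants$effect_class,
    gt(variants$alt_pre, variants$dp_pre),
    gt(variants$alt_post, variants$dp_post)
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write copy-number segments in SEG format
#'
#' Tab-separated SEG: sample, chromosome, 1-based inclusive start/end,
#' probe count, segment mean. Segments must be sorted by (chromosome,
#' start) and may not overlap within a chromosome.
#'
#' @param segments Data frame `sample`, `chrom`, `start`, `end`,
#'   `n_probes`, `mean_delta`.
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (is.unsorted(s$start))
      stop("write_seg: segments not sorted by start on ", ch)
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("write_seg: overlapping segments on ", ch)
  }
  out <- data.frame(ID = segments$sample, chrom = segments$chrom,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$n_probes,
                    seg.mean = segments$mean_delta)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file written by [write_seg()]
#'
#' @param path Path to a SEG file.
#' @return Data frame `sample`, `chrom`, `start`, `end`, `n_probes`,
#'   `mean_delta`.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(sample = df$ID, chrom = as.character(df$chrom),
             start = as.integer(df$loc.start), end = as.integer(df$loc.end),
             n_probes = as.integer(df$num.mark),
             mean_delta = as.numeric(df$seg.mean),
             stringsAsFactors = FALSE)
}

#' Summarize a cohort annotation table
#'
#' Per subtype: sample count, pCR yes/no/missing counts, the pCR percentage,
#' and the median NRI over non-missing values; plus, for patients with both
#' a pre- and a post-treatment sample, paired-cohort patient counts per
#' subtype. The default pCR percentage uses the full subtype count as
#' denominator (missing included), matching the convention of the printed
#' cohort table; `pcr_denominator = "non_missing"` switches to determined
#' cases only.
#'
#' @param annotation Annotation data frame (nonempty).
#' @param pcr_denominator `"all"` (default) or `"non_missing"`.
#' @return List of class `cohort_summary` with one entry per subtype and a
#'   `paired` element of per-subtype paired patient counts.
#' @export
cohort_summary <- function(annotation,
                           pcr_denominator = c("all", "non_missing")) {
  stopifnot(nrow(annotation) > 0)
  pcr_denominator <- match.arg(pcr_denominator)
  pre <- annotation[is.na(annotation$timepoint) |
                      annotation$timepoint == "pre", , drop = FALSE]
  by_subtype <- lapply(split(pre, pre$subtype), function(a) {
    yes <- sum(a$pcr == "yes", na.rm = TRUE)
    no <- sum(a$pcr == "no", na.rm = TRUE)
    miss <- sum(is.na(a$pcr))
    denom <- if (pcr_denominator == "all") nrow(a) else yes + no
    list(
      n = nrow(a), pcr_yes = yes, pcr_no = no, pcr_missing = miss,
      pcr_pct = if (denom > 0 && (yes + no) > 0) 100 * yes / denom
                else NA_real_,
      median_nri = if (all(is.na(a$nri))) NA_real_
                   else stats::median(a$nri, na.rm = TRUE)
    )
  })
  tp <- table(annotation$patient_id, annotation$timepoint)
  paired_ids <- if (all(c("pre", "post") %in% colnames(tp)))
    rownames(tp)[tp[, "pre"] > 0 & tp[, "post"] > 0] else character(0)
  paired_sub <- annotation$subtype[match(paired_ids, annotation$patient_id)]
  paired <- as.list(table(factor(paired_sub, levels = c("ERpos", "TN"))))
  structure(list(subtypes = by_subtype, paired = paired,
                 pcr_denominator = pcr_denominator),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (st in names(x$subtypes)) {
    s <- x$subtypes[[st]]
    cat(sprintf("%-6s n=%d  pCR yes/no/missing = %d/%d/%d  pCR%% = %s  median NRI = %s\n",
                st, s$n, s$pcr_yes, s$pcr_no, s$pcr_missing,
                ifelse(is.na(s$pcr_pct), "NA", sprintf("%.1f", s$pcr_pct)),
                ifelse(is.na(s$median_nri), "NA",
                       sprintf("%.2f", s$median_nri))))
  }
  cat(sprintf("paired patients: ERpos=%d TN=%d\n",
              x$paired$ERpos, x$paired$TN))
  invisible(x)
}

#' Path to a packaged fixture file
#'
#' @param name File name under the package's `extdata` directory.
#' @return Absolute path to the fixture.
#' @export
neostrat_fixture <- function(name) {
  p <- system.file("extdata", name, package = "neostrat")
  if (p == "") stop("fixture not found: ", name)
  p
}
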