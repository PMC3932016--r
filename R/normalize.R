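# normalize: log2 transform, median centering, probe -> gene median
# summarization, replicate medians and per-contrast fold-change profiles.

#' Log2-transform and median-center an intensity matrix
#'
#' Raw background-subtracted intensities are log2 transformed and globally
#' normalized by median subtraction. With `center = "per_array"` (default)
#' each array's own median is subtracted, so every returned column has
#' median zero; with `center = "global"` a single median over the whole
#' table is subtracted, which preserves between-array differences exactly
#' (useful when a large genome fraction is dosage-shifted; see the package
#' vignette).
#'
#' @param x a linear [expr_matrix] (all values > 0).
#' @param center `"per_array"` or `"global"`.
#' @return a log2-centered [expr_matrix].
#' @export
normalize_arrays <- function(x, center = c("per_array", "global")) {
  center <- match.arg(center)
  if (!inherits(x, "expr_matrix")) x <- expr_matrix(x, log_space = "linear")
  if (x$log_space != "linear")
    arp_stop("normalize_arrays expects linear intensities")
  vals <- x$values
  if (any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)[1L, ]
    arp_stop(sprintf("non-positive value at feature '%s', sample '%s'",
                     rownames(vals)[bad[1L]], colnames(vals)[bad[2L]]))
  }
  lg <- log2(vals)
  if (center == "per_array") {
    med <- apply(lg, 2L, stats::median)
    lg <- sweep(lg, 2L, med)
  } else {
    lg <- lg - stats::median(lg)
  }
  expr_matrix(lg, feature_level = x$feature_level, log_space = "log2")
}

#' Summarize probe-level rows into gene-level rows
#'
#' Probe sets of one gene are summarized by taking the per-sample median
#' (even probe counts: mean of the two central values). Probes missing from
#' the map are dropped with a warning.
#'
#' @param x a probe-level [expr_matrix].
#' @param probe_to_gene named character vector, probe ID -> gene ID.
#' @return a gene-level [expr_matrix] in the same value space.
#' @export
summarize_probes <- function(x, probe_to_gene) {
  if (!inherits(x, "expr_matrix")) arp_stop("'x' must be an expr_matrix")
  if (length(probe_to_gene) == 0L) arp_stop("empty probe-to-gene map")
  vals <- x$values
  probes <- rownames(vals)
  unmapped <- setdiff(probes, names(probe_to_gene))
  if (length(unmapped))
    arp_warn(length(unmapped), " probe(s) missing from the map dropped: ",
             paste(utils::head(unmapped, 5L), collapse = ", "),
             if (length(unmapped) > 5L) ", ..." else "",
             class = "arpscreen_dropped_probes")
  keep <- intersect(probes, names(probe_to_gene))
  vals <- vals[keep, , drop = FALSE]
  genes <- probe_to_gene[keep]
  out <- rowsum(vals, genes, reorder = TRUE)  # placeholder sums, replaced below
  ug <- rownames(out)
  for (j in seq_len(ncol(vals))) {
    out[, j] <- vapply(split(vals[, j], genes), stats::median,
                       numeric(1))[ug]
  }
  expr_matrix(out, feature_level = "gene", log_space = x$log_space)
}

#' Compute a fold-change comparison profile for one contrast
#'
#' Treatment and control replicate values (log2-centered space) are each
#' summarized by their per-gene median; the per-gene log2 fold change is
#' the difference of the two medians, and `fc = 2^log2fc`. With at least
#' two replicates per side, a per-gene Welch t-test is run on the
#' replicate values, Benjamini-Hochberg adjusted; with 50 or more genes a
#' Grenander-based local FDR is added. With fewer replicates the tests are
#' skipped with a warning.
#'
#' @param x a gene-level log2-centered [expr_matrix].
#' @param sample_sheet sample sheet data.frame (see [read_sample_sheet()]).
#' @param contrast_id contrast label to extract.
#' @return a `comparison_profile` data.frame with columns `gene`, `log2fc`,
#'   `fc`, `t`, `p`, `q`, `lfdr`, and attributes `contrast`, `n_treatment`,
#'   `n_control`.
#' @export
compute_comparison_profile <- function(x, sample_sheet, contrast_id) {
  if (!inherits(x, "expr_matrix") || x$log_space != "log2")
    arp_stop("profiles are computed from log2-centered gene-level matrices")
  ss <- sample_sheet[sample_sheet$contrast_id == contrast_id, , drop = FALSE]
  if (nrow(ss) == 0L) arp_stop("unknown contrast_id: ", contrast_id)
  trt <- ss$sample_id[ss$group %in% c("aneuploid", "stress")]
  ctl <- ss$sample_id[ss$group %in% c("diploid_control", "stress_control")]
  missing <- setdiff(c(trt, ctl), colnames(x$values))
  if (length(missing))
    arp_stop("sample(s) absent from expression matrix: ",
             paste(missing, collapse = ", "))
  if (length(trt) < 1L || length(ctl) < 1L)
    arp_stop("contrast ", contrast_id, " needs >=1 replicate per side")
  A <- x$values[, trt, drop = FALSE]
  B <- x$values[, ctl, drop = FALSE]
  log2fc <- .row_medians(A) - .row_medians(B)
  prof <- data.frame(gene = rownames(x$values), log2fc = log2fc,
                     fc = 2^log2fc, t = NA_real_, p = NA_real_,
                     q = NA_real_, lfdr = NA_real_,
                     stringsAsFactors = FALSE, row.names = NULL)
  if (length(trt) >= 2L && length(ctl) >= 2L) {
    wt <- .welch_rows(A, B)
    prof$t <- wt$t
    prof$p <- wt$p
    prof$q <- bh_adjust(wt$p)
    if (nrow(prof) >= 50L) {
      prof$lfdr <- estimate_local_fdr(wt$p)$lfdr
    } else {
      arp_warn("fewer than 50 genes; local FDR omitted",
               class = "arpscreen_lfdr_skipped")
    }
  } else {
    arp_warn("contrast ", contrast_id,
             ": fewer than 2 replicates per side; t-tests skipped",
             class = "arpscreen_tests_skipped")
  }
  attr(prof, "contrast") <- contrast_id
  attr(prof, "n_treatment") <- length(trt)
  attr(prof, "n_control") <- length(ctl)
  class(prof) <- c("comparison_profile", "data.frame")
  prof
}

#' Write / read a comparison profile as TSV
#' @param prof a `comparison_profile` data.frame.
#' @param path file path.
#' @return `path` (writer) or the profile (reader).
#' @export
write_profile <- function(prof, path) {
  write_result_tsv(prof, path,
                   params = c(contrast = attr(prof, "contrast") %||% "NA",
                              n_treatment = attr(prof, "n_treatment") %||% "NA",
                              n_control = attr(prof, "n_control") %||% "NA"))
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  prof <- read_result_tsv(path)
  class(prof) <- c("comparison_profile", "data.frame")
  prof
}

`%||%` <- function(a, b) if (is.null(a)) b else a
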