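# markers: the consensus aneuploidy-marker screen with stress-overlap
# flagging. A gene is a consensus marker when it passes the fold threshold
# in the same direction in every aneuploid comparison.

#' Consensus marker screen across aneuploid comparisons
#'
#' A gene present in every profile belongs to the up list when its linear
#' fold change is `>= threshold` in every comparison, and to the down list
#' when it is `<= 1/threshold` everywhere (log-symmetric reciprocal
#' threshold). Boundary behaviour is inclusive within `boundary_tol`
#' (default 1e-9); `strict = TRUE` switches to strict inequalities.
#'
#' @param profiles named list of `comparison_profile` data.frames (columns
#'   `gene`, `fc`), one per aneuploid comparison (>= 2).
#' @param threshold linear fold-change cut-off, > 1 (default 1.4).
#' @param strict use strict inequalities at the boundary.
#' @param boundary_tol numerical tolerance at the threshold boundary.
#' @return a `marker_report` list: `up`, `down` (gene IDs), `fc` (genes x
#'   comparisons fold-change matrix over all shared genes, markers first),
#'   `table` (per-marker data.frame with direction and minimal `|log2 fc|`),
#'   `threshold`.
#' @export
consensus_markers <- function(profiles, threshold = 1.4, strict = FALSE,
                              boundary_tol = 1e-9) {
  if (length(profiles) < 2L)
    arp_stop("consensus screen needs >= 2 aneuploid profiles")
  if (threshold <= 1) arp_stop("threshold must be > 1",
                               class = "arpscreen_config_error")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("comparison", seq_along(profiles))
  shared <- Reduce(intersect, lapply(profiles, function(p) p$gene))
  fc <- vapply(profiles, function(p) {
    stats::setNames(p$fc, p$gene)[shared]
  }, numeric(length(shared)))
  if (!is.matrix(fc))                   # single shared gene
    fc <- matrix(fc, nrow = length(shared),
                 dimnames = list(NULL, names(profiles)))
  rownames(fc) <- shared
  up_cut <- threshold - boundary_tol
  dn_cut <- 1 / threshold + boundary_tol
  pass_up <- if (strict) fc > threshold else fc >= up_cut
  pass_dn <- if (strict) fc < 1 / threshold else fc <= dn_cut
  up <- shared[rowSums(pass_up) == ncol(fc)]
  down <- shared[rowSums(pass_dn) == ncol(fc)]
  markers <- c(up, down)
  tab <- data.frame(
    gene = markers,
    direction = rep(c("up", "down"), c(length(up), length(down))),
    min_abs_log2fc = apply(abs(log2(fc[markers, , drop = FALSE])), 1L, min),
    stringsAsFactors = FALSE, row.names = NULL)
  ord <- c(markers, setdiff(shared, markers))
  structure(list(up = up, down = down, fc = fc[ord, , drop = FALSE],
                 table = tab, threshold = threshold),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("marker_report: %d up, %d down (threshold %.3g over %d comparisons)\n",
              length(x$up), length(x$down), x$threshold, ncol(x$fc)))
  invisible(x)
}

#' Flag consensus markers that respond to stress conditions
#'
#' For every marker, counts the stress contrasts in which the gene passes
#' the same fold threshold in the marker's own direction. Markers are
#' flagged, never removed: a stress-responsive marker stays in the report
#' with its overlap count and the names of the overlapping conditions.
#'
#' @param report a `marker_report` from [consensus_markers()].
#' @param stress_profiles named list of stress `comparison_profile`s.
#' @param threshold linear fold threshold (default: the report's own).
#' @return the report with `stress_overlap_count` and
#'   `stress_overlap_names` added to its `table`.
#' @export
stress_overlap_flags <- function(report, stress_profiles,
                                 threshold = report$threshold) {
  if (!inherits(report, "marker_report"))
    arp_stop("'report' must come from consensus_markers()")
  tab <- report$table
  counts <- integer(nrow(tab))
  names_hit <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene[i]
    hits <- character()
    for (nm in names(stress_profiles)) {
      p <- stress_profiles[[nm]]
      fc <- p$fc[match(g, p$gene)]
      if (is.na(fc)) next
      pass <- if (tab$direction[i] == "up") fc >= threshold - 1e-9
              else fc <= 1 / threshold + 1e-9
      if (pass) hits <- c(hits, nm)
    }
    counts[i] <- length(hits)
    names_hit[i] <- paste(hits, collapse = ",")
  }
  tab$stress_overlap_count <- counts
  tab$stress_overlap_names <- names_hit
  report$table <- tab
  report
}

#' Write a marker report as TSV
#'
#' Writes the per-marker table joined with the per-comparison fold changes;
#' a second file (`*_fc_matrix.tsv` next to `path` if `fc_matrix = TRUE`)
#' carries the heatmap-ready genes x comparisons fold-change matrix of the
#' marker genes.
#'
#' @param report a `marker_report`.
#' @param path file path of the report TSV.
#' @param fc_matrix also write the marker fold-change matrix.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(report, path, fc_matrix = TRUE) {
  tab <- report$table
  if (nrow(tab) > 0L) {
    fcs <- as.data.frame(report$fc[tab$gene, , drop = FALSE])
    names(fcs) <- paste0("fc_", names(fcs))
    tab <- cbind(tab, fcs)
  }
  write_result_tsv(tab, path, params = c(threshold = report$threshold,
                                         n_comparisons = ncol(report$fc)))
  if (fc_matrix && nrow(report$table) > 0L) {
    m <- report$fc[report$table$gene, , drop = FALSE]
    df <- data.frame(gene = rownames(m), as.data.frame(m), check.names = FALSE)
    write_result_tsv(df, sub("\\.tsv$", "_fc_matrix.tsv", path),
                     params = c(threshold = report$threshold))
  }
  invisible(path)
}
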