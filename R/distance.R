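# distance: Spearman distance matrices across comparison profiles and
# hierarchical clustering orders.

#' Spearman distance matrix across comparison profiles
#'
#' Profiles are intersected on their shared genes (a single shared universe,
#' not pairwise-complete); the distance between two log2 fold-change
#' vectors is `d = (1 - rho) / 2` with Spearman's rank correlation `rho`
#' (average ranks for ties), so identical rankings give 0 and exact rank
#' reversal gives 1.
#'
#' @param profiles named list of named numeric log2 fold-change vectors, or
#'   a genes x comparisons numeric matrix.
#' @param min_shared minimum number of shared genes required (default 10;
#'   a rank correlation over fewer genes is too unstable to interpret).
#' @return symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, attribute `metric = "spearman"`.
#' @export
spearman_distance_matrix <- function(profiles, min_shared = 10L) {
  if (is.list(profiles)) {
    if (length(profiles) < 2L) arp_stop("need >= 2 profiles")
    shared <- Reduce(intersect, lapply(profiles, names))
    if (length(shared) < min_shared)
      arp_stop("fewer than ", min_shared, " genes shared across profiles")
    mat <- vapply(profiles, function(p) p[shared], numeric(length(shared)))
    rownames(mat) <- shared
  } else {
    mat <- profiles
    if (ncol(mat) < 2L) arp_stop("need >= 2 profiles")
    if (nrow(mat) < min_shared)
      arp_stop("fewer than ", min_shared, " genes shared across profiles")
  }
  novar <- apply(mat, 2L, function(v) stats::sd(v) == 0)
  if (any(novar))
    arp_stop("zero-variance profile(s): ",
             paste(colnames(mat)[novar], collapse = ", "))
  rho <- stats::cor(mat, method = "spearman")
  d <- (1 - rho) / 2
  diag(d) <- 0
  attr(d, "metric") <- "spearman"
  d
}

#' Hierarchical clustering order of comparisons or features
#'
#' Accepts either a precomputed symmetric distance matrix (e.g. from
#' [spearman_distance_matrix()]) or a feature table whose rows are
#' clustered by Euclidean distance. Labels are sorted lexicographically
#' before clustering so leaf order is deterministic under distance ties.
#'
#' @param x symmetric distance matrix, or numeric feature matrix.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param metric `"precomputed"` or `"euclidean"`; by default a symmetric
#'   zero-diagonal matrix is treated as precomputed.
#' @return list with `order` (leaf labels), `hclust` (the merge tree) and
#'   `newick` (the tree as Newick text, branch lengths from merge heights).
#' @export
hierarchical_order <- function(x, linkage = c("average", "complete", "single"),
                               metric = c("auto", "precomputed", "euclidean")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  if (any(!is.finite(x))) arp_stop("non-finite entries in distance input")
  if (metric == "auto") {
    metric <- if (is.matrix(x) && nrow(x) == ncol(x) &&
                  !is.null(rownames(x)) && identical(rownames(x), colnames(x)) &&
                  isTRUE(all.equal(x, t(x), tolerance = 1e-12)) &&
                  all(abs(diag(x)) < 1e-12)) "precomputed" else "euclidean"
  }
  if (metric == "precomputed") {
    ord <- order(rownames(x))
    d <- stats::as.dist(x[ord, ord])
  } else {
    labs <- rownames(x)
    if (is.null(labs)) labs <- as.character(seq_len(nrow(x)))
    rownames(x) <- labs
    x <- x[order(labs), , drop = FALSE]
    d <- stats::dist(x, method = "euclidean")
  }
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  list(order = hc$labels[hc$order], hclust = hc,
       newick = ape::write.tree(phy))
}

#' Write a labelled distance matrix as TSV
#' @param d square distance matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(comparison = rownames(d), as.data.frame(d),
                   check.names = FALSE)
  write_result_tsv(df, path, params = c(metric = attr(d, "metric") %||% "NA"))
}
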