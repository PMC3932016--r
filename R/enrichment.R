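# enrichment: rank-based annotation enrichment per comparison with scores
# in [-1, 1], BH significance, two-comparison pairing for 2D views, and
# generalization of annotations into pathway classes.

#' Rank-based annotation score
#'
#' Genes are ranked by log2 fold change (rank 1 = largest, average ranks for
#' ties). For a category with `m` member genes among `n` ranked genes and
#' mean member rank `Rbar`, the score is
#' `s = 2 * ((n + 1) / 2 - Rbar) / (n - m)`,
#' which is +1 exactly when members occupy the top `m` ranks, -1 for the
#' bottom `m` ranks, and equals the rank-biserial correlation
#' `1 - 2 U / (m (n - m))` of the member/non-member rank comparison. A
#' category with no members, or containing every gene, has no defined score
#' and yields `NA` with a warning.
#'
#' @param fold_changes named numeric vector of log2 fold changes over all
#'   genes of the comparison.
#' @param members character vector of category member genes.
#' @return the score in `[-1, 1]`, or `NA`.
#' @export
annotation_score <- function(fold_changes, members) {
  n <- length(fold_changes)
  inset <- names(fold_changes) %in% members
  m <- sum(inset)
  if (m == 0L || m == n) {
    arp_warn("annotation score undefined (category empty or exhaustive)",
             class = "arpscreen_score_undefined")
    return(NA_real_)
  }
  ranks <- rank(-fold_changes, ties.method = "average")
  2 * ((n + 1) / 2 - mean(ranks[inset])) / (n - m)
}

#' Enrich one comparison profile against an annotation collection
#'
#' Categories with at least `min_size` members present in the profile are
#' scored with [annotation_score()]; significance compares member versus
#' non-member log2 fold changes with a Welch t-test (or Mann-Whitney), and
#' q-values are Benjamini-Hochberg adjusted across the retained categories
#' of this comparison. Each category is generalized into a pathway class
#' via [assign_general_class()].
#'
#' @param profile a `comparison_profile` (columns `gene`, `log2fc`).
#' @param annotations named list of member vectors (see [read_gmt()]).
#' @param min_size minimum present-member count (default 10).
#' @param fdr_threshold significance cut-off on q (default 0.02).
#' @param test `"welch"` (default) or `"wilcox"`.
#' @param class_keyword_map see [default_class_keywords()].
#' @return an `enrichment_table` data.frame: `category`, `n_members`,
#'   `score`, `p`, `q`, `significant`, `general_class`.
#' @export
enrich_comparison <- function(profile, annotations, min_size = 10L,
                              fdr_threshold = 0.02,
                              test = c("welch", "wilcox"),
                              class_keyword_map = default_class_keywords()) {
  test <- match.arg(test)
  fc <- stats::setNames(profile$log2fc, profile$gene)
  keep <- vapply(annotations, function(mem)
    sum(names(fc) %in% mem), integer(1)) >= min_size
  if (!any(keep)) {
    arp_warn("no annotation category passes the minimum size filter",
             class = "arpscreen_empty_enrichment")
    out <- data.frame(category = character(), n_members = integer(),
                      score = numeric(), p = numeric(), q = numeric(),
                      significant = logical(), general_class = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  ann <- annotations[keep]
  rows <- lapply(names(ann), function(nm) {
    inset <- names(fc) %in% ann[[nm]]
    s <- annotation_score(fc, ann[[nm]])
    p <- if (test == "welch") {
      welch_t_test(fc[inset], fc[!inset])$p
    } else {
      stats::wilcox.test(fc[inset], fc[!inset], exact = FALSE)$p.value
    }
    data.frame(category = nm, n_members = sum(inset), score = s, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= fdr_threshold
  out$general_class <- assign_general_class(out$category, class_keyword_map)
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Pair two enrichment tables for a 2D view
#'
#' Joins the per-comparison scores of two enrichment tables by category.
#' Under `mode = "either"` (default) categories significant in at least one
#' comparison are retained (scores absent from one table become `NA`);
#' under `mode = "both"` only categories significant in both survive.
#'
#' @param table_x,table_y `enrichment_table` objects.
#' @param mode `"either"` or `"both"`.
#' @return data.frame `category`, `score_x`, `score_y`, `q_x`, `q_y`,
#'   `general_class`.
#' @export
pair_enrichments <- function(table_x, table_y, mode = c("either", "both")) {
  mode <- match.arg(mode)
  merged <- merge(
    data.frame(category = table_x$category, score_x = table_x$score,
               q_x = table_x$q, sig_x = table_x$significant,
               general_class = table_x$general_class,
               stringsAsFactors = FALSE),
    data.frame(category = table_y$category, score_y = table_y$score,
               q_y = table_y$q, sig_y = table_y$significant,
               class_y = table_y$general_class, stringsAsFactors = FALSE),
    by = "category", all = (mode == "either"))
  merged$sig_x[is.na(merged$sig_x)] <- FALSE
  merged$sig_y[is.na(merged$sig_y)] <- FALSE
  merged$general_class <- ifelse(is.na(merged$general_class),
                                 merged$class_y, merged$general_class)
  keep <- if (mode == "either") merged$sig_x | merged$sig_y
          else merged$sig_x & merged$sig_y
  out <- merged[keep, c("category", "score_x", "score_y", "q_x", "q_y",
                        "general_class")]
  rownames(out) <- NULL
  out
}

#' Default pathway-class keyword map
#'
#' Ordered list of (class label, keywords): the first class whose keyword
#' occurs case-insensitively in a category name wins; membrane metabolism is
#' deliberately last so names like "lysosomal membrane" generalize to the
#' more specific class. Categories matching nothing become `"Others"`.
#'
#' @return named list of keyword character vectors.
#' @export
default_class_keywords <- function() {
  list(
    "Replication" = c("replication", "dna repair"),
    "Transcription" = "transcription",
    "Ribosome" = "ribosom",
    "Golgi" = "golgi",
    "ER" = "endoplasmic",
    "Lysosomes" = "lysosom",
    "Vacuole" = "vacuol",
    "Mitochondria" = "mitochond",
    "Spliceosome" = "splice",
    "MHC class proteins" = c("mhc", "antigen"),
    "Membrane metabolism" = "membrane")
}

#' Generalize annotation names into pathway classes
#'
#' Case-insensitive substring matching of class keywords against category
#' names; the first matching class in map order wins, unmatched categories
#' are labelled `"Others"`.
#'
#' @param category_names character vector of annotation names.
#' @param class_keyword_map named list, class -> keyword vector, in priority
#'   order.
#' @return character vector of class labels.
#' @export
assign_general_class <- function(category_names,
                                 class_keyword_map = default_class_keywords()) {
  if (length(class_keyword_map) == 0L) {
    arp_warn("empty class keyword map; everything labelled 'Others'",
             class = "arpscreen_empty_class_map")
    return(rep("Others", length(category_names)))
  }
  lower <- tolower(category_names)
  out <- rep("Others", length(category_names))
  for (i in seq_along(lower)) {
    for (cl in names(class_keyword_map)) {
      if (any(vapply(class_keyword_map[[cl]], grepl, logical(1), x = lower[i],
                     fixed = TRUE))) {
        out[i] <- cl
        break
      }
    }
  }
  out
}

#' Pathway-class sign matrix across comparisons
#'
#' For each (pathway class, comparison): among the class's significant
#' categories, `"+"` if at least `agreement_fraction` have positive scores,
#' `"-"` if at least that fraction have negative scores, `"+/-"` if some are
#' significant but neither side reaches the fraction, and `"/"` if no
#' member category is significant.
#'
#' @param tables named list of `enrichment_table` objects (one per
#'   comparison).
#' @param agreement_fraction default 0.75.
#' @param classes class labels forming the rows (default: the classes of
#'   [default_class_keywords()]).
#' @return character matrix, classes x comparisons, entries in
#'   `{"+", "-", "+/-", "/"}`.
#' @export
class_sign_matrix <- function(tables, agreement_fraction = 0.75,
                              classes = names(default_class_keywords())) {
  out <- matrix("/", length(classes), length(tables),
                dimnames = list(classes, names(tables)))
  for (cmp in names(tables)) {
    tab <- tables[[cmp]]
    for (cl in classes) {
      sig <- tab[tab$general_class == cl & tab$significant, , drop = FALSE]
      if (nrow(sig) == 0L) next
      fpos <- mean(sig$score > 0)
      fneg <- mean(sig$score < 0)
      out[cl, cmp] <- if (fpos >= agreement_fraction) "+"
                      else if (fneg >= agreement_fraction) "-"
                      else "+/-"
    }
  }
  out
}
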