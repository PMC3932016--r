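# io_formats: readers and writers for every external artifact.
#
# Expression tables are tab-separated, "." decimal, first column feature IDs,
# header row sample IDs. Gene sets travel in standard MSigDB-dialect GMT.
# Gene identifiers are case-sensitive plain strings; no alias resolution.

#' Construct an expression matrix container
#'
#' A thin S3 wrapper around a numeric matrix of background-subtracted
#' single-channel intensities (features x samples). `feature_level` records
#' whether rows are probes (duplicates allowed, several probes per gene) or
#' genes (duplicates rejected). `log_space` records whether values are raw
#' linear intensities (all strictly positive) or log2-transformed,
#' median-centered values.
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param feature_level `"probe"` or `"gene"`.
#' @param log_space `"linear"` or `"log2"`.
#' @return an `expr_matrix` object.
#' @export
expr_matrix <- function(values, feature_level = c("gene", "probe"),
                        log_space = c("linear", "log2")) {
  feature_level <- match.arg(feature_level)
  log_space <- match.arg(log_space)
  if (!is.matrix(values) || !is.numeric(values))
    arp_stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    arp_stop("expression matrix needs feature and sample names")
  if (anyDuplicated(colnames(values)))
    arp_stop("duplicate sample IDs: ",
             paste(unique(colnames(values)[duplicated(colnames(values))]),
                   collapse = ", "), class = "arpscreen_format_error")
  if (feature_level == "gene" && anyDuplicated(rownames(values)))
    arp_stop("duplicate feature IDs at gene level",
             class = "arpscreen_format_error")
  if (any(!is.finite(values)))
    arp_stop("non-finite values in expression matrix")
  if (log_space == "linear" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1L, ]
    arp_stop(sprintf("non-positive linear intensity at feature '%s', sample '%s'",
                     rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  structure(list(values = values, feature_level = feature_level,
                 log_space = log_space),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features (%s) x %d samples [%s]\n",
              nrow(x$values), x$feature_level, ncol(x$values), x$log_space))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a tab-separated expression table
#'
#' First column holds feature IDs, header row holds sample IDs. Any
#' non-numeric cell (including `NA`) is a parse error naming its
#' coordinates; readers never silently drop or impute.
#'
#' @param path file path.
#' @param orientation `"features_x_samples"` (default) or
#'   `"samples_x_features"`; the returned matrix is always features x samples.
#' @param feature_level `"gene"` (default) or `"probe"`.
#' @param log_space `"linear"` (default) or `"log2"`.
#' @return an [expr_matrix].
#' @export
read_expression_table <- function(path,
                                  orientation = c("features_x_samples",
                                                  "samples_x_features"),
                                  feature_level = c("gene", "probe"),
                                  log_space = c("linear", "log2")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    arp_stop("expression table needs a feature column plus >=1 sample column",
             class = "arpscreen_format_error")
  hdr <- names(raw)[-1L]
  if (orientation == "features_x_samples" && anyDuplicated(hdr))
    arp_stop("duplicate sample ID(s) in header: ",
             paste(unique(hdr[duplicated(hdr)]), collapse = ", "),
             class = "arpscreen_format_error")
  ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) | cells == "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    arp_stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                     cells[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                     hdr[bad[1L, 2L]], path),
             class = "arpscreen_parse_error")
  }
  dimnames(vals) <- list(ids, hdr)
  if (orientation == "samples_x_features") vals <- t(vals)
  expr_matrix(vals, feature_level = match.arg(feature_level),
              log_space = match.arg(log_space))
}

#' Write an expression table as TSV
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round-trip reproduces doubles bit-exactly.
#'
#' @param x an [expr_matrix] or plain numeric matrix with dimnames.
#' @param path output file path.
#' @param id_column header label of the feature-ID column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, id_column = "feature_id") {
  values <- if (inherits(x, "expr_matrix")) x$values else x
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(values)), collapse = "\t"), con)
  body <- apply(values, 1L, function(r) paste(.fmt_num(r), collapse = "\t"))
  writeLines(paste(rownames(values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard MSigDB dialect: one category per line,
#' `name TAB description TAB gene1 TAB gene2 ...`. Member lists are
#' deduplicated; categories left without members are dropped with a warning.
#'
#' @param path file path.
#' @return a named list of character member vectors with a `descriptions`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      arp_stop(sprintf("GMT line %d has fewer than 2 tab-separated fields", i),
               class = "arpscreen_format_error")
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(members) == 0L) {
      arp_warn(sprintf("GMT category '%s' (line %d) has no members; dropped",
                       f[1L], i), class = "arpscreen_dropped_category")
      next
    }
    sets[[f[1L]]] <- members
    desc[[f[1L]]] <- f[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character member vectors; an optional
#'   `descriptions` attribute supplies the second column (default `"na"`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column gene-to-chromosome map
#'
#' Duplicate rows repeating the same assignment are idempotent; a gene
#' mapped to two different chromosomes is a format error.
#'
#' @param path file path to a two-column TSV (gene ID, chromosome label).
#' @return named character vector, gene ID -> chromosome.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2L)
    arp_stop("gene map must have exactly two tab-separated columns",
             class = "arpscreen_format_error")
  # tolerate an optional header line
  if (identical(tolower(df[1L, 1L]), "gene") ||
      identical(tolower(df[1L, 1L]), "gene_id")) df <- df[-1L, , drop = FALSE]
  df <- unique(df)
  dup <- df[[1L]][duplicated(df[[1L]])]
  if (length(dup))
    arp_stop("gene(s) mapped to conflicting chromosomes: ",
             paste(unique(dup), collapse = ", "),
             class = "arpscreen_format_error")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a gene-to-chromosome map
#' @param map named character vector, gene ID -> chromosome.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(map, path) {
  utils::write.table(data.frame(gene = names(map), chromosome = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

.sample_groups <- c("diploid_control", "aneuploid", "stress", "stress_control")

#' Read a sample sheet
#'
#' Columns: `sample_id`, `cell_line`, `group` (one of `diploid_control`,
#' `aneuploid`, `stress`, `stress_control`), `contrast_id`, `replicate`.
#' Every treatment sample's `contrast_id` must resolve to at least one
#' control sample; sides with fewer than two replicates are allowed but
#' gene-level t-tests are then skipped with a warning downstream.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet data.frame
#' @param df data.frame with the columns described in [read_sample_sheet()].
#' @return the validated data.frame, invisibly classed.
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "cell_line", "group", "contrast_id", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    arp_stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
             class = "arpscreen_format_error")
  if (anyDuplicated(df$sample_id))
    arp_stop("duplicate sample IDs in sample sheet",
             class = "arpscreen_format_error")
  bad <- setdiff(unique(df$group), .sample_groups)
  if (length(bad))
    arp_stop("unknown sample group(s): ", paste(bad, collapse = ", "),
             class = "arpscreen_format_error")
  if (any(df$replicate < 1))
    arp_stop("replicate indices must be >= 1", class = "arpscreen_format_error")
  trt <- df[df$group %in% c("aneuploid", "stress"), ]
  ctl <- df[df$group %in% c("diploid_control", "stress_control"), ]
  unresolved <- setdiff(unique(trt$contrast_id), unique(ctl$contrast_id))
  if (length(unresolved))
    arp_stop("contrast(s) without control samples: ",
             paste(unresolved, collapse = ", "),
             class = "arpscreen_format_error")
  df
}

#' Write a sample sheet
#' @param df sample sheet data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
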