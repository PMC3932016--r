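# pipeline_cli: orchestration of the stages end-to-end with reproducible,
# logged runs. Each stage is individually invocable and, chained manually,
# produces byte-identical results to run_pipeline().

.scenario_dir <- function(config, outdir) {
  if (isTRUE(config$simulate)) file.path(outdir, "scenario")
  else config$input_dir
}

.list_contrasts <- function(scenario_dir) {
  sheet <- read_sample_sheet(file.path(scenario_dir, "sample_sheet.tsv"))
  ids <- unique(sheet$contrast_id)
  grp <- vapply(ids, function(id) {
    g <- sheet$group[sheet$contrast_id == id]
    if (any(g == "aneuploid")) "aneuploid" else "stress"
  }, character(1))
  list(sheet = sheet, ids = ids, type = stats::setNames(grp, ids))
}

#' Pipeline stage: normalize expression tables
#'
#' Reads each contrast's linear expression table, log2-transforms and
#' median-centers it (per [normalize_arrays()]), summarizing probe-level
#' tables to gene level first when a `probe_map.tsv` accompanies the data,
#' and writes `normalized/normalized_<contrast>.tsv`.
#'
#' @param outdir pipeline output directory.
#' @param config an `arp_config`.
#' @return invisible character vector of written files.
#' @export
stage_normalize <- function(outdir, config) {
  sdir <- .scenario_dir(config, outdir)
  info <- .list_contrasts(sdir)
  dir.create(file.path(outdir, "normalized"), showWarnings = FALSE,
             recursive = TRUE)
  probe_map_path <- file.path(sdir, "probe_map.tsv")
  probe_map <- if (file.exists(probe_map_path)) read_gene_map(probe_map_path)
               else NULL
  out <- character()
  for (id in info$ids) {
    x <- read_expression_table(
      file.path(sdir, sprintf("expression_%s.tsv", id)),
      feature_level = if (is.null(probe_map)) "gene" else "probe")
    if (!is.null(probe_map)) x <- summarize_probes(x, probe_map)
    norm <- normalize_arrays(x, center = config$centering)
    f <- file.path(outdir, "normalized", sprintf("normalized_%s.tsv", id))
    write_expression_table(norm, f, id_column = "gene")
    out <- c(out, f)
    arp_log("debug", "normalized ", id)
  }
  invisible(out)
}

#' Pipeline stage: fold-change profiles with differential tests
#'
#' Computes one [compute_comparison_profile()] per contrast from the
#' normalized matrices and writes `profiles/profile_<contrast>.tsv`.
#'
#' @inheritParams stage_normalize
#' @return invisible character vector of written files.
#' @export
stage_diffexp <- function(outdir, config) {
  sdir <- .scenario_dir(config, outdir)
  info <- .list_contrasts(sdir)
  dir.create(file.path(outdir, "profiles"), showWarnings = FALSE,
             recursive = TRUE)
  out <- character()
  for (id in info$ids) {
    norm <- read_expression_table(
      file.path(outdir, "normalized", sprintf("normalized_%s.tsv", id)),
      log_space = "log2")
    prof <- compute_comparison_profile(norm, info$sheet, id)
    f <- file.path(outdir, "profiles", sprintf("profile_%s.tsv", id))
    write_profile(prof, f)
    out <- c(out, f)
    arp_log("debug", "profiled ", id)
  }
  invisible(out)
}

.read_profiles <- function(outdir, ids) {
  profs <- lapply(ids, function(id)
    read_profile(file.path(outdir, "profiles",
                           sprintf("profile_%s.tsv", id))))
  stats::setNames(profs, ids)
}

#' Pipeline stage: annotation enrichment per contrast
#'
#' @inheritParams stage_normalize
#' @return invisible character vector of written files.
#' @export
stage_enrich <- function(outdir, config) {
  sdir <- .scenario_dir(config, outdir)
  info <- .list_contrasts(sdir)
  ann <- read_gmt(file.path(sdir, "annotations.gmt"))
  dir.create(file.path(outdir, "enrichment"), showWarnings = FALSE,
             recursive = TRUE)
  out <- character()
  for (id in info$ids) {
    prof <- .read_profiles(outdir, id)[[1L]]
    tab <- enrich_comparison(prof, ann,
                             min_size = config$min_category_size,
                             fdr_threshold = config$enrich_fdr,
                             test = config$enrichment_test)
    f <- file.path(outdir, "enrichment", sprintf("enrichment_%s.tsv", id))
    write_result_tsv(tab, f, params = c(contrast = id,
                                        fdr = config$enrich_fdr,
                                        min_size = config$min_category_size))
    out <- c(out, f)
  }
  invisible(out)
}

.read_enrichments <- function(outdir, ids) {
  tabs <- lapply(ids, function(id) {
    tab <- read_result_tsv(file.path(outdir, "enrichment",
                                     sprintf("enrichment_%s.tsv", id)))
    class(tab) <- c("enrichment_table", "data.frame")
    tab
  })
  stats::setNames(tabs, ids)
}

#' Pipeline stage: paired 2D enrichment tables
#'
#' @inheritParams stage_normalize
#' @return invisible character vector of written files.
#' @export
stage_pair <- function(outdir, config) {
  sdir <- .scenario_dir(config, outdir)
  info <- .list_contrasts(sdir)
  dir.create(file.path(outdir, "paired"), showWarnings = FALSE,
             recursive = TRUE)
  out <- character()
  for (pair in config$pairs) {
    if (!all(pair %in% info$ids)) {
      arp_warn("pair (", paste(pair, collapse = ", "),
               ") references unknown contrast(s); skipped",
               class = "arpscreen_pair_skipped")
      next
    }
    tabs <- .read_enrichments(outdir, pair)
    paired <- pair_enrichments(tabs[[1L]], tabs[[2L]])
    f <- file.path(outdir, "paired",
                   sprintf("paired_%s_vs_%s.tsv", pair[1L], pair[2L]))
    write_result_tsv(paired, f, params = c(x = pair[1L], y = pair[2L]))
    out <- c(out, f)
  }
  invisible(out)
}

#' Pipeline stage: pathway-class sign matrix
#'
#' @inheritParams stage_normalize
#' @return invisible path of the written file.
#' @export
stage_classes <- function(outdir, config) {
  sdir <- .scenario_dir(config, outdir)
  info <- .list_contrasts(sdir)
  tabs <- .read_enrichments(outdir, info$ids)
  m <- class_sign_matrix(tabs, agreement_fraction = config$agreement_fraction)
  dir.create(file.path(outdir, "classes"), showWarnings = FALSE,
             recursive = TRUE)
  df <- data.frame(class = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  f <- file.path(outdir, "classes", "class_sign_matrix.tsv")
  write_result_tsv(df, f,
                   params = c(agreement = config$agreement_fraction))
  invisible(f)
}

#' Pipeline stage: Spearman distance matrices and clustering trees
#'
#' Writes the all-contrast and the aneuploid-only Spearman distance
#' matrices with their average-linkage clustering trees as Newick text.
#'
#' @inheritParams stage_normalize
#' @return invisible character vector of written files.
#' @export
stage_distance <- function(outdir, config) {
  sdir <- .scenario_dir(config, outdir)
  info <- .list_contrasts(sdir)
  profs <- .read_profiles(outdir, info$ids)
  vecs <- lapply(profs, function(p) stats::setNames(p$log2fc, p$gene))
  dir.create(file.path(outdir, "distance"), showWarnings = FALSE,
             recursive = TRUE)
  out <- character()
  sets <- list(all = info$ids,
               aneuploid = info$ids[info$type[info$ids] == "aneuploid"])
  for (nm in names(sets)) {
    ids <- sets[[nm]]
    if (length(ids) < 2L) next
    d <- spearman_distance_matrix(vecs[ids])
    f <- file.path(outdir, "distance", sprintf("spearman_%s.tsv", nm))
    write_distance_matrix(d, f)
    tree <- hierarchical_order(d, linkage = "average")
    ft <- file.path(outdir, "distance", sprintf("tree_%s.nwk", nm))
    writeLines(tree$newick, ft)
    out <- c(out, f, ft)
  }
  invisible(out)
}

#' Pipeline stage: consensus marker screen with stress flags
#'
#' @inheritParams stage_normalize
#' @return invisible path of the marker report.
#' @export
stage_markers <- function(outdir, config) {
  sdir <- .scenario_dir(config, outdir)
  info <- .list_contrasts(sdir)
  an_ids <- info$ids[info$type[info$ids] == "aneuploid"]
  if (!is.null(config$marker_profiles))
    an_ids <- intersect(an_ids, config$marker_profiles)
  st_ids <- info$ids[info$type[info$ids] == "stress"]
  report <- consensus_markers(.read_profiles(outdir, an_ids),
                              threshold = config$fc_threshold)
  if (length(st_ids))
    report <- stress_overlap_flags(report, .read_profiles(outdir, st_ids))
  dir.create(file.path(outdir, "markers"), showWarnings = FALSE,
             recursive = TRUE)
  f <- file.path(outdir, "markers", "marker_report.tsv")
  write_marker_report(report, f)
  invisible(f)
}

#' Run the full pipeline
#'
#' Generates the synthetic scenario (when `config$simulate`), then chains
#' normalization, fold-change profiling with tests, enrichment, pairing,
#' class sign matrix, distance matrices and the consensus marker screen,
#' and writes a run manifest (`manifest.json`) with the configuration
#' snapshot, seed, package version and MD5 hashes of every output file.
#' Re-running with identical configuration and seed reproduces identical
#' output hashes.
#'
#' @param config an `arp_config` (see [load_config()]).
#' @param outdir output directory.
#' @param seed integer base seed (defaults to `config$seed`).
#' @return invisible manifest list.
#' @export
run_pipeline <- function(config, outdir, seed = config$seed) {
  old <- arp_log_level(config$log_level)
  on.exit(arp_log_level(old))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- c("simulate", "normalize", "diffexp", "enrich", "pair",
              "classes", "distance", "markers")
  status <- stats::setNames(rep("pending", length(stages)), stages)
  manifest_path <- file.path(outdir, "manifest.json")
  write_manifest <- function(failed_at = NULL) {
    files <- setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                     manifest_path)
    hashes <- tools::md5sum(files)
    names(hashes) <- sub(paste0("^", outdir, "/?"), "", names(hashes))
    manifest <- list(
      package_version = as.character(utils::packageVersion("arpscreen")),
      seed = seed,
      config = unclass(config),
      stages = as.list(status),
      failed_at = failed_at,
      files = as.list(hashes),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest
  }
  run_stage <- function(name, fun) {
    arp_log("info", "stage ", name)
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      status[[name]] <<- paste0("failed: ", conditionMessage(e))
      write_manifest(failed_at = name)
      arp_stop("stage ", name, " failed: ", conditionMessage(e))
    })
    status[[name]] <<- "ok"
  }
  if (isTRUE(config$simulate)) {
    run_stage("simulate", function()
      generate_scenario(config, seed, file.path(outdir, "scenario")))
  } else {
    status[["simulate"]] <- "skipped"
    if (!file.exists(file.path(config$input_dir, "sample_sheet.tsv")))
      arp_stop("input_dir lacks a sample_sheet.tsv and simulate is FALSE",
               class = "arpscreen_config_error")
  }
  run_stage("normalize", function() stage_normalize(outdir, config))
  run_stage("diffexp", function() stage_diffexp(outdir, config))
  run_stage("enrich", function() stage_enrich(outdir, config))
  run_stage("pair", function() stage_pair(outdir, config))
  run_stage("classes", function() stage_classes(outdir, config))
  run_stage("distance", function() stage_distance(outdir, config))
  run_stage("markers", function() stage_markers(outdir, config))
  manifest <- write_manifest()
  arp_log("info", "pipeline complete: ", outdir)
  invisible(manifest)
}
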