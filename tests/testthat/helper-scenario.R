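# Shared fixtures, built in code at test time.

# A scaled-down scenario for fast unit / pipeline tests: same 21 contrasts
# and planted structure as the default, fewer genes and smaller categories.
small_config <- function(...) {
  load_config(list(
    scenario = list(n_genes = 600L, class_pool_size = 30L,
                    categories_per_class = 2L, n_background_categories = 5L,
                    category_size_range = c(10L, 20L)),
    log_level = "warn", ...))
}

# The packaged default scenario run end-to-end, computed once per session.
.default_run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.default_run_cache$dir)) {
    dir <- file.path(tempdir(), "arpscreen_default_run")
    cfg <- load_config(list(log_level = "warn"))
    suppressWarnings(run_pipeline(cfg, dir))
    .default_run_cache$dir <- dir
    .default_run_cache$truth <- jsonlite::read_json(
      file.path(dir, "scenario", "truth.json"), simplifyVector = TRUE)
  }
  list(dir = .default_run_cache$dir, truth = .default_run_cache$truth)
}

# Write a small linear expression table and return its path.
write_tmp_expression <- function(values, dir = tempdir(),
                                 name = "expr.tsv") {
  path <- file.path(dir, name)
  write_expression_table(values, path)
  path
}

# Minimal comparison-profile data.frame from a named fc vector.
fc_profile <- function(fc) {
  data.frame(gene = names(fc), log2fc = log2(fc), fc = unname(fc),
             stringsAsFactors = FALSE)
}

# Directory checksums (manifest excluded) for byte-determinism checks.
dir_md5 <- function(dir) {
  files <- setdiff(list.files(dir, recursive = TRUE, full.names = TRUE),
                   file.path(dir, "manifest.json"))
  h <- tools::md5sum(sort(files))
  names(h) <- sub(paste0("^", dir, "/?"), "", names(h))
  h
}
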