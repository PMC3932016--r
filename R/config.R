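# Pipeline configuration: YAML in, validated list out, defaults applied,
# unknown keys rejected so typos cannot silently disable a stage.

#' Default pipeline configuration
#'
#' Thresholds mirror the study design: linear fold-change cut-off 1.4 for
#' the marker screen, annotation-enrichment FDR cut-off 0.02, minimum
#' annotated-category size 10.
#'
#' @return a named list of pipeline parameters.
#' @export
default_config <- function() {
  list(
    fc_threshold = 1.4,
    enrich_fdr = 0.02,
    min_category_size = 10L,
    agreement_fraction = 0.75,
    centering = "per_array",
    enrichment_test = "welch",
    seed = 20130319L,
    simulate = TRUE,
    input_dir = NULL,
    pairs = list(c("HPT1", "HCT116_5_4"),
                 c("HPT2", "DLD1_13_3"),
                 c("HCT116_5_4", "stress_bafilomycinA1")),
    marker_profiles = NULL,   # NULL = all aneuploid contrasts
    log_level = "info",
    scenario = default_scenario_config()
  )
}

#' Default synthetic-scenario configuration
#'
#' The defaults define the study conditions the generator emulates:
#' 13 aneuploid contrasts (7 own-lab lines including two complex
#' karyotypes, 3 DLD1-like trisomies, 3 HE35-like trisomy-8 clones) plus
#' 8 stress contrasts, three replicates per side at 10% replicate CV,
#' full dosage transmission, a ten-class response signature at 0.5 log2
#' mean shift with 75% per-line gene membership, and the fixed 18 up /
#' 5 down marker panel with 1.0-1.6 log2 planted shifts.
#'
#' @return a named list of generator parameters.
#' @export
default_scenario_config <- function() {
  list(
    n_genes = 4000L,
    n_replicates = 3L,
    noise_cv = 0.1,
    attenuation = 1.0,
    baseline_log2_mean = 8,
    baseline_log2_sd = 1.5,
    mu_class = 0.5,
    sigma_class = 0.2,
    phi = 0.75,
    class_pool_size = 60L,
    categories_per_class = 3L,
    n_background_categories = 15L,
    category_size_range = c(15L, 40L),
    marker_shift_range = c(1.0, 1.6)
  )
}

.merge_config <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    arp_stop(sprintf("unknown %s key(s): %s", where,
                     paste(unknown, collapse = ", ")),
             class = "arpscreen_config_error")
  for (k in names(user)) defaults[[k]] <- user[[k]]
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or accepts an in-memory list), applies
#' [default_config()] defaults, rejects unknown keys and validates value
#' ranges. An empty configuration is valid and yields the defaults.
#'
#' @param path YAML file path, or `NULL`.
#' @param overrides optional named list merged after the file (used by the
#'   CLI for command-line flags).
#' @return validated configuration list of class `arp_config`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (is.list(path)) {
      user <- path
    } else {
      if (!file.exists(path))
        arp_stop("config file not found: ", path,
                 class = "arpscreen_config_error")
      user <- yaml::read_yaml(path)
      if (is.null(user)) user <- list()
    }
  }
  if (!is.null(overrides)) {
    sc <- user$scenario
    user[names(overrides)] <- overrides
    if (!is.null(sc) && is.null(overrides$scenario)) user$scenario <- sc
  }
  cfg <- default_config()
  sc_user <- user$scenario
  user$scenario <- NULL
  cfg <- .merge_config(cfg, user, "config")
  if (!is.null(sc_user))
    cfg$scenario <- .merge_config(default_scenario_config(), sc_user,
                                  "scenario config")
  validate_config(cfg)
}

#' Validate a configuration list
#' @param cfg configuration list.
#' @return `cfg` with class `arp_config`.
#' @export
validate_config <- function(cfg) {
  if (!is.numeric(cfg$fc_threshold) || cfg$fc_threshold <= 1)
    arp_stop("fc_threshold must be > 1 (linear fold-change scale)",
             class = "arpscreen_config_error")
  if (cfg$enrich_fdr <= 0 || cfg$enrich_fdr >= 1)
    arp_stop("enrich_fdr must lie in (0, 1)", class = "arpscreen_config_error")
  if (cfg$min_category_size < 2)
    arp_stop("min_category_size must be >= 2", class = "arpscreen_config_error")
  if (cfg$agreement_fraction <= 0.5 || cfg$agreement_fraction > 1)
    arp_stop("agreement_fraction must lie in (0.5, 1]",
             class = "arpscreen_config_error")
  if (!cfg$centering %in% c("per_array", "global"))
    arp_stop("centering must be 'per_array' or 'global'",
             class = "arpscreen_config_error")
  if (!cfg$enrichment_test %in% c("welch", "wilcox"))
    arp_stop("enrichment_test must be 'welch' or 'wilcox'",
             class = "arpscreen_config_error")
  if (!isTRUE(cfg$simulate) && is.null(cfg$input_dir))
    arp_stop("input_dir is required when simulate is FALSE",
             class = "arpscreen_config_error")
  sc <- cfg$scenario
  if (sc$noise_cv < 0)
    arp_stop("noise_cv must be >= 0", class = "arpscreen_config_error")
  if (sc$attenuation <= 0 || sc$attenuation > 1)
    arp_stop("attenuation must lie in (0, 1]", class = "arpscreen_config_error")
  if (sc$n_genes < 100)
    arp_stop("n_genes must be >= 100", class = "arpscreen_config_error")
  if (sc$phi <= 0 || sc$phi > 1)
    arp_stop("phi must lie in (0, 1]", class = "arpscreen_config_error")
  if (sc$mu_class <= 0)
    arp_stop("mu_class must be > 0", class = "arpscreen_config_error")
  class(cfg) <- "arp_config"
  cfg
}
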