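# Internal helpers shared across modules: seeding, logging, TSV plumbing.

.arp_log_level <- new.env(parent = emptyenv())
.arp_log_level$level <- "info"

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the logging verbosity
#'
#' Log lines are written to `stderr` so that result tables written to
#' `stdout` by the command-line interface remain pipeable.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
arp_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- .arp_log_level$level
  .arp_log_level$level <- level
  invisible(old)
}

arp_log <- function(level, ...) {
  if (.log_levels[[level]] >= .log_levels[[.arp_log_level$level]]) {
    message(sprintf("[arpscreen %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Structured warning: raised as a classed condition so callers/tests can
# filter, and echoed on the log channel.
arp_warn <- function(..., class = "arpscreen_warning") {
  msg <- paste0(...)
  arp_log("warn", msg)
  warning(warningCondition(msg, class = c(class, "arpscreen_warning")))
  invisible(NULL)
}

arp_stop <- function(..., class = "arpscreen_error") {
  stop(errorCondition(paste0(...), class = c(class, "arpscreen_error")))
}

#' Derive a named random substream seed
#'
#' All randomness in the package flows from one base seed through named
#' substreams (per cell line, per stage), so that adding a stage never
#' perturbs the draws of another. The derivation hashes the stream name
#' with a 31-ary polynomial rolling hash modulo 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param name character stream name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer((h + (seed %% m) * 48271) %% m)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Format numbers for TSV output so that write -> read round-trips are
# bit-exact (17 significant digits suffice for IEEE doubles).
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

# One comment line recording provenance, written atop every result table.
.tsv_header_comment <- function(params = character()) {
  ver <- as.character(utils::packageVersion("arpscreen"))
  extra <- if (length(params)) {
    paste0("; ", paste(sprintf("%s=%s", names(params), params), collapse = ", "))
  } else ""
  sprintf("# arpscreen %s%s", ver, extra)
}

# Write a data.frame as TSV with a provenance comment line.
write_result_tsv <- function(df, path, params = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.tsv_header_comment(params), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.stat_median <- function(x) stats::median(x)

# Row-wise medians of a matrix (even count -> mean of the central pair).
.row_medians <- function(m) {
  apply(m, 1L, stats::median)
}
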