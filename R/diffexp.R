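# diffexp: Welch t-tests, Benjamini-Hochberg adjustment and a
# Grenander-based local false discovery rate.

# Vectorized Welch test over paired rows of two matrices. Degenerate
# convention: both groups zero-variance with equal means -> p = 1; with
# unequal means -> p = 0.
.welch_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  if (na < 2L || nb < 2L) arp_stop("Welch test needs >= 2 values per group")
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1L)
  vb <- rowSums((B - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (ma == mb)
    t[eq] <- 0; p[eq] <- 1
    ne <- degen & (ma != mb)
    t[ne] <- sign(ma - mb)[ne] * Inf
    p[ne] <- 0
  }
  list(t = t, p = p, df = df)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. Degenerate inputs follow a documented convention: both groups
#' zero-variance with equal means give `p = 1`; zero-variance with unequal
#' means give `p = 0`. A pooled-variance (classical Student) option is
#' available.
#'
#' @param a,b numeric vectors of replicate values (>= 2 each).
#' @param var_equal use the pooled-variance statistic instead of Welch's.
#' @return list with `t`, `p` and `df`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    arp_stop("Welch test needs >= 2 values per group")
  if (!var_equal) {
    r <- .welch_rows(matrix(a, 1L), matrix(b, 1L))
    return(list(t = unname(r$t), p = unname(r$p), df = unname(r$df)))
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = na + nb - 2))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = na + nb - 2))
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE), df = df)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: `q_i` is the minimum over all
#' `p_j >= p_i` of `m * p_j / rank_j`, capped at 1. Delegates to
#' [stats::p.adjust()] after input validation.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    arp_stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Grenander estimator of a non-increasing density on [0, 1]: slopes of the
# least concave majorant of the ECDF, computed by a stack scan over the
# points (0, 0), (p_(1), 1/m), ..., (p_(m), 1), (1, 1).
.grenander_density <- function(p_sorted) {
  m <- length(p_sorted)
  ux <- unique(p_sorted)
  Fy <- cumsum(tabulate(match(p_sorted, ux))) / m
  x <- c(0, ux); y <- c(0, Fy)
  if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, 1) }
  # least concave majorant: keep slopes strictly decreasing
  ix <- 1L                      # indices of LCM vertices
  for (i in 2L:length(x)) {
    while (length(ix) >= 2L) {
      k <- length(ix)
      s_new <- (y[i] - y[ix[k - 1L]]) / (x[i] - x[ix[k - 1L]])
      s_old <- (y[ix[k]] - y[ix[k - 1L]]) / (x[ix[k]] - x[ix[k - 1L]])
      if (s_new >= s_old) ix <- ix[-k] else break
    }
    ix <- c(ix, i)
  }
  vx <- x[ix]; vy <- y[ix]
  slopes <- diff(vy) / diff(vx)
  # density at each p: slope of the segment containing it (left-continuous)
  seg <- findInterval(p_sorted, vx, left.open = TRUE, all.inside = TRUE)
  slopes[seg]
}

#' Local false discovery rate via Storey's pi0 and the Grenander estimator
#'
#' The null proportion is `pi0 = min(1, #\{p > lambda0\} / ((1 - lambda0) m))`
#' and the p-value mixture density `f` is the Grenander (monotone
#' non-increasing) estimator, so `lfdr_i = min(1, pi0 / f(p_i))` is monotone
#' non-decreasing in `p`. Requires at least 50 p-values; otherwise the lfdr
#' is omitted with a warning and only `pi0` is returned.
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param lambda0 tail threshold for the pi0 estimate (default 0.5).
#' @return list with `lfdr` (per input, or `NULL` when skipped) and `pi0`.
#' @export
estimate_local_fdr <- function(pvalues, lambda0 = 0.5) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    arp_stop("p-values must lie in [0, 1]")
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  pi0 <- min(1, sum(pvalues[ok] > lambda0) / ((1 - lambda0) * m))
  if (m < 50L) {
    arp_warn("fewer than 50 p-values; local FDR omitted",
             class = "arpscreen_lfdr_skipped")
    return(list(lfdr = NULL, pi0 = pi0))
  }
  ord <- order(pvalues[ok])
  f <- .grenander_density(pvalues[ok][ord])
  lfdr_sorted <- pmin(1, pi0 / f)
  lfdr <- rep(NA_real_, length(pvalues))
  lfdr[ok[ord]] <- lfdr_sorted
  list(lfdr = lfdr, pi0 = pi0)
}
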