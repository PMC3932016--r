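# Normalization chain: log2 + median centering, probe summarization,
# replicate medians and fold-change profiles.

test_that("per-array median centering zeroes every column median", {
  m <- matrix(c(2, 4, 8, 16), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
  out <- normalize_arrays(expr_matrix(m, "gene", "linear"))
  expect_equal(unname(out$values[, 1]), c(-1.5, -0.5, 0.5, 1.5))

  cst <- matrix(5, 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(unname(normalize_arrays(expr_matrix(cst))$values[, 1]),
               rep(0, 3))

  set.seed(2)
  r <- matrix(exp(rnorm(1200)), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  norm <- normalize_arrays(expr_matrix(r))
  expect_true(all(abs(apply(norm$values, 2, median)) < 1e-12))
  # monotone per sample
  expect_identical(order(norm$values[, 3]), order(r[, 3]))

  bad <- r; bad[5, 2] <- 0
  expect_error(normalize_arrays(bad), "g005.*s2")
})

test_that("global centering subtracts one dataset-wide median", {
  set.seed(3)
  r <- matrix(exp(rnorm(300)), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  out <- normalize_arrays(expr_matrix(r), center = "global")
  expect_equal(median(out$values), 0)
  # between-array differences are preserved exactly
  expect_equal(out$values[, 1] - out$values[, 2], log2(r[, 1]) - log2(r[, 2]))
})

test_that("probe sets summarize to per-gene medians", {
  m <- matrix(c(1, 2, 3, 7, 10, 20, 30, 70), 4, 2,
              dimnames = list(c("p1", "p2", "p3", "p4"), c("s1", "s2")))
  x <- expr_matrix(m, feature_level = "probe", log_space = "linear")
  map <- c(p1 = "A", p2 = "A", p3 = "A", p4 = "B")
  g <- summarize_probes(x, map)
  expect_equal(g$values["A", "s1"], 2)     # odd count: middle value
  expect_equal(g$values["B", "s1"], 7)     # single probe passes through
  map2 <- c(p1 = "A", p2 = "A", p4 = "B")  # even count: mean of middle pair
  expect_warning(g2 <- summarize_probes(x, map2),
                 class = "arpscreen_dropped_probes")
  expect_equal(g2$values["A", "s2"], mean(c(10, 20)))
  expect_error(summarize_probes(x, character()), "empty")
})

test_that("comparison profiles are replicate medians differenced in log2 space", {
  genes <- paste0("g", 1:60)
  v <- matrix(0, 60, 4, dimnames = list(genes, c("t1", "t2", "c1", "c2")))
  v[1, c("t1", "t2")] <- 1                       # log2 fc 1 -> fc 2
  v[2, c("t1", "t2")] <- 0.4854                  # the 1.4-fold cut in log2
  x <- structure(list(values = v, feature_level = "gene",
                      log_space = "log2"), class = "expr_matrix")
  ss <- data.frame(sample_id = colnames(v), cell_line = "L",
                   group = rep(c("aneuploid", "diploid_control"), each = 2),
                   contrast_id = "k", replicate = c(1:2, 1:2))
  prof <- compute_comparison_profile(x, ss, "k")
  expect_equal(prof$fc[prof$gene == "g1"], 2)
  expect_equal(prof$fc[prof$gene == "g2"], 1.40, tolerance = 0.005)
  expect_true(all(prof$fc[-(1:2)] == 1))
  expect_error(compute_comparison_profile(x, ss, "nope"), "unknown contrast")

  # identical replicate sets on both sides: all fc exactly 1, p = 1
  y <- x; y$values[, c("c1", "c2")] <- y$values[, c("t1", "t2")]
  prof2 <- compute_comparison_profile(y, ss, "k")
  expect_true(all(prof2$fc == 1))
  expect_true(all(prof2$p == 1))
})

test_that("single-replicate contrasts skip tests with a warning", {
  v <- matrix(1:20 + 0, 10, 2,
              dimnames = list(paste0("g", 1:10), c("t1", "c1")))
  x <- structure(list(values = v, feature_level = "gene",
                      log_space = "log2"), class = "expr_matrix")
  ss <- data.frame(sample_id = c("t1", "c1"), cell_line = "L",
                   group = c("aneuploid", "diploid_control"),
                   contrast_id = "k", replicate = 1L)
  expect_warning(prof <- compute_comparison_profile(x, ss, "k"),
                 class = "arpscreen_tests_skipped")
  expect_true(all(is.na(prof$p)))
  expect_false(any(is.na(prof$fc)))
})

test_that("fold changes are invariant to rescaling any single input array", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:120)
  v <- matrix(exp(rnorm(120 * 6)), 120, 6,
              dimnames = list(genes, c("t1", "t2", "t3", "c1", "c2", "c3")))
  ss <- data.frame(sample_id = colnames(v), cell_line = "L",
                   group = rep(c("aneuploid", "diploid_control"), each = 3),
                   contrast_id = "k", replicate = c(1:3, 1:3))
  p1 <- compute_comparison_profile(normalize_arrays(expr_matrix(v)), ss, "k")
  v2 <- v; v2[, "t2"] <- v2[, "t2"] * 37.5
  p2 <- compute_comparison_profile(normalize_arrays(expr_matrix(v2)), ss, "k")
  expect_equal(p1$fc, p2$fc, tolerance = 1e-12)
})

test_that("zero-noise dosage scenarios recover the copy ratio through the chain", {
  spec <- default_annotation_spec(pool_size = 20L, size_range = c(10L, 15L),
                                  n_background = 2L)
  uni <- build_gene_universe(400L, seed = 21L, annotation_spec = spec)
  base <- simulate_baseline_matrix(uni, n_replicates = 3L, noise_cv = 0,
                                   seed = 22L)
  tri <- karyotype_spec("t", 2L, c(chr5 = 3L))
  trt <- apply_karyotype_dosage(base, tri, uni$gene_map)
  v <- cbind(trt$values, base$values)
  colnames(v) <- c(paste0("t", 1:3), paste0("c", 1:3))
  ss <- data.frame(sample_id = colnames(v), cell_line = "L",
                   group = rep(c("aneuploid", "diploid_control"), each = 3),
                   contrast_id = "k", replicate = c(1:3, 1:3))
  on_chr <- names(uni$gene_map)[uni$gene_map == "chr5"]

  # global centering: both sides share the centering constant, so the
  # copy ratio is recovered exactly and unaltered genes sit at fc = 1
  pg <- compute_comparison_profile(
    normalize_arrays(expr_matrix(v), center = "global"), ss, "k")
  fc <- setNames(pg$fc, pg$gene)
  expect_equal(unname(fc[on_chr]), rep(1.5, length(on_chr)), tolerance = 1e-12)
  expect_equal(unname(fc[setdiff(names(fc), on_chr)]),
               rep(1, 400 - length(on_chr)), tolerance = 1e-12)

  # per-array centering: each side is centered on its own median, so all
  # fold changes share one common factor and the on/off ratio is exact
  pa <- compute_comparison_profile(
    normalize_arrays(expr_matrix(v), center = "per_array"), ss, "k")
  fca <- setNames(pa$fc, pa$gene)
  off <- setdiff(names(fca), on_chr)
  expect_equal(length(unique(signif(fca[off], 12))), 1L)
  expect_equal(unname(fca[on_chr] / fca[off][1L]),
               rep(1.5, length(on_chr)), tolerance = 1e-12)
})
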