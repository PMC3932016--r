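# Rank-based annotation enrichment, pairing, class generalization and the
# pathway-class sign matrix.

test_that("annotation score hits its extremes and the stated arithmetic", {
  fc <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))  # g1 ranks first
  expect_equal(annotation_score(fc, c("g1", "g2")), 1)
  expect_equal(annotation_score(fc, c("g4", "g5")), -1)
  expect_equal(annotation_score(fc, c("g1", "g4")), 1 / 3)
  expect_warning(s <- annotation_score(fc, character()),
                 class = "arpscreen_score_undefined")
  expect_true(is.na(s))
  expect_warning(annotation_score(fc, names(fc)),
                 class = "arpscreen_score_undefined")
})

test_that("annotation score equals the rank-biserial correlation (oracle)", {
  set.seed(21)
  for (i in 1:1000) {
    n <- sample(20:80, 1)
    m <- sample(3:(n - 3), 1)
    # rounded values create ties, exercising average ranks
    fc <- setNames(round(rnorm(n), sample(0:2, 1)), sprintf("x%03d", 1:n))
    members <- sample(names(fc), m)
    s <- annotation_score(fc, members)
    # U = pairs in which a non-member fold change exceeds a member's
    U <- unname(suppressWarnings(
      wilcox.test(fc[setdiff(names(fc), members)], fc[members],
                  exact = FALSE)$statistic))
    expect_equal(s, 1 - 2 * U / (m * (n - m)), tolerance = 1e-10)
  }
})

test_that("annotation score is rank-based: null mean zero, monotone-invariant", {
  set.seed(22)
  fc <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  draws <- replicate(1e4, annotation_score(fc, sample(names(fc), 20)))
  expect_equal(mean(draws), 0, tolerance = 0.01)

  members <- sample(names(fc), 25)
  s1 <- annotation_score(fc, members)
  expect_equal(annotation_score(exp(fc), members), s1)
  expect_equal(annotation_score(fc^3 + 10 * fc, members), s1)
})

test_that("enrich_comparison separates a planted category and filters small ones", {
  genes <- sprintf("g%03d", 1:500)
  fc <- setNames(rep(0, 500), genes)
  fc[1:20] <- 1
  # break fold-change ties among nulls so ranks are informative
  set.seed(30)
  fc[21:500] <- rnorm(480, 0, 1e-6)
  prof <- data.frame(gene = genes, log2fc = unname(fc))
  ann <- list(planted = genes[1:20], small = genes[1:9],
              random = sample(genes, 30))
  tab <- enrich_comparison(prof, ann, min_size = 10L, fdr_threshold = 0.02)
  expect_false("small" %in% tab$category)
  planted <- tab[tab$category == "planted", ]
  expect_equal(planted$score, 1, tolerance = 1e-3)
  expect_lte(planted$q, 0.02)
})

test_that("random categories are rarely called significant at FDR 0.02", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:300)
  hits <- 0L
  for (i in 1:100) {
    prof <- data.frame(gene = genes, log2fc = rnorm(300))
    ann <- lapply(1:15, function(j) sample(genes, 25))
    names(ann) <- paste0("cat", 1:15)
    tab <- enrich_comparison(prof, ann)
    if (tab$significant[tab$category == "cat1"]) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})

test_that("pairing keeps categories by significance mode", {
  tx <- data.frame(category = c("a", "b", "c"), n_members = 20,
                   score = c(0.5, 0.2, -0.4), p = 0.01,
                   q = c(0.01, 0.5, 0.01), significant = c(TRUE, FALSE, TRUE),
                   general_class = "Others")
  ty <- data.frame(category = c("a", "b", "d"), n_members = 20,
                   score = c(0.4, 0.1, 0.9), p = 0.01,
                   q = c(0.5, 0.6, 0.01), significant = c(FALSE, FALSE, TRUE),
                   general_class = "Others")
  either <- pair_enrichments(tx, ty)
  expect_setequal(either$category, c("a", "c", "d"))  # b significant nowhere
  expect_true(is.na(either$score_y[either$category == "c"]))
  both <- pair_enrichments(tx, ty, mode = "both")
  expect_equal(nrow(both), 0L)
  ty$significant[1] <- TRUE
  expect_equal(pair_enrichments(tx, ty, mode = "both")$category, "a")
})

test_that("general classes match by ordered case-insensitive keywords", {
  expect_equal(assign_general_class("Endoplasmic Reticulum membrane"), "ER")
  expect_equal(assign_general_class("proteasome complex"), "Others")
  custom <- list(Lysosome = "lysosom", Membrane = "membrane")
  expect_equal(assign_general_class("lysosomal membrane", custom), "Lysosome")
  expect_warning(out <- assign_general_class("anything", list()),
                 class = "arpscreen_empty_class_map")
  expect_equal(out, "Others")
})

test_that("the class sign matrix encodes agreement among significant scores", {
  mk <- function(scores, sig, class = "ER") {
    data.frame(category = sprintf("%s cat %d", class, seq_along(scores)),
               n_members = 20, score = scores, p = 0.001,
               q = ifelse(sig, 0.001, 0.5), significant = sig,
               general_class = class)
  }
  tabs <- list(cmp1 = mk(c(0.3, 0.5, 0.2, 0.4), rep(TRUE, 4)),
               cmp2 = mk(c(0.3, -0.4), c(TRUE, TRUE)),
               cmp3 = mk(c(0.3, 0.5), c(FALSE, FALSE)))
  m <- class_sign_matrix(tabs)
  expect_equal(m["ER", "cmp1"], "+")
  expect_equal(m["ER", "cmp2"], "+/-")
  expect_equal(m["ER", "cmp3"], "/")
  expect_true(all(m %in% c("+", "-", "+/-", "/")))
})
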