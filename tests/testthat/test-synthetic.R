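# Synthetic-data generator: gene universe, baseline noise model, dosage,
# signature planting and full scenario emission with ground truth.

test_that("gene universe is deterministic and honours chromosome weights", {
  spec <- default_annotation_spec(pool_size = 30L, size_range = c(10L, 20L))
  u1 <- build_gene_universe(1000L, seed = 42L, annotation_spec = spec)
  u2 <- build_gene_universe(1000L, seed = 42L, annotation_spec = spec)
  expect_identical(u1, u2)
  u3 <- build_gene_universe(1000L, seed = 43L, annotation_spec = spec)
  expect_false(identical(u1$gene_map, u3$gene_map))

  # all categories respect the minimum size
  expect_true(all(lengths(u1$annotations) >= 10L))
  expect_length(u1$annotations, 11L * 3L + 15L)

  # weights concentrated on chr1: with p = 0.97 over 1000 draws the
  # probability of fewer than 90% chr1 genes is below 1e-10
  w <- c(chr1 = 0.97, chr2 = 0.03)
  u <- build_gene_universe(1000L, chromosome_weights = w, seed = 1L,
                           annotation_spec = spec)
  expect_gt(mean(u$gene_map == "chr1"), 0.9)

  expect_error(
    build_gene_universe(200L, seed = 1L,
                        annotation_spec = default_annotation_spec(pool_size = 60L)),
    class = "arpscreen_config_error")
})

test_that("baseline matrices reproduce the requested replicate noise", {
  genes <- sprintf("g%04d", 1:1000)
  z <- simulate_baseline_matrix(genes, n_replicates = 4L, noise_cv = 0,
                                seed = 5L)
  expect_true(all(z$values[, 1] == z$values[, 2]))
  expect_true(all(z$values > 0))

  x <- simulate_baseline_matrix(genes, n_replicates = 6L, noise_cv = 0.1,
                                seed = 5L)
  cvs <- apply(x$values, 1L, function(v) sd(v) / mean(v))
  expect_gt(median(cvs), 0.07)
  expect_lt(median(cvs), 0.13)

  y <- simulate_baseline_matrix(genes, n_replicates = 6L, noise_cv = 0.1,
                                seed = 5L)
  expect_identical(x$values, y$values)
  expect_error(simulate_baseline_matrix(genes, noise_cv = -1),
               class = "arpscreen_config_error")
})

test_that("karyotype dosage scales genes by (copy/base)^attenuation", {
  genes <- sprintf("g%02d", 1:20)
  map <- setNames(rep(c("chr5", "chr7"), each = 10L), genes)
  m <- matrix(100, 20, 3, dimnames = list(genes, paste0("r", 1:3)))

  tri <- karyotype_spec("t5", 2L, c(chr5 = 3L))
  out <- apply_karyotype_dosage(m, tri, map)
  expect_equal(out[1:10, ], m[1:10, ] * 1.5)
  expect_equal(out[11:20, ], m[11:20, ])

  tetra <- karyotype_spec("t5x4", 2L, c(chr5 = 4L))
  expect_equal(apply_karyotype_dosage(m, tetra, map)[1, 1], 200)

  half <- apply_karyotype_dosage(m, tri, map, attenuation = 0.5)
  expect_equal(half[1, 1], 100 * sqrt(1.5))

  bad <- karyotype_spec("x", 2L, c(chr99 = 3L))
  expect_error(apply_karyotype_dosage(m, bad, map), "chr99")
})

test_that("signature shifts hit a per-line random fraction of each class pool", {
  genes <- sprintf("g%03d", 1:200)
  pools <- list(ER = genes[1:40])
  m <- matrix(64, 200, 2, dimnames = list(genes, c("a", "b")))

  # degenerate subset: phi = 1, sigma = 0, mu = 1 shifts every pool gene +1
  sig <- arp_signature_spec(mu_class = 1, sigma_class = 0, phi = 1,
                            pools = pools)
  sig$classes <- sig$classes[sig$classes$class == "ER", ]
  res <- apply_signature_shifts(m, sig, seed = 3L)
  expect_equal(unname(res$shifts[genes[1:40]]), rep(1, 40))
  expect_equal(res$matrix[1:40, ], m[1:40, ] * 2)
  expect_equal(res$matrix[41:200, ], m[41:200, ])

  # phi = 0.5 on a 40-gene pool shifts exactly 20 genes, and the subset
  # depends on the per-line seed
  sig$classes$phi <- 0.5
  r1 <- apply_signature_shifts(m, sig, seed = 101L)
  r2 <- apply_signature_shifts(m, sig, seed = 102L)
  expect_length(r1$affected$ER, 20L)
  expect_length(r2$affected$ER, 20L)
  expect_false(setequal(r1$affected$ER, r2$affected$ER))
})

test_that("the bafilomycin-like stress profile leaves the ER class unshifted", {
  genes <- c(sprintf("g%03d", 1:300), "FRY")
  pools <- list(ER = genes[1:30], `Membrane metabolism` = genes[31:60],
                Replication = genes[61:90])
  sig <- arp_signature_spec(pools = pools)
  m <- matrix(64, 301, 2, dimnames = list(genes, c("a", "b")))
  panel <- default_marker_panel()
  panel$shift_range <- c(1, 1.6)
  res <- apply_signature_shifts(
    m, sig, markers_spec = panel,
    stress_profile = list(name = "bafilomycinA1",
                          directions = stress_class_patterns()$bafilomycinA1),
    seed = 9L)
  expect_true(all(res$shifts[pools$ER] == 0))
  expect_false(all(res$shifts[pools$`Membrane metabolism`] == 0))
  rep_shifts <- res$shifts[pools$Replication]
  expect_lt(mean(rep_shifts[rep_shifts != 0]), 0)
  # only the shared marker is planted under stress
  expect_gt(res$shifts[["FRY"]], 0)
})

test_that("generated scenarios carry the planted truth and reproduce bytes", {
  cfg <- small_config()
  d1 <- file.path(withr::local_tempdir(), "s1")
  truth <- generate_scenario(cfg, seed = 77L, outdir = d1)

  sheet <- read_sample_sheet(file.path(d1, "sample_sheet.tsv"))
  an <- unique(sheet$contrast_id[sheet$group == "aneuploid"])
  expect_length(an, 13L)
  expect_length(unique(sheet$contrast_id[sheet$group == "stress"]), 8L)

  expect_equal(truth$markers_down,
               c("XYLB", "LOXL3", "MYB_NFIB", "EEPD", "ARHGEF39"))
  expect_length(truth$markers_up, 18L)
  expect_equal(truth$shared_stress_marker, "FRY")

  # every planted up-marker exceeds the fold threshold in every aneuploid line
  for (id in truth$aneuploid_contrasts) {
    ef <- unlist(truth$expected_fold[[id]])
    expect_true(all(ef[truth$markers_up] >= cfg$fc_threshold))
    expect_true(all(ef[truth$markers_down] <= 1 / cfg$fc_threshold))
  }

  d2 <- file.path(withr::local_tempdir(), "s2")
  generate_scenario(cfg, seed = 77L, outdir = d2)
  expect_identical(unname(dir_md5(d1)), unname(dir_md5(d2)))

  # a different seed keeps the marker panel but moves the affected subsets
  d3 <- file.path(withr::local_tempdir(), "s3")
  truth3 <- generate_scenario(cfg, seed = 78L, outdir = d3)
  expect_identical(truth3$markers_up, truth$markers_up)
  expect_false(identical(truth3$expected_fold, truth$expected_fold))
})
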