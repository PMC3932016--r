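# Consensus marker screen and stress-overlap flagging.

test_that("consensus requires the threshold in every comparison", {
  profs <- list(
    c1 = fc_profile(c(up = 1.5, near = 1.5, dn = 0.60, none = 1.0)),
    c2 = fc_profile(c(up = 1.45, near = 1.39, dn = 0.70, none = 1.1)),
    c3 = fc_profile(c(up = 2.0, near = 2.0, dn = 0.50, none = 0.9)))
  rep <- consensus_markers(profs, threshold = 1.4)
  expect_equal(rep$up, "up")            # all three above 1.4
  expect_false("near" %in% rep$up)      # 1.39 fails the all-quantifier
  expect_equal(rep$down, "dn")          # all below 1/1.4 ~ 0.714
  expect_length(intersect(rep$up, rep$down), 0L)
  expect_error(consensus_markers(profs[1]), ">= 2")
  expect_error(consensus_markers(profs, threshold = 1),
               class = "arpscreen_config_error")
})

test_that("boundary genes are included by default and excluded when strict", {
  profs <- list(a = fc_profile(c(g = 1.4)), b = fc_profile(c(g = 1.4)))
  expect_equal(consensus_markers(profs, 1.4)$up, "g")
  expect_length(consensus_markers(profs, 1.4, strict = TRUE)$up, 0L)
})

test_that("raising the threshold never adds a marker (monotonicity)", {
  set.seed(51)
  genes <- sprintf("g%03d", 1:200)
  for (i in 1:10) {
    profs <- lapply(1:5, function(j)
      fc_profile(setNames(2^rnorm(200, 0, 0.6), genes)))
    names(profs) <- paste0("c", 1:5)
    lo <- consensus_markers(profs, 1.3)
    hi <- consensus_markers(profs, 1.6)
    expect_true(all(hi$up %in% lo$up))
    expect_true(all(hi$down %in% lo$down))
  }
})

test_that("stress overlap counts same-direction passes only and never removes", {
  profs <- list(a = fc_profile(c(m1 = 2, m2 = 2, d1 = 0.5)),
                b = fc_profile(c(m1 = 1.8, m2 = 1.6, d1 = 0.6)))
  rep <- consensus_markers(profs, 1.4)
  stress <- list(
    s1 = fc_profile(c(m1 = 2.0, m2 = 0.5, d1 = 1.0)),   # m2 opposite: no count
    s2 = fc_profile(c(m1 = 1.5, m2 = 1.0, d1 = 0.5)))   # d1 down-passes
  out <- stress_overlap_flags(rep, stress)
  tab <- out$table
  expect_equal(tab$stress_overlap_count[tab$gene == "m1"], 2L)
  expect_equal(tab$stress_overlap_names[tab$gene == "m1"], "s1,s2")
  expect_equal(tab$stress_overlap_count[tab$gene == "m2"], 0L)
  expect_equal(tab$stress_overlap_count[tab$gene == "d1"], 1L)
  expect_setequal(tab$gene, c("m1", "m2", "d1"))  # flagged, not removed
})

test_that("marker recovery matches planted truth across seeds (scaled scenario)", {
  cfg <- small_config()
  for (seed in c(301L, 302L, 303L)) {
    dir <- file.path(withr::local_tempdir(), paste0("run", seed))
    truth <- generate_scenario(cfg, seed = seed,
                               outdir = file.path(dir, "scenario"))
    suppressWarnings({
      stage_normalize(dir, cfg)
      stage_diffexp(dir, cfg)
      f <- stage_markers(dir, cfg)
    })
    tab <- read.delim(f, comment.char = "#")
    expect_setequal(tab$gene[tab$direction == "up"], truth$markers_up)
    expect_setequal(tab$gene[tab$direction == "down"], truth$markers_down)
  }
})
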