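# synthetic_data: generator for expression datasets with the statistical
# structure the analysis assumes -- chromosome-dosage effects, a shared
# pathway-response signature with line-variable gene membership, a fixed
# consensus marker panel, stress profiles -- plus machine-readable truth.

#' The fixed consensus marker panel
#'
#' The default panel planted by the generator: 18 upregulated and 5
#' downregulated genes with their chromosome assignments. One up-marker
#' (`FRY`) is additionally planted in every stress profile, so that the
#' stress-overlap flagging step has exactly one true positive. `MIA` carries
#' no printed chromosome in its source table; the generator assigns it chr19
#' (its human locus) -- a synthetic assignment. The fusion transcript is
#' carried under the plain identifier `MYB_NFIB`.
#'
#' @return list with `up`, `down`, `shared_stress_marker` and `chromosomes`
#'   (named character vector, gene -> chromosome).
#' @export
default_marker_panel <- function() {
  chrom <- c(
    PLAUR = "chr19", RAB27B = "chr18", P4HA2 = "chr5", FRY = "chr13",
    BDKRB1 = "chr14", HOXB5 = "chr17", GDF15 = "chr19", OASL = "chr12",
    SERPINE2 = "chr2", IFI44 = "chr1", AMDHD1 = "chr12", TMEM171 = "chr5",
    GLRX = "chr5", TMEM169 = "chr2", DMBT1 = "chr10", COL13A1 = "chr10",
    SH2D1B = "chr1", MIA = "chr19",
    XYLB = "chr3", LOXL3 = "chr2", MYB_NFIB = "chr6", EEPD = "chr7",
    ARHGEF39 = "chr9")
  list(up = names(chrom)[1:18], down = names(chrom)[19:23],
       shared_stress_marker = "FRY", chromosomes = chrom)
}

.arp_classes <- c("Replication", "Transcription", "Ribosome", "Golgi", "ER",
                  "Lysosomes", "Membrane metabolism", "Vacuole",
                  "Mitochondria", "Spliceosome", "MHC class proteins")

# Naming stems so generated category names carry the keywords the
# class-generalization step matches on.
.class_stems <- c(
  "Replication" = "dna replication", "Transcription" = "transcription",
  "Ribosome" = "ribosome biogenesis", "Golgi" = "golgi apparatus",
  "ER" = "endoplasmic reticulum", "Lysosomes" = "lysosome",
  "Membrane metabolism" = "membrane lipid metabolism",
  "Vacuole" = "lytic vacuole", "Mitochondria" = "mitochondrion",
  "Spliceosome" = "spliceosome",
  "MHC class proteins" = "mhc protein complex")

#' Aneuploidy response signature specification
#'
#' Default planted direction pattern of the recurrent response: ER, Golgi,
#' lysosome, vacuole, membrane metabolism and MHC classes up; replication,
#' transcription, ribosome and spliceosome down; mitochondria unplanted
#' (direction 0), serving as a null class.
#'
#' @param mu_class mean log2 shift of affected genes (> 0).
#' @param sigma_class s.d. of the per-gene log2 shift.
#' @param phi fraction of each class pool affected per cell line, in (0, 1].
#' @param pools named list of class gene pools (from [build_gene_universe()]).
#' @return list with `classes` (data.frame class/direction/mu/sigma/phi) and
#'   `pools`.
#' @export
arp_signature_spec <- function(mu_class = 0.5, sigma_class = 0.2, phi = 0.75,
                               pools = NULL) {
  if (mu_class <= 0) arp_stop("mu_class must be > 0",
                              class = "arpscreen_config_error")
  direction <- c(Replication = -1, Transcription = -1, Ribosome = -1,
                 Golgi = 1, ER = 1, Lysosomes = 1,
                 `Membrane metabolism` = 1, Vacuole = 1, Mitochondria = 0,
                 Spliceosome = -1, `MHC class proteins` = 1)
  list(classes = data.frame(class = names(direction),
                            direction = unname(direction),
                            mu = mu_class, sigma = sigma_class, phi = phi,
                            stringsAsFactors = FALSE),
       pools = pools)
}

#' Planted class patterns of the stress conditions
#'
#' Eight stress contrasts. Only the bafilomycin-like profile is tied to the
#' aneuploidy signature: it shares the downregulated DNA/RNA classes and
#' membrane upregulation but leaves ER, Golgi and lysosome unshifted. The
#' actinomycin-D profile shares transcription-related downregulation with
#' partial membrane/ER overlap; the remaining conditions carry patterns
#' distinct from (partly opposed to) the aneuploidy response.
#'
#' @return named list: condition -> named numeric vector of class directions.
#' @export
stress_class_patterns <- function() {
  list(
    H2O2          = c(Mitochondria = 1, Transcription = 1),
    NO            = c(Mitochondria = 1, Golgi = -1),
    hydroxyurea   = c(Replication = -1),
    actinomycinD  = c(Replication = -1, Transcription = -1, Spliceosome = -1,
                      Ribosome = -1, ER = 1, `Membrane metabolism` = 1,
                      Lysosomes = 1),
    bafilomycinA1 = c(Replication = -1, Transcription = -1, Ribosome = -1,
                      Spliceosome = -1, `Membrane metabolism` = 1),
    hypoxia       = c(Mitochondria = -1, Transcription = 1),
    lowglucose    = c(`MHC class proteins` = -1, Spliceosome = 1),
    highglucose   = c(Ribosome = 1, Vacuole = -1))
}

#' Default chromosome weights
#'
#' Rough relative gene counts of the 24 human chromosomes, used to place
#' simulated genes.
#'
#' @return named numeric vector summing to 1.
#' @export
default_chromosome_weights <- function() {
  w <- c(chr1 = 2000, chr2 = 1200, chr3 = 1000, chr4 = 750, chr5 = 850,
         chr6 = 1000, chr7 = 900, chr8 = 700, chr9 = 780, chr10 = 730,
         chr11 = 1300, chr12 = 1000, chr13 = 320, chr14 = 600, chr15 = 600,
         chr16 = 800, chr17 = 1150, chr18 = 270, chr19 = 1400, chr20 = 540,
         chr21 = 230, chr22 = 440, chrX = 840, chrY = 70)
  w / sum(w)
}

#' Default annotation specification
#'
#' @param categories_per_class categories generated per pathway class.
#' @param n_background additional ungeneralizable background categories.
#' @param pool_size genes in each class pool.
#' @param size_range integer range of category sizes.
#' @param min_size minimum category size.
#' @return a list consumed by [build_gene_universe()].
#' @export
default_annotation_spec <- function(categories_per_class = 3L,
                                    n_background = 15L, pool_size = 60L,
                                    size_range = c(15L, 40L), min_size = 10L) {
  list(classes = .arp_classes, categories_per_class = categories_per_class,
       n_background = n_background, pool_size = pool_size,
       size_range = size_range, min_size = min_size)
}

#' Build a synthetic gene universe
#'
#' Deterministically (for a fixed seed) creates gene identifiers, assigns
#' them to chromosomes by the supplied weights, carves out one gene pool per
#' pathway class, and generates an annotation collection: several categories
#' per class drawn from that class's pool (so categories of one class
#' overlap), plus background categories drawn from unpooled genes.
#'
#' @param n_genes total number of genes (>= 100).
#' @param chromosome_weights named sampling weights per chromosome.
#' @param annotation_spec see [default_annotation_spec()].
#' @param seed integer seed.
#' @param fixed_genes optional named character vector (gene -> chromosome)
#'   of genes placed verbatim, e.g. the marker panel; these are excluded
#'   from class pools and categories.
#' @return list with `gene_map` (named chromosome vector), `annotations`
#'   (named list of member vectors), `class_pools` (named list) and `genes`.
#' @export
build_gene_universe <- function(n_genes = 4000L,
                                chromosome_weights = default_chromosome_weights(),
                                annotation_spec = default_annotation_spec(),
                                seed = 1L, fixed_genes = NULL) {
  if (n_genes < 100) arp_stop("n_genes must be >= 100",
                              class = "arpscreen_config_error")
  spec <- annotation_spec
  n_classes <- length(spec$classes)
  n_free <- n_genes - length(fixed_genes)
  if (n_classes * spec$pool_size > n_free)
    arp_stop("annotation spec requests more category members than genes",
             class = "arpscreen_config_error")
  if (spec$size_range[2] > spec$pool_size)
    arp_stop("category size range exceeds the class pool size",
             class = "arpscreen_config_error")
  with_seed(seed, {
    ids <- sprintf("GENE%05d", seq_len(n_free))
    chrom <- sample(names(chromosome_weights), n_free, replace = TRUE,
                    prob = chromosome_weights)
    gene_map <- stats::setNames(chrom, ids)
    if (!is.null(fixed_genes)) gene_map <- c(fixed_genes, gene_map)

    shuffled <- sample(ids)
    pools <- stats::setNames(vector("list", n_classes), spec$classes)
    offset <- 0L
    for (cl in spec$classes) {
      pools[[cl]] <- shuffled[(offset + 1L):(offset + spec$pool_size)]
      offset <- offset + spec$pool_size
    }
    background_genes <- shuffled[(offset + 1L):n_free]

    annotations <- list()
    desc <- character()
    flavors <- c("part", "process", "complex", "pathway", "organization",
                 "assembly")
    for (cl in spec$classes) {
      for (i in seq_len(spec$categories_per_class)) {
        sz <- sample(spec$size_range[1]:spec$size_range[2], 1L)
        nm <- sprintf("%s %s %d", .class_stems[[cl]],
                      flavors[(i - 1L) %% length(flavors) + 1L], i)
        annotations[[nm]] <- sort(sample(pools[[cl]], sz))
        desc[[nm]] <- sprintf("synthetic category, class %s", cl)
      }
    }
    for (i in seq_len(spec$n_background)) {
      sz <- sample(spec$size_range[1]:spec$size_range[2], 1L)
      nm <- sprintf("uncharacterized set %d", i)
      annotations[[nm]] <- sort(sample(background_genes, sz))
      desc[[nm]] <- "synthetic background category"
    }
    attr(annotations, "descriptions") <- desc
    list(gene_map = gene_map, annotations = annotations, class_pools = pools,
         genes = names(gene_map))
  })
}

# Mean-one multiplicative log-normal noise with coefficient of variation cv.
.replicate_noise <- function(n_genes, n_replicates, cv) {
  if (cv == 0) return(matrix(1, n_genes, n_replicates))
  sdlog <- sqrt(log(1 + cv^2))
  matrix(exp(stats::rnorm(n_genes * n_replicates, -sdlog^2 / 2, sdlog)),
         n_genes, n_replicates)
}

#' Simulate a diploid baseline expression matrix
#'
#' Per-gene baseline means are log-normal (`2^N(baseline_log2_mean,
#' baseline_log2_sd)`); replicate noise is multiplicative log-normal with
#' coefficient of variation `noise_cv` (mean one), so the per-gene
#' replicate CV approximates `noise_cv`.
#'
#' @param genes character vector of gene IDs (or a universe list from
#'   [build_gene_universe()]).
#' @param n_replicates number of replicate arrays.
#' @param noise_cv replicate coefficient of variation (>= 0).
#' @param seed integer seed.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale location and spread
#'   of the per-gene baseline means.
#' @return a linear-scale [expr_matrix] (strictly positive).
#' @export
simulate_baseline_matrix <- function(genes, n_replicates = 3L, noise_cv = 0.1,
                                     seed = 1L, baseline_log2_mean = 8,
                                     baseline_log2_sd = 1.5) {
  if (is.list(genes)) genes <- genes$genes
  if (noise_cv < 0) arp_stop("noise_cv must be >= 0",
                             class = "arpscreen_config_error")
  with_seed(seed, {
    b <- 2^stats::rnorm(length(genes), baseline_log2_mean, baseline_log2_sd)
    vals <- b * .replicate_noise(length(genes), n_replicates, noise_cv)
    dimnames(vals) <- list(genes, sprintf("rep%d", seq_len(n_replicates)))
    expr_matrix(vals, feature_level = "gene", log_space = "linear")
  })
}

#' Karyotype specification
#'
#' @param label cell-line label.
#' @param base_ploidy base copy number per chromosome (default 2; the
#'   complex hypotetraploid lines use 4).
#' @param copies named integer vector of per-chromosome copy numbers
#'   deviating from the base, e.g. `c(chr5 = 4)` for tetrasomy 5.
#' @return a `karyotype` list.
#' @export
karyotype_spec <- function(label, base_ploidy = 2L, copies = integer()) {
  if (any(copies < 0)) arp_stop("copy numbers must be >= 0")
  structure(list(label = label, base_ploidy = base_ploidy, copies = copies),
            class = "karyotype")
}

#' Apply chromosome-dosage scaling to an expression matrix
#'
#' Genes on a chromosome with copy number `c` in a karyotype of base ploidy
#' `b` are scaled by `(c/b)^attenuation` (linear scale); genes on unaltered
#' chromosomes are untouched. With full transmission (`attenuation = 1`) a
#' trisomic chromosome in a diploid background scales its genes by exactly
#' 1.5.
#'
#' @param x linear [expr_matrix] (or plain matrix with gene rownames).
#' @param karyotype a [karyotype_spec()].
#' @param gene_map named chromosome vector (gene -> chromosome).
#' @param attenuation dosage transmission exponent in (0, 1].
#' @return object of the same type as `x`, scaled.
#' @export
apply_karyotype_dosage <- function(x, karyotype, gene_map, attenuation = 1) {
  if (attenuation <= 0 || attenuation > 1)
    arp_stop("attenuation must lie in (0, 1]",
             class = "arpscreen_config_error")
  vals <- if (inherits(x, "expr_matrix")) x$values else x
  missing_chr <- setdiff(names(karyotype$copies), unique(gene_map))
  if (length(missing_chr))
    arp_stop("karyotype chromosome(s) absent from gene map: ",
             paste(missing_chr, collapse = ", "))
  fac <- dosage_factors(karyotype, gene_map, attenuation)
  fac <- fac[rownames(vals)]
  fac[is.na(fac)] <- 1
  out <- vals * fac
  if (inherits(x, "expr_matrix"))
    expr_matrix(out, feature_level = x$feature_level, log_space = x$log_space)
  else out
}

#' Per-gene linear dosage factors of a karyotype
#' @inheritParams apply_karyotype_dosage
#' @return named numeric vector over `names(gene_map)`.
#' @export
dosage_factors <- function(karyotype, gene_map, attenuation = 1) {
  fac <- stats::setNames(rep(1, length(gene_map)), names(gene_map))
  for (chr in names(karyotype$copies)) {
    ratio <- karyotype$copies[[chr]] / karyotype$base_ploidy
    fac[gene_map == chr] <- ratio^attenuation
  }
  fac
}

# Draw the per-gene log2 shift vector of one cell line: class-signature
# shifts on a seeded random fraction phi of each pool, plus marker shifts.
.draw_line_shifts <- function(genes, signature_spec, markers_spec = NULL,
                              stress_profile = NULL, seed = 1L) {
  shifts <- stats::setNames(rep(0, length(genes)), genes)
  affected <- list()
  cls <- signature_spec$classes
  directions <- stats::setNames(cls$direction, cls$class)
  if (!is.null(stress_profile)) {
    directions[] <- 0
    pat <- stress_profile$directions
    directions[names(pat)] <- pat
  }
  with_seed(seed, {
    for (i in seq_len(nrow(cls))) {
      cl <- cls$class[i]
      dir <- directions[[cl]]
      if (dir == 0) next
      pool <- intersect(signature_spec$pools[[cl]], genes)
      k <- round(cls$phi[i] * length(pool))
      if (k == 0) next
      hit <- sample(pool, k)
      shifts[hit] <- shifts[hit] +
        stats::rnorm(k, dir * cls$mu[i], cls$sigma[i])
      affected[[cl]] <- hit
    }
    if (!is.null(markers_spec)) {
      rng <- markers_spec$shift_range
      if (is.null(stress_profile)) {
        up <- markers_spec$up
        down <- markers_spec$down
        missing <- setdiff(c(up, down), genes)
        if (length(missing))
          arp_stop("marker gene(s) not in universe: ",
                   paste(missing, collapse = ", "))
        shifts[up] <- shifts[up] + stats::runif(length(up), rng[1], rng[2])
        shifts[down] <- shifts[down] - stats::runif(length(down), rng[1], rng[2])
      } else {
        sm <- markers_spec$shared_stress_marker
        if (!sm %in% genes)
          arp_stop("marker gene(s) not in universe: ", sm)
        shifts[sm] <- shifts[sm] + stats::runif(1, rng[1], rng[2])
      }
    }
  })
  list(shifts = shifts, affected = affected, directions = directions)
}

#' Plant signature and marker shifts into an expression matrix
#'
#' For each pathway class with a non-zero direction, a seeded random subset
#' of fraction `phi` of the class's gene pool receives a log2 shift drawn
#' from `Normal(direction * mu, sigma)`; different seeds (cell lines) affect
#' different subsets. Marker genes receive fixed uniform shifts from
#' `markers_spec$shift_range`, upward for the up panel and downward for the
#' down panel. When `stress_profile` is supplied, its class-direction
#' pattern replaces the signature's (classes absent from the pattern are
#' unshifted -- the bafilomycin-like profile therefore leaves ER, Golgi and
#' lysosome untouched) and only the shared stress marker is planted.
#'
#' @param x linear [expr_matrix] or plain matrix with gene rownames.
#' @param signature_spec from [arp_signature_spec()] (with pools set).
#' @param markers_spec from [default_marker_panel()] plus a `shift_range`;
#'   `NULL` to plant no markers.
#' @param stress_profile `NULL`, or `list(name=, directions=)` with a named
#'   class-direction vector (see [stress_class_patterns()]).
#' @param seed integer seed (vary per cell line).
#' @return list with `matrix` (same type as `x`), `shifts` (named per-gene
#'   log2 shift vector) and `affected` (class -> shifted genes).
#' @export
apply_signature_shifts <- function(x, signature_spec, markers_spec = NULL,
                                   stress_profile = NULL, seed = 1L) {
  vals <- if (inherits(x, "expr_matrix")) x$values else x
  drawn <- .draw_line_shifts(rownames(vals), signature_spec, markers_spec,
                             stress_profile, seed)
  out <- vals * 2^drawn$shifts
  if (inherits(x, "expr_matrix"))
    out <- expr_matrix(out, feature_level = x$feature_level,
                       log_space = x$log_space)
  list(matrix = out, shifts = drawn$shifts, affected = drawn$affected)
}

# The 21 contrasts of the default scenario: 13 aneuploid (7 own-lab with two
# complex karyotypes, 3 DLD1-like, 3 HE35-like trisomy-8 clones) + 8 stress.
default_scenario_lines <- function() {
  k <- function(label, base, copies) karyotype_spec(label, base, copies)
  an <- list(
    list(id = "HCT116_3_3",     line = "HCT116", kt = k("HCT116 3/3", 2L, c(chr3 = 3L))),
    list(id = "HCT116_5_4",     line = "HCT116", kt = k("HCT116 5/4", 2L, c(chr5 = 4L))),
    list(id = "HCT116_5_4s",    line = "HCT116 H2B-GFP", kt = k("HCT116 5/4*", 2L, c(chr5 = 4L))),
    list(id = "HPT1",           line = "HCT116 H2B-GFP",
         kt = k("HPT1", 4L, c(chr4 = 3L, chr6 = 3L, chr10 = 3L, chr13 = 3L,
                              chr18 = 2L, chr20 = 5L))),
    list(id = "HPT2",           line = "HCT116 H2B-GFP",
         kt = k("HPT2", 4L, c(chr2 = 3L, chr7 = 3L, chr9 = 3L, chr16 = 2L,
                              chr21 = 5L))),
    list(id = "RPE1_5_3_12_3",  line = "RPE1", kt = k("RPE1 5/3 12/3", 2L, c(chr5 = 3L, chr12 = 3L))),
    list(id = "RPE1_21_3",      line = "RPE1 H2B-GFP", kt = k("RPE1 21/3*", 2L, c(chr21 = 3L))),
    list(id = "DLD1_3_3",       line = "DLD1", kt = k("DLD1 3/3", 2L, c(chr3 = 3L))),
    list(id = "DLD1_7_3",       line = "DLD1", kt = k("DLD1 7/3", 2L, c(chr7 = 3L))),
    list(id = "DLD1_13_3",      line = "DLD1", kt = k("DLD1 13/3", 2L, c(chr13 = 3L))),
    list(id = "HE35_8_3_c1",    line = "HE35", kt = k("HE35 8/3_1", 2L, c(chr8 = 3L))),
    list(id = "HE35_8_3_c2",    line = "HE35", kt = k("HE35 8/3_2", 2L, c(chr8 = 3L))),
    list(id = "HE35_8_3_c3",    line = "HE35", kt = k("HE35 8/3_3", 2L, c(chr8 = 3L))))
  for (i in seq_along(an)) an[[i]]$type <- "aneuploid"
  st <- lapply(names(stress_class_patterns()), function(cond) {
    list(id = paste0("stress_", cond), line = "HCT116", kt = NULL,
         type = "stress", condition = cond)
  })
  c(an, st)
}

#' Generate the full synthetic scenario on disk
#'
#' Writes, under `outdir`: one expression table per contrast (treatment and
#' matched control replicate columns, linear intensities), a sample sheet, a
#' gene-to-chromosome map, a GMT annotation collection and a ground-truth
#' JSON (`truth.json`). Re-running with the same configuration and seed
#' reproduces the files byte-identically.
#'
#' @param config an `arp_config` (see [load_config()]); its `$scenario`
#'   block holds the generator parameters.
#' @param seed integer base seed (defaults to `config$seed`).
#' @param outdir output directory (created if needed).
#' @return the truth list, invisibly.
#' @export
generate_scenario <- function(config = load_config(), seed = config$seed,
                              outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    arp_stop("cannot create output directory: ", outdir)
  sc <- config$scenario
  panel <- default_marker_panel()
  panel$shift_range <- sc$marker_shift_range
  spec <- default_annotation_spec(
    categories_per_class = sc$categories_per_class,
    n_background = sc$n_background_categories,
    pool_size = sc$class_pool_size,
    size_range = sc$category_size_range,
    min_size = config$min_category_size)
  uni <- build_gene_universe(sc$n_genes, default_chromosome_weights(), spec,
                             seed = substream_seed(seed, "universe"),
                             fixed_genes = panel$chromosomes)
  sig <- arp_signature_spec(sc$mu_class, sc$sigma_class, sc$phi,
                            pools = uni$class_pools)
  b <- with_seed(substream_seed(seed, "baseline"),
                 2^stats::rnorm(length(uni$genes), sc$baseline_log2_mean,
                                sc$baseline_log2_sd))
  names(b) <- uni$genes
  # Markers model trans-regulated, dosage-independent responses: exclude
  # them from cis-dosage scaling so planted folds are the marker shifts.
  map_nomark <- uni$gene_map[setdiff(uni$genes, c(panel$up, panel$down))]

  lines <- default_scenario_lines()
  patterns <- stress_class_patterns()
  r <- sc$n_replicates
  sheet <- list()
  truth_fold <- list()
  truth_dirs <- list()
  for (ln in lines) {
    id <- ln$id
    dos <- rep(1, length(uni$genes))
    names(dos) <- uni$genes
    stress_profile <- NULL
    if (ln$type == "aneuploid") {
      dfac <- dosage_factors(ln$kt, map_nomark, sc$attenuation)
      dos[names(dfac)] <- dfac
    } else {
      stress_profile <- list(name = ln$condition,
                             directions = patterns[[ln$condition]])
    }
    drawn <- .draw_line_shifts(uni$genes, sig,
                               markers_spec = panel,
                               stress_profile = stress_profile,
                               seed = substream_seed(seed, paste0("line_", id)))
    efold <- dos * 2^drawn$shifts
    tmean <- b * efold
    noise <- with_seed(substream_seed(seed, paste0("noise_", id)),
                       .replicate_noise(length(uni$genes), 2L * r, sc$noise_cv))
    vals <- cbind(tmean * noise[, seq_len(r), drop = FALSE],
                  b * noise[, r + seq_len(r), drop = FALSE])
    colnames(vals) <- c(sprintf("%s_T_%d", id, seq_len(r)),
                        sprintf("%s_C_%d", id, seq_len(r)))
    rownames(vals) <- uni$genes
    write_expression_table(
      expr_matrix(vals, "gene", "linear"),
      file.path(outdir, sprintf("expression_%s.tsv", id)), "gene")
    grp_t <- if (ln$type == "aneuploid") "aneuploid" else "stress"
    grp_c <- if (ln$type == "aneuploid") "diploid_control" else "stress_control"
    sheet[[id]] <- data.frame(
      sample_id = colnames(vals),
      cell_line = ln$line,
      group = rep(c(grp_t, grp_c), each = r),
      contrast_id = id,
      replicate = rep(seq_len(r), 2L),
      stringsAsFactors = FALSE)
    truth_fold[[id]] <- as.list(efold[efold != 1])
    truth_dirs[[id]] <- as.list(drawn$directions[drawn$directions != 0])
  }
  sheet <- do.call(rbind, sheet)
  rownames(sheet) <- NULL
  write_sample_sheet(sheet, file.path(outdir, "sample_sheet.tsv"))
  write_gene_map(uni$gene_map, file.path(outdir, "gene_map.tsv"))
  write_gmt(uni$annotations, file.path(outdir, "annotations.gmt"))
  truth <- list(
    seed = seed,
    markers_up = panel$up,
    markers_down = panel$down,
    shared_stress_marker = panel$shared_stress_marker,
    aneuploid_contrasts = vapply(lines[vapply(lines, function(l)
      l$type == "aneuploid", logical(1))], `[[`, character(1), "id"),
    stress_contrasts = vapply(lines[vapply(lines, function(l)
      l$type == "stress", logical(1))], `[[`, character(1), "id"),
    class_directions = truth_dirs,
    class_pools = uni$class_pools,
    expected_fold = truth_fold,
    scenario = sc)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
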