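test_that("target profiles realize the documented shapes", {
  set.seed(301)
  b <- make_gc_target_profile("B", 100, 45, 6)
  expect_true(which.max(b) %in% c(50, 51))
  expect_equal(b[1], min(b), tolerance = 1e-9)
  expect_equal(b[100], min(b), tolerance = 1e-9)
  expect_equal(make_gc_target_profile("D", 100, 40, 6), rep(40, 100))
  a <- make_gc_target_profile("A", 100, 45, 6)
  expect_equal(abs(a[100] - a[1]), 6, tolerance = 0.1)
  for (cl in gradient_classes()) {
    p <- make_gc_target_profile(cl, 100, 45, 5)
    expect_equal(mean(p), 45, tolerance = 0.5)
  }
  # half-shapes have one flat half
  bm <- make_gc_target_profile("Bminus", 100, 45, 5)
  expect_true(sd(bm[1:50]) == 0 || sd(bm[51:100]) == 0)
  expect_error(make_gc_target_profile("X", 100, 45, 5), "unknown gradient class")
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(n_chroms = 2, n_tads = 10, seed = 77)
  s1 <- synthesize_genome(cfg)
  s2 <- synthesize_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
})

test_that("chromosome tiling yields plausible TAD counts and valid intervals", {
  cfg <- synthetic_config(n_chroms = 3, chrom_length = 2e6,
                          tad_length_range = c(100000, 400000), seed = 41)
  sim <- synthesize_genome(cfg)
  counts <- table(sim$tads$chrom)
  expect_true(all(counts >= 5 & counts <= 20))
  expect_true(all(sim$tads$end <= 2e6))
  expect_true(all(sim$tads$start >= 0))
  # TADs do not overlap within a chromosome
  for (ch in unique(sim$tads$chrom)) {
    t <- sim$tads[sim$tads$chrom == ch, ]
    expect_true(all(t$start[-1] >= t$end[-nrow(t)]))
  }
  expect_error(synthetic_config(n_chroms = 1, chrom_length = 2e6,
                                class_mix = c(A = 0.7)), "sum to 1")
  cfg_bad <- synthetic_config(n_chroms = 1, chrom_length = 50000,
                              tad_length_range = c(100000, 400000), seed = 1)
  expect_error(synthesize_genome(cfg_bad), "infeasible tiling")
})

test_that("classes are allotted exactly per the mix", {
  suite <- standard_suite()
  expect_equal(unname(table(suite$sim$truth$true_class)[gradient_classes()]),
               rep(100L, 6), ignore_attr = TRUE)
})

test_that("realized profiles track their targets when amplitude dominates noise", {
  cfg <- synthetic_config(n_chroms = 2, n_tads = 60, gradient_amplitude = 8,
                          bin_noise_sd = 1, seed = 42)
  sim <- synthesize_genome(cfg)
  prof <- tad_profiles(sim$genome, sim$tads)
  targets <- attr(sim$truth, "target_profile")
  nonflat <- sim$truth$true_class != "D"
  rs <- vapply(which(nonflat), function(i) cor(prof$profile[i, ], targets[i, ]),
               numeric(1))
  expect_true(all(rs >= 0.8))
  # realized mean GC close to the drawn truth
  expect_equal(prof$meta$mean_gc, sim$truth$true_mean_gc, tolerance = 0.5)
})

test_that("expression construction hits its Tau targets and hub shift is calibrated", {
  suite <- standard_suite()
  feats <- suite$feats
  tv <- tau(feats$expression)
  truth_class <- feats$gene_truth$true_tau_class
  expect_true(all(tv[truth_class == "housekeeping"] < 0.3))
  expect_true(all(tv[truth_class == "tissue_specific"] > 0.8))
  expect_equal(ncol(feats$expression), 27)

  gt <- suite$gc_track
  sp <- feats$hubs$label == "speckle"
  nu <- feats$hubs$label == "nucleolar"
  d <- mean(gt$gc[sp], na.rm = TRUE) - mean(gt$gc[nu], na.rm = TRUE)
  expect_equal(d, 5, tolerance = 0.5)
})

test_that("synthetic contact matrices are symmetric with non-negative integer counts", {
  cfg <- synthetic_config(n_chroms = 3, n_tads = 30, hub_resolution = 25000,
                          icp_gc_coupling = 0.5, seed = 43)
  sim <- synthesize_genome(cfg)
  gt <- windowed_gc(sim$genome, resolution = cfg$hub_resolution)
  cm <- synthesize_contacts(gt, cfg)
  expect_true(Matrix::isSymmetric(cm$counts))
  expect_true(all(cm$counts@x >= 0))
  expect_true(all(cm$counts@x == round(cm$counts@x)))
})

test_that("written files round-trip to the in-memory objects", {
  cfg <- synthetic_config(n_chroms = 2, n_tads = 24, hub_resolution = 20000,
                          seed = 44)
  ds <- synthesize_all(cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds, dir)
  genome <- read_genome_fasta(paths[["genome"]])
  expect_identical(as.character(genome), as.character(ds$genome$genome))
  tads <- read_bed(paths[["tads"]])
  expect_equal(tads$start, ds$genome$tads$start)
  tpm <- read_expression_table(paths[["expression"]])
  expect_equal(tpm, ds$features$expression)
  sizes <- stats::setNames(Biostrings::width(genome), names(genome))
  cm <- read_contacts(paths[["contacts"]], cfg$hub_resolution, sizes)
  # map the generator bins onto the full genome bin table and compare counts
  key <- function(b) paste(b$chrom, b$start)
  idx <- match(key(ds$contacts$bins), key(cm$bins))
  expect_false(anyNA(idx))
  expect_equal(as.matrix(cm$counts[idx, idx]), as.matrix(ds$contacts$counts),
               ignore_attr = TRUE)
})
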