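test_that("relative positions use midpoints and the full-containment rule", {
  tads <- data.frame(chrom = "chr1", start = 0, end = 1000, name = "t1")
  feats <- data.frame(chrom = "chr1",
                      start = c(100, 900, 0, 2000),
                      end = c(200, 1100, 1, 2100),
                      name = c("in", "spanning", "at_start", "outside"))
  rp <- relative_positions(tads, feats)
  expect_equal(rp$records$rel_pos[rp$records$feature_id == "in"], 0.15)
  expect_equal(rp$records$rel_pos[rp$records$feature_id == "at_start"], 0.0005)
  expect_false("spanning" %in% rp$records$feature_id)
  expect_equal(rp$n_assigned, 2)
  expect_equal(rp$n_boundary_dropped, 1)
  expect_equal(rp$n_outside, 1)
  # accounting conservation
  expect_equal(rp$n_assigned + rp$n_boundary_dropped + rp$n_outside, nrow(feats))
})

test_that("nested TADs: the smallest container wins", {
  tads <- data.frame(chrom = "chr1", start = c(0, 100), end = c(1000, 400),
                     name = c("outer", "inner"))
  feats <- data.frame(chrom = "chr1", start = 200, end = 220, name = "f")
  rp <- relative_positions(tads, feats)
  expect_equal(rp$records$tad_id, "inner")
  expect_equal(rp$records$rel_pos, (210 - 100) / 300)
})

test_that("mirroring the coordinate system maps rel_pos to 1 - rel_pos", {
  set.seed(601)
  L <- 100000
  tads <- data.frame(chrom = "chr1", start = 20000, end = 80000, name = "t")
  s <- sort(sample(25000:70000, 30))
  feats <- data.frame(chrom = "chr1", start = s, end = s + 500,
                      name = sprintf("f%02d", 1:30))
  fwd <- relative_positions(tads, feats)
  tads_m <- data.frame(chrom = "chr1", start = L - tads$end, end = L - tads$start,
                       name = "t")
  feats_m <- data.frame(chrom = "chr1", start = L - feats$end, end = L - feats$start,
                        name = feats$name)
  rev <- relative_positions(tads_m, feats_m)
  expect_equal(rev$records$rel_pos[match(fwd$records$feature_id,
                                         rev$records$feature_id)],
               1 - fwd$records$rel_pos)
})

test_that("positional density: point mass, normalization, and boundary shapes", {
  d <- positional_density(rep(0.5, 50))
  expect_equal(d$kde$x[which.max(d$kde$density)], 0.5, tolerance = 0.02)

  set.seed(602)
  u <- runif(500)
  du <- positional_density(u)
  dx <- diff(du$kde$x[1:2])
  expect_equal(sum(du$kde$density) * dx, 1, tolerance = 0.01)

  # U-shaped placement: border mass exceeds central mass
  b <- rbeta(1000, 0.5, 0.5)
  db <- positional_density(b)
  border <- sum(db$histogram$count[db$histogram$bin_start < 0.1 |
                                   db$histogram$bin_end > 0.9])
  centre <- sum(db$histogram$count[db$histogram$bin_start >= 0.45 &
                                   db$histogram$bin_end <= 0.55])
  expect_gt(border, centre)

  expect_null(positional_density(runif(5))$kde)
  expect_warning(positional_density(numeric(0)), "no records")
})

test_that("Tau matches the max-normalized formula on the transformed values", {
  # analytic limits
  expect_equal(tau(rep(7, 27)), 0)
  one_hot <- c(100, rep(0, 26))
  expect_equal(tau(one_hot), 1)
  # hand-computed 4-tissue example on log2(TPM + 1)
  row <- c(8, 2, 0.5, 0.5)
  x <- log2(row + 1)
  by_hand <- sum(1 - x / max(x)) / (length(x) - 1)
  expect_equal(tau(row), by_hand, tolerance = 1e-9)
  # raw-transform scale invariance
  set.seed(603)
  r <- runif(10, 0, 50)
  expect_equal(tau(3.7 * r, transform = "raw"), tau(r, transform = "raw"),
               tolerance = 1e-12)
  expect_true(is.na(tau(rep(0, 5))))
  expect_error(tau(c(1, -2)), "non-negative")
  expect_error(tau(5), "at least 2")
})

test_that("gene stratification uses strict Tau cut-points", {
  # raw transform lets exact boundary values be constructed: N = 2 tissues,
  # tau = 1 - x2/x1
  m <- rbind(hk = c(10, 8),         # tau 0.2
             at_03 = c(10, 7),      # tau 0.3 exactly
             mid = c(10, 5),        # tau 0.5
             at_08 = c(10, 2),      # tau 0.8 exactly
             ts = c(10, 1),         # tau 0.9
             zero = c(0, 0))
  colnames(m) <- c("t1", "t2")
  res <- stratify_genes(m, transform = "raw")
  cls <- setNames(res$genes$expression_class, res$genes$gene_id)
  expect_equal(unname(cls[c("hk", "at_03", "mid", "at_08", "ts")]),
               c("housekeeping", "intermediate", "intermediate",
                 "intermediate", "tissue_specific"))
  expect_equal(res$excluded, "zero")
  expect_equal(res$genes$mean_tpm[res$genes$gene_id == "hk"], 9)
  expect_equal(res$genes$log10_mean_tpm[res$genes$gene_id == "hk"], log10(9))
})

test_that("family densities: arithmetic, share normalization, generator gradient", {
  tads <- data.frame(chrom = "chr1", start = 0, end = 200000,
                     name = "t1", family = "H1")
  genes <- data.frame(chrom = "chr1", start = c(1, 2, 3, 4) * 10000,
                      end = c(1, 2, 3, 4) * 10000 + 1000,
                      name = paste0("g", 1:4))
  dt <- family_density_table(tads, list(gene = genes))
  expect_equal(dt$gene_per_100kb, 2)
  expect_equal(dt$length_share, 1)

  suite <- standard_suite()
  tads_fam <- data.frame(suite$sim$tads, family = suite$sim$truth$true_family)
  dt2 <- family_density_table(tads_fam,
                              list(gene = suite$feats$genes,
                                   super_enhancer = suite$feats$super_enhancers,
                                   ctcf = suite$feats$ctcf))
  expect_equal(dt2$family, c("L1", "L2", "H1", "H2", "H3"))
  expect_equal(sum(dt2$length_share), 1, tolerance = 1e-9)
  expect_true(all(diff(dt2$gene_per_100kb) >= 0))
  expect_true(all(diff(dt2$super_enhancer_per_100kb) >= 0))
  expect_true(all(diff(dt2$ctcf_per_100kb) >= 0))
})

test_that("housekeeping density comparison detects a known rate difference", {
  set.seed(604)
  n <- 200; L <- 100000
  starts <- seq(0, by = L + 1000, length.out = 2 * n)
  tads <- data.frame(chrom = "chr1", start = starts, end = starts + L,
                     class = rep(c("B", "C"), each = n))
  place_genes <- function(rates) {
    do.call(rbind, lapply(seq_len(2 * n), function(i) {
      k <- rpois(1, rates[i])
      if (k == 0) return(NULL)
      s <- tads$start[i] + sample.int(L - 2000, k)
      data.frame(chrom = "chr1", start = s, end = s + 1000,
                 name = sprintf("g_%d_%d", i, seq_len(k)))
    }))
  }
  genes <- place_genes(ifelse(tads$class == "B", 4, 2))
  gene_classes <- data.frame(gene_id = genes$name, tau = 0.1,
                             expression_class = "housekeeping",
                             mean_tpm = 10, log10_mean_tpm = 1)
  res <- class_expression_comparison(tads, genes, gene_classes)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$medians[["B"]], res$medians[["C"]])

  genes0 <- place_genes(rep(3, 2 * n))
  gc0 <- data.frame(gene_id = genes0$name, tau = 0.1,
                    expression_class = "housekeeping",
                    mean_tpm = 10, log10_mean_tpm = 1)
  res0 <- class_expression_comparison(tads, genes0, gc0)
  expect_gt(res0$p_value, 0.05)

  expect_error(class_expression_comparison(tads[c(1, 201), ], genes, gene_classes),
               "at least 2")
})
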