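test_that("half correlations recover canonical shapes and conventions", {
  ramp <- seq(40, 46, length.out = 100)
  expect_equal(unname(half_correlations(ramp)), c(1, 1))
  tri <- make_gc_target_profile("B", 100, 45, 6)
  r <- half_correlations(tri)
  expect_gt(r["r1"], 0.99)
  expect_lt(r["r2"], -0.99)
  # zero-variance half is flat by convention
  expect_equal(unname(half_correlations(rep(42, 100))), c(0, 0))
  # too few unmasked bins in a half makes the profile unclassifiable
  p <- ramp; p[1:48] <- NA
  expect_true(is.na(half_correlations(p)["r1"]))
  expect_error(half_correlations(seq_len(99)), "even")
})

test_that("sign-pair mapping covers all nine cases", {
  expect_equal(classify_gradient(0.9, -0.9), "B")
  expect_equal(classify_gradient(-0.2, 0.3), "D")
  expect_equal(classify_gradient(0.7, 0.1), "Bminus")
  expect_equal(classify_gradient(-0.1, -0.7), "Bminus")
  expect_equal(classify_gradient(0.5, 0.5), "A")
  expect_equal(classify_gradient(-0.5, -0.5), "A")
  expect_equal(classify_gradient(-0.5, 0.5), "C")
  expect_equal(classify_gradient(-0.5, 0.1), "Cminus")
  expect_equal(classify_gradient(0.1, 0.5), "Cminus")
  # threshold boundary: |r| = flat_threshold counts as a gradient
  expect_equal(classify_gradient(0.4, 0.4), "A")
  expect_equal(classify_gradient(0.39, -0.39), "D")
})

test_that("classification is invariant to profile reversal and affine rescaling", {
  set.seed(201)
  for (i in 1:500) {
    p <- random_profile()
    r <- half_correlations(p)
    rr <- half_correlations(rev(p))
    # reversal maps (r1, r2) to (-r2, -r1)
    expect_equal(unname(rr), unname(-r[2:1]), tolerance = 1e-12)
    expect_equal(classify_gradient(rr[1], rr[2]), classify_gradient(r[1], r[2]))
    a <- runif(1, 0.1, 3); b <- runif(1, -10, 10)
    r2 <- half_correlations(a * p + b)
    expect_equal(classify_gradient(r2[1], r2[2]), classify_gradient(r[1], r[2]))
  }
})

test_that("attenuated half-shapes promote to full shapes at a lower flat threshold", {
  set.seed(202)
  # half-bell with a weak second gradient: r2 realized between the two cuts
  p <- c(seq(40, 46, length.out = 50), seq(46, 45.75, length.out = 50) + rnorm(50, 0, 0.3))
  r <- half_correlations(p)
  expect_equal(classify_gradient(r[1], r[2], flat_threshold = 0.4), "Bminus")
  expect_equal(classify_gradient(r[1], r[2], flat_threshold = abs(r[2]) * 0.9), "B")
  pm <- -p + 90
  rm <- half_correlations(pm)
  expect_equal(classify_gradient(rm[1], rm[2], flat_threshold = 0.4), "Cminus")
  expect_equal(classify_gradient(rm[1], rm[2], flat_threshold = abs(rm[2]) * 0.9), "C")
})

test_that("classify_all tabulates frequencies that sum to one per stratum", {
  set.seed(203)
  mats <- t(replicate(100, make_gc_target_profile("B", 100, 45, 6) + rnorm(100, 0, 0.3)))
  res <- classify_all(mats)
  expect_equal(res$frequency$proportion[res$frequency$class == "B" &
                                        res$frequency$stratum == "overall"], 1)
  suite <- standard_suite()
  freq <- suite$cl$frequency
  for (s in unique(freq$stratum))
    expect_equal(sum(freq$proportion[freq$stratum == s]), 1, tolerance = 1e-9)
  # proportions close to the generating mix
  overall <- freq[freq$stratum == "overall", ]
  expect_true(all(abs(overall$proportion - 1 / 6) < 0.03))
  expect_warning(classify_all(matrix(numeric(0), 0, 100)), "no profiles")
})

test_that("profiles with an unclassifiable half are excluded and reported", {
  m <- rbind(seq(40, 46, length.out = 100),
             c(rep(NA, 48), 41, 42, seq(43, 46, length.out = 50)))
  rownames(m) <- c("ok", "bad")
  res <- classify_all(m)
  expect_equal(res$excluded, "bad")
  expect_equal(res$per_tad$class[1], "A")
})

test_that("transition matrix conserves per-class counts under perturbation", {
  cfg <- synthetic_config(n_chroms = 2, n_tads = 12,
                          tad_length_range = c(150000, 200000),
                          mean_gc_range = c(36, 56), seed = 31)
  sim <- synthesize_genome(cfg)
  orig <- classify_all(tad_profiles(sim$genome, sim$tads))
  for (m in c("expand", "shrink")) {
    pr <- perturb_and_reclassify(sim$genome, sim$tads, 50000, m)
    counts <- table(factor(orig$per_tad$class, levels = gradient_classes()))
    expect_equal(unname(rowSums(pr$transition)), as.vector(counts))
  }
})

test_that("shrinking below the feasible length lands in the excluded column", {
  cfg <- synthetic_config(n_chroms = 2, n_tads = 8,
                          tad_length_range = c(20000, 30000), seed = 32)
  sim <- synthesize_genome(cfg)
  pr <- perturb_and_reclassify(sim$genome, sim$tads, 50000, "shrink")
  expect_equal(sum(pr$transition[, "excluded"]), 8)
})

test_that("substructure enrichment recovers a known rate ratio", {
  set.seed(204)
  # 200 TADs per class on a long virtual chromosome; B gets 3x the sub-TAD rate
  n <- 200; L <- 200000
  starts <- seq(0, by = L + 1000, length.out = 2 * n)
  tads <- data.frame(chrom = "chr1", start = starts, end = starts + L,
                     class = rep(c("B", "C"), each = n))
  rate <- ifelse(tads$class == "B", 6, 2)   # per TAD
  subs <- do.call(rbind, lapply(seq_len(2 * n), function(i) {
    k <- rpois(1, rate[i])
    if (k == 0) return(NULL)
    s <- tads$start[i] + sort(sample.int(L - 5000, k))
    data.frame(chrom = "chr1", start = s, end = s + 4000)
  }))
  res <- substructure_enrichment(tads, subs, "B", "C")
  expect_gt(res$ratio, 2.5)
  expect_lt(res$ratio, 3.5)
  expect_lt(res$p_value, 1e-6)

  # null: identical rates
  subs0 <- do.call(rbind, lapply(seq_len(2 * n), function(i) {
    k <- rpois(1, 4)
    if (k == 0) return(NULL)
    s <- tads$start[i] + sort(sample.int(L - 5000, k))
    data.frame(chrom = "chr1", start = s, end = s + 4000)
  }))
  res0 <- substructure_enrichment(tads, subs0, "B", "C")
  expect_gt(res0$p_value, 0.05)
  expect_equal(res0$ratio, 1, tolerance = 0.25)

  # degenerate: empty class b -> undefined ratio
  tads_z <- tads
  resz <- substructure_enrichment(tads_z, subs[subs$start < tads$start[n + 1], ],
                                  "B", "C")
  expect_true(resz$undefined)
  expect_true(is.na(resz$ratio))

  expect_error(substructure_enrichment(tads[c(1, n + 1, n + 2), ], subs, "B", "C"),
               "at least 2")
})
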