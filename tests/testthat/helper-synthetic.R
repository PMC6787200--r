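# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

# The standard validation suite: 600 TADs, 100 per class, mean GC uniform on
# 33-59%, amplitude 5, per-bin noise sd 1, seed 7; profiles, classification,
# PCA, and feature/hub tracks computed once and reused.
standard_suite <- function() {
  if (is.null(.fixture_cache$suite)) {
    cfg <- standard_suite_config(seed = 7)
    sim <- synthesize_genome(cfg)
    prof <- tad_profiles(sim$genome, sim$tads)
    cl <- classify_all(prof)
    pca <- fit_pca(prof, k = 3)
    set.seed(20240001)
    feats <- synthesize_features_and_expression(sim)
    gt <- windowed_gc(sim$genome, resolution = cfg$hub_resolution)
    .fixture_cache$suite <- list(cfg = cfg, sim = sim, prof = prof, cl = cl,
                                 pca = pca, feats = feats, gc_track = gt)
  }
  .fixture_cache$suite
}

# Noiseless variant of the standard suite (bin_noise_sd = 0).
noiseless_suite <- function() {
  if (is.null(.fixture_cache$noiseless)) {
    cfg <- standard_suite_config(seed = 7, bin_noise_sd = 0)
    sim <- synthesize_genome(cfg)
    prof <- tad_profiles(sim$genome, sim$tads)
    cl <- classify_all(prof)
    .fixture_cache$noiseless <- list(cfg = cfg, sim = sim, prof = prof, cl = cl)
  }
  .fixture_cache$noiseless
}

# Random GC-like profile: smooth random-walk base plus noise, values in a
# plausible GC range.
random_profile <- function(n = 100) {
  base <- cumsum(stats::rnorm(n, 0, 0.5))
  40 + 5 * (base - mean(base)) / max(1e-9, stats::sd(base)) + stats::rnorm(n, 0, 1)
}

# Independent covariance-formula Pearson correlation (sum-based, no cor()).
cov_formula_r <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Independent per-half correlations: explicit covariance formula per half,
# with the same zero-variance-is-flat convention.
oracle_half_correlations <- function(bins) {
  n <- length(bins)
  h <- n %/% 2
  one <- function(y) {
    x <- seq_along(y)
    if (stats::var(y) == 0) return(0)
    cov_formula_r(x, y)
  }
  c(one(bins[1:h]), one(bins[(h + 1):n]))
}

# Brute-force ICP by explicit double loop over a dense matrix.
oracle_icp <- function(mat, chrom_of, include_diagonal = TRUE) {
  n <- nrow(mat)
  out <- numeric(n)
  for (i in 1:n) {
    inter <- 0; total <- 0
    for (j in 1:n) {
      if (!include_diagonal && i == j) next
      total <- total + mat[i, j]
      if (chrom_of[i] != chrom_of[j]) inter <- inter + mat[i, j]
    }
    out[i] <- if (total == 0) NA_real_ else inter / total
  }
  out
}

# Random small symmetric contact matrix over 2-4 chromosomes.
random_contact_fixture <- function(max_bins = 20) {
  n_chrom <- sample(2:4, 1)
  bins_per <- sample(2:(max_bins %/% n_chrom), n_chrom, replace = TRUE)
  chrom_of <- rep(paste0("chr", seq_len(n_chrom)), bins_per)
  n <- length(chrom_of)
  m <- matrix(rpois(n * n, 3), n, n)
  m <- m + t(m)
  sizes <- stats::setNames(as.numeric(bins_per) * 1000, paste0("chr", seq_len(n_chrom)))
  bins <- genome_bins(sizes, 1000)
  list(cm = contact_matrix(m, bins, 1000), dense = m, chrom_of = chrom_of)
}

# Random DNA string of length n (ACGT only).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
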