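#' Configuration for the synthetic genome generator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' generator emulates the statistical structure the analysis assumes:
#' TADs with one of six GC-gradient shapes, mean GC spanning the isochore
#' range, a controllable GC shift between speckle and nucleolar hub bins,
#' a calibrated GC-contact coupling, class-dependent placement of genes /
#' super-enhancers / CTCF sites, and Tau-structured expression.
#'
#' @param n_chroms Number of chromosomes.
#' @param n_tads Total number of TADs to generate; chromosomes are sized to
#'   fit them. Alternatively set `chrom_length` and leave `n_tads = NULL`
#'   to tile fixed-length chromosomes.
#' @param chrom_length Chromosome length in bp (used when `n_tads` is
#'   `NULL`).
#' @param tad_length_range Min/max TAD length in bp; drawn uniformly and
#'   rounded to a multiple of `n_bins` so profile bins are equal-length.
#' @param class_mix Named proportions over the six gradient classes;
#'   must sum to 1. Classes are allotted exactly per mix up to rounding.
#' @param mean_gc_range Per-TAD mean GC% drawn uniformly from this range
#'   (default 33-59, the span of the five isochore families).
#' @param gradient_amplitude Peak-to-edge span of the GC gradient in GC
#'   percentage points (default 5).
#' @param bin_noise_sd Per-bin Gaussian noise on the target GC%, in
#'   percentage points (default 1).
#' @param hub_gc_shift Target difference (speckle minus nucleolar) of hub
#'   bin mean GC%, in percentage points.
#' @param icp_gc_coupling Target Pearson correlation between per-bin ICP
#'   and GC%, in `[0, 1]`.
#' @param n_bins Profile bins per TAD (default 100).
#' @param gap_length Inter-TAD gap in bp, filled with background sequence.
#' @param background_gc GC% of inter-TAD gaps (default 40).
#' @param hub_resolution Bin size for the hub track and contact matrix, bp.
#' @param n_tissues Number of tissues in the expression table (default 27).
#' @param seed Integer seed; a fixed seed makes every output reproducible.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chroms = 4L,
                             n_tads = NULL,
                             chrom_length = NULL,
                             tad_length_range = c(10000L, 30000L),
                             class_mix = NULL,
                             mean_gc_range = c(33, 59),
                             gradient_amplitude = 5,
                             bin_noise_sd = 1,
                             hub_gc_shift = 5,
                             icp_gc_coupling = 0.6,
                             n_bins = 100L,
                             gap_length = 2000L,
                             background_gc = 40,
                             hub_resolution = 1e6,
                             n_tissues = 27L,
                             seed = 7L) {
  if (is.null(class_mix))
    class_mix <- stats::setNames(rep(1 / 6, 6), gradient_classes())
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% gradient_classes()))
    stop("unknown class in class_mix: ",
         setdiff(names(class_mix), gradient_classes())[1L])
  if (mean_gc_range[1] <= 0 || mean_gc_range[2] >= 100 ||
      mean_gc_range[1] > mean_gc_range[2])
    stop("mean_gc_range must be within (0, 100)")
  if (icp_gc_coupling < 0 || icp_gc_coupling > 1)
    stop("icp_gc_coupling must be in [0, 1]")
  if (is.null(n_tads) && is.null(chrom_length))
    stop("provide either n_tads or chrom_length")
  stopifnot(gradient_amplitude >= 0, bin_noise_sd >= 0, n_bins >= 4,
            tad_length_range[1] >= 2 * n_bins,
            tad_length_range[1] <= tad_length_range[2])
  structure(list(n_chroms = as.integer(n_chroms), n_tads = n_tads,
                 chrom_length = chrom_length,
                 tad_length_range = tad_length_range, class_mix = class_mix,
                 mean_gc_range = mean_gc_range,
                 gradient_amplitude = gradient_amplitude,
                 bin_noise_sd = bin_noise_sd, hub_gc_shift = hub_gc_shift,
                 icp_gc_coupling = icp_gc_coupling, n_bins = as.integer(n_bins),
                 gap_length = as.integer(gap_length),
                 background_gc = background_gc,
                 hub_resolution = hub_resolution,
                 n_tissues = as.integer(n_tissues), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Target GC profile for a gradient class
#'
#' Builds the noiseless per-bin target GC% profile of one TAD. Shapes:
#' `A` a linear ramp (random sign) spanning `amplitude`; `B` a symmetric
#' triangle peaking at the central bins; `C` the inverted triangle;
#' `Bminus` a ramp over one random half up to a high plateau covering the
#' other half; `Cminus` the mirror with a low interior plateau; `D` flat at
#' `mean_gc`. Every profile is centered so its mean equals `mean_gc`.
#' Random choices (ramp sign, which half ramps) use the current RNG state.
#'
#' @param true_class One of [gradient_classes()].
#' @param n_bins Number of bins (>= 4).
#' @param mean_gc Target mean GC%.
#' @param amplitude Gradient span in GC percentage points (>= 0).
#' @return Numeric vector of length `n_bins`.
#' @export
make_gc_target_profile <- function(true_class, n_bins = 100L, mean_gc = 45,
                                   amplitude = 5) {
  stopifnot(n_bins >= 4L, amplitude >= 0)
  half <- n_bins %/% 2L
  shape <- switch(true_class,
    A = {
      sgn <- if (stats::runif(1) < 0.5) 1 else -1
      sgn * seq(-0.5, 0.5, length.out = n_bins)
    },
    B = {
      u <- abs(seq_len(n_bins) - (n_bins + 1) / 2)
      1 - u / max(u)
    },
    C = {
      u <- abs(seq_len(n_bins) - (n_bins + 1) / 2)
      u / max(u) - 1
    },
    Bminus = {
      ramp_first <- stats::runif(1) < 0.5
      s <- c(seq(0, 1, length.out = half), rep(1, n_bins - half))
      if (ramp_first) s else rev(s)
    },
    Cminus = {
      ramp_first <- stats::runif(1) < 0.5
      s <- c(seq(1, 0, length.out = half), rep(0, n_bins - half))
      if (ramp_first) s else rev(s)
    },
    D = rep(0, n_bins),
    stop("unknown gradient class: ", true_class)
  )
  mean_gc + amplitude * (shape - mean(shape))
}

# Allot exactly n classes according to mix (largest remainder), shuffled.
.allot_classes <- function(n, mix) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(names(mix), times = base))
}

# Exact-count bin sequence: realized bin GC equals the drawn per-bin target
# up to integer rounding, so bin_noise_sd is the single noise dial.
.bin_sequence <- function(bin_len, gc_frac) {
  n_gc <- round(bin_len * gc_frac)
  is_gc <- logical(bin_len)
  if (n_gc > 0) is_gc[sample.int(bin_len, n_gc)] <- TRUE
  b <- integer(bin_len)
  b[is_gc] <- ifelse(stats::runif(n_gc) < 0.5, 3L, 2L)        # G / C
  b[!is_gc] <- ifelse(stats::runif(bin_len - n_gc) < 0.5, 1L, 4L)  # A / T
  b
}

#' Synthesize a toy genome with GC-gradient TADs
#'
#' Generates chromosome sequences tiled by TADs whose 100-bin GC profiles
#' follow known gradient classes. TAD lengths are uniform on
#' `tad_length_range` (rounded to a multiple of `n_bins` so bins are
#' equal-length); classes are allotted exactly per `class_mix`; each TAD
#' gets a mean GC% uniform on `mean_gc_range` and a target profile from
#' [make_gc_target_profile()]. Per bin, the realized GC fraction is the
#' target plus `Normal(0, bin_noise_sd)` (clamped to 5-95%), and the bin
#' sequence contains exactly that count of G/C bases in random order, so
#' the realized profile tracks the target with `bin_noise_sd` as the only
#' noise source. Inter-TAD gaps are background sequence at `background_gc`.
#' All randomness derives from `config$seed`; a fixed seed reproduces the
#' genome bit-for-bit.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_genome`: `genome` (`DNAStringSet`),
#'   `tads` (data frame `chrom`, `start`, `end`, `name`), `truth` (data
#'   frame with `tad_id`, `true_class`, `true_mean_gc`, `true_family`, and
#'   the target profile matrix as attribute `target_profile`), `config`.
#' @export
synthesize_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_bins <- config$n_bins
  gap <- config$gap_length
  rlen <- function(k) {
    L <- stats::runif(k, config$tad_length_range[1], config$tad_length_range[2])
    pmax(n_bins, round(L / n_bins)) * n_bins
  }
  # plan TADs per chromosome
  plan <- vector("list", config$n_chroms)
  if (!is.null(config$n_tads)) {
    lens <- rlen(config$n_tads)
    chrom_of <- sort(rep_len(seq_len(config$n_chroms), config$n_tads))
    for (c_i in seq_len(config$n_chroms)) plan[[c_i]] <- lens[chrom_of == c_i]
  } else {
    for (c_i in seq_len(config$n_chroms)) {
      lens <- numeric(0)
      used <- gap
      repeat {
        L <- rlen(1L)
        if (used + L + gap > config$chrom_length) break
        lens <- c(lens, L)
        used <- used + L + gap
      }
      if (length(lens) == 0L)
        stop("infeasible tiling: chromosome too short for tad_length_range")
      plan[[c_i]] <- lens
    }
  }
  n_tads <- sum(lengths(plan))
  classes <- .allot_classes(n_tads, config$class_mix)
  mean_gcs <- stats::runif(n_tads, config$mean_gc_range[1], config$mean_gc_range[2])

  seqs <- vector("list", config$n_chroms)
  tad_rows <- vector("list", n_tads)
  targets <- matrix(NA_real_, n_tads, n_bins)
  k <- 0L
  lv <- c("A", "C", "G", "T")
  for (c_i in seq_len(config$n_chroms)) {
    lens <- plan[[c_i]]
    chrom_len <- if (!is.null(config$chrom_length)) config$chrom_length else
      sum(lens) + gap * (length(lens) + 1L)
    codes <- integer(chrom_len)
    pos <- 0L
    for (t_i in seq_along(lens)) {
      # leading gap
      codes[(pos + 1L):(pos + gap)] <-
        ifelse(stats::runif(gap) < config$background_gc / 100,
               ifelse(stats::runif(gap) < 0.5, 3L, 2L),
               ifelse(stats::runif(gap) < 0.5, 1L, 4L))
      pos <- pos + gap
      k <- k + 1L
      L <- lens[t_i]
      bin_len <- L %/% n_bins
      target <- make_gc_target_profile(classes[k], n_bins, mean_gcs[k],
                                       config$gradient_amplitude)
      targets[k, ] <- target
      q <- (target + stats::rnorm(n_bins, 0, config$bin_noise_sd)) / 100
      q <- pmin(pmax(q, 0.05), 0.95)
      for (b in seq_len(n_bins)) {
        codes[(pos + 1L):(pos + bin_len)] <- .bin_sequence(bin_len, q[b])
        pos <- pos + bin_len
      }
      tad_rows[[k]] <- data.frame(chrom = paste0("chr", c_i),
                                  start = pos - L, end = pos,
                                  name = sprintf("tad_%04d", k),
                                  stringsAsFactors = FALSE)
    }
    # trailing fill to chromosome end
    if (pos < chrom_len) {
      nfill <- chrom_len - pos
      codes[(pos + 1L):chrom_len] <-
        ifelse(stats::runif(nfill) < config$background_gc / 100,
               ifelse(stats::runif(nfill) < 0.5, 3L, 2L),
               ifelse(stats::runif(nfill) < 0.5, 1L, 4L))
    }
    seqs[[c_i]] <- paste(lv[codes], collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- paste0("chr", seq_len(config$n_chroms))
  tads <- do.call(rbind, tad_rows)
  truth <- data.frame(tad_id = tads$name, chrom = tads$chrom,
                      start = tads$start, end = tads$end,
                      true_class = classes, true_mean_gc = mean_gcs,
                      true_family = assign_family(mean_gcs),
                      stringsAsFactors = FALSE)
  attr(truth, "target_profile") <- targets
  structure(list(genome = genome, tads = tads, truth = truth, config = config),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d chromosomes (%.1f Mb), %d TADs\n",
              length(x$genome), sum(Biostrings::width(x$genome)) / 1e6,
              nrow(x$tads)))
  print(table(x$truth$true_class))
  invisible(x)
}

#' Synthesize a contact matrix with calibrated GC-ICP coupling
#'
#' Builds a Poisson-sampled symmetric contact matrix over the bins of a GC
#' track such that the Pearson correlation between the measured per-bin ICP
#' and GC% hits `config$icp_gc_coupling` (within about 0.05). Each bin's
#' interchromosomal propensity is `logistic(alpha + beta * gc + noise)`;
#' `beta` is calibrated by bisection against the realized correlation, with
#' the candidate matrices rebuilt from a fixed internal sub-seed so the
#' calibration target is a deterministic function of `beta`. A coupling of
#' 0 sets `beta = 0`.
#'
#' @param gc_track Windowed GC track (data frame from [windowed_gc()]);
#'   needs at least 2 chromosomes and >= 10 unmasked bins.
#' @param config A [synthetic_config()]; uses `icp_gc_coupling`.
#' @param mean_icp Target mean ICP level (default 0.35).
#' @param total_per_bin Expected total contacts per bin (default 2000).
#' @param n_partners Interaction partners sampled per bin per side
#'   (default 40; larger values reduce the partner-sampling noise that
#'   attenuates the achievable coupling).
#' @return A [contact_matrix()] over the unmasked bins of `gc_track`.
#' @export
synthesize_contacts <- function(gc_track, config, mean_icp = 0.35,
                                total_per_bin = 2000, n_partners = 40L) {
  stopifnot(inherits(config, "synthetic_config"))
  rho <- config$icp_gc_coupling
  if (rho < 0 || rho > 1) stop("icp_gc_coupling must be in [0, 1]")
  keep <- !is.na(gc_track$gc)
  g <- gc_track$gc[keep]
  chrom <- gc_track$chrom[keep]
  if (length(unique(chrom)) < 2L)
    stop("need at least 2 chromosomes for interchromosomal contacts")
  if (length(g) < 10L) stop("too few unmasked bins")
  n <- length(g)
  bins <- data.frame(chrom = chrom, start = gc_track$start[keep],
                     end = gc_track$end[keep], bin = seq_len(n))
  bin_size <- max(gc_track$end - gc_track$start)
  gs <- (g - mean(g)) / stats::sd(g)
  sub_seed <- sample.int(.Machine$integer.max, 1L)

  build <- function(beta) {
    set.seed(sub_seed)
    eps <- stats::rnorm(n, 0, 0.3)
    t_i <- stats::plogis(stats::qlogis(mean_icp) + beta * gs + eps)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    other <- lapply(unique(chrom), function(ch) which(chrom != ch))
    same <- lapply(unique(chrom), function(ch) which(chrom == ch))
    names(other) <- names(same) <- unique(chrom)
    for (i in seq_len(n)) {
      po <- other[[chrom[i]]]
      ps <- same[[chrom[i]]]
      ko <- min(n_partners, length(po))
      ks <- min(n_partners, length(ps))
      jo <- if (ko > 0) po[sample.int(length(po), ko)] else integer(0)
      js <- ps[sample.int(length(ps), ks)]
      co <- stats::rpois(ko, total_per_bin * t_i[i] / max(ko, 1L))
      cs <- stats::rpois(ks, total_per_bin * (1 - t_i[i]) / max(ks, 1L))
      ii <- c(ii, rep.int(i, ko + ks)); jj <- c(jj, jo, js); xx <- c(xx, co, cs)
    }
    lo <- pmin(ii, jj); hi <- pmax(ii, jj)
    up <- Matrix::sparseMatrix(i = lo, j = hi, x = xx, dims = c(n, n))
    full <- up + Matrix::t(up)
    Matrix::diag(full) <- Matrix::diag(up)
    contact_matrix(full, bins, bin_size)
  }
  measure <- function(cm) {
    icp <- compute_icp(cm)
    ok <- !is.na(icp$icp)
    stats::cor(g[ok], icp$icp[ok])
  }
  if (rho == 0) return(build(0))
  lo_b <- 0; hi_b <- 8
  cm <- NULL
  for (it in seq_len(25L)) {
    mid <- (lo_b + hi_b) / 2
    cm <- build(mid)
    r <- measure(cm)
    if (abs(r - rho) < 0.02) break
    if (r < rho) lo_b <- mid else hi_b <- mid
  }
  cm
}

# Greedy label assignment on sorted GC values: start from a random balanced
# split (difference ~ 0) and swap extreme members across groups until the
# speckle-minus-nucleolar mean GC difference reaches the target.
.assign_hub_labels <- function(gc, shift, tol = 0.1) {
  n <- length(gc)
  speckle <- sample.int(n, n %/% 2L)
  is_sp <- seq_len(n) %in% speckle
  diff_of <- function(sp) mean(gc[sp]) - mean(gc[!sp])
  d <- diff_of(is_sp)
  repeat {
    if (abs(d - shift) <= tol || d >= shift) break
    cand_out <- which(is_sp)[which.min(gc[is_sp])]   # lowest-GC speckle bin
    cand_in <- which(!is_sp)[which.max(gc[!is_sp])]  # highest-GC nucleolar bin
    if (gc[cand_in] <= gc[cand_out]) break           # no swap can increase diff
    new_sp <- is_sp
    new_sp[cand_out] <- FALSE; new_sp[cand_in] <- TRUE
    d_new <- diff_of(new_sp)
    if (abs(d_new - shift) >= abs(d - shift)) break  # past the target
    is_sp <- new_sp; d <- d_new
  }
  ifelse(is_sp, "speckle", "nucleolar")
}

#' Synthesize feature tracks, expression and hub labels
#'
#' Given a synthetic genome, generates: gene / super-enhancer / CTCF
#' interval tracks with class-dependent positional biases (border-biased
#' `Beta(0.5, 0.5)` midpoints in valley-class TADs for genes and CTCF;
#' centre-biased `Beta(4, 4)` super-enhancers in bell-class TADs; uniform
#' otherwise) and per-100-kb rates increasing from L1 to H3 families; a
#' gene-by-tissue TPM table in which housekeeping genes get near-uniform
#' expression (target Tau < 0.3), tissue-specific genes one-tissue-dominated
#' expression (target Tau > 0.8) and intermediate genes graded expression;
#' and a hub track whose speckle bins exceed nucleolar bins in mean GC% by
#' `config$hub_gc_shift` (greedy assignment on the windowed GC track at
#' `config$hub_resolution`). Housekeeping genes are placed at a higher rate
#' in bell-class than valley-class TADs. Uses the current RNG state; seed
#' via `set.seed()` (or use [synthesize_all()]).
#'
#' @param sim A `synthetic_genome` from [synthesize_genome()].
#' @param gene_rates,se_rates,ctcf_rates Named per-family rates
#'   (features per 100 kb, names L1..H3), increasing by default.
#' @param hk_prob_by_class Named probability that a gene is housekeeping,
#'   by gradient class group (`bell`, `valley`, `other`).
#' @param ts_prob Probability that a non-housekeeping gene is
#'   tissue-specific rather than intermediate.
#' @return List of class `synthetic_features`: `genes`, `super_enhancers`,
#'   `ctcf` (BED-like data frames), `expression` (TPM matrix), `gene_truth`
#'   (data frame `gene_id`, `tad_id`, `true_tau_class`), `hubs` (data frame
#'   `chrom`, `start`, `end`, `label`).
#' @export
synthesize_features_and_expression <- function(sim,
    gene_rates = c(L1 = 0.5, L2 = 1.2, H1 = 2.2, H2 = 3.5, H3 = 5),
    se_rates = c(L1 = 0.2, L2 = 0.5, H1 = 0.9, H2 = 1.4, H3 = 2),
    ctcf_rates = c(L1 = 1, L2 = 2.2, H1 = 3.6, H2 = 5.2, H3 = 7),
    hk_prob_by_class = c(bell = 0.45, valley = 0.25, other = 0.35),
    ts_prob = 0.3) {
  stopifnot(inherits(sim, "synthetic_genome"))
  truth <- sim$truth
  config <- sim$config
  n_tads <- nrow(truth)
  group_of <- function(cl) ifelse(cl %in% c("B", "Bminus"), "bell",
                           ifelse(cl %in% c("C", "Cminus"), "valley", "other"))

  draw_midpoints <- function(k, cl, kind) {
    grp <- group_of(cl)
    if (kind %in% c("gene", "ctcf") && grp == "valley")
      stats::rbeta(k, 0.5, 0.5)
    else if (kind == "super_enhancer" && grp == "bell")
      stats::rbeta(k, 4, 4)
    else stats::runif(k)
  }
  place <- function(kind, rates, len_frac_range) {
    rows <- list(); tad_of <- integer(0)
    for (t_i in seq_len(n_tads)) {
      L <- truth$end[t_i] - truth$start[t_i]
      lam <- rates[[truth$true_family[t_i]]] * L / 1e5
      k <- stats::rpois(1L, lam)
      if (k == 0L) next
      flen <- if (is.null(len_frac_range)) rep(20L, k) else
        pmax(10L, round(stats::runif(k, len_frac_range[1], len_frac_range[2]) * L))
      half <- flen / (2 * L)
      m <- half + draw_midpoints(k, truth$true_class[t_i], kind) * (1 - 2 * half)
      start <- truth$start[t_i] + round(m * L - flen / 2)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = truth$chrom[t_i], start = start, end = start + flen,
                   stringsAsFactors = FALSE)
      tad_of <- c(tad_of, rep.int(t_i, k))
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    df$name <- sprintf("%s_%05d", kind, seq_len(nrow(df)))
    attr(df, "tad_index") <- tad_of
    df
  }

  genes <- place("gene", gene_rates, c(0.02, 0.05))
  ses <- place("super_enhancer", se_rates, c(0.01, 0.03))
  ctcf <- place("ctcf", ctcf_rates, NULL)

  # expression with Tau structure
  n_genes <- nrow(genes)
  tad_of_gene <- attr(genes, "tad_index")
  grp <- group_of(truth$true_class[tad_of_gene])
  p_hk <- hk_prob_by_class[grp]
  u <- stats::runif(n_genes)
  tau_class <- ifelse(u < p_hk, "housekeeping",
                      ifelse(u < p_hk + (1 - p_hk) * ts_prob,
                             "tissue_specific", "intermediate"))
  nt <- config$n_tissues
  tpm <- matrix(0, n_genes, nt,
                dimnames = list(genes$name, sprintf("tissue_%02d", seq_len(nt))))
  for (i in seq_len(n_genes)) {
    tpm[i, ] <- switch(tau_class[i],
      housekeeping = {
        base <- 2^stats::rnorm(1, 5, 1)
        base * 2^stats::rnorm(nt, 0, 0.25)
      },
      tissue_specific = {
        v <- stats::runif(nt, 0, 0.5)
        v[sample.int(nt, 1L)] <- 2^stats::runif(1, 7, 10)
        v
      },
      intermediate = {
        xmax <- stats::runif(1, 4, 8)
        2^(xmax * stats::runif(nt, 0.2, 0.8)) - 1
      })
  }
  gene_truth <- data.frame(gene_id = genes$name,
                           tad_id = truth$tad_id[tad_of_gene],
                           tad_class = truth$true_class[tad_of_gene],
                           true_tau_class = tau_class,
                           stringsAsFactors = FALSE)

  # hub labels on the windowed GC track
  gt <- windowed_gc(sim$genome, resolution = config$hub_resolution)
  ok <- !is.na(gt$gc)
  label <- rep("unassigned", nrow(gt))
  label[ok] <- .assign_hub_labels(gt$gc[ok], config$hub_gc_shift)
  hubs <- data.frame(chrom = gt$chrom, start = gt$start, end = gt$end,
                     label = label, stringsAsFactors = FALSE)

  structure(list(genes = genes, super_enhancers = ses, ctcf = ctcf,
                 expression = tpm, gene_truth = gene_truth, hubs = hubs),
            class = "synthetic_features")
}

#' One-call synthetic data set
#'
#' Runs [synthesize_genome()], [synthesize_features_and_expression()] and
#' [synthesize_contacts()] (on the windowed GC track at
#' `config$hub_resolution`) under a single seed.
#'
#' @param config A [synthetic_config()].
#' @param contacts Also build the contact matrix (default `TRUE`).
#' @return List of class `synthetic_dataset`: `genome` (the
#'   `synthetic_genome`), `features` (the `synthetic_features`), `gc_track`
#'   (windowed GC at `hub_resolution`), `contacts` (a `contact_matrix` or
#'   `NULL`).
#' @export
synthesize_all <- function(config, contacts = TRUE) {
  sim <- synthesize_genome(config)
  feats <- synthesize_features_and_expression(sim)
  gt <- windowed_gc(sim$genome, resolution = config$hub_resolution)
  cm <- if (contacts) synthesize_contacts(gt, config) else NULL
  structure(list(genome = sim, features = feats, gc_track = gt, contacts = cm),
            class = "synthetic_dataset")
}

#' Standard synthetic validation suite
#'
#' The fixed conditions used throughout the package's validation: 600 TADs
#' (100 per gradient class), per-TAD mean GC uniform on 33-59%, gradient
#' amplitude 5 GC points, per-bin noise sd 1 GC point, TAD lengths
#' 10-30 kb over 6 chromosomes.
#'
#' @param seed Integer seed (default 7).
#' @param bin_noise_sd Per-bin noise sd (default 1; 0 gives the noiseless
#'   variant).
#' @return A [synthetic_config()].
#' @export
standard_suite_config <- function(seed = 7L, bin_noise_sd = 1) {
  synthetic_config(n_chroms = 6L, n_tads = 600L,
                   tad_length_range = c(10000L, 30000L),
                   mean_gc_range = c(33, 59), gradient_amplitude = 5,
                   bin_noise_sd = bin_noise_sd, hub_gc_shift = 5,
                   icp_gc_coupling = 0.6, hub_resolution = 50000,
                   seed = seed)
}

#' Write a synthetic data set to standard-format files
#'
#' Emits FASTA (genome), BED (TADs, genes, super-enhancers, CTCF, hub
#' labels), a sparse triplet contact TSV, the expression TSV, and the truth
#' tables as TSV.
#'
#' @param ds A `synthetic_dataset` from [synthesize_all()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(genome = p("genome.fa"), tads = p("tads.bed"),
             genes = p("genes.bed"), super_enhancers = p("super_enhancers.bed"),
             ctcf = p("ctcf.bed"), hubs = p("hubs.bed"),
             expression = p("expression.tsv"), contacts = p("contacts.tsv"),
             tad_truth = p("tad_truth.tsv"), gene_truth = p("gene_truth.tsv"))
  write_genome_fasta(ds$genome$genome, paths["genome"])
  write_bed(ds$genome$tads, paths["tads"])
  write_bed(ds$features$genes, paths["genes"])
  write_bed(ds$features$super_enhancers, paths["super_enhancers"])
  write_bed(ds$features$ctcf, paths["ctcf"])
  write_bed(ds$features$hubs, paths["hubs"])
  write_expression_table(ds$features$expression, paths["expression"])
  if (!is.null(ds$contacts)) {
    cm <- ds$contacts
    tri <- methods::as(Matrix::triu(cm$counts), "TsparseMatrix")
    bi <- tri@i + 1L; bj <- tri@j + 1L
    # chrom/position triplets keep bin identity independent of bin numbering
    utils::write.table(
      data.frame(cm$bins$chrom[bi],
                 format(cm$bins$start[bi], scientific = FALSE, trim = TRUE),
                 cm$bins$chrom[bj],
                 format(cm$bins$start[bj], scientific = FALSE, trim = TRUE),
                 tri@x),
      paths["contacts"], sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(ds$genome$truth, paths["tad_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$features$gene_truth, paths["gene_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
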