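#' Relative positions of features within TADs
#'
#' Assigns each feature to a TAD only when the feature is fully contained
#' (`feature.start >= tad.start` and `feature.end <= tad.end`); features
#' spanning a TAD border or outside every TAD are dropped and counted. The
#' relative position is an index from 0.0 to 1.0: the feature midpoint minus
#' the TAD start, divided by the TAD length, so values near 0 or 1 mean the
#' feature sits close to a border and values around 0.5 near the centre.
#' With overlapping/nested TAD calls, the smallest containing TAD wins
#' (leftmost on ties). An auxiliary `band` column marks border
#' (0-0.2, 0.8-1.0) versus centre (0.3-0.7) positions.
#'
#' @param tads Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `name`.
#' @param features Data frame with `chrom`, `start`, `end`, optional `name`
#'   and `kind`.
#' @return List: `records` (data frame `feature_id`, `tad_id`, `rel_pos`,
#'   `kind`, `band`), `n_assigned`, `n_boundary_dropped` (overlap a TAD but
#'   extend beyond it), `n_outside` (no overlap with any TAD).
#' @export
relative_positions <- function(tads, features) {
  tid <- if ("name" %in% names(tads)) as.character(tads$name) else
    sprintf("tad_%04d", seq_len(nrow(tads)))
  fid <- if ("name" %in% names(features)) as.character(features$name) else
    sprintf("feat_%05d", seq_len(nrow(features)))
  kind <- if ("kind" %in% names(features)) as.character(features$kind) else
    rep(NA_character_, nrow(features))
  gr_t <- GenomicRanges::GRanges(tads$chrom,
                                 IRanges::IRanges(tads$start + 1L, tads$end))
  gr_f <- GenomicRanges::GRanges(features$chrom,
                                 IRanges::IRanges(features$start + 1L, features$end))
  within <- GenomicRanges::findOverlaps(gr_f, gr_t, type = "within")
  any_ov <- GenomicRanges::findOverlaps(gr_f, gr_t)
  qh <- S4Vectors::queryHits(within)
  sh <- S4Vectors::subjectHits(within)
  # smallest containing TAD wins; order guarantees leftmost wins ties
  tlen <- tads$end - tads$start
  ord <- order(qh, tlen[sh], tads$start[sh])
  qh <- qh[ord]; sh <- sh[ord]
  first <- !duplicated(qh)
  fi <- qh[first]; ti <- sh[first]
  mid <- (features$start[fi] + features$end[fi]) / 2
  rel <- (mid - tads$start[ti]) / tlen[ti]
  band <- ifelse(rel <= 0.2 | rel >= 0.8, "border",
                 ifelse(rel >= 0.3 & rel <= 0.7, "centre", "intermediate"))
  records <- data.frame(feature_id = fid[fi], tad_id = tid[ti], rel_pos = rel,
                        kind = kind[fi], band = band, stringsAsFactors = FALSE)
  overlapping <- unique(S4Vectors::queryHits(any_ov))
  contained <- unique(S4Vectors::queryHits(within))
  list(records = records,
       n_assigned = length(contained),
       n_boundary_dropped = length(setdiff(overlapping, contained)),
       n_outside = nrow(features) - length(overlapping))
}

#' Positional density of features over the TAD unit interval
#'
#' Histogram (default 20 bins over `[0, 1]`) and, when at least 10 records
#' are available, a Gaussian kernel density estimate with reflective
#' boundary correction at 0 and 1 (the data are mirrored about both ends so
#' the estimate integrates to ~1 on `[0, 1]`); bandwidth by Silverman's
#' rule on the original data. The density value at the 75% position is
#' reported as a border-shift marker.
#'
#' @param rel_pos Numeric vector of relative positions in `[0, 1]` (e.g.
#'   `records$rel_pos` from [relative_positions()]).
#' @param n_position_bins Histogram bins (default 20).
#' @param n_grid KDE evaluation grid size (default 512).
#' @return List: `histogram` (data frame `bin_start`, `bin_end`, `count`,
#'   `density`), `kde` (data frame `x`, `density`, or `NULL` if < 10
#'   records), `marker_75` (KDE density at x = 0.75, `NA` without KDE),
#'   `n`.
#' @export
positional_density <- function(rel_pos, n_position_bins = 20L, n_grid = 512L) {
  rel_pos <- rel_pos[!is.na(rel_pos)]
  n <- length(rel_pos)
  if (n == 0L) {
    warning("no records; empty positional density")
    return(list(histogram = data.frame(), kde = NULL, marker_75 = NA_real_, n = 0L))
  }
  stopifnot(all(rel_pos >= 0 & rel_pos <= 1))
  brk <- seq(0, 1, length.out = n_position_bins + 1L)
  h <- graphics::hist(rel_pos, breaks = brk, plot = FALSE, include.lowest = TRUE)
  hist_df <- data.frame(bin_start = brk[-length(brk)], bin_end = brk[-1L],
                        count = h$counts, density = h$density)
  kde <- NULL; marker <- NA_real_
  if (n >= 10L) {
    bw <- stats::bw.nrd0(rel_pos)
    aug <- c(rel_pos, -rel_pos, 2 - rel_pos)
    d <- stats::density(aug, bw = bw, n = n_grid, from = 0, to = 1)
    kde <- data.frame(x = d$x, density = 3 * d$y)
    marker <- 3 * stats::density(aug, bw = bw, n = 1L, from = 0.75, to = 0.75)$y
  }
  list(histogram = hist_df, kde = kde, marker_75 = marker, n = n)
}

#' Tissue-specificity index Tau
#'
#' `Tau = sum_i (1 - x_hat_i) / (N - 1)` where `x_hat_i = x_i / max_i x_i`
#' over the N tissues. By default expression is transformed as
#' `x = log2(TPM + 1)` before the index is computed (`transform = "log2"`),
#' the established practice for RNA-seq; `transform = "raw"` uses TPM
#' directly. Tau is 0 for a gene expressed identically in every tissue
#' (housekeeping limit) and 1 for expression confined to a single tissue.
#' All-zero rows are undefined (`NA`).
#'
#' @param tpm Numeric vector of TPM values across tissues (N >= 2), or a
#'   genes x tissues matrix (row-wise computation).
#' @param transform `"log2"` (default) or `"raw"`.
#' @return Numeric Tau in `[0, 1]` (vector for matrix input), `NA` for
#'   all-zero rows.
#' @export
tau <- function(tpm, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  if (is.matrix(tpm)) return(apply(tpm, 1L, tau, transform = transform))
  if (length(tpm) < 2L) stop("Tau needs at least 2 tissues")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (all(tpm == 0)) return(NA_real_)
  x <- if (transform == "log2") log2(tpm + 1) else tpm
  xhat <- x / max(x)
  sum(1 - xhat) / (length(x) - 1L)
}

#' Stratify genes into housekeeping / tissue-specific / intermediate
#'
#' Computes Tau per gene and classifies with strict cut-points: Tau below
#' `thresholds[1]` (default 0.3) is housekeeping, Tau above `thresholds[2]`
#' (default 0.8) is tissue-specific, anything else (including Tau exactly at
#' a cut-point) is intermediate. Also reports the arithmetic mean TPM across
#' tissues and its log10. Genes with undefined Tau (all-zero rows) are
#' excluded and reported.
#'
#' @param tpm Genes x tissues TPM matrix with rownames
#'   (e.g. [read_expression_table()]).
#' @param thresholds Length-2 numeric, housekeeping / tissue-specific cuts.
#' @param transform Tau transform, see [tau()].
#' @return List: `genes` (data frame `gene_id`, `tau`, `expression_class`,
#'   `mean_tpm`, `log10_mean_tpm`), `excluded` (ids with undefined Tau).
#' @export
stratify_genes <- function(tpm, thresholds = c(0.3, 0.8),
                           transform = c("log2", "raw")) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  tv <- tau(tpm, transform = match.arg(transform))
  mean_tpm <- rowMeans(tpm)
  cls <- ifelse(tv < thresholds[1], "housekeeping",
                ifelse(tv > thresholds[2], "tissue_specific", "intermediate"))
  genes <- data.frame(gene_id = rownames(tpm), tau = tv,
                      expression_class = cls, mean_tpm = mean_tpm,
                      log10_mean_tpm = ifelse(mean_tpm > 0, log10(mean_tpm), NA_real_),
                      stringsAsFactors = FALSE, row.names = NULL)
  excluded <- genes$gene_id[is.na(genes$tau)]
  list(genes = genes[!is.na(genes$tau), , drop = FALSE], excluded = excluded)
}

#' Per-100-kb feature densities by isochore family
#'
#' For each isochore family: the number of fully contained features of each
#' kind per 100 kb of family TAD length, the mean log10(mean TPM) of
#' contained genes, and the family's share of total TAD length.
#'
#' @param tads Data frame with `chrom`, `start`, `end`, `family` (and
#'   optional `name`).
#' @param feature_sets Named list of feature data frames (`chrom`, `start`,
#'   `end`, optional `name`), e.g.
#'   `list(gene = ..., super_enhancer = ..., ctcf = ...)`.
#' @param gene_classes Optional `genes` data frame from [stratify_genes()];
#'   when given (and a `gene` feature set with `name` ids is present), mean
#'   log10(mean TPM) is summarized per family.
#' @return Data frame, one row per family present: `family`, `total_length`,
#'   `length_share`, `<kind>_per_100kb` columns, and `mean_log10_tpm` when
#'   expression is supplied.
#' @export
family_density_table <- function(tads, feature_sets, gene_classes = NULL) {
  stopifnot("family" %in% names(tads))
  fams <- intersect(c("L1", "L2", "H1", "H2", "H3"), unique(tads$family))
  tlen <- tads$end - tads$start
  gr_t <- GenomicRanges::GRanges(tads$chrom,
                                 IRanges::IRanges(tads$start + 1L, tads$end))
  out <- data.frame(family = fams,
                    total_length = vapply(fams, function(f)
                      sum(tlen[tads$family == f & !is.na(tads$family)]), numeric(1)))
  out$length_share <- out$total_length / sum(tlen, na.rm = TRUE)
  for (kind in names(feature_sets)) {
    fs <- feature_sets[[kind]]
    gr_f <- GenomicRanges::GRanges(fs$chrom,
                                   IRanges::IRanges(fs$start + 1L, fs$end))
    hits <- GenomicRanges::findOverlaps(gr_f, gr_t, type = "within")
    fam_of_hit <- tads$family[S4Vectors::subjectHits(hits)]
    cnt <- vapply(fams, function(f)
      sum(fam_of_hit == f, na.rm = TRUE), numeric(1))
    out[[paste0(kind, "_per_100kb")]] <-
      ifelse(out$total_length > 0, cnt / (out$total_length / 1e5), NA_real_)
    if (kind == "gene" && !is.null(gene_classes)) {
      gid <- if ("name" %in% names(fs)) as.character(fs$name) else NULL
      if (!is.null(gid)) {
        lt <- gene_classes$log10_mean_tpm[match(gid[S4Vectors::queryHits(hits)],
                                                gene_classes$gene_id)]
        out$mean_log10_tpm <- vapply(fams, function(f)
          mean(lt[fam_of_hit == f], na.rm = TRUE), numeric(1))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Housekeeping-gene density comparison between two TAD classes
#'
#' Per-TAD density (per 100 kb) of fully contained housekeeping genes,
#' compared between two gradient classes with a two-sided Wilcoxon rank-sum
#' test.
#'
#' @param tads Data frame with `chrom`, `start`, `end`, `class` and optional
#'   `name`.
#' @param genes Gene intervals (`chrom`, `start`, `end`, `name` = gene id).
#' @param gene_classes `genes` data frame from [stratify_genes()].
#' @param class_a,class_b Gradient classes to compare (default B vs C).
#' @param expression_class Which expression class to count
#'   (default `"housekeeping"`).
#' @return List: `densities` (per-TAD table), `medians` (named, per class),
#'   `w_statistic`, `p_value`.
#' @export
class_expression_comparison <- function(tads, genes, gene_classes,
                                        class_a = "B", class_b = "C",
                                        expression_class = "housekeeping") {
  stopifnot("class" %in% names(tads))
  na <- sum(tads$class == class_a, na.rm = TRUE)
  nb <- sum(tads$class == class_b, na.rm = TRUE)
  if (na < 2L || nb < 2L)
    stop("need at least 2 TADs per compared class")
  keep_genes <- genes$name %in%
    gene_classes$gene_id[gene_classes$expression_class == expression_class]
  g <- genes[keep_genes, , drop = FALSE]
  tsel <- tads[tads$class %in% c(class_a, class_b), , drop = FALSE]
  gr_t <- GenomicRanges::GRanges(tsel$chrom,
                                 IRanges::IRanges(tsel$start + 1L, tsel$end))
  gr_g <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  hits <- GenomicRanges::findOverlaps(gr_g, gr_t, type = "within")
  cnt <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(tsel))
  dens <- cnt / ((tsel$end - tsel$start) / 1e5)
  da <- dens[tsel$class == class_a]
  db <- dens[tsel$class == class_b]
  wt <- stats::wilcox.test(da, db, exact = FALSE)
  list(densities = data.frame(class = tsel$class, density_per_100kb = dens),
       medians = stats::setNames(c(stats::median(da), stats::median(db)),
                                 c(class_a, class_b)),
       w_statistic = unname(wt$statistic), p_value = wt$p.value)
}
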