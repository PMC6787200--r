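#' Interchromosomal contact probability (ICP) per bin
#'
#' For each genomic bin i, `ICP_i = sum of contacts with bins on other
#' chromosomes / sum of all contacts of bin i` (inter- plus
#' intra-chromosomal). ICP describes the propensity of a region to form
#' interchromosomal contacts and lies in `[0, 1]`. Bins with zero total
#' contacts have undefined ICP (`NA`). The diagonal (self-bin) count is
#' included in the intra-chromosomal part of the denominator by default --
#' the literal reading of the definition; set `include_diagonal = FALSE` to
#' drop it.
#'
#' @param cm A [contact_matrix()].
#' @param include_diagonal Include self-contacts in the denominator
#'   (default `TRUE`).
#' @return Data frame: `chrom`, `start`, `end`, `bin`, `inter`, `total`,
#'   `icp` (`NA` where undefined).
#' @export
compute_icp <- function(cm, include_diagonal = TRUE) {
  stopifnot(inherits(cm, "contact_matrix"))
  counts <- cm$counts
  if (!Matrix::isSymmetric(counts, tol = 0))
    stop("asymmetric contact matrix; symmetrize at read time")
  bins <- cm$bins
  total <- Matrix::rowSums(counts)
  if (!include_diagonal) total <- total - Matrix::diag(counts)
  # intra sums via per-chromosome block row sums
  intra <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    intra[idx] <- Matrix::rowSums(counts[idx, idx, drop = FALSE])
    if (!include_diagonal)
      intra[idx] <- intra[idx] - Matrix::diag(counts)[idx]
  }
  inter <- total - intra
  icp <- ifelse(total > 0, inter / total, NA_real_)
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             bin = bins$bin, inter = inter, total = total, icp = icp)
}

#' Compare GC% between hub labels
#'
#' Tests whether 1 Mb (or other fixed-resolution) bins assigned to the
#' active/speckle hub are GC-richer than bins assigned to the
#' inactive/nucleolar hub. Reports boxplot five-number summaries per label
#' and a two-sample t-test (Student pooled-variance by default, matching
#' the classical test; Welch via `var_equal = FALSE`). Unassigned bins are
#' excluded.
#'
#' @param hubs Data frame with `chrom`, `start`, `end`, `label` where label
#'   is `"nucleolar"`, `"speckle"`, or `"unassigned"` (e.g. BED4 via
#'   [read_bed()] with the 4th column renamed).
#' @param gc_track Windowed GC track from [windowed_gc()] at the same
#'   resolution and assembly.
#' @param var_equal Pooled-variance Student test (default `TRUE`).
#' @return List: `summary` (per-label n, mean, five-number summary),
#'   `mean_difference` (speckle minus nucleolar), `t_statistic`, `p_value`,
#'   `undefined` flag when the test is degenerate.
#' @export
hub_gc_comparison <- function(hubs, gc_track, var_equal = TRUE) {
  lab <- if ("label" %in% names(hubs)) hubs$label else hubs$name
  if (is.null(lab)) stop("hub track needs a 'label' (or 'name') column")
  key <- function(d) paste(d$chrom, d$start)
  gc <- gc_track$gc[match(key(hubs), key(gc_track))]
  keep <- lab %in% c("nucleolar", "speckle") & !is.na(gc)
  g <- split(gc[keep], lab[keep])
  if (length(g) < 2L || any(vapply(g, length, 1L) == 0L))
    stop("both hub label groups must be non-empty")
  summ <- do.call(rbind, lapply(names(g), function(nm) {
    fv <- stats::fivenum(g[[nm]])
    data.frame(label = nm, n = length(g[[nm]]), mean_gc = mean(g[[nm]]),
               min = fv[1], q1 = fv[2], median = fv[3], q3 = fv[4], max = fv[5])
  }))
  diff <- mean(g$speckle) - mean(g$nucleolar)
  undefined <- length(g$speckle) < 2L || length(g$nucleolar) < 2L ||
    (stats::sd(g$speckle) == 0 && stats::sd(g$nucleolar) == 0)
  if (undefined) {
    return(list(summary = summ, mean_difference = diff, t_statistic = NA_real_,
                p_value = NA_real_, undefined = TRUE))
  }
  tt <- stats::t.test(g$speckle, g$nucleolar, var.equal = var_equal)
  list(summary = summ, mean_difference = diff,
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       undefined = FALSE)
}

#' Genome-wide correlation between ICP and GC%
#'
#' Pearson correlation (with two-sided p-value) between per-bin ICP and
#' per-bin GC%, over bins where both are defined.
#'
#' @param icp ICP table from [compute_icp()].
#' @param gc_track GC track from [windowed_gc()] at the matching resolution.
#' @return List: `r`, `p_value`, `n`, `pairs` (the per-bin paired table);
#'   `undefined = TRUE` with `r = NA` if either vector is constant.
#' @export
icp_gc_correlation <- function(icp, gc_track) {
  key <- function(d) paste(d$chrom, d$start)
  gc <- gc_track$gc[match(key(icp), key(gc_track))]
  keep <- !is.na(gc) & !is.na(icp$icp)
  if (sum(keep) < 3L) stop("fewer than 3 paired bins")
  x <- gc[keep]; y <- icp$icp[keep]
  pairs <- data.frame(chrom = icp$chrom[keep], start = icp$start[keep],
                      gc = x, icp = y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                pairs = pairs, undefined = TRUE))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       pairs = pairs, undefined = FALSE)
}

#' Linear models between GC% and contact intensity
#'
#' Ordinary least squares in both directions (`icp ~ gc` and `gc ~ icp`),
#' reported separately: because OLS minimizes vertical residuals, the
#' reverse fit is not the reciprocal of the forward fit unless `|r| = 1`.
#' Either fit can be used to predict the expected interaction intensity
#' from composition, or the expected GC content from interaction intensity.
#'
#' @param gc Numeric vector of per-bin GC%.
#' @param icp Numeric vector of per-bin ICP, same length.
#' @return List of class `contact_model`: `forward` and `reverse`, each with
#'   `slope`, `intercept`, `residual_sd`; shared `r` and `n`; and
#'   `predict_icp(gc)` / `predict_gc(icp)` closures.
#' @export
linear_contact_model <- function(gc, icp) {
  keep <- !is.na(gc) & !is.na(icp)
  gc <- gc[keep]; icp <- icp[keep]
  if (length(gc) < 3L) stop("need at least 3 points")
  if (stats::sd(gc) == 0 || stats::sd(icp) == 0)
    stop("zero predictor variance; linear model undefined")
  f <- stats::lm(icp ~ gc)
  r <- stats::lm(gc ~ icp)
  coefs <- function(m) list(slope = unname(stats::coef(m)[2L]),
                            intercept = unname(stats::coef(m)[1L]),
                            residual_sd = stats::sigma(m))
  fw <- coefs(f); rv <- coefs(r)
  structure(list(
    forward = fw, reverse = rv, r = stats::cor(gc, icp), n = length(gc),
    predict_icp = function(gc_new) fw$intercept + fw$slope * gc_new,
    predict_gc = function(icp_new) rv$intercept + rv$slope * icp_new
  ), class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf("contact_model (n = %d, r = %.3f)\n", x$n, x$r))
  cat(sprintf("  icp ~ gc: slope %.4g, intercept %.4g\n",
              x$forward$slope, x$forward$intercept))
  cat(sprintf("  gc ~ icp: slope %.4g, intercept %.4g\n",
              x$reverse$slope, x$reverse$intercept))
  invisible(x)
}

#' Aligned GC/ICP profile along one chromosome
#'
#' Per-window table of GC% and ICP for plotting sliding-window co-profiles;
#' masked or undefined windows are `NA` in the respective column.
#'
#' @param gc_track GC track from [windowed_gc()].
#' @param icp ICP table from [compute_icp()] at the same resolution.
#' @param chrom Chromosome name.
#' @return Data frame: `start`, `gc`, `icp`, one row per window.
#' @export
coprofile <- function(gc_track, icp, chrom) {
  if (!chrom %in% gc_track$chrom || !chrom %in% icp$chrom)
    stop("chromosome not present in both tracks: ", chrom)
  g <- gc_track[gc_track$chrom == chrom, ]
  i <- icp[icp$chrom == chrom, ]
  data.frame(start = g$start, gc = g$gc,
             icp = i$icp[match(g$start, i$start)])
}
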