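#' PCA of the N x 100 TAD GC matrix
#'
#' Principal component analysis of the binned GC profile matrix (rows =
#' TADs/loops, columns = profile bins). By default columns are centered but
#' not scaled to unit variance: scaling the bin columns would flatten the
#' GC-level signal that makes the first component track mean GC%. Masked
#' bins are mean-imputed within their row before fitting; fully masked rows
#' must be excluded upstream. Component signs follow a fixed convention
#' (each loading vector is oriented so its largest-magnitude element is
#' positive), making results deterministic.
#'
#' @param gc_matrix N x n_bins numeric matrix, or a `tad_profiles` object.
#' @param k Number of components to keep (default 3: F1, F2, F3).
#' @param center Center columns (default `TRUE`).
#' @param scale Scale columns to unit variance (default `FALSE`).
#' @return List of class `gc_pca`: `scores` (N x k, columns `F1..Fk`),
#'   `loadings` (n_bins x k), `explained` (fraction of variance per kept
#'   component), `center`, `scale`.
#' @export
fit_pca <- function(gc_matrix, k = 3L, center = TRUE, scale = FALSE) {
  if (inherits(gc_matrix, "tad_profiles")) gc_matrix <- gc_matrix$profile
  m <- as.matrix(gc_matrix)
  if (anyNA(m)) {
    rm_ <- rowMeans(m, na.rm = TRUE)
    if (any(!is.finite(rm_)))
      stop("fully masked rows must be excluded before PCA")
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- rm_[idx[, 1L]]
  }
  if (k > min(dim(m))) stop("k exceeds matrix rank bound min(N, n_bins)")
  fit <- stats::prcomp(m, center = center, scale. = scale)
  flip <- vapply(seq_len(ncol(fit$rotation)), function(j) {
    v <- fit$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(fit$rotation, 2L, flip, `*`)
  sco <- sweep(fit$x, 2L, flip, `*`)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  keep <- seq_len(k)
  scores <- sco[, keep, drop = FALSE]
  colnames(scores) <- paste0("F", keep)
  loadings <- rot[, keep, drop = FALSE]
  colnames(loadings) <- paste0("F", keep)
  structure(list(scores = scores, loadings = loadings,
                 explained = unname(expl[keep]), center = center, scale = scale,
                 sdev = fit$sdev),
            class = "gc_pca")
}

#' @export
print.gc_pca <- function(x, ...) {
  cat(sprintf("gc_pca: %d rows, %d components; explained fractions: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", x$explained), collapse = ", ")))
  invisible(x)
}

#' Correlation of the first principal component with mean GC%
#'
#' Absolute Pearson correlation between F1 scores and the per-TAD mean GC%.
#' Reported as an absolute value so it is invariant to the component sign
#' convention.
#'
#' @param pca A `gc_pca` object from [fit_pca()].
#' @param mean_gc Numeric vector of per-TAD mean GC%, same order as the
#'   matrix rows.
#' @return `|Pearson r|`; `NA` with a warning if either input has zero
#'   variance.
#' @export
f1_gc_correlation <- function(pca, mean_gc) {
  f1 <- pca$scores[, "F1"]
  if (length(f1) != length(mean_gc)) stop("length mismatch")
  if (stats::sd(mean_gc) == 0 || stats::sd(f1) == 0) {
    warning("zero variance; F1-GC correlation undefined")
    return(NA_real_)
  }
  abs(stats::cor(f1, mean_gc))
}

#' Separation of bell-like vs valley-like classes in the (F2, F3) plane
#'
#' Quantifies how clearly the bell-shaped super-group (classes B and Bminus)
#' separates from the valley-shaped super-group (C and Cminus) using only
#' the second and third component scores: per-class and per-super-group
#' centroids, the silhouette coefficient of the two super-groups, and the
#' accuracy of a nearest-centroid rule (each TAD assigned to the closer
#' super-group centroid).
#'
#' @param pca A `gc_pca` with at least 3 components.
#' @param labels Gradient class label per row (from [classify_all()]); rows
#'   with labels outside B/Bminus/C/Cminus are ignored.
#' @return List: `centroids` (per class), `supergroup_centroids`,
#'   `silhouette` (mean silhouette width of the two super-groups),
#'   `centroid_accuracy`, `n` (TADs used).
#' @export
cluster_separation <- function(pca, labels) {
  if (ncol(pca$scores) < 3L) stop("need at least 3 components (F2, F3)")
  labels <- as.character(labels)
  sg <- ifelse(labels %in% c("B", "Bminus"), "bell",
               ifelse(labels %in% c("C", "Cminus"), "valley", NA))
  keep <- !is.na(sg)
  if (sum(sg[keep] == "bell") == 0L || sum(sg[keep] == "valley") == 0L)
    stop("both super-groups (B/Bminus and C/Cminus) must be non-empty")
  xy <- pca$scores[keep, c("F2", "F3"), drop = FALSE]
  grp <- sg[keep]
  cls <- labels[keep]
  centroids <- do.call(rbind, lapply(split(seq_along(cls), cls), function(i)
    colMeans(xy[i, , drop = FALSE])))
  sg_centroids <- do.call(rbind, lapply(split(seq_along(grp), grp), function(i)
    colMeans(xy[i, , drop = FALSE])))
  d2 <- function(p, q) (p[, 1] - q[1])^2 + (p[, 2] - q[2])^2
  pred <- ifelse(d2(xy, sg_centroids["bell", ]) <= d2(xy, sg_centroids["valley", ]),
                 "bell", "valley")
  acc <- mean(pred == grp)
  sil <- cluster::silhouette(as.integer(factor(grp)), stats::dist(xy))
  list(centroids = centroids, supergroup_centroids = sg_centroids,
       silhouette = mean(sil[, "sil_width"]), centroid_accuracy = acc,
       n = nrow(xy))
}
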