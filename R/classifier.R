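#' Per-half Pearson correlations of a binned GC profile
#'
#' Splits the profile into a first half (bins 1..n/2) and a second half
#' (bins n/2+1..n) and computes, within each half, the Pearson correlation
#' between bin GC% and within-half bin index. Masked (`NA`) bins are dropped
#' pairwise within their half. A constant (zero-variance) half has `r`
#' defined as 0 (the definitional flat case). A half with fewer than 3
#' unmasked bins makes the profile unclassifiable and returns `NA` for that
#' half.
#'
#' @param bins Numeric GC% profile of even length (default layout 100 bins).
#' @return Named numeric vector `c(r1, r2)`.
#' @export
half_correlations <- function(bins) {
  n <- length(bins)
  if (n %% 2L != 0L) stop("profile length must be even")
  half <- n %/% 2L
  r_of <- function(y) {
    x <- seq_along(y)
    ok <- !is.na(y)
    if (sum(ok) < 3L) return(NA_real_)
    y <- y[ok]; x <- x[ok]
    if (stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  c(r1 = r_of(bins[seq_len(half)]), r2 = r_of(bins[(half + 1L):n]))
}

#' Gradient classes
#'
#' The six intra-TAD GC-gradient classes: `A` (monotone increase or
#' decrease), `B` (bell/peak), `C` (valley), `Bminus` (half bell), `Cminus`
#' (half valley), `D` (flat or uncorrelated).
#' @return Character vector of class labels in canonical order.
#' @export
gradient_classes <- function() c("A", "B", "C", "Bminus", "Cminus", "D")

#' Classify a profile from its per-half correlations
#'
#' Each half correlation is reduced to a sign: `+` if `r >= flat_threshold`,
#' `-` if `r <= -flat_threshold`, `0` otherwise. The sign pair maps to a
#' class: `(0,0) -> D`; `(+,+)` or `(-,-) -> A`; `(+,-) -> B`;
#' `(-,+) -> C`; `(+,0)` or `(0,-) -> Bminus` (plateau-high interior);
#' `(-,0)` or `(0,+) -> Cminus` (plateau-low interior). Reversing a profile
#' maps `(r1, r2)` to `(-r2, -r1)`, so every class is orientation-invariant
#' by construction (5' and 3' gradient patterns are equivalent).
#'
#' @param r1,r2 Per-half Pearson correlations (vectorized).
#' @param flat_threshold Absolute-r cut below which a half is flat
#'   (default 0.4).
#' @return Character vector of class labels; `NA` where either half is `NA`.
#' @export
classify_gradient <- function(r1, r2, flat_threshold = 0.4) {
  stopifnot(flat_threshold > 0, flat_threshold < 1)
  s <- function(r) ifelse(r >= flat_threshold, 1L, ifelse(r <= -flat_threshold, -1L, 0L))
  s1 <- s(r1); s2 <- s(r2)
  key <- paste(s1, s2)
  map <- c("0 0" = "D",
           "1 1" = "A", "-1 -1" = "A",
           "1 -1" = "B", "-1 1" = "C",
           "1 0" = "Bminus", "0 -1" = "Bminus",
           "-1 0" = "Cminus", "0 1" = "Cminus")
  out <- unname(map[key])
  out[is.na(r1) | is.na(r2)] <- NA_character_
  out
}

#' Classify all TAD/loop profiles and tabulate class frequencies
#'
#' Computes per-half correlations and gradient classes for every row of a
#' profile matrix, and tabulates class counts and proportions overall and
#' stratified by isochore family. TADs with an unclassifiable half (< 3
#' unmasked bins) are excluded and reported separately.
#'
#' @param profiles A `tad_profiles` object from [tad_profiles()], or a bare
#'   N x n_bins numeric matrix.
#' @param flat_threshold Flat/non-flat cut on `|r|` (default 0.4).
#' @return A list of class `tad_classification`: `per_tad` (data frame with
#'   `tad_id`, `r1`, `r2`, `class`, and `mean_gc`/`family` when available),
#'   `frequency` (per-family and overall counts and proportions),
#'   `excluded` (character vector of excluded TAD ids).
#' @export
classify_all <- function(profiles, flat_threshold = 0.4) {
  if (inherits(profiles, "tad_profiles")) {
    mat <- profiles$profile
    meta <- profiles$meta
  } else {
    mat <- as.matrix(profiles)
    meta <- NULL
  }
  if (nrow(mat) == 0L) {
    warning("no profiles to classify")
    return(structure(list(per_tad = data.frame(), frequency = data.frame(),
                          excluded = character(0)),
                     class = "tad_classification"))
  }
  rr <- t(apply(mat, 1L, half_correlations))
  cls <- classify_gradient(rr[, 1L], rr[, 2L], flat_threshold)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("tad_%04d", seq_len(nrow(mat)))
  per_tad <- data.frame(tad_id = ids, r1 = rr[, 1L], r2 = rr[, 2L],
                        class = cls, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    per_tad$mean_gc <- meta$mean_gc
    per_tad$family <- meta$family
  }
  excluded <- ids[is.na(cls)]
  kept <- per_tad[!is.na(cls), , drop = FALSE]
  strata <- if (!is.null(meta)) kept$family else rep("all", nrow(kept))
  freq <- class_frequency_table(kept$class, strata)
  structure(list(per_tad = per_tad, frequency = freq, excluded = excluded,
                 flat_threshold = flat_threshold),
            class = "tad_classification")
}

#' @export
print.tad_classification <- function(x, ...) {
  cat(sprintf("tad_classification: %d classified, %d excluded\n",
              sum(!is.na(x$per_tad$class)), length(x$excluded)))
  print(x$frequency)
  invisible(x)
}

#' Class frequency table, stratified
#'
#' @param classes Character vector of class labels.
#' @param strata Stratum label per TAD (e.g. isochore family); `"overall"`
#'   row always included.
#' @return Data frame with `stratum`, `class`, `count`, `proportion`;
#'   proportions sum to 1 within each stratum.
#' @export
class_frequency_table <- function(classes, strata = NULL) {
  lv <- gradient_classes()
  if (is.null(strata)) strata <- rep("overall", length(classes))
  strata <- as.character(strata)
  blocks <- c(list(overall = rep(TRUE, length(classes))),
              lapply(stats::setNames(nm = sort(unique(strata[!is.na(strata)]))),
                     function(s) !is.na(strata) & strata == s))
  rows <- lapply(names(blocks), function(nm) {
    cl <- classes[blocks[[nm]]]
    counts <- table(factor(cl, levels = lv))
    data.frame(stratum = nm, class = lv, count = as.integer(counts),
               proportion = if (sum(counts) > 0) as.numeric(counts / sum(counts))
                            else rep(NA_real_, length(lv)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Boundary perturbation: re-classify after resizing TADs
#'
#' Re-estimates each TAD's gradient class after increasing (`expand`) or
#' decreasing (`shrink`) its size by `delta` bp on both the 5' and 3' ends,
#' and cross-tabulates original vs perturbed class. Expanded intervals are
#' clipped to chromosome bounds; TADs too short to shrink (length <=
#' `2 * delta + n_bins`) are counted in an `excluded` column.
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param tads Data frame with `chrom`, `start`, `end` (and optional `name`).
#' @param delta Perturbation in bp on each end (default 50000).
#' @param mode `"expand"` or `"shrink"`.
#' @param n_bins Bins per profile (default 100).
#' @param flat_threshold Flat cut for classification.
#' @return A list of class `perturbation_result`: `transition` (6 x 7 matrix,
#'   rows original class, columns perturbed class plus `excluded`),
#'   `stay_rate` (per-class proportion keeping its class), `per_tad`
#'   (data frame of original and perturbed labels).
#' @export
perturb_and_reclassify <- function(genome, tads, delta = 50000L,
                                   mode = c("expand", "shrink"),
                                   n_bins = 100L, flat_threshold = 0.4) {
  mode <- match.arg(mode)
  stopifnot(delta > 0)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  orig <- classify_all(tad_profiles(genome, tads, n_bins), flat_threshold)
  sgn <- if (mode == "expand") 1L else -1L
  new_start <- pmax(0, tads$start - sgn * delta)
  new_end <- pmin(chrom_len[tads$chrom], tads$end + sgn * delta)
  feasible <- new_end - new_start >= n_bins
  pert_class <- rep(NA_character_, nrow(tads))
  if (any(feasible)) {
    ptads <- data.frame(chrom = tads$chrom[feasible], start = new_start[feasible],
                        end = new_end[feasible])
    pc <- classify_all(tad_profiles(genome, ptads, n_bins), flat_threshold)
    pert_class[feasible] <- pc$per_tad$class
  }
  lv <- gradient_classes()
  trans <- table(factor(orig$per_tad$class, levels = lv),
                 factor(ifelse(is.na(pert_class), "excluded", pert_class),
                        levels = c(lv, "excluded")))
  trans <- unclass(trans)
  stay <- vapply(lv, function(cl) {
    tot <- sum(trans[cl, ])
    if (tot == 0) NA_real_ else trans[cl, cl] / tot
  }, numeric(1))
  structure(list(transition = trans, stay_rate = stay, mode = mode,
                 delta = delta,
                 per_tad = data.frame(tad_id = orig$per_tad$tad_id,
                                      original = orig$per_tad$class,
                                      perturbed = pert_class,
                                      stringsAsFactors = FALSE)),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("perturbation_result (%s by %g bp per end)\n", x$mode, x$delta))
  print(x$transition)
  cat("stay rates:\n"); print(round(x$stay_rate, 3))
  invisible(x)
}

#' Sub-structure enrichment between two TAD classes
#'
#' Compares the per-100-kb density of sub-TAD/loop features between two
#' gradient classes. A sub-structure is assigned to a TAD only if fully
#' contained in it. Reports the ratio of class mean densities and a Welch
#' two-sample t-test on the per-TAD densities.
#'
#' @param tads Data frame with `chrom`, `start`, `end`, `class` (gradient
#'   class label per TAD, e.g. merged from [classify_all()]).
#' @param sub_tads Data frame of sub-structure intervals (`chrom`, `start`,
#'   `end`).
#' @param class_a,class_b Class labels to compare (ratio = a over b).
#' @return List: `ratio` (mean density a / mean density b; `NA` and
#'   `undefined = TRUE` when the denominator mean is 0), `t_statistic`,
#'   `p_value`, `densities` (per-TAD table).
#' @export
substructure_enrichment <- function(tads, sub_tads, class_a = "B", class_b = "C") {
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(tads)))
  keep <- tads$class %in% c(class_a, class_b)
  if (sum(tads$class == class_a, na.rm = TRUE) < 2L ||
      sum(tads$class == class_b, na.rm = TRUE) < 2L)
    stop("need at least 2 TADs in each compared class for the t-test")
  tsub <- tads[keep, , drop = FALSE]
  gr_t <- GenomicRanges::GRanges(tsub$chrom,
                                 IRanges::IRanges(tsub$start + 1L, tsub$end))
  gr_s <- GenomicRanges::GRanges(sub_tads$chrom,
                                 IRanges::IRanges(sub_tads$start + 1L, sub_tads$end))
  hits <- GenomicRanges::findOverlaps(gr_s, gr_t, type = "within")
  counts <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(tsub))
  dens <- counts / ((tsub$end - tsub$start) / 1e5)
  da <- dens[tsub$class == class_a]
  db <- dens[tsub$class == class_b]
  ratio <- if (mean(db) == 0) NA_real_ else mean(da) / mean(db)
  tt <- stats::t.test(da, db, var.equal = FALSE)
  list(ratio = ratio, undefined = mean(db) == 0,
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       densities = data.frame(tad_id = seq_len(nrow(tsub)), class = tsub$class,
                              density_per_100kb = dens))
}
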