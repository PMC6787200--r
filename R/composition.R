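#' Isochore family GC% boundaries
#'
#' Fixed cut-points partitioning mean GC% into the five isochore families
#' L1, L2, H1, H2, H3. Intervals are half-open on the left (a TAD with mean
#' GC exactly at a cut-point belongs to the upper family) and clamped at the
#' extremes: anything below 37% is L1, anything at or above 53% is H3.
#'
#' @return Named numeric vector of left cut-points (GC%) for L2..H3.
#' @export
isochore_boundaries <- function() {
  c(L2 = 37, H1 = 41, H2 = 46, H3 = 53)
}

#' GC content of a sequence
#'
#' `100 * (G + C) / (A + C + G + T)`. `N` and other IUPAC ambiguity codes
#' are excluded from the denominator. Returns `NA` (masked) when the
#' non-ACGT fraction exceeds `mask_threshold`, or for an empty sequence.
#' Lowercase (soft-masked) bases count as their base identity.
#'
#' @param sequence A character string, `DNAString`, or `DNAStringSet`
#'   (vectorized over elements).
#' @param mask_threshold Maximum tolerated non-ACGT fraction (default 0.5).
#' @return Numeric GC% in `[0, 100]`, `NA` where masked.
#' @export
gc_content <- function(sequence, mask_threshold = 0.5) {
  if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
  if (methods::is(sequence, "DNAString"))
    sequence <- Biostrings::DNAStringSet(list(sequence))
  counts <- Biostrings::letterFrequency(sequence, letters = c("A", "C", "G", "T"))
  acgt <- rowSums(counts)
  total <- Biostrings::width(sequence)
  gc <- 100 * (counts[, "G"] + counts[, "C"]) / acgt
  masked <- total == 0 | (total - acgt) / pmax(total, 1L) > mask_threshold
  gc[masked] <- NA_real_
  unname(gc)
}

#' Windowed GC% track over a genome
#'
#' Tiles each chromosome with non-overlapping windows of `resolution` bp and
#' computes per-window GC% with the N-exclusion rule of [gc_content()]. A
#' final partial window is kept if it covers at least 10% of `resolution`,
#' otherwise it is masked. Windows whose non-ACGT fraction exceeds
#' `mask_threshold` are masked (`gc = NA`).
#'
#' @param genome A `DNAStringSet` (or path to a FASTA file).
#' @param resolution Window size in bp (>= 1).
#' @param mask_threshold Maximum tolerated non-ACGT fraction per window.
#' @return Data frame with `chrom`, `start`, `end`, `gc`, `n_fraction`
#'   (non-ACGT fraction), one row per window; `gc` is `NA` where masked.
#' @export
windowed_gc <- function(genome, resolution = 1e6, mask_threshold = 0.5) {
  stopifnot(resolution >= 1)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  pieces <- lapply(names(genome), function(ch) {
    L <- length(genome[[ch]])
    starts <- seq(0, L - 1, by = resolution)
    ends <- pmin(starts + resolution, L)
    v <- Biostrings::Views(genome[[ch]], start = starts + 1L, end = ends)
    counts <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    acgt <- rowSums(counts)
    w <- ends - starts
    gc <- 100 * (counts[, "G"] + counts[, "C"]) / acgt
    n_fraction <- (w - acgt) / w
    masked <- acgt == 0 | n_fraction > mask_threshold | w < 0.1 * resolution
    gc[masked] <- NA_real_
    data.frame(chrom = ch, start = starts, end = ends, gc = unname(gc),
               n_fraction = unname(n_fraction), stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# Split [0, len) into n near-equal pieces; lengths differ by <= 1 bp and the
# remainder goes to the leftmost bins. Returns integer vector of bin lengths.
.bin_lengths <- function(len, n) {
  base <- len %/% n
  rem <- len %% n
  c(rep.int(base + 1L, rem), rep.int(base, n - rem))
}

#' 100-bin GC profile of a single TAD or loop
#'
#' Splits the interval into `n_bins` near-equal bins (lengths differ by at
#' most 1 bp; the remainder is distributed to the leftmost bins) and computes
#' per-bin GC% via [gc_content()].
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param chrom,start,end Interval in 0-based half-open coordinates.
#' @param n_bins Number of bins (default 100).
#' @param mask_threshold Per-bin masking threshold on the non-ACGT fraction.
#' @return Numeric vector of length `n_bins` (GC%, `NA` where masked).
#' @export
tad_gc_profile <- function(genome, chrom, start, end, n_bins = 100L,
                           mask_threshold = 0.5) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  if (end - start < n_bins)
    stop("interval shorter than n_bins (", end - start, " bp < ", n_bins,
         " bins); use a smaller n_bins")
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  lens <- .bin_lengths(end - start, n_bins)
  bstarts <- start + cumsum(c(0L, lens[-n_bins]))
  v <- Biostrings::Views(genome[[chrom]], start = bstarts + 1L,
                         end = bstarts + lens)
  counts <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
  acgt <- rowSums(counts)
  gc <- 100 * (counts[, "G"] + counts[, "C"]) / acgt
  masked <- acgt == 0 | (lens - acgt) / lens > mask_threshold
  gc[masked] <- NA_real_
  unname(gc)
}

#' Binned GC profiles for a set of TADs/loops
#'
#' Computes the N x `n_bins` GC matrix: one row per interval, columns the
#' within-interval bins, together with per-TAD mean GC% (over unmasked bins)
#' and isochore family.
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param tads Data frame with `chrom`, `start`, `end` (0-based half-open),
#'   optionally `name`; e.g. from [read_bed()].
#' @param n_bins Number of bins per interval (default 100).
#' @param mask_threshold Per-bin masking threshold.
#' @return A list of class `tad_profiles` with elements `profile` (N x
#'   `n_bins` matrix, rownames = TAD ids) and `meta` (data frame: `tad_id`,
#'   `chrom`, `start`, `end`, `mean_gc`, `family`).
#' @export
tad_profiles <- function(genome, tads, n_bins = 100L, mask_threshold = 0.5) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  n <- nrow(tads)
  ids <- if ("name" %in% names(tads)) as.character(tads$name) else
    sprintf("tad_%04d", seq_len(n))
  prof <- matrix(NA_real_, nrow = n, ncol = n_bins, dimnames = list(ids, NULL))
  for (k in seq_len(n)) {
    prof[k, ] <- tad_gc_profile(genome, tads$chrom[k], tads$start[k],
                                tads$end[k], n_bins, mask_threshold)
  }
  mean_gc <- unname(rowMeans(prof, na.rm = TRUE))
  mean_gc[!is.finite(mean_gc)] <- NA_real_
  meta <- data.frame(tad_id = ids, chrom = tads$chrom, start = tads$start,
                     end = tads$end, mean_gc = mean_gc,
                     family = assign_family(mean_gc),
                     stringsAsFactors = FALSE)
  structure(list(profile = prof, meta = meta, n_bins = n_bins),
            class = "tad_profiles")
}

#' @export
print.tad_profiles <- function(x, ...) {
  cat(sprintf("tad_profiles: %d intervals x %d bins\n", nrow(x$profile), x$n_bins))
  print(table(x$meta$family, useNA = "ifany"))
  invisible(x)
}

#' Assign isochore family from mean GC%
#'
#' Half-open lookup against [isochore_boundaries()]: L1 below 37%, L2
#' `[37,41)`, H1 `[41,46)`, H2 `[46,53)`, H3 at or above 53%. Values outside
#' the nominal 33-59% span are clamped into the extreme families. Masked
#' (`NA`) means are unassigned (`NA`).
#'
#' @param mean_gc Numeric vector of mean GC% in `[0, 100]`.
#' @return Character vector of family labels (`L1`,`L2`,`H1`,`H2`,`H3`).
#' @export
assign_family <- function(mean_gc) {
  cuts <- isochore_boundaries()
  fam <- cut(mean_gc, breaks = c(-Inf, cuts, Inf), right = FALSE,
             labels = c("L1", names(cuts)))
  as.character(fam)
}
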