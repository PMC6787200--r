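#' Read a genome FASTA file
#'
#' Reads a (multi-record) FASTA file into a [Biostrings::DNAStringSet].
#' Sequences are uppercased; IUPAC ambiguity codes and `N` are preserved.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per record.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("FASTA parse error: empty file: ", path)
  if (!startsWith(first, ">"))
    stop("FASTA parse error at line 1: expected '>' header, got: ", first)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA parse error: no records in ", path)
  if (any(Biostrings::width(seqs) == 0L)) {
    bad <- names(seqs)[Biostrings::width(seqs) == 0L][1L]
    stop("FASTA parse error: record '", bad, "' has no sequence")
  }
  if (anyDuplicated(names(seqs)))
    stop("FASTA parse error: duplicated record names")
  seqs
}

#' Write a genome FASTA file
#'
#' @param seqs A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Parses BED3/BED4/BED6 into a data frame with the BED convention enforced:
#' 0-based half-open `[start, end)` coordinates. All downstream functions in
#' this package assume this convention; inputs in 1-based inclusive
#' coordinates must be converted at this boundary via `one_based = TRUE`.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @param one_based If `TRUE`, input coordinates are 1-based inclusive and
#'   are converted to 0-based half-open on read.
#' @return A data frame with columns `chrom`, `start`, `end`, and, when
#'   present in the file, `name` (4th column) and `score`/`strand`
#'   (5th/6th). Extra columns beyond 6 are kept as `extra1`, `extra2`, ...
#' @export
read_bed <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED parse error: fewer than 3 columns in ", path)
  start <- suppressWarnings(as.numeric(raw[[2L]]))
  end <- suppressWarnings(as.numeric(raw[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad) > 0L)
    stop("BED parse error: non-integer coordinate at line ", bad[1L])
  if (one_based) start <- start - 1
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0L)
    stop("BED validation error: start >= end (or start < 0) at line ", bad[1L])
  out <- data.frame(chrom = raw[[1L]], start = start, end = end,
                    stringsAsFactors = FALSE)
  extras <- c("name", "score", "strand")
  if (ncol(raw) > 3L) {
    for (j in 4:ncol(raw)) {
      nm <- if (j - 3L <= length(extras)) extras[j - 3L] else paste0("extra", j - 6L)
      out[[nm]] <- raw[[j]]
    }
  }
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus any additional columns, tab-separated,
#' no header, no quoting. Round-trips [read_bed()] output byte-identically
#' for canonical 3-column input.
#'
#' @param x Data frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  cols <- c("chrom", "start", "end", setdiff(names(x), c("chrom", "start", "end")))
  df <- x[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct the genome-wide bin table for a set of chromosome sizes
#'
#' Tiling bins of width `bin_size`; the last bin of each chromosome may be
#' shorter. Bins carry a global 1-based index used by [contact_matrix()].
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp.
#' @return Data frame with `chrom`, `start`, `end`, `bin` (global index).
#' @export
genome_bins <- function(chrom_sizes, bin_size) {
  stopifnot(bin_size >= 1, length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)))
  pieces <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    starts <- seq(0, L - 1, by = bin_size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + bin_size, L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin <- seq_len(nrow(out))
  out
}

#' Construct a contact matrix object
#'
#' A symmetric, chromosome-aware binned contact matrix. Counts are stored
#' sparsely; `bins` maps the global bin index to genomic coordinates.
#'
#' @param counts A square symmetric matrix (base or `Matrix` sparse) of
#'   non-negative contact counts, dimension = number of bins.
#' @param bins Bin table as produced by [genome_bins()].
#' @param bin_size Bin width in bp.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bins, bin_size) {
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != ncol(counts)) stop("contact matrix must be square")
  if (nrow(counts) != nrow(bins)) stop("counts dimension does not match bin table")
  if (any(counts@x < 0)) stop("contact counts must be non-negative")
  if (!Matrix::isSymmetric(counts, tol = 0))
    stop("contact matrix must be symmetric (symmetrize at read time)")
  structure(list(counts = counts, bins = bins, bin_size = bin_size),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins (%d chromosomes) at %g bp; %g total counts\n",
              nrow(x$bins), length(unique(x$bins$chrom)), x$bin_size,
              sum(x$counts) / 2 + sum(Matrix::diag(x$counts)) / 2))
  invisible(x)
}

#' Read a sparse triplet contact file
#'
#' Accepts two tab-separated layouts (no header): `binA binB count` with
#' 1-based global bin indices, or `chromA posA chromB posB count` where
#' positions are 0-based bp assigned to the containing bin. Both triangles
#' may be present; entries are summed and the matrix is symmetrized so that
#' `C[i,j] = C[j,i]` equals the total over both orderings.
#'
#' @param path Path to the triplet TSV.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return A [contact_matrix()].
#' @export
read_contacts <- function(path, bin_size, chrom_sizes) {
  if (!file.exists(path)) stop("contact file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  bins <- genome_bins(chrom_sizes, bin_size)
  n <- nrow(bins)
  if (ncol(raw) == 3L) {
    i <- as.integer(raw[[1L]]); j <- as.integer(raw[[2L]]); cnt <- as.numeric(raw[[3L]])
    if (any(is.na(i)) || any(is.na(j))) stop("contact parse error: non-integer bin index")
    if (any(i < 1L | i > n | j < 1L | j > n))
      stop("contact validation error: bin index outside genome (1..", n, ")")
  } else if (ncol(raw) == 5L) {
    cnt <- as.numeric(raw[[5L]])
    i <- .pos_to_bin(raw[[1L]], as.numeric(raw[[2L]]), bins, bin_size, chrom_sizes)
    j <- .pos_to_bin(raw[[3L]], as.numeric(raw[[4L]]), bins, bin_size, chrom_sizes)
  } else {
    stop("contact parse error: expected 3 or 5 columns, got ", ncol(raw))
  }
  if (any(is.na(cnt)) || any(cnt < 0))
    stop("contact validation error: negative or missing count")
  # accumulate both orderings onto the upper triangle, then mirror
  lo <- pmin(i, j); hi <- pmax(i, j)
  up <- Matrix::sparseMatrix(i = lo, j = hi, x = cnt, dims = c(n, n))
  full <- up + Matrix::t(up)
  Matrix::diag(full) <- Matrix::diag(up)   # diagonal was doubled by the mirror
  contact_matrix(full, bins, bin_size)
}

.pos_to_bin <- function(chrom, pos, bins, bin_size, chrom_sizes) {
  if (!all(chrom %in% names(chrom_sizes)))
    stop("contact validation error: unknown chromosome ",
         setdiff(unique(chrom), names(chrom_sizes))[1L])
  if (any(pos < 0 | pos >= chrom_sizes[chrom]))
    stop("contact validation error: position outside chromosome bounds")
  first <- tapply(bins$bin, bins$chrom, min)[chrom]
  as.integer(first + floor(pos / bin_size))
}

#' Read a gene-by-tissue expression table
#'
#' First column gene id, header row of tissue names, TPM values.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix (genes x tissues) with gene ids as rownames.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1L, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression parse error: non-numeric value")
  if (any(m < 0)) stop("expression validation error: negative TPM")
  if (anyDuplicated(rownames(m))) stop("expression validation error: duplicated gene ids")
  if (anyDuplicated(colnames(m))) stop("expression validation error: duplicated tissue names")
  m
}

#' Write a gene-by-tissue expression table
#'
#' @param tpm Numeric matrix, genes x tissues, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tpm, path) {
  df <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a per-window track as bedGraph
#'
#' @param track Data frame with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default `"gc"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "gc") {
  stopifnot(value %in% names(track))
  keep <- !is.na(track[[value]])
  df <- data.frame(track$chrom, format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   track[[value]])[keep, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
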