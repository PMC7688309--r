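#' Filter cells on usable read depth
#'
#' Standard initial quality cutoff for snATAC cells: keep cells with at least
#' `min_usable_reads` unique, non-mitochondrial reads. The peak set is
#' unchanged.
#'
#' @param matrix a `PeakMatrix` with populated `usable_reads`.
#' @param min_usable_reads inclusive threshold (default 1000).
#' @return a `PeakMatrix` restricted to passing cells.
#' @export
filter_cells <- function(matrix, min_usable_reads = 1000) {
  keep <- matrix$cells$usable_reads >= min_usable_reads
  if (!any(keep)) warning("no cells pass usable-read threshold ",
                          min_usable_reads)
  matrix[, keep]
}

#' Per-cell sequencing probability
#'
#' Probability that any given distinct molecule of a library of complexity C
#' is observed at least once among k sequenced reads, assuming unbiased
#' amplification: `s = 1 - (1 - 1/C)^k`.
#'
#' @param C library complexity (distinct molecules), `C >= 1`.
#' @param k total read count, `k >= 0`.
#' @return probability in `[0, 1]` (vectorized).
#' @export
sequencing_probability <- function(C, k) {
  if (any(C < 1)) stop("library complexity C must be >= 1")
  if (any(k < 0)) stop("read count k must be >= 0")
  1 - (1 - 1 / C)^k
}

#' Relative accessibility scores
#'
#' Per-peak scores `A_i = 1e6 * sum_j O_ij / sum_ij O_ij` over a cell subset;
#' by construction `sum_i A_i = 1e6`, making scores comparable across samples.
#'
#' @param matrix a `PeakMatrix`.
#' @param cell_subset optional cell index / barcodes / logical mask.
#' @return named numeric vector of per-peak scores summing to 1e6.
#' @export
relative_accessibility <- function(matrix, cell_subset = NULL) {
  if (!is.null(cell_subset)) matrix <- matrix[, cell_subset]
  rs <- Matrix::rowSums(matrix$counts)
  tot <- sum(rs)
  if (tot <= 0) stop("all counts are zero over the requested cell subset")
  setNames(1e6 * rs / tot, matrix$peaks$id)
}

#' Complexity-adjusted accessibility scores
#'
#' Per-peak scores `A_i = Z * sum_j O_ij / sum_j C_j s_j`, where `s_j` is the
#' per-cell sequencing probability and Z the constant making the scores sum
#' to 1e6. The denominator corrects the expected read yield of the cell set
#' for library complexity and sampling depth, which is what makes scores
#' computed on different cell sets (donors, clusters, samples) comparable.
#'
#' @param matrix a `PeakMatrix` with `library_complexity` and `usable_reads`.
#' @param cell_subset optional cell index / barcodes / logical mask.
#' @return named numeric vector of per-peak scores summing to 1e6.
#' @export
complexity_adjusted_accessibility <- function(matrix, cell_subset = NULL) {
  if (!is.null(cell_subset)) matrix <- matrix[, cell_subset]
  cells <- matrix$cells
  s <- sequencing_probability(cells$library_complexity, cells$usable_reads)
  nonzero_cells <- Matrix::colSums(matrix$counts) > 0
  if (any(s == 0 & nonzero_cells))
    stop("cell(s) with zero sequencing probability but nonzero counts: ",
         paste(head(cells$barcode[s == 0 & nonzero_cells], 3), collapse = ", "))
  denom <- sum(cells$library_complexity * s)
  if (denom <= 0) stop("denominator sum(C_j * s_j) must be > 0")
  rs <- Matrix::rowSums(matrix$counts)
  a <- rs / denom
  if (sum(a) <= 0) stop("all counts are zero over the requested cell subset")
  setNames(1e6 * a / sum(a), matrix$peaks$id)
}

#' Relative percent-of-cells statistics
#'
#' For a partitioning S of the cells and a background peak set P, computes
#' per partition i and peak j: `m_ij`, the fraction of cells of the partition
#' with at least one read in the peak; the within-partition score
#' `s_ij = 1e6 * m_ij / sum_{j in P} m_ij`; and the cross-partition relative
#' ratio `RS_ij = s_ij / sum_i s_ij`. Normalizing by cell fractions rather
#' than reads corrects for differential read depth between partitions.
#' Peaks with `m = 0` in every partition have undefined RS, reported as NA
#' (never 0 — that would fake evidence of absence).
#'
#' @param matrix a `PeakMatrix`.
#' @param partitions either the name of a column of `matrix$cells` (e.g.
#'   `"cluster"`, `"donor_id"`, `"age_group"`) or a named list of barcode
#'   vectors; partitions must be disjoint and nonempty.
#' @param background_peaks peak ids defining the background set P
#'   (default: all peaks). Must contain the peaks of interest.
#' @return object of class `cell_fraction_table`: list of matrices `m`, `s`,
#'   `RS` (partitions x peaks).
#' @export
cell_fraction_table <- function(matrix, partitions,
                                background_peaks = NULL) {
  cells <- matrix$cells
  if (is.character(partitions) && length(partitions) == 1 &&
      partitions %in% names(cells)) {
    f <- cells[[partitions]]
    parts <- split(cells$barcode, f)
  } else if (is.list(partitions)) {
    parts <- partitions
    if (anyDuplicated(unlist(parts))) stop("partitions must be disjoint")
  } else stop("partitions must be a cell metadata column name or a list")
  if (any(lengths(parts) == 0)) stop("partition with zero cells")
  if (is.null(background_peaks)) background_peaks <- matrix$peaks$id
  if (!all(background_peaks %in% matrix$peaks$id))
    stop("background peaks absent from the matrix")
  sub <- matrix[background_peaks, ]
  bin <- sub$counts >= 1
  m <- do.call(rbind, lapply(parts, function(bcs) {
    j <- match(bcs, sub$cells$barcode)
    if (anyNA(j)) stop("unknown barcode in partition")
    Matrix::rowSums(bin[, j, drop = FALSE]) / length(j)
  }))
  colnames(m) <- background_peaks
  row_tot <- rowSums(m)
  s <- 1e6 * m / row_tot
  s[row_tot == 0, ] <- NA_real_
  col_tot <- colSums(s)
  RS <- sweep(s, 2, col_tot, "/")
  RS[, !is.na(col_tot) & col_tot == 0] <- NA_real_
  structure(list(m = m, s = s, RS = RS), class = "cell_fraction_table")
}

#' @export
print.cell_fraction_table <- function(x, ...) {
  cat("cell_fraction_table:", nrow(x$m), "partitions x", ncol(x$m),
      "peaks\n")
  invisible(x)
}
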