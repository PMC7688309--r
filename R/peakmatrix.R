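#' Construct a peak set
#'
#' Peaks are pseudo-loci: called accessible regions treated as single countable
#' units (conceptually, the set of minimal enzyme-accessible loci they span).
#' Coordinates are 0-based half-open (BED convention); accessibility is
#' unstranded, so no strand is stored.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start < end`, 0-based half-open.
#' @param id unique peak identifiers; default `chrom:start-end`.
#' @return data.frame with columns chrom, start, end, id.
#' @export
peak_set <- function(chrom, start, end, id = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, start, end)
  if (any(start >= end)) stop("peak start must be < end")
  if (any(start < 0)) stop("peak start must be >= 0")
  if (anyDuplicated(id)) stop("peak ids must be unique")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             id = as.character(id), stringsAsFactors = FALSE)
}

#' Construct per-cell metadata records
#'
#' @param barcode unique cell barcodes.
#' @param donor_id donor identifiers.
#' @param age_group one of `"30wkGA"`, `"3yo"`, `"30yo"`.
#' @param sex `"M"` or `"F"`.
#' @param cluster cell-type label.
#' @param usable_reads unique non-mitochondrial read count k_j (>= 0).
#' @param library_complexity estimated distinct molecules C_j (>= 1).
#' @param dataset_id optional technical batch label (defaults to donor_id).
#' @return data.frame of cell records.
#' @export
cell_records <- function(barcode, donor_id, age_group, sex, cluster,
                         usable_reads, library_complexity,
                         dataset_id = donor_id) {
  if (anyDuplicated(barcode)) stop("duplicate barcodes")
  if (!all(age_group %in% AGE_GROUPS))
    stop("age_group must be one of: ", paste(AGE_GROUPS, collapse = ", "))
  usable_reads <- as.numeric(usable_reads)
  library_complexity <- as.numeric(library_complexity)
  if (any(usable_reads < 0)) stop("usable_reads must be >= 0")
  if (any(library_complexity < 1)) stop("library_complexity must be >= 1")
  data.frame(barcode = as.character(barcode), donor_id = as.character(donor_id),
             age_group = as.character(age_group), sex = as.character(sex),
             cluster = as.character(cluster), usable_reads = usable_reads,
             library_complexity = library_complexity,
             dataset_id = as.character(dataset_id), stringsAsFactors = FALSE)
}

#' Peak-by-cell count matrix container
#'
#' Bundles a sparse non-negative integer count matrix O (peaks x cells) with
#' its peak set and cell metadata.
#'
#' @param counts matrix or sparse Matrix of non-negative integers
#'   (peaks x cells).
#' @param peaks data.frame from [peak_set()].
#' @param cells data.frame from [cell_records()].
#' @return an object of class `PeakMatrix`.
#' @export
peak_matrix <- function(counts, peaks, cells) {
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(counts * 1, sparse = TRUE)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != nrow(peaks))
    stop("counts has ", nrow(counts), " rows but ", nrow(peaks), " peaks")
  if (ncol(counts) != nrow(cells))
    stop("counts has ", ncol(counts), " columns but ", nrow(cells), " cells")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  if (anyDuplicated(cells$barcode)) stop("duplicate barcodes")
  if (anyDuplicated(peaks$id)) stop("duplicate peak ids")
  rownames(counts) <- peaks$id
  colnames(counts) <- cells$barcode
  structure(list(counts = counts, peaks = peaks, cells = cells),
            class = "PeakMatrix")
}

#' @export
dim.PeakMatrix <- function(x) dim(x$counts)

#' @export
print.PeakMatrix <- function(x, ...) {
  cat("PeakMatrix:", nrow(x$counts), "peaks x", ncol(x$counts), "cells;",
      length(x$counts@x), "nonzero entries\n")
  invisible(x)
}

#' Subset a PeakMatrix by peaks and/or cells
#'
#' @param x a `PeakMatrix`.
#' @param i peak index (integer, logical, or peak id).
#' @param j cell index (integer, logical, or barcode).
#' @param ... ignored.
#' @return a `PeakMatrix`.
#' @export
`[.PeakMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$peaks$id)
  if (is.character(j)) j <- match(j, x$cells$barcode)
  peak_matrix(x$counts[i, j, drop = FALSE],
              x$peaks[i, , drop = FALSE],
              x$cells[j, , drop = FALSE])
}

#' Peaks of a PeakMatrix as a GRanges
#'
#' @param x a `PeakMatrix` or a peak data.frame.
#' @return a [GenomicRanges::GRanges] (1-based closed internally, converted
#'   from the stored 0-based half-open coordinates).
#' @export
peaks_granges <- function(x) {
  pk <- if (inherits(x, "PeakMatrix")) x$peaks else x
  GenomicRanges::GRanges(pk$chrom,
                         IRanges::IRanges(start = pk$start + 1L, end = pk$end),
                         id = pk$id)
}
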