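#' Gene-by-nucleus UMI matrix container
#'
#' @param counts matrix or sparse Matrix of non-negative integer UMI counts
#'   (genes x nuclei).
#' @param genes gene identifiers (length nrow).
#' @param cells data.frame with columns barcode, donor_id, age_group,
#'   cluster (one row per nucleus).
#' @param normalized internal flag; TRUE after [lognormalize()].
#' @return object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, genes, cells, normalized = FALSE) {
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(counts * 1, sparse = TRUE)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(genes)) stop("genes length mismatch")
  if (ncol(counts) != nrow(cells)) stop("cells mismatch")
  x <- counts@x
  if (!normalized && length(x) && (any(x < 0) || any(x != round(x))))
    stop("UMI counts must be non-negative integers")
  if (anyDuplicated(cells$barcode)) stop("duplicate barcodes")
  rownames(counts) <- genes
  colnames(counts) <- cells$barcode
  structure(list(counts = counts, genes = as.character(genes),
                 cells = cells, normalized = normalized),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "nuclei", if (x$normalized) "(log-normalized)", "\n")
  invisible(x)
}

#' Read a gene-by-nucleus matrix triplet
#'
#' @param matrix_path MatrixMarket file.
#' @param genes_path one gene id per line (no header).
#' @param barcodes_path TSV with header: barcode, donor_id, age_group,
#'   cluster.
#' @return an `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(matrix_path, genes_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  bc <- read.delim(barcodes_path, stringsAsFactors = FALSE)
  if (nrow(m) != length(genes) || ncol(m) != nrow(bc))
    stop("dimension mismatch between matrix, genes and barcodes")
  expression_matrix(m, genes, bc)
}

#' Write a gene-by-nucleus matrix triplet
#' @param x an `ExpressionMatrix`.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @export
write_expression_matrix <- function(x, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("expr.mtx", "genes.tsv",
                                           "expr_barcodes.tsv")))
  Matrix::writeMM(x$counts, paths[1])
  writeLines(x$genes, paths[2])
  write.table(x$cells, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Quality-filter an expression matrix
#'
#' Keeps genes detected (>= 1 UMI) in at least `min_cells_per_gene` nuclei,
#' then nuclei whose detected-gene count lies in
#' `[min_genes, max_genes]` (inclusive). The gene filter is applied before
#' the cell filter; the operation is idempotent.
#'
#' @param matrix an `ExpressionMatrix` of raw counts.
#' @param min_cells_per_gene default 3.
#' @param min_genes,max_genes detected-gene bounds per nucleus
#'   (defaults 500 and 4000).
#' @return filtered `ExpressionMatrix`.
#' @export
qc_expression <- function(matrix, min_cells_per_gene = 3, min_genes = 500,
                          max_genes = 4000) {
  B <- matrix$counts >= 1
  gk <- Matrix::rowSums(B) >= min_cells_per_gene
  B <- B[gk, , drop = FALSE]
  det <- Matrix::colSums(B)
  ck <- det >= min_genes & det <= max_genes
  expression_matrix(matrix$counts[gk, ck, drop = FALSE],
                    matrix$genes[gk], matrix$cells[ck, , drop = FALSE])
}

#' Log-normalize UMI counts
#'
#' `x -> ln(1 + scale * x / total)` per nucleus; nuclei with zero totals
#' must be removed beforehand (QC does this).
#'
#' @param matrix an `ExpressionMatrix` of raw counts.
#' @param scale scaling factor (default 10000).
#' @return an `ExpressionMatrix` with `normalized = TRUE`.
#' @export
lognormalize <- function(matrix, scale = 10000) {
  tot <- Matrix::colSums(matrix$counts)
  if (any(tot == 0)) stop("nucleus with zero total UMI count; run QC first")
  norm <- matrix$counts %*% Matrix::Diagonal(x = scale / tot)
  norm@x <- log1p(norm@x)
  expression_matrix(norm, matrix$genes, matrix$cells, normalized = TRUE)
}

#' Fraction of nuclei expressing a gene, per group
#'
#' A nucleus "expresses" a gene iff it has at least one UMI for it.
#' Fractions are reported at full precision; any display rounding belongs to
#' the report layer.
#'
#' @param matrix an `ExpressionMatrix` (raw counts).
#' @param gene gene id.
#' @param grouping cell metadata column (e.g. "cluster", "donor_id") or a
#'   vector of group labels per nucleus.
#' @return data.frame(gene, group, n_expressing, n_total, fraction).
#' @export
expressing_fraction <- function(matrix, gene, grouping = "cluster") {
  gi <- match(gene, matrix$genes)
  if (is.na(gi)) stop("gene not found: ", gene)
  expr <- as.numeric(matrix$counts[gi, ]) >= 1
  g <- if (length(grouping) == 1 && grouping %in% names(matrix$cells))
    matrix$cells[[grouping]] else grouping
  tab <- lapply(split(expr, g), function(e)
    c(n_expressing = sum(e), n_total = length(e)))
  out <- data.frame(gene = gene, group = names(tab),
                    do.call(rbind, tab), stringsAsFactors = FALSE)
  out$fraction <- out$n_expressing / out$n_total
  rownames(out) <- NULL
  out
}

#' Age-group t-tests on per-donor expressing fractions
#'
#' Unpaired two-tailed t-tests on per-donor fractions between each pair of
#' age groups. Pooled (equal-variance) by default; Welch available.
#'
#' @param donor_fractions data.frame with columns donor_id, age_group,
#'   fraction (one row per donor).
#' @param var_equal pooled-variance t when TRUE (default), Welch otherwise.
#' @return data.frame(groupA, groupB, t, p).
#' @export
fraction_age_test <- function(donor_fractions, var_equal = TRUE) {
  gs <- intersect(AGE_GROUPS, unique(donor_fractions$age_group))
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pair) {
    a <- donor_fractions$fraction[donor_fractions$age_group == pair[1]]
    b <- donor_fractions$fraction[donor_fractions$age_group == pair[2]]
    if (length(a) < 2 || length(b) < 2)
      stop("need >= 2 donors per age group")
    if (var_equal) {
      tp <- pooled_t(a, b)
      data.frame(groupA = pair[1], groupB = pair[2], t = tp[["t"]],
                 p = tp[["p"]])
    } else {
      ht <- stats::t.test(a, b)
      data.frame(groupA = pair[1], groupB = pair[2],
                 t = unname(ht$statistic), p = ht$p.value)
    }
  })
  do.call(rbind, rows)
}

#' Median normalized expression among expressing nuclei of one sample
#'
#' @param matrix a log-normalized `ExpressionMatrix`.
#' @param gene gene id.
#' @param sample donor id (matched against `donor_id`).
#' @return median of normalized values over the sample's nuclei with at
#'   least one UMI; `NA` if none.
#' @export
median_expressing <- function(matrix, gene, sample) {
  if (!matrix$normalized) stop("matrix must be log-normalized")
  gi <- match(gene, matrix$genes)
  if (is.na(gi)) stop("gene not found: ", gene)
  v <- as.numeric(matrix$counts[gi, matrix$cells$donor_id == sample])
  v <- v[v > 0]
  if (!length(v)) return(NA_real_)
  median(v)
}
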