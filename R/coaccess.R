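#' Aggregate cells into metacells
#'
#' Sparse per-cell accessibility is densified by aggregating each sampled
#' seed cell with its nearest neighbors. Unless an embedding is supplied, a
#' TF-IDF transform of the binarized matrix followed by a truncated SVD
#' (`n_dims` components) is computed internally; neighbors are taken by
#' cosine similarity. A candidate metacell is rejected when it shares more
#' than `overlap_cap` of its members with any accepted metacell. Aggregated
#' values are sums of binarized cell values.
#'
#' @param matrix a `PeakMatrix`.
#' @param k_neighbors metacell size (seed + k-1 neighbors; default 50).
#' @param seed integer seed controlling seed-cell order.
#' @param embedding optional cells x dims numeric matrix.
#' @param n_dims truncated-SVD dimensionality (default 30).
#' @param overlap_cap maximum member-sharing fraction (default 0.10).
#' @return object of class `MetacellMatrix`: aggregated counts
#'   (peaks x metacells), member map, per-metacell totals, and the peak set.
#' @export
build_metacells <- function(matrix, k_neighbors = 50, seed = 1,
                            embedding = NULL, n_dims = 30,
                            overlap_cap = 0.10) {
  n <- ncol(matrix$counts)
  if (n < k_neighbors)
    stop("fewer cells (", n, ") than k_neighbors (", k_neighbors, ")")
  B <- matrix$counts > 0
  if (is.null(embedding)) embedding <- lsi_embedding(B, n_dims)
  nrm <- sqrt(rowSums(embedding^2))
  nrm[nrm == 0] <- 1
  E <- embedding / nrm
  order_seeds <- with_stream(seed, "metacell_seeds", sample.int(n))
  accepted <- list()
  max_share <- floor(overlap_cap * k_neighbors)
  for (s in order_seeds) {
    sims <- as.numeric(E %*% E[s, ])
    members <- order(sims, decreasing = TRUE)[seq_len(k_neighbors)]
    if (!(s %in% members)) members[k_neighbors] <- s
    ok <- TRUE
    for (a in accepted)
      if (length(intersect(a, members)) > max_share) { ok <- FALSE; break }
    if (ok) accepted[[length(accepted) + 1L]] <- sort(members)
  }
  counts <- vapply(accepted, function(m)
    Matrix::rowSums(B[, m, drop = FALSE]), numeric(nrow(B)))
  counts <- matrix(counts, nrow = nrow(B),
                   dimnames = list(matrix$peaks$id, NULL))
  members <- lapply(accepted, function(m) matrix$cells$barcode[m])
  structure(list(counts = counts, members = members,
                 totals = colSums(counts), peaks = matrix$peaks,
                 k_neighbors = k_neighbors),
            class = "MetacellMatrix")
}

#' @export
print.MetacellMatrix <- function(x, ...) {
  cat("MetacellMatrix:", nrow(x$counts), "peaks x", ncol(x$counts),
      "metacells (k =", x$k_neighbors, ")\n")
  invisible(x)
}

# TF-IDF + truncated SVD embedding of a binarized peak-by-cell matrix,
# computed through the eigendecomposition of the cell-cell Gram matrix.
lsi_embedding <- function(B, n_dims = 30) {
  X <- Matrix::t(B * 1)
  depth <- Matrix::rowSums(X)
  depth[depth == 0] <- 1
  tf <- X / depth
  idf <- log(1 + nrow(X) / (1 + Matrix::colSums(X)))
  tfidf <- tf %*% Matrix::Diagonal(x = idf)
  K <- as.matrix(Matrix::tcrossprod(tfidf))
  eg <- eigen(K, symmetric = TRUE)
  d <- min(n_dims, sum(eg$values > 1e-10))
  eg$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(d)], 0)), d)
}

peak_mid <- function(peaks) (peaks$start + peaks$end) / 2

# Sliding windows (50% overlap) over the peak territory of each chromosome.
# Returns a data.frame(chrom, start, end); only windows holding >= 2 peak
# midpoints are kept.
tile_windows <- function(peaks, window_bp, step = window_bp / 2) {
  mids <- peak_mid(peaks)
  out <- list()
  for (ch in unique(peaks$chrom)) {
    m <- mids[peaks$chrom == ch]
    lo <- floor(min(m) / step) * step
    starts <- seq(lo, max(m), by = step)
    for (s in starts) {
      inw <- sum(m >= s & m < s + window_bp)
      if (inw >= 2)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = s,
                                              end = s + window_bp)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = numeric(),
                                      end = numeric()))
  do.call(rbind, out)
}

#' Distance-penalized co-accessibility within one genomic window
#'
#' Metacell counts are depth-normalized (divided by the metacell total over
#' all peaks, rescaled by the median total), then each peak is centered and
#' scaled. The precision matrix maximizing
#' `log det(Theta) - tr(S Theta) - sum_{a!=b} rho_ab |Theta_ab|` with
#' `rho_ab = lambda0 * sqrt(d_ab / window_bp)` is estimated, and the
#' co-accessibility score of a pair is its partial correlation
#' `-Theta_ab / sqrt(Theta_aa Theta_bb)`. Pairs spanning the window boundary
#' receive no score from this window.
#'
#' @param metacells a `MetacellMatrix`.
#' @param window list or one-row data.frame with chrom, start, end.
#' @param lambda0 penalty scale (see [calibrate_penalty()]).
#' @param window_bp distance scale of the penalty (default: window width).
#' @return data.frame(peak_a, peak_b, distance, score) over unordered peak
#'   pairs inside the window, anchors in genome order.
#' @export
window_coaccessibility <- function(metacells, window, lambda0,
                                   window_bp = NULL) {
  if (ncol(metacells$counts) < 10)
    stop("need >= 10 metacells, got ", ncol(metacells$counts))
  window_bp <- window_bp %||% (window$end - window$start)
  pk <- metacells$peaks
  mids <- peak_mid(pk)
  idx <- which(pk$chrom == window$chrom & mids >= window$start &
                 mids < window$end)
  if (length(idx) < 2)
    stop("fewer than 2 peaks in window")
  idx <- idx[order(mids[idx])]
  tot <- metacells$totals
  tot[tot == 0] <- 1
  X <- t(metacells$counts[idx, , drop = FALSE]) / tot * median(tot)
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) {
    idx <- idx[keep]
    if (length(idx) < 2) return(empty_pairs())
    X <- X[, keep, drop = FALSE]
  }
  S <- cov(scale(X))
  D <- abs(outer(mids[idx], mids[idx], "-"))
  Rho <- lambda0 * sqrt(D / window_bp)
  diag(Rho) <- 0
  R <- partial_cor(glasso_fit(S, Rho))
  ut <- which(upper.tri(R), arr.ind = TRUE)
  data.frame(peak_a = pk$id[idx][ut[, 1]], peak_b = pk$id[idx][ut[, 2]],
             distance = D[ut], score = R[ut], stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(peak_a = character(), peak_b = character(),
             distance = numeric(), score = numeric())
}

#' Calibrate the distance-penalty scale
#'
#' Finds (by 20 bisection steps) the smallest `lambda0` such that, over a
#' sample of at most `max_windows` windows, the fraction of nonzero partial
#' correlations among pairs separated by more than `window_bp / 2` is at
#' most `target_far_sparsity`.
#'
#' @param metacells a `MetacellMatrix`.
#' @param window_bp window width in bp.
#' @param target_far_sparsity tolerated far-pair nonzero fraction
#'   (default 0.05).
#' @param seed seed for the window sample.
#' @param max_windows windows used for calibration (default 20).
#' @return penalty scale `lambda0`.
#' @export
calibrate_penalty <- function(metacells, window_bp,
                              target_far_sparsity = 0.05, seed = 1,
                              max_windows = 20) {
  wins <- tile_windows(metacells$peaks, window_bp)
  if (nrow(wins)) {
    mids <- peak_mid(metacells$peaks)
    has_far <- vapply(seq_len(nrow(wins)), function(i) {
      m <- mids[metacells$peaks$chrom == wins$chrom[i] &
                  mids >= wins$start[i] & mids < wins$end[i]]
      length(m) >= 2 && (max(m) - min(m)) > window_bp / 2
    }, logical(1))
    wins <- wins[has_far, , drop = FALSE]
  }
  if (!nrow(wins))
    stop("calibration error: no window contains a far peak pair")
  if (nrow(wins) > max_windows) {
    pick <- with_stream(seed, "calibrate_penalty",
                        sample.int(nrow(wins), max_windows))
    wins <- wins[pick, , drop = FALSE]
  }
  far_frac <- function(lambda0) {
    nz <- 0L; far <- 0L
    for (i in seq_len(nrow(wins))) {
      sc <- window_coaccessibility(metacells, wins[i, ], lambda0, window_bp)
      isfar <- sc$distance > window_bp / 2
      far <- far + sum(isfar)
      nz <- nz + sum(isfar & abs(sc$score) > 1e-8)
    }
    if (far == 0) 0 else nz / far
  }
  hi <- 0.01
  while (far_frac(hi) > target_far_sparsity && hi < 1e4) hi <- hi * 2
  lo <- 0
  for (i in seq_len(20)) {
    mid <- (lo + hi) / 2
    if (far_frac(mid) <= target_far_sparsity) hi <- mid else lo <- mid
  }
  hi
}

#' Ensemble co-accessibility analysis
#'
#' Runs one window-scored analysis per cluster (window `window_cluster`) plus
#' `subset_runs` analyses on random cell subsets of size
#' `min(subset_size, n_cells)` (window `window_subset`). Within a run, a pair
#' scored in several overlapping windows receives the mean; across runs,
#' links are merged by pair identity into score arrays. A pair absent from a
#' run is missing from that run's array, not zero.
#'
#' @param matrix a `PeakMatrix`.
#' @param clusters cell metadata column holding cluster labels
#'   (default "cluster").
#' @param window_cluster window size for per-cluster runs (default 1e6 bp).
#' @param window_subset window size for subset runs (default 250000 bp).
#' @param subset_runs number of random-subset runs (default 5).
#' @param subset_size cells per subset run (default 15000).
#' @param k_neighbors metacell size (default 50).
#' @param lambda0 penalty scale; calibrated per window size when NULL.
#' @param include_cluster_runs pool per-cluster runs into the score arrays
#'   (default TRUE; FALSE gives subset-only arrays).
#' @param seed master seed.
#' @return data.frame of links with list column `scores`, plus coordinates,
#'   `n_runs` and `mean_score`.
#' @export
run_ensemble <- function(matrix, clusters = "cluster",
                         window_cluster = 1e6, window_subset = 250000,
                         subset_runs = 5, subset_size = 15000,
                         k_neighbors = 50, lambda0 = NULL,
                         include_cluster_runs = TRUE, seed = 1) {
  runs <- list()
  if (include_cluster_runs) {
    for (cl in sort(unique(matrix$cells[[clusters]]))) {
      j <- which(matrix$cells[[clusters]] == cl)
      if (length(j) < k_neighbors) {
        message("skipping cluster ", cl, ": fewer cells than k_neighbors")
        next
      }
      runs[[length(runs) + 1L]] <- list(cells = j, window = window_cluster,
                                        name = paste0("cluster_", cl))
    }
  }
  n <- ncol(matrix$counts)
  for (r in seq_len(subset_runs)) {
    j <- with_stream(seed, paste0("subset_", r),
                     sample.int(n, min(subset_size, n)))
    runs[[length(runs) + 1L]] <- list(cells = j, window = window_subset,
                                      name = paste0("subset_", r))
  }
  lam_cache <- list()
  per_run <- list()
  for (run in runs) {
    mc <- build_metacells(matrix[, run$cells], k_neighbors = k_neighbors,
                          seed = sub_seed(seed, run$name))
    if (ncol(mc$counts) < 10) {
      message("skipping run ", run$name, ": only ", ncol(mc$counts),
              " metacells (need >= 10)")
      next
    }
    key <- as.character(run$window)
    lam <- lambda0
    if (is.null(lam)) {
      if (is.null(lam_cache[[key]]))
        lam_cache[[key]] <- calibrate_penalty(mc, run$window, seed = seed)
      lam <- lam_cache[[key]]
    }
    wins <- tile_windows(mc$peaks, run$window)
    sc <- lapply(seq_len(nrow(wins)), function(i)
      window_coaccessibility(mc, wins[i, ], lam, run$window))
    sc <- do.call(rbind, sc)
    if (is.null(sc) || !nrow(sc)) next
    agg <- stats::aggregate(score ~ peak_a + peak_b + distance, data = sc,
                            FUN = mean)
    per_run[[run$name]] <- agg
  }
  if (!length(per_run)) return(cbind(empty_pairs(), n_runs = integer(),
                                     mean_score = numeric()))
  all_sc <- do.call(rbind, per_run)
  key <- paste(all_sc$peak_a, all_sc$peak_b, sep = "\r")
  split_sc <- split(all_sc$score, key)
  keys <- names(split_sc)
  first <- all_sc[match(keys, key), c("peak_a", "peak_b", "distance")]
  pk <- matrix$peaks
  ia <- match(first$peak_a, pk$id); ib <- match(first$peak_b, pk$id)
  out <- data.frame(
    peak_a = first$peak_a, peak_b = first$peak_b,
    chrom_a = pk$chrom[ia], start_a = pk$start[ia], end_a = pk$end[ia],
    chrom_b = pk$chrom[ib], start_b = pk$start[ib], end_b = pk$end[ib],
    distance = first$distance,
    n_runs = lengths(split_sc),
    mean_score = vapply(split_sc, mean, numeric(1)),
    stringsAsFactors = FALSE)
  out$scores <- unname(split_sc)
  rownames(out) <- NULL
  out[order(out$chrom_a, out$start_a, out$start_b), ]
}

#' Merge-test co-accessibility links
#'
#' One-sample two-sided t-test of each link's score array against 0; a link
#' is retained when `p < alpha`. Links observed in fewer than `min_runs`
#' runs are dropped. A zero-variance array with nonzero mean yields p = 0
#' (retained); with zero mean, p = 1.
#'
#' @param links link table from [run_ensemble()].
#' @param alpha retention threshold on the t-test p-value (default 0.10).
#' @param min_runs minimum number of score observations (default 2).
#' @return the link table with `t_stat`, `t_p` and `retained` columns.
#' @export
test_links <- function(links, alpha = 0.10, min_runs = 2) {
  links <- links[links$n_runs >= min_runs, , drop = FALSE]
  tt <- vapply(links$scores, function(s) {
    m <- mean(s); sdv <- sd(s)
    if (sdv == 0) {
      if (m == 0) c(0, 1) else c(sign(m) * Inf, 0)
    } else {
      t <- m / (sdv / sqrt(length(s)))
      c(t, 2 * pt(-abs(t), df = length(s) - 1))
    }
  }, numeric(2))
  links$t_stat <- if (nrow(links)) tt[1, ] else numeric(0)
  links$t_p <- if (nrow(links)) tt[2, ] else numeric(0)
  links$retained <- links$t_p < alpha
  links
}

#' Link retained co-accessible pairs to gene promoters
#'
#' Promoters are the 1000-bp regions centered on each protein-coding TSS
#' (TSS +/- `flank`). A link is reported for a gene when exactly one of its
#' anchors overlaps the gene's promoter, the link is retained, and its mean
#' score strictly exceeds `min_score`.
#'
#' @param links tested link table ([test_links()]).
#' @param promoter_table data.frame with gene, chrom, tss (0-based), strand,
#'   biotype.
#' @param min_score strict lower bound on mean score (default 0.05).
#' @param flank half-width of the promoter (default 500 bp).
#' @return data.frame(gene, promoter_peak, distal_peak, mean_score, t_p).
#' @export
link_promoters <- function(links, promoter_table, min_score = 0.05,
                           flank = 500) {
  skipped <- unique(promoter_table$gene[
    !promoter_table$gene %in%
      promoter_table$gene[promoter_table$biotype == "protein_coding"]])
  if (length(skipped))
    message("skipping gene(s) without protein-coding TSS: ",
            paste(skipped, collapse = ", "))
  pr <- promoter_table[promoter_table$biotype == "protein_coding", ,
                       drop = FALSE]
  keep <- links$retained & links$mean_score > min_score
  links <- links[keep, , drop = FALSE]
  if (!nrow(links) || !nrow(pr))
    return(data.frame(gene = character(), promoter_peak = character(),
                      distal_peak = character(), mean_score = numeric(),
                      t_p = numeric()))
  prg <- GenomicRanges::GRanges(pr$chrom,
                                IRanges::IRanges(start = pr$tss - flank + 1L,
                                                 end = pr$tss + flank))
  ga <- GenomicRanges::GRanges(links$chrom_a,
                               IRanges::IRanges(links$start_a + 1L,
                                                links$end_a))
  gb <- GenomicRanges::GRanges(links$chrom_b,
                               IRanges::IRanges(links$start_b + 1L,
                                                links$end_b))
  ha <- GenomicRanges::findOverlaps(ga, prg)
  hb <- GenomicRanges::findOverlaps(gb, prg)
  rows <- list()
  for (g in unique(pr$gene)) {
    pidx <- which(pr$gene == g)
    a_hit <- unique(S4Vectors::queryHits(ha)[
      S4Vectors::subjectHits(ha) %in% pidx])
    b_hit <- unique(S4Vectors::queryHits(hb)[
      S4Vectors::subjectHits(hb) %in% pidx])
    only_a <- setdiff(a_hit, b_hit)
    only_b <- setdiff(b_hit, a_hit)
    if (length(only_a))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, promoter_peak = links$peak_a[only_a],
        distal_peak = links$peak_b[only_a],
        mean_score = links$mean_score[only_a], t_p = links$t_p[only_a])
    if (length(only_b))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, promoter_peak = links$peak_b[only_b],
        distal_peak = links$peak_a[only_b],
        mean_score = links$mean_score[only_b], t_p = links$t_p[only_b])
  }
  if (!length(rows))
    return(data.frame(gene = character(), promoter_peak = character(),
                      distal_peak = character(), mean_score = numeric(),
                      t_p = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
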