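#' Pseudobulk a PeakMatrix by donor within one cell type
#'
#' Sums counts over the cells of the given cluster per donor. Donors without
#' cells of the type are excluded with a message. Per-donor totals over all
#' peaks are stored as model offsets.
#'
#' @param matrix a `PeakMatrix`.
#' @param cell_type cluster label to pseudobulk.
#' @param cluster_col cell metadata column holding cluster labels.
#' @return object of class `PseudobulkTable`: counts (peaks x donors),
#'   donor metadata, per-donor totals.
#' @export
pseudobulk <- function(matrix, cell_type, cluster_col = "cluster") {
  cells <- matrix$cells
  sel <- cells[[cluster_col]] == cell_type
  if (!any(sel)) stop("no cells of type ", cell_type)
  all_donors <- sort(unique(cells$donor_id))
  donors <- sort(unique(cells$donor_id[sel]))
  dropped <- setdiff(all_donors, donors)
  if (length(dropped))
    message("excluding donor(s) without ", cell_type, " cells: ",
            paste(dropped, collapse = ", "))
  counts <- vapply(donors, function(d) {
    j <- which(sel & cells$donor_id == d)
    Matrix::rowSums(matrix$counts[, j, drop = FALSE])
  }, numeric(nrow(matrix$counts)))
  counts <- matrix(counts, nrow = nrow(matrix$counts),
                   dimnames = list(matrix$peaks$id, donors))
  meta <- unique(cells[sel, c("donor_id", "age_group", "sex", "dataset_id")])
  meta <- meta[match(donors, meta$donor_id), ]
  rownames(meta) <- NULL
  structure(list(counts = counts, donors = meta,
                 totals = colSums(counts), cell_type = cell_type),
            class = "PseudobulkTable")
}

#' @export
print.PseudobulkTable <- function(x, ...) {
  cat("PseudobulkTable:", nrow(x$counts), "peaks x", ncol(x$counts),
      "donors (", x$cell_type, ")\n")
  invisible(x)
}

# Shrunken per-peak NB dispersion. Per-peak evidence is the Cox-Reid
# adjusted profile likelihood APL_i(alpha) (the adjustment compensates for
# the coefficients estimated per peak, which would otherwise bias plain MLEs
# far downward at n ~ 6); the shrinkage is applied on the likelihood scale:
# each peak maximizes (1 - shrink) * APL_i + shrink * trend, where the trend
# is the trimmed mean of the per-peak APL curves across peaks. Sharing
# likelihood rather than point estimates keeps peaks whose own profile is
# flat (apparently Poisson at tiny n) from collapsing to zero dispersion.
# The default weight follows the prior-degrees-of-freedom convention,
# shrink = prior_df / (prior_df + residual df), so shrinkage strengthens as
# replication weakens; prior_df = 10.
estimate_dispersions <- function(y, X, off, shrink = NULL, trim = 0.1,
                                 prior_df = 10,
                                 grid = seq(-7, 3, length.out = 15)) {
  if (is.null(shrink)) {
    d_resid <- max(ncol(y) - ncol(X), 0)
    shrink <- prior_df / (prior_df + d_resid)
  }
  apl_at <- function(yi, la) {
    al <- exp(la)
    fam <- MASS::negative.binomial(theta = 1 / al)
    ft <- suppressWarnings(stats::glm.fit(X, yi, offset = off,
                                          family = fam))
    m <- ft$fitted.values
    w <- m / (1 + al * m)
    ll <- sum(stats::dnbinom(yi, mu = m, size = 1 / al, log = TRUE))
    cr <- 0.5 * determinant(crossprod(X * sqrt(w)),
                            logarithm = TRUE)$modulus
    ll - as.numeric(cr)
  }
  A <- t(vapply(seq_len(nrow(y)), function(i)
    vapply(grid, function(la) apl_at(y[i, ], la), numeric(1)),
    numeric(length(grid))))
  trend <- apply(A, 2, mean, trim = trim)
  vapply(seq_len(nrow(y)), function(i) {
    f <- stats::splinefun(grid, (1 - shrink) * A[i, ] + shrink * trend)
    exp(optimize(function(la) -f(la), range(grid))$minimum)
  }, numeric(1))
}

#' Pairwise negative-binomial differential accessibility test
#'
#' Per-peak NB log-linear model of pseudobulk counts on age group plus
#' technical covariates, with the log per-donor total as offset. Dispersions
#' are per-peak maximum-likelihood estimates shrunk 50/50 (on the log scale)
#' toward the trimmed mean across peaks; the group effect is assessed by a
#' likelihood-ratio test at the shrunken dispersion, with Benjamini-Hochberg
#' correction across tested peaks. All-zero peaks are excluded. Covariates
#' that are constant or aliased over the tested donors are dropped.
#'
#' @param pb a `PseudobulkTable`.
#' @param groupA,groupB age-group labels to compare.
#' @param covariates donor metadata columns used as technical covariates
#'   (default sex and dataset_id).
#' @return data.frame(peak_id, logFC (log2), lr, pvalue, fdr).
#' @export
nb_pairwise_test <- function(pb, groupA, groupB,
                             covariates = c("sex", "dataset_id")) {
  sel <- pb$donors$age_group %in% c(groupA, groupB)
  meta <- pb$donors[sel, , drop = FALSE]
  if (sum(meta$age_group == groupA) < 2 || sum(meta$age_group == groupB) < 2)
    stop("need >= 2 donors per group")
  y <- pb$counts[, sel, drop = FALSE]
  off <- log(pb$totals[sel])
  keep <- rowSums(y) > 0
  y <- y[keep, , drop = FALSE]
  group <- factor(meta$age_group, levels = c(groupA, groupB))
  covs <- list()
  for (cv in covariates) {
    v <- factor(meta[[cv]])
    if (nlevels(droplevels(v)) > 1) covs[[cv]] <- droplevels(v)
  }
  df_full <- data.frame(group = group)
  for (nm in names(covs)) df_full[[nm]] <- covs[[nm]]
  X_full <- stats::model.matrix(~ ., df_full)
  qrX <- qr(X_full)
  X_full <- X_full[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  grp_col <- grep("^group", colnames(X_full))
  if (!length(grp_col)) stop("group effect aliased with covariates")
  X_red <- X_full[, -grp_col, drop = FALSE]

  n_peak <- nrow(y)
  fit_mu <- function(X, yi, family) {
    suppressWarnings(stats::glm.fit(X, yi, offset = off, family = family))
  }
  alpha <- estimate_dispersions(y, X_full, off)
  res <- vapply(seq_len(n_peak), function(i) {
    fam <- MASS::negative.binomial(theta = 1 / alpha[i])
    ff <- fit_mu(X_full, y[i, ], fam)
    fr <- fit_mu(X_red, y[i, ], fam)
    lr <- max(fr$deviance - ff$deviance, 0)
    beta <- ff$coefficients[grp_col[1]]
    c(beta / log(2), lr, pchisq(lr, df = length(grp_col), lower.tail = FALSE))
  }, numeric(3))
  out <- data.frame(peak_id = rownames(y), logFC = res[1, ], lr = res[2, ],
                    pvalue = res[3, ], stringsAsFactors = FALSE)
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}

#' Union of age-dynamic peaks over pairwise comparisons
#'
#' @param results list of results from [nb_pairwise_test()], one per age
#'   pair.
#' @param fdr FDR threshold (default 0.05).
#' @return character vector of peak ids significant in any comparison.
#' @export
age_dynamic_union <- function(results, fdr = 0.05) {
  sort(unique(unlist(lapply(results, function(r)
    r$peak_id[r$fdr < fdr]))))
}

#' Davies-Bouldin index
#'
#' `R_xy = (s_x + s_y) / d_xy` with `s_x` the mean Euclidean distance of the
#' members of cluster x to its centroid and `d_xy` the distance between
#' centroids; `DB = (1/K) sum_x max_{y != x} R_xy`. Lower is better.
#' Coincident centroids give `DB = Inf`.
#'
#' @param points numeric matrix (observations x features).
#' @param labels cluster assignment (length nrow(points), >= 2 clusters,
#'   each nonempty).
#' @return the DB value.
#' @export
db_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2) stop("need >= 2 clusters")
  cent <- do.call(rbind, lapply(cls, function(cl)
    colMeans(points[labels == cl, , drop = FALSE])))
  s <- vapply(seq_along(cls), function(i) {
    P <- points[labels == cls[i], , drop = FALSE]
    mean(sqrt(rowSums((P - rep(cent[i, ], each = nrow(P)))^2)))
  }, numeric(1))
  d <- as.matrix(stats::dist(cent))
  K <- length(cls)
  R <- outer(s, s, "+") / d
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Select K for K-means temporal clustering by the Davies-Bouldin criterion
#'
#' Rows (per-peak accessibility profiles over age groups) are scaled to unit
#' sum, K-means is run for each K in `k_range` keeping the best-inertia
#' solution over `restarts` seeded starts, and the K minimizing the
#' Davies-Bouldin index is selected (ties broken toward smaller K).
#'
#' @param profiles numeric matrix, peaks x age groups.
#' @param k_range candidate cluster counts (default 5:8).
#' @param seed integer seed.
#' @param restarts K-means restarts per K (default 20).
#' @return list(K, labels, db = named DB values per K).
#' @export
select_k_kmeans <- function(profiles, k_range = 5:8, seed = 1,
                            restarts = 20) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < max(k_range))
    stop("fewer peaks than the largest K")
  rs <- rowSums(profiles)
  if (any(rs == 0)) stop("profile row(s) with zero sum")
  X <- profiles / rs
  fits <- list()
  db <- setNames(rep(NA_real_, length(k_range)), k_range)
  for (K in k_range) {
    km <- with_stream(seed, paste0("kmeans_", K),
                      kmeans(X, centers = K, nstart = restarts,
                             iter.max = 100))
    fits[[as.character(K)]] <- km
    db[as.character(K)] <- db_index(X, km$cluster)
  }
  best <- k_range[which.min(db)]  # which.min takes the first (smallest K) tie
  list(K = best, labels = fits[[as.character(best)]]$cluster, db = db)
}

# Pooled-variance two-sample t-test returning c(t, p); handles the
# zero-variance degenerate cases explicitly.
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) return(c(t = 0, p = 1))
    return(c(t = sign(dm) * Inf, p = 0))
  }
  t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  c(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

#' Locus-restricted equal-variance t-tests on per-donor cell fractions
#'
#' For each candidate peak and each pair of age groups, an independent
#' two-sample t-test with equal variance on the per-donor within-donor
#' fraction scores (the `s` statistic of [cell_fraction_table()] computed
#' with donors as partitions against the merged peak background). Raw
#' p-values are reported (locus-restricted mode; no multiplicity
#' correction), with significance marked at p < 0.05.
#'
#' @param fractions numeric matrix of per-donor scores (donors x peaks),
#'   e.g. `t(cell_fraction_table(m, "donor_id")$s[, candidate_ids])`.
#' @param donor_age_group age-group label per donor (rows of `fractions`).
#' @param age_pairs list of length-2 character vectors (default: all three
#'   pairs of the standard age groups present).
#' @return data.frame(peak_id, groupA, groupB, t, p, significant).
#' @export
locus_ttest <- function(fractions, donor_age_group, age_pairs = NULL) {
  fractions <- as.matrix(fractions)
  if (is.null(age_pairs)) {
    gs <- intersect(AGE_GROUPS, unique(donor_age_group))
    age_pairs <- utils::combn(gs, 2, simplify = FALSE)
  }
  rows <- list()
  for (pair in age_pairs) {
    ia <- which(donor_age_group == pair[1])
    ib <- which(donor_age_group == pair[2])
    if (length(ia) < 2 || length(ib) < 2)
      stop("need >= 2 donors per age group (", pair[1], " vs ", pair[2], ")")
    for (j in seq_len(ncol(fractions))) {
      tp <- pooled_t(fractions[ia, j], fractions[ib, j])
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = colnames(fractions)[j] %||% as.character(j),
        groupA = pair[1], groupB = pair[2], t = tp[["t"]], p = tp[["p"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out
}
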