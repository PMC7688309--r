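make_pb <- function(y, age, sex = NULL, ds = NULL) {
  n <- ncol(y)
  if (is.null(rownames(y))) rownames(y) <- sprintf("pk%04d", seq_len(nrow(y)))
  donors <- data.frame(donor_id = sprintf("d%02d", seq_len(n)),
                       age_group = age,
                       sex = sex %||% rep_len(c("M", "F"), n),
                       dataset_id = ds %||% rep_len(c("b1", "b2"), n),
                       stringsAsFactors = FALSE)
  colnames(y) <- donors$donor_id
  structure(list(counts = y, donors = donors, totals = colSums(y),
                 cell_type = "AT2"), class = "PseudobulkTable")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pseudobulk sums member cells per donor and ignores cell order", {
  counts <- cbind(c(1, 5), c(0, 2), c(2, 0), c(0, 1), c(0, 3))
  pm <- make_pm(counts, donor = c("d1", "d1", "d1", "d2", "d2"))
  pb <- pseudobulk(pm, "AT2")
  expect_equal(unname(pb$counts[1, ]), c(3, 0))
  expect_equal(unname(pb$counts[2, ]), c(7, 4))
  expect_equal(unname(pb$totals), unname(colSums(pb$counts)))
  perm <- c(4, 2, 5, 1, 3)
  pb2 <- pseudobulk(pm[, perm], "AT2")
  expect_equal(pb$counts, pb2$counts)
  # donor without cells of the type is excluded with a message
  pm$cells$cluster[4:5] <- "AT1"
  expect_message(pb3 <- pseudobulk(pm, "AT2"), "d2")
  expect_equal(ncol(pb3$counts), 1L)
})

test_that("NB pairwise test excludes zero peaks and enforces replication", {
  set.seed(3)
  y <- matrix(rnbinom(50 * 6, mu = 30, size = 5), 50, 6)
  y[7, ] <- 0
  pb <- make_pb(y, rep(c("30wkGA", "30yo"), each = 3))
  r <- nb_pairwise_test(pb, "30wkGA", "30yo", covariates = character(0))
  expect_false("pk0007" %in% r$peak_id)
  expect_equal(nrow(r), 49L)
  expect_true(all(r$pvalue >= 0 & r$pvalue <= 1))
  # BH monotonicity: sorted by p, fdr is non-decreasing
  o <- order(r$pvalue)
  expect_true(all(diff(r$fdr[o]) >= -1e-12))
  pb2 <- make_pb(y[, 1:4], c("30wkGA", "30wkGA", "30wkGA", "30yo"))
  expect_error(nb_pairwise_test(pb2, "30wkGA", "30yo"), ">= 2 donors")
})

test_that("NB inference agrees with edgeR on a planted fixture", {
  skip_if_not_installed("edgeR")
  set.seed(12)
  n_peak <- 300
  y <- matrix(rnbinom(n_peak * 6, mu = 60, size = 8), n_peak, 6,
              dimnames = list(sprintf("pk%04d", seq_len(n_peak)), NULL))
  de <- 1:40
  y[de, 4:6] <- matrix(rnbinom(40 * 3, mu = 240, size = 8), 40)
  age <- rep(c("30wkGA", "30yo"), each = 3)
  pb <- make_pb(y, age)
  ours <- nb_pairwise_test(pb, "30wkGA", "30yo", covariates = character(0))

  dge <- edgeR::DGEList(counts = y, group = age)
  dge <- edgeR::estimateDisp(dge, model.matrix(~age))
  fit <- edgeR::glmFit(dge, model.matrix(~age))
  et <- edgeR::glmLRT(fit, coef = 2)$table
  expect_gt(cor(ours$logFC, et$logFC), 0.98)
  expect_gt(cor(-log10(ours$pvalue), -log10(et$PValue)), 0.9)
  ours_sig <- ours$peak_id[ours$fdr < 0.05]
  edger_sig <- rownames(y)[p.adjust(et$PValue, "BH") < 0.05]
  jacc <- length(intersect(ours_sig, edger_sig)) /
    length(union(ours_sig, edger_sig))
  expect_gt(jacc, 0.8)
})

test_that("covariates that are constant or aliased are dropped, not
           crashed on", {
  set.seed(4)
  y <- matrix(rnbinom(30 * 6, mu = 40, size = 5), 30, 6)
  pb <- make_pb(y, rep(c("30wkGA", "3yo"), each = 3),
                sex = rep("M", 6), ds = rep(c("b1", "b2"), 3))
  r <- nb_pairwise_test(pb, "30wkGA", "3yo")
  expect_equal(nrow(r), 30L)
})

test_that("age-dynamic union has union semantics", {
  r1 <- data.frame(peak_id = c("a", "b"), fdr = c(0.01, 0.2))
  r2 <- data.frame(peak_id = c("b", "c"), fdr = c(0.04, 0.9))
  expect_equal(age_dynamic_union(list(r1, r2)), c("a", "b"))
  expect_equal(age_dynamic_union(list(r1, r2), fdr = 1e-3), character(0))
  u <- age_dynamic_union(list(r1, r2))
  expect_gte(length(u), sum(r1$fdr < 0.05))
  expect_gte(length(u), sum(r2$fdr < 0.05))
})

test_that("Davies-Bouldin index matches hand-computed values and degenerate
           cases", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(db_index(pts, lab), 0.1)
  # coincident centroids
  pts2 <- matrix(c(0, 2, 1, 1, 5), ncol = 1)
  expect_equal(db_index(pts2, c(1, 1, 2, 2, 3)), Inf)
  # singletons with distinct positions: zero scatter, DB = 0
  pts3 <- matrix(c(0, 3, 9), ncol = 1)
  expect_equal(db_index(pts3, 1:3), 0)
  expect_error(db_index(pts3, rep(1, 3)), ">= 2 clusters")
})

test_that("K selection is seeded, range-respecting, and errors on tiny
           input", {
  tp <- sim_temporal_profiles(400, noise_sd = 0.03, seed = 2)
  s1 <- select_k_kmeans(tp$profiles, 5:8, seed = 4)
  s2 <- select_k_kmeans(tp$profiles, 5:8, seed = 4)
  expect_identical(s1$labels, s2$labels)
  expect_true(s1$K %in% 5:8)
  forced <- select_k_kmeans(tp$profiles, k_range = 2, seed = 4)
  expect_equal(forced$K, 2)
  expect_error(select_k_kmeans(tp$profiles[1:4, ], 5:8, seed = 1),
               "fewer peaks")
})

test_that("locus t-test matches the pooled-variance oracle and handles
           zero variance", {
  fr <- rbind(c(1), c(2), c(3), c(4), c(5), c(6))
  colnames(fr) <- "pk1"
  age <- rep(c("30wkGA", "3yo"), each = 3)
  r <- locus_ttest(fr, age, list(c("30wkGA", "3yo")))
  ht <- t.test(fr[1:3, 1], fr[4:6, 1], var.equal = TRUE)
  expect_equal(r$t, unname(ht$statistic), tolerance = 1e-9)
  expect_equal(r$p, ht$p.value, tolerance = 1e-9)
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(round(r$p, 3), 0.021)
  expect_true(r$significant)

  same <- matrix(0.1, 6, 1, dimnames = list(NULL, "pk1"))
  r2 <- locus_ttest(same, age, list(c("30wkGA", "3yo")))
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  diffm <- matrix(c(1, 1, 1, 2, 2, 2), ncol = 1,
                  dimnames = list(NULL, "pk1"))
  r3 <- locus_ttest(diffm, age, list(c("30wkGA", "3yo")))
  expect_equal(r3$p, 0)
  expect_error(locus_ttest(fr[1:4, , drop = FALSE],
                           c("30wkGA", "3yo", "3yo", "3yo"),
                           list(c("30wkGA", "3yo"))), ">= 2 donors")
})

test_that("locus t-test p-values are uniform under the null", {
  set.seed(31)
  n_rep <- 5000
  a <- matrix(rnorm(3 * n_rep), n_rep)
  b <- matrix(rnorm(3 * n_rep), n_rep)
  p <- vapply(seq_len(n_rep), function(i)
    atacage:::pooled_t(a[i, ], b[i, ])[["p"]], numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted dynamic peaks land in direction-consistent temporal
           clusters", {
  cf <- sim_config(n_peaks = 200, cells_per_donor = 200,
                   genome_length = 1.6e6, n_coaccess_modules = 0,
                   n_dynamic_peaks = 60, dynamic_shift = 1.2)
  co <- simulate_cohort(cf, seed = 3)
  pm <- filter_cells(co$atac)
  pb <- pseudobulk(pm, "AT2")
  pairs <- list(c("30wkGA", "3yo"), c("30wkGA", "30yo"), c("3yo", "30yo"))
  res <- lapply(pairs, function(p) nb_pairwise_test(pb, p[1], p[2]))
  un <- age_dynamic_union(res, 0.05)
  dyn <- names(co$truth$planted_dynamic_peaks)
  expect_gt(mean(dyn %in% un), 0.7)
  prof <- sapply(c("30wkGA", "3yo", "30yo"), function(ag)
    relative_accessibility(pm, pm$cells$age_group == ag)[un])
  sel <- select_k_kmeans(prof, 2:4, seed = 9)
  cent <- apply(prof / rowSums(prof), 2, function(x)
    tapply(x, sel$labels, mean))
  mono_up <- which(apply(cent, 1, function(r) all(diff(r) > 0)))
  mono_dn <- which(apply(cent, 1, function(r) all(diff(r) < 0)))
  truth_dir <- co$truth$planted_dynamic_peaks[un[un %in% dyn]]
  lab <- sel$labels[un %in% dyn]
  agree <- mean((truth_dir == "up" & lab %in% mono_up) |
                  (truth_dir == "down" & lab %in% mono_dn))
  expect_gte(agree, 0.8)
})
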