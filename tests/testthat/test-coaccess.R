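test_that("metacells of identical cells aggregate to k times the cell
           value", {
  counts <- matrix(rep(c(1, 0, 2, 0, 1), 100), 5, 100)
  pm <- make_pm(counts)
  mc <- build_metacells(pm, k_neighbors = 50, seed = 3)
  expect_true(ncol(mc$counts) >= 1)
  # binarized aggregation: each metacell sums 50 identical binary profiles
  expect_equal(unname(mc$counts[, 1]), c(1, 0, 1, 0, 1) * 50)
  expect_true(all(lengths(mc$members) == 50))
  mc2 <- build_metacells(pm, k_neighbors = 50, seed = 3)
  expect_identical(mc$members, mc2$members)
  expect_error(build_metacells(pm[, 1:10], k_neighbors = 50), "fewer cells")
})

test_that("metacells do not mix well-separated cell populations", {
  set.seed(8)
  popA <- matrix(rbinom(20 * 100, 1, rep(c(0.9, 0.05), each = 10)), 20, 100)
  popB <- matrix(rbinom(20 * 100, 1, rep(c(0.05, 0.9), each = 10)), 20, 100)
  pm <- make_pm(cbind(popA, popB))
  mc <- build_metacells(pm, k_neighbors = 25, seed = 1)
  labels <- rep(c("A", "B"), each = 100)
  purity <- vapply(mc$members, function(m) {
    l <- labels[match(m, pm$cells$barcode)]
    max(table(l)) / length(l)
  }, numeric(1))
  expect_true(all(purity == 1))
})

test_that("window scores recover a duplicated profile and stay near zero
           for independent peaks", {
  set.seed(5)
  n_mc <- 200
  n_pk <- 32
  shared <- rpois(n_mc, 5)
  counts <- rbind(shared, shared + rpois(n_mc, 0.2),
                  matrix(rpois((n_pk - 2) * n_mc, 5), n_pk - 2))
  pk <- peak_set(rep("chr1", n_pk), (1:n_pk) * 1200,
                 (1:n_pk) * 1200 + 400)
  mc <- structure(list(counts = unname(counts), members = list(),
                       totals = colSums(counts), peaks = pk,
                       k_neighbors = 1), class = "MetacellMatrix")
  rownames(mc$counts) <- pk$id
  sc <- window_coaccessibility(mc, list(chrom = "chr1", start = 0,
                                        end = 50000), lambda0 = 0.05)
  near <- sc[sc$peak_a == pk$id[1] & sc$peak_b == pk$id[2], ]
  expect_gt(near$score, 0.9)
  one_pair <- sc[sc$peak_a == pk$id[3] & sc$peak_b == pk$id[4], ]
  expect_lt(abs(one_pair$score), 0.1)
  indep <- sc[!(sc$peak_a %in% pk$id[1:2]) & !(sc$peak_b %in% pk$id[1:2]), ]
  expect_lt(median(abs(indep$score)), 0.05)
  # no self pairs, scores bounded
  expect_true(all(sc$peak_a != sc$peak_b))
  expect_true(all(abs(sc$score) <= 1))
})

test_that("singular covariance without penalty raises guidance to increase
           lambda0", {
  counts <- rbind(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                  c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                  c(2, 1, 2, 1, 2, 1, 2, 1, 2, 1))
  pk <- peak_set(rep("chr1", 3), (1:3) * 1000, (1:3) * 1000 + 400)
  mc <- structure(list(counts = counts, members = list(),
                       totals = colSums(counts), peaks = pk,
                       k_neighbors = 1), class = "MetacellMatrix")
  rownames(mc$counts) <- pk$id
  expect_error(window_coaccessibility(mc, list(chrom = "chr1", start = 0,
                                               end = 5000), lambda0 = 0),
               "lambda0")
  expect_error(window_coaccessibility(mc, list(chrom = "chr1", start = 0,
                                               end = 1500), 0.1),
               "fewer than 2 peaks")
})

test_that("penalized solver agrees with a generic convex-optimizer oracle
           on small windows", {
  set.seed(4)
  for (p in 2:4) {
    X <- matrix(rnorm(60 * p), 60, p)
    X[, 1] <- X[, 1] + 0.8 * X[, p]
    S <- cov(scale(X))
    Rho <- matrix(0.1, p, p)
    diag(Rho) <- 0
    ours <- atacage:::partial_cor(atacage:::glasso_fit(S, Rho))
    oracle <- atacage:::partial_cor(glasso_oracle(S, Rho))
    expect_lt(max(abs(ours - oracle)), 1e-3)
    # pure-R reference path agrees with the compiled path
    ours_r <- atacage:::partial_cor(atacage:::glasso_fit_r(S, Rho))
    expect_lt(max(abs(ours - ours_r)), 1e-6)
    expect_equal(ours, t(ours))
  }
})

test_that("penalty calibration bounds far-pair density and is monotone", {
  set.seed(6)
  counts <- matrix(rpois(40 * 80, 3), 40, 80)
  pk <- peak_set(rep("chr1", 40), (1:40) * 5000, (1:40) * 5000 + 400)
  mc <- structure(list(counts = counts, members = list(),
                       totals = colSums(counts), peaks = pk,
                       k_neighbors = 1), class = "MetacellMatrix")
  rownames(mc$counts) <- pk$id
  lam <- calibrate_penalty(mc, window_bp = 100000, seed = 2,
                           max_windows = 100)  # all windows used
  wins <- atacage:::tile_windows(pk, 100000)
  far_frac <- function(l) {
    far <- 0L; nz <- 0L
    for (i in seq_len(nrow(wins))) {
      sc <- window_coaccessibility(mc, wins[i, ], l, 100000)
      isfar <- sc$distance > 50000
      far <- far + sum(isfar)
      nz <- nz + sum(isfar & abs(sc$score) > 1e-8)
    }
    nz / far
  }
  expect_lte(far_frac(lam), 0.05)
  win <- list(chrom = "chr1", start = 0, end = 100000)
  nz1 <- function(l) {
    sc <- window_coaccessibility(mc, win, l, 100000)
    sum(abs(sc$score) > 1e-8)
  }
  expect_lte(nz1(2 * lam), nz1(lam))
  # windows that can never contain a far pair -> calibration error
  pk1 <- peak_set("chr1", 1000, 1400)
  mc1 <- structure(list(counts = counts[1, , drop = FALSE],
                        members = list(), totals = colSums(counts),
                        peaks = pk1, k_neighbors = 1),
                   class = "MetacellMatrix")
  expect_error(calibrate_penalty(mc1, 100000, seed = 2),
               "calibration error")
})

test_that("ensemble runs per cluster plus subsets and merges determin-
           istically", {
  cf <- sim_config(n_peaks = 60, cells_per_donor = 70, genome_length = 6e5,
                   n_coaccess_modules = 3, n_genes = 3, n_dynamic_peaks = 0,
                   cell_types = c(AT2 = 0.45, AT1 = 0.35, Mac = 0.2))
  co <- simulate_cohort(cf, seed = 2)
  links <- suppressMessages(
    run_ensemble(co$atac, subset_runs = 2, subset_size = 300,
                 k_neighbors = 15, window_cluster = 3e5,
                 window_subset = 2e5, seed = 5))
  expect_true(all(links$n_runs <= 3 + 2))
  expect_true(all(lengths(links$scores) == links$n_runs))
  expect_true(all(abs(links$mean_score) <= 1))
  links2 <- suppressMessages(
    run_ensemble(co$atac, subset_runs = 2, subset_size = 300,
                 k_neighbors = 15, window_cluster = 3e5,
                 window_subset = 2e5, seed = 5))
  expect_identical(links, links2)
})

test_that("link merge t-test matches the one-sample t oracle and handles
           degenerate arrays", {
  mk <- function(scores) {
    data.frame(peak_a = "a", peak_b = "b", chrom_a = "chr1", start_a = 0L,
               end_a = 10L, chrom_b = "chr1", start_b = 100L, end_b = 110L,
               distance = 100, n_runs = length(scores),
               mean_score = mean(scores)) -> df
    df$scores <- list(scores)
    df
  }
  s1 <- c(0.2, 0.25, 0.18, 0.22, 0.21)
  r1 <- test_links(mk(s1))
  ht <- t.test(s1)
  expect_equal(r1$t_stat, unname(ht$statistic), tolerance = 1e-9)
  expect_equal(r1$t_p, ht$p.value, tolerance = 1e-9)
  expect_lt(r1$t_p, 0.001)
  expect_true(r1$retained)

  s2 <- c(0.1, -0.1, 0.05, -0.05, 0)
  r2 <- test_links(mk(s2))
  expect_equal(r2$t_stat, 0)
  expect_false(r2$retained)

  expect_equal(nrow(test_links(mk(0.5))), 0L)        # < min_runs dropped
  r4 <- test_links(mk(c(0.3, 0.3, 0.3)))             # zero variance
  expect_equal(r4$t_p, 0)
  expect_true(r4$retained)
  r5 <- test_links(mk(c(0, 0, 0)))
  expect_equal(r5$t_p, 1)

  # widening alpha never drops a retained link
  tab <- do.call(rbind, lapply(list(s1, s2, c(0.05, 0.06, 0.2)), mk))
  a1 <- test_links(tab, alpha = 0.05)
  a2 <- test_links(tab, alpha = 0.20)
  expect_true(all(which(a1$retained) %in% which(a2$retained)))
})

test_that("promoter linking applies the strict score filter and the
           exactly-one-anchor rule", {
  mk <- function(a, b, score, sa, sb) {
    df <- data.frame(peak_a = a, peak_b = b, chrom_a = "chr1",
                     start_a = sa, end_a = sa + 200L, chrom_b = "chr1",
                     start_b = sb, end_b = sb + 200L, distance = sb - sa,
                     n_runs = 5L, mean_score = score, t_stat = 5,
                     t_p = 0.01, retained = TRUE)
    df
  }
  pr <- data.frame(gene = c("GENE1", "NCRNA1"), chrom = "chr1",
                   tss = c(1100L, 50000L), strand = c("+", "-"),
                   biotype = c("protein_coding", "lincRNA"))
  links <- rbind(mk("p1", "p2", 0.06, 1000L, 9000L),   # anchor a in promoter
                 mk("p3", "p4", 0.05, 1000L, 9000L),   # exactly 0.05: out
                 mk("p5", "p6", 0.30, 1000L, 1100L))   # both in promoter
  expect_message(out <- link_promoters(links, pr), "NCRNA1")
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene, "GENE1")
  expect_equal(out$promoter_peak, "p1")
  expect_equal(out$distal_peak, "p2")
})
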