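vt <- function(...) variant_table(data.frame(...))

test_that("cohort filters drop singletons and long indels", {
  v <- vt(chrom = "chr1", pos = c(10, 20, 30, 40, 50),
          ref = c("A", "A", "A", "A", "A"),
          alt = c("C", "G", "ACGTT", "ACGT", "T"),
          allele_count = c(1, 2, 5, 5, 2))
  f <- filter_variants(v)
  # singleton (pos 10) and 4-bp insertion (pos 30) removed
  expect_equal(f$pos, c(20, 40, 50))
  # 4-bp insertion removed, 3-bp kept
  v2 <- vt(chrom = "chr1", pos = c(1, 2), ref = c("A", "A"),
           alt = c("ACGTT", "ACGT"), allele_count = c(9, 9))
  expect_equal(filter_variants(v2)$alt, "ACGT")
  expect_equal(nrow(filter_variants(v[0, ])), 0L)
})

test_that("commonness folds allele frequencies and stays strict", {
  v <- vt(chrom = "chr1", pos = 1:3, ref = "G", alt = "A",
          allele_count = 5,
          af_eas = c(0.005, 0.01, 0.995),
          af_eur = c(0.45, 0.01, 0.998))
  expect_equal(is_common(v), c(TRUE, FALSE, FALSE))
  v2 <- vt(chrom = "chr1", pos = 1, ref = "G", alt = "A", allele_count = 5)
  expect_true(is.na(is_common(v2)))
})

test_that("point-mass PWM scores and exact p-values match enumeration", {
  p <- point_mass_pwm("ACG")
  hits <- pwm_best_hits("TTACGTT", p, p_threshold = 0.02)
  fw <- hits[hits$strand == "+", ]
  expect_equal(fw$offset, 3L)
  expect_equal(fw$score, 6)          # 3 * log2(1 / 0.25) bits
  expect_equal(fw$p, 1 / 64)
  # reverse complement CGT on the minus strand scores identically
  hits_rc <- pwm_best_hits("AAACGTAA", p, p_threshold = 0.02)
  expect_true(any(hits_rc$strand == "-" & hits_rc$score == 6))
  # sequence with no qualifying offset
  expect_equal(nrow(pwm_best_hits("TTTTTT", p, p_threshold = 0.02)), 0L)
  # offsets covering N are skipped
  expect_equal(nrow(pwm_best_hits("TTANGTT", p, p_threshold = 0.5)), 0L)
})

test_that("DP match p-values equal brute-force enumeration for widths
           up to 8", {
  set.seed(14)
  for (w in c(4, 6, 8)) {
    M <- matrix(stats::rgamma(w * 4, 1), w, 4)
    M <- M / rowSums(M)
    p <- pwm("rand", M, background = c(0.3, 0.2, 0.2, 0.3))
    sf_bf <- pwm_bruteforce_sf(p)
    L <- atacage:::int_logodds(p, 1000)
    sf_dp <- atacage:::pwm_score_sf(
      atacage:::pwm_score_dist(L, p$background))
    sc <- sort(unique(as.vector(outer(
      outer(L[1, ], L[2, ], "+"), 0, "+"))))
    probe <- unique(round(seq(sum(apply(L, 1, min)), sum(apply(L, 1, max)),
                              length.out = 41)))
    for (s in probe) expect_equal(sf_dp(s), sf_bf(s), tolerance = 1e-12)
  }
})

test_that("allele-aware scanning flags planted disrupting variants and a
           destroyed point-mass match drops the alt hit", {
  # hand-built case: non-palindromic consensus planted at position 11..14,
  # variant at its 2nd base; zero-probability mismatch kills the alt match
  g <- c(chr1 = "TTTTTTTTTTACGGTTTTTTTTT")
  p <- point_mass_pwm("ACGG")
  v <- vt(chrom = "chr1", pos = 12, ref = "C", alt = "A", allele_count = 5)
  sm <- scan_variant_motifs(v, g, list(p), p_threshold = 0.01)
  expect_equal(sm$n_ref_hits, 1L)
  expect_equal(sm$n_alt_hits, 0L)
  expect_true(sm$allelic_binding)  # at least one allele
  # mismatching ref allele is caught
  vbad <- vt(chrom = "chr1", pos = 12, ref = "G", alt = "A",
             allele_count = 5)
  expect_error(scan_variant_motifs(vbad, g, list(p)), "mismatch")
  vout <- vt(chrom = "chr1", pos = 9999, ref = "C", alt = "A",
             allele_count = 5)
  expect_error(scan_variant_motifs(vout, g, list(p)), "bounds")
  # no placement scoring anywhere -> no allelic binding
  vfar <- vt(chrom = "chr1", pos = 5, ref = "T", alt = "G",
             allele_count = 5)
  expect_false(scan_variant_motifs(vfar, g, list(p),
                                   p_threshold = 1e-3)$allelic_binding)
})

test_that("planted disrupting variants in the synthetic genome are
           recovered with high sensitivity", {
  cf <- sim_config(n_peaks = 150, genome_length = 1.2e6,
                   n_disrupting_variants = 12, n_benign_variants = 25)
  gb <- simulate_genome(cf, seed = 17)
  vv <- filter_variants(gb$variants)
  sm <- scan_variant_motifs(vv, gb$genome, gb$pwms)
  dis <- sm$key %in% gb$truth$motif_disrupting_variants
  expect_gte(mean(sm$allelic_binding[dis]), 0.9)
  # benign variants sit in random sequence; most have no significant motif
  expect_lt(mean(sm$allelic_binding[!dis]), 0.25)
})

test_that("delta scores sum 11-mer weights over the 19-bp window", {
  set.seed(22)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                      collapse = ""))
  pos <- 30L
  ref <- substr(g, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- vt(chrom = "chr1", pos = pos, ref = ref, alt = alt, allele_count = 5)
  win_ref <- atacage:::extract_allele_window(g, "chr1", pos, ref, ref, 9L)
  win_alt <- atacage:::extract_allele_window(g, "chr1", pos, ref, alt, 9L)
  kms <- unique(c(atacage:::kmers_of(win_ref, 11),
                  atacage:::kmers_of(win_alt, 11)))
  # all-zero table -> delta 0
  tb0 <- kmer_weight_table(setNames(rep(0, length(kms)), kms),
                           revcomp_fallback = FALSE)
  expect_equal(unname(delta_score(v, g, tb0)), 0)
  # single weight on a ref-only k-mer -> delta = -w
  ref_only <- setdiff(atacage:::kmers_of(win_ref, 11),
                      atacage:::kmers_of(win_alt, 11))[1]
  wts <- setNames(rep(0, length(kms)), kms)
  wts[ref_only] <- 2.5
  tb1 <- kmer_weight_table(wts, revcomp_fallback = FALSE)
  expect_equal(unname(delta_score(v, g, tb1)), -2.5)
  # independent enumeration of the 9 windows per allele
  w_rand <- setNames(rnorm(length(kms)), kms)
  tb2 <- kmer_weight_table(w_rand, revcomp_fallback = FALSE)
  manual <- sum(w_rand[atacage:::kmers_of(win_alt, 11)]) -
    sum(w_rand[atacage:::kmers_of(win_ref, 11)])
  expect_equal(unname(delta_score(v, g, tb2)), manual, tolerance = 1e-12)
  # antisymmetry: swapping ref and alt negates delta
  g_swap <- g
  substr(g_swap[["chr1"]], pos, pos) <- alt
  v_swap <- vt(chrom = "chr1", pos = pos, ref = alt, alt = ref,
               allele_count = 5)
  expect_equal(delta_score(v_swap, g_swap, tb2), -delta_score(v, g, tb2),
               ignore_attr = TRUE)
  # missing k-mer is reported by name
  tb3 <- kmer_weight_table(wts[-1], revcomp_fallback = FALSE)
  expect_error(delta_score(v, g, tb3), "no weight for k-mer")
  # indels are rejected
  vi <- vt(chrom = "chr1", pos = pos, ref = ref,
           alt = paste0(ref, "AA"), allele_count = 5)
  expect_error(delta_score(vi, g, tb0), "SNVs only")
})

test_that("permutation null: degenerate, deterministic and monotone", {
  set.seed(23)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                      collapse = ""))
  pos <- seq(30, 470, by = 25)
  ref <- vapply(pos, function(p) substr(g, p, p), "")
  alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  v <- vt(chrom = "chr1", pos = pos, ref = ref, alt = alt, allele_count = 5)
  kms <- unique(unlist(lapply(seq_along(pos), function(i) c(
    atacage:::kmers_of(atacage:::extract_allele_window(
      g, "chr1", pos[i], ref[i], ref[i], 9L), 11),
    atacage:::kmers_of(atacage:::extract_allele_window(
      g, "chr1", pos[i], ref[i], alt[i], 9L), 11)))))
  tb <- kmer_weight_table(setNames(rnorm(length(kms)), kms),
                          revcomp_fallback = FALSE)
  r1 <- delta_null_test(v, g, tb, n_perm = 50, seed = 6)
  r2 <- delta_null_test(v, g, tb, n_perm = 50, seed = 6)
  expect_identical(r1, r2)
  expect_true(all(is.finite(r1$z)))
  # significant set shrinks monotonically as the threshold tightens
  r_loose <- delta_null_test(v, g, tb, n_perm = 50, seed = 6, fdr = 0.5)
  r_tight <- delta_null_test(v, g, tb, n_perm = 50, seed = 6, fdr = 0.05)
  expect_true(all(r_tight$key[r_tight$significant] %in%
                    r_loose$key[r_loose$significant]))
  # all-equal weights -> every permutation identical -> z missing
  tb_const <- kmer_weight_table(setNames(rep(1, length(kms)), kms),
                                revcomp_fallback = FALSE)
  rc <- delta_null_test(v, g, tb_const, n_perm = 20, seed = 6)
  expect_true(all(is.na(rc$z)))
  expect_false(any(rc$significant))
})

test_that("variant-peak overlap respects the half-open convention", {
  pk <- peak_set("chr1", c(100, 500), c(200, 600),
                 id = c("pkA", "pkB"))
  pk$cell_types <- c("AT2,AT1", "AT2")
  v <- vt(chrom = "chr1", pos = c(101, 100, 200, 201, 350),
          ref = "A", alt = "C", allele_count = 5,
          ppa = c(0.9, NA, NA, NA, NA))
  ov <- overlap_annotate(v, pk)
  # pos 101 = first base of [100, 200); pos 100 is outside; pos 200 is the
  # last base; pos 201 and 350 fall between peaks
  expect_equal(ov$key, variant_key(v)[c(1, 3)])
  expect_equal(ov$peak_id, c("pkA", "pkA"))
  expect_equal(ov$cell_types[1], "AT2,AT1")
  expect_equal(ov$ppa[1], 0.9)
})
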