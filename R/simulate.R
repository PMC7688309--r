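#' Configuration for the synthetic cohort and genome generators
#'
#' Defaults emulate a three-age-group cohort (30wkGA, 3yo, 30yo; three
#' donors per group) with cell-type structure, heterogeneous library
#' complexity, planted co-accessible peak modules, planted age-dynamic
#' peaks, planted motif occurrences with disrupting variants, and known
#' expressing fractions.
#'
#' @param n_donors_per_age donors per age group (default 3).
#' @param cell_types named proportions summing to 1.
#' @param cells_per_donor snATAC cells per donor.
#' @param n_peaks number of peaks.
#' @param peak_width peak width in bp.
#' @param genome_length chromosome length (single chromosome "chr1").
#' @param base_logit_mean,base_logit_sd per-peak baseline accessibility on
#'   the logit scale.
#' @param celltype_logit_sd sd of per-(peak, cell type) logit effects.
#' @param baseline_access_prob optional explicit peaks x cell-types
#'   probability matrix overriding the generated baselines.
#' @param complexity_lognormal c(meanlog, sdlog) for library complexity C_j.
#' @param donor_complexity_spread total spread of per-donor offsets applied
#'   to the complexity meanlog (plants donor complexity differences).
#' @param donor_depth_spread total log-scale spread of per-donor offsets on
#'   the read multiple (plants donor sequencing-depth differences, hence
#'   donor-varying sequencing probabilities s_j).
#' @param reads_per_complexity k_j ~ Poisson(reads_per_complexity * C_j),
#'   modulated per donor by `donor_depth_spread`.
#' @param n_coaccess_modules,coaccess_module_size,coaccess_rho planted
#'   co-accessibility modules: count, member peaks per module (consecutive
#'   in the genome), and latent-factor strength in (0, 1).
#' @param n_dynamic_peaks,dynamic_shift planted age-dynamic peaks (half
#'   increasing, half decreasing) and the per-age-step logit shift.
#' @param n_genes genes; the first genes get their TSS inside the first peak
#'   of successive co-accessibility modules (so planted links are
#'   promoter-anchored).
#' @param rna_cells_per_donor snRNA nuclei per donor.
#' @param expr_fraction_range range of planted expressing fractions.
#' @param n_motifs,motif_width planted motif count and width.
#' @param n_disrupting_variants,n_benign_variants,n_filtered_variants
#'   variant counts: motif-disrupting SNVs, benign SNVs, and
#'   filter-exercising records (singletons / long indels).
#' @param kmer_weight_sd sd of the synthetic 11-mer weights.
#' @param kmer_k k-mer length of the weight table (default 11).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_donors_per_age = 3,
                       cell_types = c(AT2 = 0.5, AT1 = 0.3, Mac = 0.2),
                       cells_per_donor = 250,
                       n_peaks = 300,
                       peak_width = 400,
                       genome_length = 2400000,
                       base_logit_mean = -2.2,
                       base_logit_sd = 0.7,
                       celltype_logit_sd = 0.8,
                       baseline_access_prob = NULL,
                       complexity_lognormal = c(meanlog = log(4000),
                                                sdlog = 0.4),
                       donor_complexity_spread = 0.6,
                       donor_depth_spread = 0.8,
                       reads_per_complexity = 2,
                       n_coaccess_modules = 6,
                       coaccess_module_size = 3,
                       coaccess_rho = 0.6,
                       n_dynamic_peaks = 40,
                       dynamic_shift = 1.2,
                       n_genes = 8,
                       rna_cells_per_donor = 150,
                       expr_fraction_range = c(0.05, 0.7),
                       n_motifs = 2,
                       motif_width = 10,
                       n_disrupting_variants = 10,
                       n_benign_variants = 30,
                       n_filtered_variants = 5,
                       kmer_weight_sd = 1,
                       kmer_k = 11) {
  cfg <- as.list(environment())
  if (abs(sum(cell_types) - 1) > 1e-8)
    stop("cell type proportions must sum to 1")
  counts <- c(n_donors_per_age, cells_per_donor, n_peaks,
              n_coaccess_modules, n_dynamic_peaks, n_genes,
              n_disrupting_variants, n_benign_variants, n_filtered_variants)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (!is.null(baseline_access_prob) &&
      (any(baseline_access_prob < 0) || any(baseline_access_prob > 1)))
    stop("baseline probabilities must be in [0,1]")
  if (coaccess_rho <= 0 || coaccess_rho >= 1)
    stop("coaccess_rho must be in (0,1)")
  structure(cfg, class = "sim_config")
}

# Genomic layout shared by the cohort and genome generators: peak positions,
# module / dynamic-peak assignments, genes, motif occurrences and variant
# positions. Same (config, seed) => same layout in both generators.
sim_layout <- function(config, seed) {
  with_stream(seed, "layout", {
    cf <- config
    slot <- floor(cf$genome_length / (cf$n_peaks + 1))
    if (slot <= cf$peak_width + 100)
      stop("genome too short to place requested peaks")
    jitter_max <- max(1, slot - cf$peak_width - 50)
    start <- (seq_len(cf$n_peaks) - 1) * slot + 50 +
      sample.int(jitter_max, cf$n_peaks, replace = TRUE)
    peaks <- peak_set("chr1", start, start + cf$peak_width,
                      id = sprintf("peak%04d", seq_len(cf$n_peaks)))

    msz <- cf$coaccess_module_size
    module_of <- rep(NA_integer_, cf$n_peaks)
    if (cf$n_coaccess_modules > 0) {
      stride <- floor(cf$n_peaks / (cf$n_coaccess_modules + 1))
      if (stride < msz + 2) stop("too many modules for the peak count")
      module_starts <- stride * seq_len(cf$n_coaccess_modules) - msz
      for (m in seq_len(cf$n_coaccess_modules))
        module_of[module_starts[m] + seq_len(msz) - 1] <- m
    }

    free <- which(is.na(module_of))
    n_dyn <- min(cf$n_dynamic_peaks, length(free))
    dynamic_idx <- sort(sample(free, n_dyn))
    dynamic_dir <- rep(c("up", "down"), length.out = n_dyn)

    genes <- data.frame(gene = sprintf("G%02d", seq_len(cf$n_genes)),
                        chrom = "chr1", tss = NA_real_, strand = "+",
                        biotype = "protein_coding",
                        stringsAsFactors = FALSE)
    mod_first <- which(!is.na(module_of) & !duplicated(module_of))
    host <- c(mod_first,
              sample(setdiff(free, dynamic_idx),
                     max(0, cf$n_genes - length(mod_first))))
    host <- host[seq_len(cf$n_genes)]
    genes$tss <- floor((peaks$start[host] + peaks$end[host]) / 2)
    genes$strand <- rep(c("+", "-"), length.out = cf$n_genes)
    genes$host_peak <- peaks$id[host]

    # motif occurrences inside distinct non-module peaks
    n_occ <- cf$n_disrupting_variants
    occ_peaks <- sample(setdiff(free, host), n_occ)
    occ <- data.frame(
      peak = peaks$id[occ_peaks],
      motif = rep(seq_len(max(cf$n_motifs, 1)), length.out = n_occ),
      start0 = peaks$start[occ_peaks] + 40 +
        sample.int(cf$peak_width - cf$motif_width - 80, n_occ,
                   replace = TRUE))
    consensus <- vapply(seq_len(cf$n_motifs), function(i)
      paste(sample(c("A", "C", "G", "T"), cf$motif_width, replace = TRUE),
            collapse = ""), character(1))
    list(peaks = peaks, module_of = module_of, dynamic_idx = dynamic_idx,
         dynamic_dir = dynamic_dir, genes = genes, occ = occ,
         consensus = consensus)
  })
}

sim_donor_table <- function(config) {
  n <- config$n_donors_per_age * 3
  data.frame(donor_id = sprintf("d%02d", seq_len(n)),
             age_group = rep(AGE_GROUPS, each = config$n_donors_per_age),
             sex = rep_len(c("M", "F"), n),
             dataset_id = rep_len(c("batch1", "batch2"), n),
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic snATAC + snRNA cohort with planted truth
#'
#' Per-cell accessibility is generated as allele-count (0/1/2) draws with
#' success probability `logistic(baseline + age shift + latent co-access
#' factor)`, then thinned per fragment by the sequencing probability
#' `s_j = 1 - (1 - 1/C_j)^{k_j}` computed from the cell's simulated library
#' complexity and read count. Expression UMIs are drawn so that the fraction
#' of nuclei with >= 1 UMI matches the planted expressing fraction in
#' expectation. Identical (config, seed) gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed; all randomness flows from it via named
#'   substreams.
#' @return list with elements `atac` (a `PeakMatrix`), `rna` (an
#'   `ExpressionMatrix`) and `truth` (planted link pairs, dynamic peaks,
#'   expressing fractions, expected per-peak fragment counts, module and
#'   donor structure).
#' @export
simulate_cohort <- function(config, seed = 1) {
  cf <- config
  lay <- sim_layout(cf, seed)
  donors <- sim_donor_table(cf)
  n_donor <- nrow(donors)
  n_cell <- n_donor * cf$cells_per_donor
  ct_names <- names(cf$cell_types)

  cells <- with_stream(seed, "cells", {
    donor_i <- rep(seq_len(n_donor), each = cf$cells_per_donor)
    ct <- sample(ct_names, n_cell, replace = TRUE, prob = cf$cell_types)
    within_age <- order(rep_len(1:3, n_donor))  # spread within age groups
    mu_off <- seq(-cf$donor_complexity_spread / 2,
                  cf$donor_complexity_spread / 2,
                  length.out = n_donor)[within_age]
    C <- pmax(1, round(rlnorm(n_cell,
                              cf$complexity_lognormal[1] + mu_off[donor_i],
                              cf$complexity_lognormal[2])))
    depth_off <- exp(seq(-cf$donor_depth_spread / 2,
                         cf$donor_depth_spread / 2,
                         length.out = n_donor))[within_age]
    k <- rpois(n_cell, cf$reads_per_complexity * depth_off[donor_i] * C)
    cell_records(sprintf("cell%05d", seq_len(n_cell)),
                 donors$donor_id[donor_i], donors$age_group[donor_i],
                 donors$sex[donor_i], ct, k, C,
                 dataset_id = donors$dataset_id[donor_i])
  })
  s_j <- sequencing_probability(cells$library_complexity,
                                cells$usable_reads)

  logit0 <- with_stream(seed, "baseline", {
    if (!is.null(cf$baseline_access_prob)) {
      stats::qlogis(pmin(pmax(cf$baseline_access_prob, 1e-6), 1 - 1e-6))
    } else {
      base <- rnorm(cf$n_peaks, cf$base_logit_mean, cf$base_logit_sd)
      lg <- base + matrix(rnorm(cf$n_peaks * length(ct_names), 0,
                                cf$celltype_logit_sd),
                          cf$n_peaks, length(ct_names))
      # module peaks carry at least typical baseline accessibility in every
      # cell type: a planted co-accessibility factor on a near-silent peak
      # would be unidentifiable at any cohort size
      inmod <- !is.na(lay$module_of)
      lg[inmod, ] <- pmax(lg[inmod, ], cf$base_logit_mean)
      lg
    }
  })
  colnames(logit0) <- ct_names

  age_i <- match(cells$age_group, AGE_GROUPS)
  shift <- matrix(0, cf$n_peaks, 3)
  for (j in seq_along(lay$dynamic_idx)) {
    pr <- if (lay$dynamic_dir[j] == "up") c(0, 1, 2) else c(2, 1, 0)
    shift[lay$dynamic_idx[j], ] <- pr * cf$dynamic_shift
  }

  counts <- with_stream(seed, "counts", {
    lambda <- 2.5 * cf$coaccess_rho
    nmod <- max(cf$n_coaccess_modules, 0)
    z <- if (nmod > 0) matrix(rnorm(nmod * n_cell), nmod, n_cell) else NULL
    ct_i <- match(cells$cluster, ct_names)
    logit <- logit0[, ct_i, drop = FALSE] + shift[, age_i, drop = FALSE]
    inmod <- which(!is.na(lay$module_of))
    if (length(inmod))
      logit[inmod, ] <- logit[inmod, ] +
        lambda * z[lay$module_of[inmod], , drop = FALSE]
    p <- stats::plogis(logit)
    frag <- matrix(rbinom(length(p), 2, p), cf$n_peaks, n_cell)
    obs <- matrix(rbinom(length(frag), frag,
                         rep(s_j, each = cf$n_peaks)),
                  cf$n_peaks, n_cell)
    list(obs = obs, expected = rowSums(2 * p))
  })
  atac <- peak_matrix(Matrix::Matrix(counts$obs, sparse = TRUE),
                      lay$peaks, cells)

  expr_truth <- with_stream(seed, "expr_truth", {
    grid <- expand.grid(gene = lay$genes$gene, cluster = ct_names,
                        age_group = AGE_GROUPS, stringsAsFactors = FALSE)
    grid$fraction <- runif(nrow(grid), cf$expr_fraction_range[1],
                           cf$expr_fraction_range[2])
    grid
  })
  rna <- with_stream(seed, "rna", {
    n_nuc <- n_donor * cf$rna_cells_per_donor
    donor_i <- rep(seq_len(n_donor), each = cf$rna_cells_per_donor)
    ct <- sample(ct_names, n_nuc, replace = TRUE, prob = cf$cell_types)
    meta <- data.frame(barcode = sprintf("nuc%05d", seq_len(n_nuc)),
                       donor_id = donors$donor_id[donor_i],
                       age_group = donors$age_group[donor_i],
                       cluster = ct, stringsAsFactors = FALSE)
    key <- paste(meta$cluster, meta$age_group)
    tkey <- paste(expr_truth$cluster, expr_truth$age_group)
    umis <- vapply(seq_len(nrow(lay$genes)), function(g) {
      f <- expr_truth$fraction[expr_truth$gene == lay$genes$gene[g]][
        match(key, tkey[expr_truth$gene == lay$genes$gene[g]])]
      rpois(n_nuc, -log(1 - f))
    }, numeric(n_nuc))
    expression_matrix(Matrix::Matrix(t(umis), sparse = TRUE),
                      lay$genes$gene, meta)
  })

  link_pairs <- NULL
  if (any(!is.na(lay$module_of))) {
    link_pairs <- do.call(rbind, lapply(
      unique(stats::na.omit(lay$module_of)), function(m) {
        ids <- lay$peaks$id[which(lay$module_of == m)]
        t(utils::combn(sort(ids), 2))
      }))
    colnames(link_pairs) <- c("peak_a", "peak_b")
    link_pairs <- as.data.frame(link_pairs, stringsAsFactors = FALSE)
  }
  dyn <- setNames(lay$dynamic_dir, lay$peaks$id[lay$dynamic_idx])
  truth <- list(planted_link_pairs = link_pairs,
                planted_dynamic_peaks = dyn,
                module_of = setNames(lay$module_of, lay$peaks$id),
                expressing_fraction_truth = expr_truth,
                expected_fragments = setNames(counts$expected,
                                              lay$peaks$id),
                genes = lay$genes, donors = donors)
  list(atac = atac, rna = rna, truth = truth)
}

#' Simulate a genome bundle with planted motifs and variants
#'
#' Generates the chromosome sequence, the peak set and promoter table (the
#' same layout [simulate_cohort()] uses for the same config and seed),
#' near-consensus PWMs for the planted motifs, a variant table (disrupting
#' SNVs inside planted motif occurrences, benign SNVs, and
#' filter-exercising singletons / long indels), and an 11-mer weight table
#' covering every k-mer in any variant's scoring windows.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return list(genome, peaks, promoters, pwms, variants, kmer_weights,
#'   truth) where truth holds the keys of planted motif-disrupting variants.
#' @export
simulate_genome <- function(config, seed = 1) {
  cf <- config
  lay <- sim_layout(cf, seed)
  genome <- with_stream(seed, "sequence", {
    g <- paste(sample(c("A", "C", "G", "T"), cf$genome_length,
                      replace = TRUE), collapse = "")
    for (i in seq_len(nrow(lay$occ))) {
      cons <- lay$consensus[lay$occ$motif[i]]
      substr(g, lay$occ$start0[i] + 1,
             lay$occ$start0[i] + nchar(cons)) <- cons
    }
    c(chr1 = g)
  })

  pwms <- lapply(seq_len(cf$n_motifs), function(m) {
    cons <- strsplit(lay$consensus[m], "")[[1]]
    M <- matrix(0.01, length(cons), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    M[cbind(seq_along(cons), match(cons, colnames(M)))] <- 0.97
    pwm(sprintf("MOTIF%d", m), M)
  })

  build_variants <- function() {
    bases <- c("A", "C", "G", "T")
    rows <- list()
    for (i in seq_len(nrow(lay$occ))) {
      off <- sample.int(cf$motif_width, 1)
      pos <- lay$occ$start0[i] + off  # 1-based position of motif base `off`
      ref <- substr(genome[["chr1"]], pos, pos)
      alt <- sample(setdiff(bases, ref), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr1", pos = pos, ref = ref, alt = alt,
        allele_count = sample(2:50, 1), planted = "disrupting")
    }
    pk <- lay$peaks
    occ_zone <- unique(lay$occ$peak)
    host <- sample(setdiff(pk$id, occ_zone), cf$n_benign_variants,
                   replace = cf$n_benign_variants > length(setdiff(pk$id,
                                                                   occ_zone)))
    for (id in host) {
      j <- match(id, pk$id)
      pos <- sample((pk$start[j] + 1):(pk$end[j]), 1)
      ref <- substr(genome[["chr1"]], pos, pos)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr1", pos = pos, ref = ref,
        alt = sample(setdiff(bases, ref), 1),
        allele_count = sample(2:50, 1), planted = "benign")
    }
    for (i in seq_len(cf$n_filtered_variants)) {
      pos <- sample(cf$genome_length - 20, 1)
      ref <- substr(genome[["chr1"]], pos, pos)
      if (i %% 2 == 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "chr1", pos = pos, ref = ref,
          alt = sample(setdiff(bases, ref), 1),
          allele_count = 1L, planted = "singleton")
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "chr1", pos = pos, ref = ref,
          alt = paste0(ref, paste(sample(bases, 5, replace = TRUE),
                                  collapse = "")),
          allele_count = sample(2:50, 1), planted = "long_indel")
      }
    }
    if (!length(rows))
      return(variant_table(data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      allele_count = integer(),
                                      planted = character(),
                                      af_eur = numeric(), af_eas = numeric(),
                                      af_afr = numeric(), ppa = numeric())))
    df <- do.call(rbind, rows)
    n <- nrow(df)
    df$af_eur <- round(runif(n, 0, 0.5), 4)
    df$af_eas <- round(runif(n, 0, 0.5), 4)
    df$af_afr <- round(runif(n, 0, 0.5), 4)
    rare <- sample(n, max(1, n %/% 5))
    df[rare, c("af_eur", "af_eas", "af_afr")] <- round(
      matrix(runif(length(rare) * 3, 0, 0.008), length(rare)), 5)
    df$ppa <- NA_real_
    cred <- sample(n, min(5, n))
    df$ppa[cred] <- round(runif(length(cred)), 3)
    variant_table(df)
  }
  variants <- with_stream(seed, "variants", build_variants())

  build_kmer_weights <- function() {
    snv <- as.data.frame(variants)
    snv <- if (nrow(snv))
      snv[nchar(snv$ref) == 1 & nchar(snv$alt) == 1, ] else snv
    if (!nrow(snv))
      return(kmer_weight_table(setNames(numeric(0), character(0)),
                               k = cf$kmer_k))
    kms <- unlist(lapply(seq_len(nrow(snv)), function(i) {
      c(kmers_of(extract_allele_window(genome, snv$chrom[i], snv$pos[i],
                                       snv$ref[i], snv$ref[i],
                                       cf$kmer_k - 2L), cf$kmer_k),
        kmers_of(extract_allele_window(genome, snv$chrom[i], snv$pos[i],
                                       snv$ref[i], snv$alt[i],
                                       cf$kmer_k - 2L), cf$kmer_k))
    }))
    kms <- unique(kms)
    kmer_weight_table(setNames(rnorm(length(kms), 0, cf$kmer_weight_sd),
                               kms))
  }
  kmer_weights <- with_stream(seed, "kmer_weights", build_kmer_weights())

  truth <- list(
    motif_disrupting_variants = variant_key(variants)[
      variants$planted == "disrupting"],
    consensus = lay$consensus, occurrences = lay$occ)
  list(genome = genome, peaks = lay$peaks,
       promoters = lay$genes[, c("gene", "chrom", "tss", "strand",
                                 "biotype")],
       pwms = pwms, variants = variants, kmer_weights = kmer_weights,
       truth = truth)
}

#' Synthetic loci-by-timepoint profiles from planted temporal archetypes
#'
#' Five well-separated unit-sum archetype profiles over three age groups;
#' each locus is an archetype plus Gaussian noise. Used to exercise
#' Davies-Bouldin K selection against a known K.
#'
#' @param n_loci number of loci (default 5000).
#' @param noise_sd Gaussian noise sd (default 0.03).
#' @param seed integer seed.
#' @return list(profiles (n_loci x 3), labels, k = 5).
#' @export
sim_temporal_profiles <- function(n_loci = 5000, noise_sd = 0.03, seed = 1) {
  arch <- rbind(c(0.60, 0.30, 0.10),
                c(0.10, 0.30, 0.60),
                c(0.20, 0.60, 0.20),
                c(0.45, 0.45, 0.10),
                c(0.10, 0.45, 0.45))
  with_stream(seed, "temporal_profiles", {
    lab <- sample(rep_len(seq_len(nrow(arch)), n_loci))
    X <- arch[lab, , drop = FALSE] +
      matrix(rnorm(n_loci * 3, 0, noise_sd), n_loci, 3)
    X <- pmax(X, 1e-3)
    colnames(X) <- AGE_GROUPS
    list(profiles = X, labels = lab, k = nrow(arch))
  })
}

#' Write a simulated cohort and genome bundle to disk
#'
#' Emits exactly the file formats the readers consume: the matrix triplets,
#' genome FASTA, promoter TSV, MEME motifs, variant TSV and k-mer weight
#' TSV.
#'
#' @param cohort result of [simulate_cohort()].
#' @param genome_bundle result of [simulate_genome()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_sim_outputs <- function(cohort, genome_bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_peak_matrix(cohort$atac, dir)
  write_expression_matrix(cohort$rna, dir)
  write_genome(genome_bundle$genome, file.path(dir, "genome.fa"))
  write.table(genome_bundle$promoters, file.path(dir, "promoters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_pwms(genome_bundle$pwms, file.path(dir, "motifs.meme"))
  write_variants(genome_bundle$variants, file.path(dir, "variants.tsv"))
  write_kmer_weights(genome_bundle$kmer_weights,
                     file.path(dir, "kmer_weights.tsv"))
  invisible(dir)
}
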