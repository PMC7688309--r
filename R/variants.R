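#' Cohort filters for candidate regulatory variants
#'
#' Removes singletons (cohort allele count 1) and indels longer than 3 bp
#' (absolute ref/alt length difference > 3). SNVs always pass the length
#' rule.
#'
#' @param variants a `variant_table`.
#' @return filtered `variant_table`.
#' @export
filter_variants <- function(variants) {
  keep <- variants$allele_count != 1 &
    abs(nchar(variants$ref) - nchar(variants$alt)) <= 3
  variant_table(as.data.frame(variants)[keep, , drop = FALSE])
}

#' Common-variant flag from population allele frequencies
#'
#' The minor allele frequency in a population with allele frequency f is
#' `min(f, 1 - f)`; a variant is common when its MAF strictly exceeds
#' `maf_threshold` in at least one population. Variants with no frequency
#' data get NA, not FALSE.
#'
#' @param variants a `variant_table` with `af_*` columns.
#' @param maf_threshold strict threshold (default 0.01).
#' @return logical vector (NA where no frequency data).
#' @export
is_common <- function(variants, maf_threshold = 0.01) {
  pop_cols <- attr(variants, "pop_cols")
  if (is.null(pop_cols) || !length(pop_cols))
    return(rep(NA, nrow(variants)))
  af <- as.matrix(as.data.frame(variants)[, pop_cols, drop = FALSE])
  maf <- pmin(af, 1 - af)
  out <- apply(maf, 1, function(m) {
    m <- m[!is.na(m)]
    if (!length(m)) NA else any(m > maf_threshold)
  })
  unname(out)
}

# Integer-rounded log-odds matrix (bits x scale); -Inf where the motif
# probability is zero.
int_logodds <- function(pwm, scale = 1000) {
  M <- log2(sweep(pwm$matrix, 2, pwm$background, "/"))
  L <- round(scale * M)
  L[pwm$matrix == 0] <- -Inf
  L
}

# Exact null score distribution by dynamic programming over the
# integer-rounded scores: returns the achievable score values and their
# background probabilities (mass on -Inf paths is excluded; it can never
# reach a finite threshold).
pwm_score_dist <- function(L, background) {
  w <- nrow(L)
  fin_min <- apply(L, 1, function(r) min(r[is.finite(r)]))
  fin_max <- apply(L, 1, function(r) max(r[is.finite(r)]))
  probs <- 1
  for (i in seq_len(w)) {
    span <- fin_max[i] - fin_min[i]
    new <- numeric(length(probs) + span)
    for (b in 1:4) {
      if (!is.finite(L[i, b])) next
      sh <- L[i, b] - fin_min[i]
      ii <- seq_along(probs) + sh
      new[ii] <- new[ii] + probs * background[b]
    }
    probs <- new
  }
  list(values = sum(fin_min) + seq_along(probs) - 1, probs = probs)
}

# Survival function P(score >= s) from a pwm_score_dist.
pwm_score_sf <- function(dist) {
  sf <- rev(cumsum(rev(dist$probs)))
  function(s) {
    i <- s - dist$values[1] + 1
    if (i <= 0) return(sum(dist$probs))
    if (i > length(sf)) return(0)
    sf[i]
  }
}

scan_strand <- function(chars, L, sfun, scale) {
  w <- nrow(L)
  n <- length(chars)
  if (n < w) return(NULL)
  n_off <- n - w + 1
  sc <- numeric(n_off)
  for (i in seq_len(w)) {
    ci <- chars[i:(i + n_off - 1)]
    v <- ifelse(is.na(ci), -Inf, L[i, ifelse(is.na(ci), 1, ci)])
    sc <- sc + v
  }
  ok <- is.finite(sc)
  if (!any(ok)) return(NULL)
  p <- vapply(sc[ok], sfun, numeric(1))
  data.frame(offset = which(ok), score = sc[ok] / scale, p = p)
}

#' Scan a sequence with a PWM, with exact match p-values
#'
#' Log-odds scores (bits, against the PWM's 0-order background) at every
#' offset on both strands. The match p-value `P(score >= s | background)` is
#' computed exactly by dynamic programming over the integer-rounded score
#' distribution (scale x1000). Offsets covering an N are skipped. Returned
#' hits are those with `p < p_threshold`.
#'
#' @param sequence character string over ACGTN.
#' @param pwm a `PWM`.
#' @param p_threshold match p-value threshold (default 1e-4).
#' @param scale integer rounding scale (default 1000).
#' @return data.frame(offset (1-based start on the forward sequence),
#'   strand, score (bits), p).
#' @export
pwm_best_hits <- function(sequence, pwm, p_threshold = 1e-4, scale = 1000) {
  L <- int_logodds(pwm, scale)
  sfun <- pwm_score_sf(pwm_score_dist(L, pwm$background))
  base_idx <- function(s) {
    i <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
    i
  }
  n <- nchar(sequence)
  w <- nrow(L)
  fw <- scan_strand(base_idx(sequence), L, sfun, scale)
  rv <- scan_strand(base_idx(revcomp(sequence)), L, sfun, scale)
  out <- list()
  if (!is.null(fw)) out$fw <- cbind(fw, strand = "+")
  if (!is.null(rv)) {
    rv$offset <- n - rv$offset - w + 2L
    out$rv <- cbind(rv, strand = "-")
  }
  if (!length(out))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), p = numeric()))
  res <- do.call(rbind, out)
  res <- res[res$p < p_threshold, c("offset", "strand", "score", "p")]
  rownames(res) <- NULL
  res
}

extract_allele_window <- function(genome, chrom, pos, ref, allele, flank) {
  g <- genome[[chrom]]
  if (is.null(g)) stop("chromosome not in genome: ", chrom)
  n <- nchar(g)
  if (pos < 1 || pos + nchar(ref) - 1 > n)
    stop("variant outside genome bounds: ", chrom, ":", pos)
  obs <- substr(g, pos, pos + nchar(ref) - 1)
  if (obs != ref)
    stop("ref allele mismatch at ", chrom, ":", pos, " (genome has ", obs,
         ")")
  lo <- pos - flank
  hi <- pos + nchar(ref) - 1 + flank
  if (lo < 1 || hi > n)
    stop("variant window outside genome bounds: ", chrom, ":", pos)
  paste0(substr(g, lo, pos - 1), allele, substr(g, pos + nchar(ref), hi))
}

#' Allele-aware motif scan around variants
#'
#' For each variant and allele, extracts the surrounding reference sequence
#' with the allele substituted — `(motif width - 1)` bp of flank on each
#' side, so every motif placement overlapping the variant is scored — and
#' scans it with each PWM. A variant has allelic TF binding when at least
#' one allele has at least one significant hit for at least one PWM.
#'
#' @param variants a `variant_table`.
#' @param genome named character vector of chromosome sequences.
#' @param pwms list of `PWM` objects.
#' @param p_threshold match p-value threshold (default 1e-4).
#' @return data.frame with key, allelic_binding, n_ref_hits, n_alt_hits and
#'   list columns ref_hits / alt_hits (per-variant hit tables carrying the
#'   PWM name).
#' @export
scan_variant_motifs <- function(variants, genome, pwms, p_threshold = 1e-4) {
  keys <- variant_key(variants)
  one_allele <- function(i, allele) {
    hits <- lapply(pwms, function(p) {
      flank <- nrow(p$matrix) - 1
      s <- extract_allele_window(genome, variants$chrom[i], variants$pos[i],
                                 variants$ref[i], allele, flank)
      h <- pwm_best_hits(s, p, p_threshold)
      if (nrow(h)) cbind(pwm = p$name, h) else NULL
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits)) data.frame(pwm = character(), offset = integer(),
                                  strand = character(), score = numeric(),
                                  p = numeric()) else hits
  }
  ref_hits <- lapply(seq_len(nrow(variants)), function(i)
    one_allele(i, variants$ref[i]))
  alt_hits <- lapply(seq_len(nrow(variants)), function(i)
    one_allele(i, variants$alt[i]))
  out <- data.frame(key = keys,
                    n_ref_hits = vapply(ref_hits, nrow, 0L),
                    n_alt_hits = vapply(alt_hits, nrow, 0L),
                    stringsAsFactors = FALSE)
  out$allelic_binding <- out$n_ref_hits + out$n_alt_hits > 0
  out$ref_hits <- ref_hits
  out$alt_hits <- alt_hits
  out
}

# Resolve k-mers to indices into the weight vector, honoring the
# reverse-complement fallback policy.
resolve_kmer_idx <- function(kms, table) {
  idx <- match(kms, names(table$weights))
  if (anyNA(idx) && table$revcomp_fallback) {
    nai <- which(is.na(idx))
    idx[nai] <- match(revcomp(kms[nai]), names(table$weights))
  }
  if (anyNA(idx))
    stop("no weight for k-mer ", kms[which(is.na(idx))[1]])
  idx
}

variant_kmer_idx <- function(variants, genome, table) {
  k <- table$k
  flank <- k - 2L  # 19-bp window holding the 9 constituent 11-mers (k = 11)
  ref_idx <- matrix(0L, nrow(variants), k - 2L)
  alt_idx <- ref_idx
  for (i in seq_len(nrow(variants))) {
    if (nchar(variants$ref[i]) != 1 || nchar(variants$alt[i]) != 1)
      stop("delta scoring is defined for SNVs only")
    wr <- extract_allele_window(genome, variants$chrom[i], variants$pos[i],
                                variants$ref[i], variants$ref[i], flank)
    wa <- extract_allele_window(genome, variants$chrom[i], variants$pos[i],
                                variants$ref[i], variants$alt[i], flank)
    ref_idx[i, ] <- resolve_kmer_idx(kmers_of(wr, k), table)
    alt_idx[i, ] <- resolve_kmer_idx(kmers_of(wa, k), table)
  }
  list(ref = ref_idx, alt = alt_idx)
}

#' k-mer delta score of a variant
#'
#' For each allele, sums the weight-table entries over the constituent
#' k-mers of the 19-bp window around the variant (±9 bp of flank; 9
#' overlapping 11-mers for k = 11); `delta = score(alt) - score(ref)`.
#' Defined for SNVs only.
#'
#' @param variants a `variant_table` of SNVs.
#' @param genome named character vector of chromosome sequences.
#' @param table a `kmer_weights` object.
#' @return named numeric vector of delta scores.
#' @export
delta_score <- function(variants, genome, table) {
  idx <- variant_kmer_idx(variants, genome, table)
  w <- unname(table$weights)
  setNames(rowSums(matrix(w[idx$alt], nrow(variants))) -
             rowSums(matrix(w[idx$ref], nrow(variants))),
           variant_key(variants))
}

#' Permutation null for k-mer delta scores
#'
#' For each of `n_perm` permutations, the weight values are randomly
#' reassigned among the k-mers (one permutation of the value multiset per
#' round) and every variant is re-scored; the per-variant null mean and sd
#' give `z = (delta - mean_null) / sd_null`, a two-sided normal p-value,
#' Benjamini-Hochberg q-values across variants, and a significance call at
#' `q < fdr`. When the null sd is 0 the z-score is undefined and reported
#' missing.
#'
#' @param variants a `variant_table` of SNVs.
#' @param genome named character vector of chromosome sequences.
#' @param table a `kmer_weights` object.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param fdr significance threshold on q (default 0.1).
#' @return data.frame(key, delta, z, p, q, significant).
#' @export
delta_null_test <- function(variants, genome, table, n_perm = 100, seed = 1,
                            fdr = 0.1) {
  idx <- variant_kmer_idx(variants, genome, table)
  w <- unname(table$weights)
  nv <- nrow(variants)
  score <- function(wv)
    rowSums(matrix(wv[idx$alt], nv)) - rowSums(matrix(wv[idx$ref], nv))
  delta <- score(w)
  perm <- with_stream(seed, "delta_null", {
    vapply(seq_len(n_perm), function(i) score(sample(w)), numeric(nv))
  })
  perm <- matrix(perm, nrow = nv)
  mu <- rowMeans(perm)
  sdv <- apply(perm, 1, sd)
  z <- ifelse(sdv == 0, NA_real_, (delta - mu) / sdv)
  p <- 2 * pnorm(-abs(z))
  q <- p.adjust(p, method = "BH")
  data.frame(key = variant_key(variants), delta = delta, z = z, p = p,
             q = q, significant = !is.na(q) & q < fdr,
             stringsAsFactors = FALSE)
}

#' Annotate variants with overlapping peaks
#'
#' A variant at 1-based position p overlaps a 0-based half-open peak
#' `[start, end)` iff `start <= p - 1 < end`. The annotation carries the
#' peak id, the peak's accessible cell types when provided, and the
#' variant's fine-mapping PPA when present.
#'
#' @param variants a `variant_table` (optionally with a `ppa` column).
#' @param peaks peak data.frame ([peak_set()]), optionally with a
#'   `cell_types` column (comma-separated accessible cell types).
#' @return data.frame(key, peak_id, cell_types, ppa); one row per
#'   (variant, overlapping peak), none for variants between peaks.
#' @export
overlap_annotate <- function(variants, peaks) {
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  ov <- GenomicRanges::findOverlaps(vg, pg)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  data.frame(key = variant_key(variants)[qi],
             peak_id = peaks$id[si],
             cell_types = if ("cell_types" %in% names(peaks))
               peaks$cell_types[si] else NA_character_,
             ppa = if ("ppa" %in% names(variants))
               variants$ppa[qi] else NA_real_,
             stringsAsFactors = FALSE)
}
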