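#' Read a peak-by-cell matrix triplet
#'
#' Reads the MatrixMarket / BED / barcode-TSV triplet convention used for
#' single-cell genomics count matrices. Peaks are rows; a transposed matrix is
#' detected by the dimension check and rejected rather than guessed.
#'
#' @param matrix_path MatrixMarket coordinate file (.mtx).
#' @param peaks_path BED3+ file (chrom, start, end, optional id).
#' @param barcodes_path TSV with header and columns barcode, donor_id,
#'   age_group, sex, cluster, usable_reads, library_complexity
#'   (optional dataset_id).
#' @return a [peak_matrix()].
#' @export
read_peak_matrix <- function(matrix_path, peaks_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  pk <- read_bed_peaks(peaks_path)
  bc <- read.delim(barcodes_path, stringsAsFactors = FALSE)
  req <- c("barcode", "donor_id", "age_group", "sex", "cluster",
           "usable_reads", "library_complexity")
  miss <- setdiff(req, names(bc))
  if (length(miss)) stop("barcodes file missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(m) != nrow(pk) || ncol(m) != nrow(bc))
    stop(sprintf(paste0("dimension mismatch: matrix is %d x %d but there are ",
                        "%d peaks and %d barcodes"),
                 nrow(m), ncol(m), nrow(pk), nrow(bc)))
  cells <- cell_records(bc$barcode, bc$donor_id, bc$age_group, bc$sex,
                        bc$cluster, bc$usable_reads, bc$library_complexity,
                        dataset_id = bc$dataset_id %||% bc$donor_id)
  peak_matrix(m, pk, cells)
}

read_bed_peaks <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(bed) < 3) stop("peaks BED needs >= 3 columns")
  peak_set(bed[[1]], bed[[2]], bed[[3]],
           id = if (ncol(bed) >= 4) bed[[4]] else NULL)
}

#' Write a peak-by-cell matrix triplet
#'
#' @param x a `PeakMatrix`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the three paths written.
#' @export
write_peak_matrix <- function(x, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "peaks.bed",
                                           "barcodes.tsv")))
  Matrix::writeMM(x$counts, paths[1])
  write.table(x$peaks, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(x$cells, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read position weight matrices in MEME minimal format
#'
#' @param meme_path path to a MEME minimal motif file.
#' @return list of PWM objects (name, matrix with columns A,C,G,T,
#'   background), class `PWM` each.
#' @export
read_pwms <- function(meme_path) {
  lines <- readLines(meme_path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    v <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(v) <- toks[seq(1, length(toks), by = 2)]
    bg <- v[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks found")
  pwms <- lapply(starts, function(s) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + grep("letter-probability matrix",
                    lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    pwm(name, mat, background = bg)
  })
  pwms
}

#' Construct a PWM object
#'
#' @param name motif name.
#' @param matrix width x 4 matrix of base probabilities (columns A,C,G,T);
#'   each row must sum to 1 within 1e-3.
#' @param background length-4 background base probabilities.
#' @return object of class `PWM`.
#' @export
pwm <- function(name, matrix, background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) stop("PWM matrix must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 1) stop("empty PWM")
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 1e-3))
    stop("PWM row(s) not summing to 1: ", name,
         " (row ", which(abs(rs - 1) > 1e-3)[1], ")")
  matrix <- matrix / rs
  background <- as.numeric(background) / sum(background)
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = matrix,
                 background = setNames(background, c("A", "C", "G", "T"))),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cons <- paste(c("A", "C", "G", "T")[apply(x$matrix, 1, which.max)],
                collapse = "")
  cat("PWM", x$name, "width", nrow(x$matrix), "consensus", cons, "\n")
  invisible(x)
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms list of `PWM` objects.
#' @param path output path.
#' @export
write_pwms <- function(pwms, path) {
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           paste(sprintf("%s %.6f", names(bg), bg), collapse = " "), "")
  for (p in pwms) {
    out <- c(out, paste("MOTIF", p$name),
             sprintf("letter-probability matrix: alength= 4 w= %d",
                     nrow(p$matrix)),
             apply(p$matrix, 1, function(r)
               paste(sprintf("%.6f", r), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a variant table
#'
#' TSV with header; required columns chrom, pos (1-based), ref, alt,
#' allele_count; any column named `af_<population>` is read as a population
#' allele frequency; optional ppa column holds fine-mapping posterior
#' probabilities.
#'
#' @param table_path path to the TSV.
#' @return data.frame of class `variant_table` with attribute `pop_cols`.
#' @export
read_variants <- function(table_path) {
  df <- read.delim(table_path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "allele_count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  variant_table(df)
}

#' Construct / validate a variant table
#'
#' @param df data.frame with the columns described in [read_variants()].
#' @return validated data.frame of class `variant_table`.
#' @export
variant_table <- function(df) {
  if (nrow(df)) {
    if (any(df$pos <= 0)) stop("variant pos must be >= 1 (1-based)")
    if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
    if (any(!grepl("^[ACGT]+$", df$ref)) || any(!grepl("^[ACGT]+$", df$alt)))
      stop("alleles must be over {A,C,G,T}")
  }
  pop_cols <- grep("^af_", names(df), value = TRUE)
  for (pc in pop_cols)
    if (any(df[[pc]] < 0 | df[[pc]] > 1, na.rm = TRUE))
      stop("population frequencies must be in [0,1]: ", pc)
  if ("ppa" %in% names(df) &&
      any(df$ppa < 0 | df$ppa > 1, na.rm = TRUE))
    stop("ppa must be in [0,1]")
  df$pos <- as.integer(df$pos)
  structure(df, class = c("variant_table", "data.frame"),
            pop_cols = pop_cols)
}

#' Write a variant table
#' @param variants a `variant_table`.
#' @param path output TSV path.
#' @export
write_variants <- function(variants, path) {
  write.table(as.data.frame(variants), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

variant_key <- function(variants) {
  sprintf("%s:%d:%s>%s", variants$chrom, variants$pos,
          variants$ref, variants$alt)
}

#' Write co-accessibility links as BEDPE
#'
#' Ten standard BEDPE columns (score column carries the mean score, strands
#' "."), plus mean_score, n_runs, t_p, retained. Anchors are ordered so that
#' (chromA, startA) <= (chromB, startB); unordered input anchors are swapped
#' with a message.
#'
#' @param links a link table from [test_links()] (or [run_ensemble()], in
#'   which case the test columns are NA).
#' @param path output path.
#' @export
write_links <- function(links, path) {
  hdr <- paste0("#chromA\tstartA\tendA\tchromB\tstartB\tendB\tname\tscore",
                "\tstrandA\tstrandB\tmean_score\tn_runs\tt_p\tretained")
  if (!nrow(links)) { writeLines(hdr, path); return(invisible(path)) }
  swap <- links$chrom_a > links$chrom_b |
    (links$chrom_a == links$chrom_b & links$start_a > links$start_b)
  if (any(swap)) {
    message("write_links: reordering ", sum(swap), " link anchor pair(s)")
    for (cc in c("chrom", "start", "end", "peak")) {
      a <- links[[paste0(cc, "_a")]][swap]
      links[[paste0(cc, "_a")]][swap] <- links[[paste0(cc, "_b")]][swap]
      links[[paste0(cc, "_b")]][swap] <- a
    }
  }
  df <- data.frame(links$chrom_a, links$start_a, links$end_a,
                   links$chrom_b, links$start_b, links$end_b,
                   name = paste0(links$peak_a, "|", links$peak_b),
                   score = links$mean_score, sA = ".", sB = ".",
                   mean_score = links$mean_score, n_runs = links$n_runs,
                   t_p = links$t_p %||% NA_real_,
                   retained = links$retained %||% NA)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE link file written by [write_links()]
#' @param path BEDPE path.
#' @return data.frame of links.
#' @export
read_links <- function(path) {
  cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "name", "score", "strand_a", "strand_b", "mean_score", "n_runs",
            "t_p", "retained")
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = cols)
  if (!nrow(df)) return(df)
  nm <- strsplit(df$name, "|", fixed = TRUE)
  df$peak_a <- vapply(nm, `[`, "", 1)
  df$peak_b <- vapply(nm, `[`, "", 2)
  df$retained <- as.logical(df$retained)
  df
}

#' Read a promoter / gene annotation table
#'
#' TSV with header and columns gene, chrom, tss (0-based position of the
#' transcription start site), strand, biotype.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_promoters <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "tss", "strand", "biotype")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("promoter table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Construct a k-mer weight table
#'
#' @param weights named numeric vector; names are uppercase ACGT words, all
#'   the same length.
#' @param revcomp_fallback if TRUE, a k-mer absent from the table may be
#'   looked up by its reverse complement.
#' @param k word length; required only for an empty table.
#' @return object of class `kmer_weights` with fields k, weights,
#'   revcomp_fallback.
#' @export
kmer_weight_table <- function(weights, revcomp_fallback = TRUE, k = NULL) {
  kms <- names(weights)
  if (!length(weights)) {
    if (is.null(k)) stop("k is required for an empty weight table")
    return(structure(list(k = k, weights = setNames(numeric(0),
                                                    character(0)),
                          revcomp_fallback = isTRUE(revcomp_fallback)),
                     class = "kmer_weights"))
  }
  if (is.null(kms)) stop("weights must be a named vector")
  k <- unique(nchar(kms))
  if (length(k) != 1) stop("all k-mers must have the same length")
  if (any(!grepl("^[ACGT]+$", kms))) stop("k-mers must be uppercase ACGT")
  structure(list(k = k, weights = weights,
                 revcomp_fallback = isTRUE(revcomp_fallback)),
            class = "kmer_weights")
}

#' Read a k-mer weight table (TSV: kmer, weight)
#' @param path TSV path with header columns kmer, weight.
#' @param revcomp_fallback see [kmer_weight_table()].
#' @return a `kmer_weights` object.
#' @export
read_kmer_weights <- function(path, revcomp_fallback = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  kmer_weight_table(setNames(df$weight, df$kmer), revcomp_fallback)
}

#' Write a k-mer weight table
#' @param table a `kmer_weights` object.
#' @param path output TSV path.
#' @export
write_kmer_weights <- function(table, path) {
  write.table(data.frame(kmer = names(table$weights),
                         weight = unname(table$weights)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA as plain character sequences
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write a genome FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
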