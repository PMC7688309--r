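# Small programmatic fixtures and independent oracles shared across tests.

make_cells <- function(n, donor = "d01", age = "30wkGA", sex = "M",
                       cluster = "AT2", reads = 2000, complexity = 1000,
                       prefix = "c") {
  cell_records(sprintf("%s%04d", prefix, seq_len(n)),
               rep_len(donor, n), rep_len(age, n), rep_len(sex, n),
               rep_len(cluster, n), rep_len(reads, n),
               rep_len(complexity, n))
}

make_pm <- function(counts, ...) {
  counts <- as.matrix(counts)
  pk <- peak_set(rep("chr1", nrow(counts)),
                 seq_len(nrow(counts)) * 1000,
                 seq_len(nrow(counts)) * 1000 + 400)
  peak_matrix(counts, pk, make_cells(ncol(counts), ...))
}

make_em <- function(counts, genes = NULL, cluster = "AT2",
                    donor = "d01", age = "30wkGA") {
  counts <- as.matrix(counts)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(counts)))
  n <- ncol(counts)
  cells <- data.frame(barcode = sprintf("n%05d", seq_len(n)),
                      donor_id = rep_len(donor, n),
                      age_group = rep_len(age, n),
                      cluster = rep_len(cluster, n),
                      stringsAsFactors = FALSE)
  expression_matrix(counts, genes, cells)
}

point_mass_pwm <- function(consensus, name = "PM") {
  b <- strsplit(consensus, "")[[1]]
  M <- matrix(0, length(b), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  M[cbind(seq_along(b), match(b, colnames(M)))] <- 1
  pwm(name, M)
}

# Independent oracle for the penalized precision estimate: direct Nelder-Mead
# minimization of -log det(Theta) + tr(S Theta) + sum rho |Theta_ab| over
# symmetric positive-definite matrices (infeasible points barriered out).
glasso_oracle <- function(S, Rho, rounds = 10) {
  p <- ncol(S)
  ut <- which(upper.tri(S, diag = TRUE))
  obj <- function(th) {
    Th <- matrix(0, p, p)
    Th[ut] <- th
    Th <- Th + t(Th) - diag(diag(Th))
    ev <- tryCatch(min(eigen(Th, symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) -1)
    if (!is.finite(ev) || ev <= 1e-10) return(1e10)
    as.numeric(-determinant(Th)$modulus + sum(S * Th) +
                 sum(Rho[upper.tri(Rho)] * 2 * abs(Th[upper.tri(Th)])))
  }
  fit <- list(par = diag(1 / diag(S))[ut])
  for (r in seq_len(rounds))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 1e5, reltol = 1e-15))
  Th <- matrix(0, p, p)
  Th[ut] <- fit$par
  Th + t(Th) - diag(diag(Th))
}

# Brute-force exact PWM match p-values: enumerate all 4^w sequences, score
# them with the same integer-rounded log-odds matrix, and weight by the
# background. Returns P(score >= s) as a function of the integer score.
pwm_bruteforce_sf <- function(pwm, scale = 1000) {
  L <- atacage:::int_logodds(pwm, scale)
  w <- nrow(L)
  sc <- 0
  pr <- 1
  for (i in seq_len(w)) {
    sc <- as.vector(outer(sc, L[i, ], "+"))
    pr <- as.vector(outer(pr, pwm$background, "*"))
  }
  function(s) sum(pr[sc >= s])
}
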