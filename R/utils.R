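#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats cov kmeans median optimize p.adjust pchisq pnorm pt
#'   quantile rbinom rlnorm rnorm rpois runif sd setNames var poisson
#' @importFrom utils read.delim write.table head
#' @importFrom Rcpp evalCpp
#' @useDynLib atacage, .registration = TRUE
NULL

# Derive a reproducible sub-seed for a named random substream.  All generators
# in the package draw from streams derived this way, so partial reruns with the
# same master seed are reproducible stream by stream.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + h * 101) %% 2147483647)
}

with_stream <- function(seed, stream, expr) {
  set.seed(sub_seed(seed, stream))
  expr
}

# Reverse complement for plain ACGT character vectors (vectorized).
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# All k-mers of a string as a character vector (n - k + 1 of them).
kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AGE_GROUPS <- c("30wkGA", "3yo", "30yo")

#' Convert a 1-based variant position to 0-based half-open coordinates
#'
#' Peaks follow the BED convention (0-based, half-open) while variants follow
#' the VCF convention (1-based). This is the single bridge between the two:
#' a 1-based position `p` occupies the 0-based half-open interval
#' `[p - 1, p)`.
#'
#' @param pos integer vector of 1-based positions.
#' @return integer vector of 0-based start coordinates.
#' @export
pos_1to0 <- function(pos) {
  stopifnot(all(pos >= 1))
  as.integer(pos) - 1L
}
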