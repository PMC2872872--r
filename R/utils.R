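#' @useDynLib repeatsurveyr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rmultinom rnorm rpois runif lm chisq.test coef
#'   setNames
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

REPEAT_CLASSES <- c("retrotransposon", "transposon", "MITE",
                    "centromeric_tandem", "rDNA", "telomere", "unclassified")

#' Reverse complement
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements, names preserved.
#' @export
revcomp <- function(x) revcomp_cpp(as.character(x))

#' Random i.i.d. DNA sequence
#'
#' Draws a sequence with independent bases at a given GC fraction. Uses the
#' current RNG stream; callers are responsible for seeding.
#'
#' @param n length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return a single character string.
#' @export
random_dna <- function(n, gc = 0.44) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- c(65L, 67L, 71L, 84L) # A C G T
  intToUtf8(codes[sample.int(4L, n, replace = TRUE, prob = p)])
}

#' Introduce substitutions into a sequence
#'
#' `mutate_positions` substitutes the bases at given 1-based positions with
#' a uniformly chosen different base; `mutate_seq` substitutes a binomial
#' number of positions at a per-base rate. Both use the current RNG stream.
#' These are the simulator's mutation primitives, exported because they are
#' also the natural way to build diverged fixtures.
#'
#' @param seq a DNA string.
#' @param pos 1-based positions to substitute.
#' @return the mutated string.
#' @export
mutate_positions <- function(seq, pos) {
  if (length(pos) == 0) return(seq)
  r <- charToRaw(seq)
  cur <- rawToChar(r[pos], multiple = TRUE)
  new <- vapply(cur, function(b) {
    alt <- DNA_BASES[DNA_BASES != b]
    if (length(alt) == 0) alt <- DNA_BASES
    sample(alt, 1L)
  }, character(1), USE.NAMES = FALSE)
  r[pos] <- charToRaw(paste0(new, collapse = ""))
  rawToChar(r)
}

#' @rdname mutate_positions
#' @param rate per-base substitution probability.
#' @export
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0) return(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0) return(seq)
  mutate_positions(seq, sample.int(n, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dna <- function(x) !grepl("[^ACGTN]", x)
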