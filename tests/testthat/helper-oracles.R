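# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own primitives (no seed index, no C++ kernels) so that
# equivalence tests compare two independent routes.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# All-pairs overlap scan: for every pair, orientation and offset, check
# whether the overlap spans >= k, contains an exact identical run >= k and
# has identity >= region_identity. Returns a sorted "i-j" key set.
oracle_overlap_pairs <- function(reads, k = 14, region_identity = 0.90) {
  n <- length(reads)
  ints <- lapply(reads, function(s) utf8ToInt(s))
  rints <- lapply(oracle_revcomp(reads), function(s) utf8ToInt(s))
  nchr <- utf8ToInt("N")
  pair_has_overlap <- function(a, b) {
    la <- length(a); lb <- length(b)
    for (off in (-(lb - k)):(la - k)) {
      lo <- max(0L, off); hi <- min(la, off + lb)
      span <- hi - lo
      if (span < k) next
      av <- a[(lo + 1):hi]
      bv <- b[(lo - off + 1):(hi - off)]
      eq <- av == bv & av != nchr
      if (sum(!eq) > floor((1 - region_identity) * span)) next
      r <- rle(eq)
      if (any(r$values & r$lengths >= k)) return(TRUE)
    }
    FALSE
  }
  keys <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (pair_has_overlap(ints[[i]], ints[[j]]) ||
          pair_has_overlap(ints[[i]], rints[[j]])) {
        keys <- c(keys, paste0(i, "-", j))
      }
    }
  }
  sort(keys)
}

# Exhaustive ungapped signature scan in plain R, vectorised over target
# windows: for each target and signature length, a window matrix holds the
# target bases at every offset, and per-signature mismatch counts are row
# sums of inequality.
oracle_srna_scan <- function(sigs, targets, max_mm = 1) {
  nchr <- utf8ToInt("N")
  tvs <- lapply(targets, utf8ToInt)
  win_cache <- list()
  window_matrix <- function(t, L) {
    key <- paste(t, L)
    if (is.null(win_cache[[key]])) {
      tv <- tvs[[t]]
      M <- length(tv) - L
      if (M < 0) return(NULL)
      w <- vapply(seq_len(L), function(k) tv[(0:M) + k],
                  numeric(M + 1))
      if (M == 0) w <- matrix(w, nrow = 1)
      win_cache[[key]] <<- w
    }
    win_cache[[key]]
  }
  out <- list()
  for (s in seq_along(sigs)) {
    q <- utf8ToInt(sigs[[s]])
    qr <- utf8ToInt(oracle_revcomp(sigs[[s]]))
    L <- length(q)
    for (t in seq_along(targets)) {
      w <- window_matrix(t, L)
      if (is.null(w)) next
      bad <- w == nchr
      mm_f <- rowSums(sweep(w, 2, q, `!=`) | bad)
      mm_r <- rowSums(sweep(w, 2, qr, `!=`) | bad)
      for (p in which(mm_f <= max_mm)) {
        out[[length(out) + 1]] <- data.frame(
          sig = s, target = t, position = p - 1, strand = "+",
          stringsAsFactors = FALSE)
      }
      for (p in which(mm_r <= max_mm)) {
        out[[length(out) + 1]] <- data.frame(
          sig = s, target = t, position = p - 1, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sig = integer(), target = integer(),
                      position = integer(), strand = character()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$sig, df$target, df$position, df$strand), ]
  rownames(df) <- NULL
  df
}

# Smith-Waterman score oracle via Biostrings. The package scores gaps as
# open + extend * (run - 1); Biostrings as opening + extension * run, so
# the opening penalty is shifted by one extension.
oracle_sw_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 4, gap_extend = 0.3) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open - gap_extend,
    gapExtension = gap_extend)
  Biostrings::score(al)
}

# A read set with planted exact overlaps plus unrelated reads.
make_overlap_fixture <- function(seed = 1, n_random = 40, n_pairs = 8,
                                 len = c(60, 90), k = 14) {
  set.seed(seed)
  rnd <- function(l) random_dna(l, 0.5)
  reads <- character(0)
  for (i in seq_len(n_pairs)) {
    core <- rnd(sample(k:(k + 20), 1))
    a <- paste0(rnd(sample(20:40, 1)), core)
    b <- paste0(core, rnd(sample(20:40, 1)))
    if (i %% 2 == 0) b <- oracle_revcomp(b)
    reads <- c(reads, a, b)
  }
  reads <- c(reads, vapply(seq_len(n_random), function(i)
    rnd(sample(len[1]:len[2], 1)), character(1)))
  names(reads) <- sprintf("t%03d", seq_along(reads))
  reads
}
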