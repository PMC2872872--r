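#' Map small-RNA signatures to target sequences
#'
#' Exhaustive ungapped mapping: every placement of the full signature on
#' either strand of any target with at most `max_mismatch` substitutions is
#' reported (for 18-32-mers, one mismatch subsumes a >= 94% identity rule).
#' Indels are not tolerated: a hit must cover 100% of the signature.
#' Signatures outside the 18-32 nt range are skipped with a warning.
#'
#' @param signatures data frame with signature_id and sequence columns (as
#'   from [simulate_srna()]), or a named character vector.
#' @param targets named character vector of target sequences.
#' @param max_mismatch maximum substitutions (default 1).
#' @return data frame: signature_id, target_id, position (0-based, forward
#'   strand), strand, mismatches.
#' @export
map_srna <- function(signatures, targets, max_mismatch = 1) {
  stopifnot(length(targets) > 0, !is.null(names(targets)))
  if (is.character(signatures)) {
    signatures <- data.frame(signature_id = names(signatures),
                             sequence = unname(signatures),
                             stringsAsFactors = FALSE)
  }
  len <- nchar(signatures$sequence)
  ok <- len >= 18 & len <= 32
  if (!all(ok)) {
    warning(sum(!ok), " signature(s) outside the 18-32 nt range skipped")
    signatures <- signatures[ok, , drop = FALSE]
  }
  if (nrow(signatures) == 0) {
    return(data.frame(signature_id = character(), target_id = character(),
                      position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  hits <- map_srna_cpp(unname(targets), signatures$sequence,
                       as.integer(max_mismatch))
  data.frame(signature_id = signatures$signature_id[hits$sig_idx],
             target_id = names(targets)[hits$target_idx],
             position = hits$position, strand = hits$strand,
             mismatches = hits$mismatches, stringsAsFactors = FALSE)
}

#' Transcripts-per-quarter-million normalisation
#'
#' `TPQ = count / library_total * 250000`: normalised abundance in
#' transcripts per quarter-million sequenced signatures.
#'
#' @param count matched signature count (vectorised).
#' @param library_total total signatures sequenced in the library.
#' @return normalised abundance.
#' @export
tpq_normalize <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be positive")
  count / library_total * 250000
}

#' Small-RNA rate per genomic kilobase of a repeat
#'
#' Matched count divided by the estimated kilobases of the repeat present
#' in the genome (`copy_number * length_bp / 1000`).
#'
#' @param matched_count matched signature count.
#' @param copy_number estimated copies per genome.
#' @param length_bp repeat length.
#' @return rate per genomic kb (vectorised).
#' @export
per_kb_rate <- function(matched_count, copy_number, length_bp) {
  kb <- copy_number * length_bp / 1000
  if (any(kb <= 0)) stop("zero genomic kb: repeat excluded from rates")
  matched_count / kb
}

#' Bin repeats by copy number and aggregate small-RNA rates
#'
#' Repeats are binned by estimated copy number (bins `[b*i, b*(i+1))` for
#' width `b`); per repeat class and bin, matched signature abundances and
#' genomic kilobases are summed and their ratio is the class/bin rate. A
#' signature's abundance is credited to every cluster it hits. Empty bins
#' are omitted.
#'
#' @param clusters data frame with cluster_id, repeat_class, copy_number,
#'   length_bp.
#' @param hits hit data frame from [map_srna()].
#' @param signatures signature data frame (signature_id, abundance, length).
#' @param bin_width copy-number bin width, in `[25, 200]`.
#' @param only_24nt restrict to 24-nt signatures?
#' @return data frame: repeat_class, bin_min, bin_max, n_clusters,
#'   matched_count, genomic_kb, rate_per_kb.
#' @export
bin_and_aggregate <- function(clusters, hits, signatures, bin_width = 100,
                              only_24nt = FALSE) {
  stopifnot(bin_width >= 25, bin_width <= 200)
  sig <- signatures
  if (only_24nt) {
    len <- sig$length %||% nchar(sig$sequence)
    sig <- sig[len == 24, , drop = FALSE]
  }
  h <- hits[hits$signature_id %in% sig$signature_id, , drop = FALSE]
  # abundance credited to every cluster hit, once per (signature, cluster)
  h <- unique(h[, c("signature_id", "target_id")])
  ab <- sig$abundance[match(h$signature_id, sig$signature_id)]
  cl_count <- tapply(ab, h$target_id, sum)
  cl <- clusters
  cl$matched_count <- as.numeric(cl_count[cl$cluster_id])
  cl$matched_count[is.na(cl$matched_count)] <- 0
  cl$genomic_kb <- cl$copy_number * cl$length_bp / 1000
  cl$bin_min <- bin_width * floor(cl$copy_number / bin_width)
  agg <- stats::aggregate(
    cbind(matched_count, genomic_kb) ~ repeat_class + bin_min, data = cl,
    FUN = sum)
  nn <- stats::aggregate(cbind(n_clusters = copy_number) ~ repeat_class +
                           bin_min, data = cl, FUN = length)
  agg <- merge(agg, nn)
  agg$bin_max <- agg$bin_min + bin_width
  agg$rate_per_kb <- agg$matched_count / agg$genomic_kb
  agg <- agg[order(agg$repeat_class, agg$bin_min),
             c("repeat_class", "bin_min", "bin_max", "n_clusters",
               "matched_count", "genomic_kb", "rate_per_kb")]
  rownames(agg) <- NULL
  agg
}

#' Linearity and non-uniformity of binned small-RNA production
#'
#' Aggregates the binned table over classes, regresses total matched
#' signatures per bin on the bin's minimum copy number (ordinary least
#' squares) for the R-squared, and tests the observed per-bin totals
#' against a uniform expectation with a chi-square goodness-of-fit test.
#'
#' @param binned output of [bin_and_aggregate()].
#' @return list: r_squared, chi_square_p, n_bins, totals (per-bin data
#'   frame).
#' @export
linearity_stats <- function(binned) {
  tot <- stats::aggregate(matched_count ~ bin_min, data = binned,
                          FUN = sum)
  if (nrow(tot) < 3) stop("need at least 3 non-empty bins")
  fit <- lm(matched_count ~ bin_min, data = tot)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  x <- tot$matched_count
  p <- if (sum(x) == 0) 1 else
    suppressWarnings(chisq.test(x)$p.value)
  if (all(x == x[1])) p <- 1
  list(r_squared = r2, chi_square_p = p, n_bins = nrow(tot), totals = tot)
}

#' Share of matched small-RNA abundance per repeat class
#'
#' A signature hitting clusters of several classes has its abundance
#' apportioned equally among those classes, so shares sum to 100 over the
#' matched abundance.
#'
#' @param hits hit data frame from [map_srna()].
#' @param signatures signature data frame (signature_id, abundance).
#' @param clusters data frame mapping cluster_id to repeat_class.
#' @return data frame: repeat_class, abundance, percent.
#' @export
class_share <- function(hits, signatures, clusters) {
  if (nrow(hits) == 0) {
    return(data.frame(repeat_class = character(), abundance = numeric(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  h <- unique(hits[, c("signature_id", "target_id")])
  h$repeat_class <- clusters$repeat_class[match(h$target_id,
                                                clusters$cluster_id)]
  h <- unique(h[, c("signature_id", "repeat_class")])
  nclass <- table(h$signature_id)
  ab <- signatures$abundance[match(h$signature_id,
                                   signatures$signature_id)]
  w <- ab / as.numeric(nclass[h$signature_id])
  share <- tapply(w, h$repeat_class, sum)
  out <- data.frame(repeat_class = names(share),
                    abundance = as.numeric(share),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$abundance / sum(out$abundance)
  out[order(-out$percent), ]
}

#' Signature length distribution
#'
#' @param signatures signature data frame (length or sequence, abundance).
#' @return data frame: length, abundance, fraction.
#' @export
size_distribution <- function(signatures) {
  len <- signatures$length %||% nchar(signatures$sequence)
  ab <- signatures$abundance %||% rep(1, nrow(signatures))
  tot <- tapply(ab, len, sum)
  data.frame(length = as.integer(names(tot)), abundance = as.numeric(tot),
             fraction = as.numeric(tot) / sum(tot))
}
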