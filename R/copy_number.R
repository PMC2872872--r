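#' Count aligned reads per window of a target
#'
#' Tiles the target with non-overlapping windows of `window_bp` and counts,
#' per window, the reads whose alignment (at or above `min_identity`)
#' overlaps the window by at least one base. A read counts at most once per
#' window regardless of how many alignments it has there.
#'
#' @param alignments alignment data frame of reads against one target.
#' @param target_length_bp length of the target sequence.
#' @param window_bp window size (default 1000). Targets shorter than the
#'   window collapse to a single whole-target window with a warning.
#' @param min_identity minimum fractional identity (default 0.90).
#' @return data frame: window_start (0-based), window_end (exclusive), N.
#' @export
count_window_hits <- function(alignments, target_length_bp,
                              window_bp = 1000, min_identity = 0.90) {
  stopifnot(target_length_bp > 0)
  if (target_length_bp < window_bp) {
    warning("target (", target_length_bp, " bp) shorter than window (",
            window_bp, " bp); using a single whole-target window")
    window_bp <- target_length_bp
  }
  starts <- seq(0, target_length_bp - 1, by = window_bp)
  ends <- pmin(starts + window_bp, target_length_bp)
  out <- data.frame(window_start = starts, window_end = ends,
                    N = 0L)
  aln <- alignments[alignments$percent_identity >= 100 * min_identity, ,
                    drop = FALSE]
  if (nrow(aln) == 0) return(out)
  slo <- pmin(aln$subject_start, aln$subject_end)
  shi <- pmax(aln$subject_start, aln$subject_end)
  win <- IRanges::IRanges(start = starts + 1, end = ends)
  hit <- IRanges::findOverlaps(IRanges::IRanges(slo, shi), win)
  if (length(hit) > 0) {
    pair <- unique(data.frame(read = aln$query_id[S4Vectors::from(hit)],
                              win = S4Vectors::to(hit)))
    tab <- table(pair$win)
    out$N[as.integer(names(tab))] <- as.integer(tab)
  }
  out
}

#' Copy number from read-depth over a window
#'
#' `CN = N * L / (c * (w + L))`: with uniform sampling at coverage `c`, a
#' single-copy window of `w` bp is expected to collect `c * (w + L) / L`
#' reads (any read whose span touches the window), so the observed count
#' scaled by that expectation is the copy number. Zero exactly when no
#' reads match.
#'
#' @param N reads matching the window.
#' @param window_bp window (or whole-target) length w.
#' @param mean_read_bp mean read length L.
#' @param coverage survey coverage fraction c.
#' @return copy-number estimate (vectorised over `N`/`window_bp`).
#' @export
estimate_copy_number <- function(N, window_bp, mean_read_bp = 229,
                                 coverage) {
  if (any(coverage <= 0)) stop("coverage must be positive")
  stopifnot(all(N >= 0), all(window_bp > 0), mean_read_bp > 0)
  N * mean_read_bp / (coverage * (window_bp + mean_read_bp))
}

#' Genome fraction of a repeat family
#'
#' `copy_number * length_bp / genome_bp`, also reported as a percentage
#' rounded to two decimals. Fractions above 1 (over-collapsed repeats)
#' warn and are clipped in the percentage report only.
#'
#' @param copy_number estimated copies per genome.
#' @param length_bp repeat (cluster) length.
#' @param genome_bp genome size.
#' @return list: fraction (raw), percent (rounded to 2 decimals, clipped
#'   at 100).
#' @export
genome_fraction <- function(copy_number, length_bp, genome_bp) {
  stopifnot(all(length_bp > 0), all(genome_bp > 0), all(copy_number >= 0))
  f <- copy_number * length_bp / genome_bp
  if (any(f > 1)) {
    warning("genome fraction exceeds 1 (over-collapsed repeat); ",
            "percentage clipped in report")
  }
  list(fraction = f, percent = round(pmin(f, 1) * 100, 2))
}

#' Ranked table of the most abundant repeats
#'
#' Ranks annotated copy-number estimates by genome fraction and, among
#' clusters sharing an identical best library hit, keeps only the
#' highest-ranked, so each known family appears once. Unannotated clusters
#' (no best hit) are each kept.
#'
#' @param estimates data frame with cluster_id, length_bp, copy_number,
#'   genome_fraction and best_hit_id (NA when unannotated) columns.
#' @param n number of rows to report (default 10).
#' @return the top-`n` data frame, ranked by genome fraction.
#' @export
top_repeats_table <- function(estimates, n = 10) {
  stopifnot(all(c("cluster_id", "genome_fraction") %in% names(estimates)))
  df <- estimates[order(-estimates$genome_fraction), , drop = FALSE]
  if ("best_hit_id" %in% names(df)) {
    ann <- !is.na(df$best_hit_id)
    dup <- ann & duplicated(df$best_hit_id)
    df <- df[!dup, , drop = FALSE]
  }
  df <- head(df, n)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Fraction of survey reads matching the repeat catalogue
#'
#' A read counts once if it matches any cluster consensus at or above
#' `min_identity` over at least `min_length_frac` of its own length,
#' regardless of how many clusters it hits.
#'
#' @param reads named character vector of reads.
#' @param consensi named character vector of cluster consensus sequences.
#' @param min_identity minimum fractional identity (default 0.90).
#' @param min_length_frac minimum aligned fraction of the read length
#'   (default 0.90; full-length matching with tolerance for read-end
#'   errors).
#' @param params aligner parameters.
#' @return list: fraction, n_matched, matched (read ids).
#' @export
fraction_reads_in_repeats <- function(reads, consensi, min_identity = 0.90,
                                      min_length_frac = 0.90,
                                      params = aligner_params()) {
  stopifnot(length(consensi) > 0)
  aln <- align_many(reads, consensi, params)
  if (nrow(aln) > 0) {
    qlen <- nchar(reads)[match(aln$query_id, names(reads))]
    span <- aln$query_end - aln$query_start + 1
    ok <- aln$percent_identity >= 100 * min_identity &
      span >= min_length_frac * qlen
    matched <- unique(aln$query_id[ok])
  } else matched <- character(0)
  list(fraction = length(matched) / length(reads),
       n_matched = length(matched), matched = matched)
}
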