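#' Aligner parameter set
#'
#' Parameters of the internal seed-and-extend local nucleotide aligner.
#' Seeding uses exact words of `word_size` (default 11, the classic tile
#' size for fast candidate detection); extension runs an affine-gap local
#' alignment around each seeded region. Match/mismatch scores are +1/-1,
#' held internally on a x100 integer scale on which the default gap
#' penalties (open 400, extend 30) live. `karlin_K` and `karlin_lambda` are
#' the ungapped nucleotide Karlin-Altschul constants used by [evalue()].
#'
#' @param word_size exact-match seed length (>= 4).
#' @param min_score minimum reported alignment score, in match units.
#' @param gap_open,gap_extend positive gap penalties on the x100 scale.
#' @param match,mismatch per-base scores in match units.
#' @param karlin_K,karlin_lambda e-value constants.
#' @param min_identity minimum fractional identity of reported alignments.
#' @param both_strands search the reverse complement of the query too?
#' @return an object of class `aligner_params`.
#' @export
aligner_params <- function(word_size = 11, min_score = 30,
                           gap_open = 400, gap_extend = 30,
                           match = 1, mismatch = -1,
                           karlin_K = 0.711, karlin_lambda = 1.37,
                           min_identity = 0, both_strands = TRUE) {
  stopifnot(word_size >= 4, gap_open > 0, gap_extend > 0,
            match > 0, mismatch < 0, min_identity >= 0, min_identity <= 1)
  structure(list(word_size = as.integer(word_size), min_score = min_score,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 karlin_K = karlin_K, karlin_lambda = karlin_lambda,
                 min_identity = min_identity,
                 both_strands = isTRUE(both_strands)),
            class = "aligner_params")
}

# Exact-word index of a subject sequence: word -> integer positions (1-based).
# Words containing N are not indexed (N never seeds).
seed_index <- function(subject, word_size) {
  n <- nchar(subject)
  if (n < word_size) return(list(words = character(), pos = list()))
  starts <- seq_len(n - word_size + 1L)
  words <- substring(subject, starts, starts + word_size - 1L)
  keep <- !grepl("N", words, fixed = TRUE)
  split(starts[keep], words[keep])
}

# Align one oriented query against a subject with a prebuilt index.
# Returns rows in subject-forward coordinates.
align_oriented <- function(query, subject, idx, params, pad = 40L) {
  k <- params$word_size
  nq <- nchar(query)
  ns <- nchar(subject)
  if (nq < k) return(NULL)
  qstarts <- seq_len(nq - k + 1L)
  qwords <- substring(query, qstarts, qstarts + k - 1L)
  hit <- qwords %in% names(idx)
  if (!any(hit)) return(NULL)
  qpos <- qstarts[hit]
  spos_list <- idx[qwords[hit]]
  qrep <- rep(qpos, lengths(spos_list))
  srep <- unlist(spos_list, use.names = FALSE)
  diag <- srep - qrep
  # cluster seeds into candidate subject regions: group by diagonal bands,
  # then split bands at large subject gaps
  ord <- order(diag, srep)
  diag <- diag[ord]; srep <- srep[ord]
  band <- cumsum(c(TRUE, diff(diag) > pad))
  regions <- list()
  for (b in split(seq_along(band), band)) {
    s <- sort(srep[b])
    brk <- cumsum(c(TRUE, diff(s) > nq))
    for (g in split(s, brk)) {
      lo <- max(1L, min(g) - nq - pad)
      hi <- min(ns, max(g) + k + nq + pad)
      regions[[length(regions) + 1L]] <- c(lo, hi)
    }
  }
  # merge overlapping candidate regions
  regions <- do.call(rbind, regions)
  regions <- regions[order(regions[, 1]), , drop = FALSE]
  merged <- list(regions[1, ])
  if (nrow(regions) > 1) {
    for (i in 2:nrow(regions)) {
      last <- merged[[length(merged)]]
      if (regions[i, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], regions[i, 2]))
      } else merged[[length(merged) + 1L]] <- regions[i, ]
    }
  }
  out <- list()
  for (reg in merged) {
    sub <- substring(subject, reg[1], reg[2])
    al <- sw_align_cpp(query, sub, 100L * params$match,
                       100L * params$mismatch, params$gap_open,
                       params$gap_extend)
    if (al$score <= 0) next
    al$b_start <- al$b_start + reg[1] - 1L
    al$b_end <- al$b_end + reg[1] - 1L
    out[[length(out) + 1L]] <- al
  }
  out
}

#' Local alignment of a query against a subject
#'
#' Seed-and-extend local aligner: exact seed words of `word_size` locate
#' candidate regions, each of which is resolved by an affine-gap local
#' alignment. Both strands are searched when `params$both_strands` is TRUE;
#' minus-strand alignments report swapped subject coordinates (the tabular
#' dialect convention). Overlapping alignments of the same query/subject
#' pair and strand are reduced to the highest-scoring one. Equal scores are
#' broken by leftmost query start, then leftmost subject start.
#'
#' @param query,subject DNA sequences (single strings over ACGTN).
#' @param params an [aligner_params()] object.
#' @param query_id,subject_id identifiers used in the output table.
#' @param db_len effective database length for e-values (defaults to the
#'   subject length).
#' @return alignment data frame in the 12-column dialect (plus `strand` and
#'   raw `score`), one row per retained local alignment, ordered by
#'   decreasing score.
#' @export
align <- function(query, subject, params = aligner_params(),
                  query_id = "query", subject_id = "subject",
                  db_len = NULL) {
  stopifnot(inherits(params, "aligner_params"))
  if (nchar(query) < params$word_size) {
    warning("query shorter than word size (", nchar(query), " < ",
            params$word_size, "); no alignment attempted")
    return(empty_alignments())
  }
  idx <- seed_index(subject, params$word_size)
  align_indexed(query, subject, idx, params, query_id, subject_id,
                db_len %||% nchar(subject))
}

align_indexed <- function(query, subject, idx, params, query_id, subject_id,
                          db_len) {
  nq <- nchar(query)
  rows <- list()
  collect <- function(al, strand) {
    score <- al$score / 100
    len <- al$length
    ident <- al$matches / len
    if (score < params$min_score || ident < params$min_identity) return()
    if (strand == "+") {
      qs <- al$a_start; qe <- al$a_end
      ss <- al$b_start; se <- al$b_end
    } else {
      # alignment was computed on the reverse complement of the query:
      # map back to query-forward coordinates, swap subject coordinates
      qs <- nq - al$a_end + 1L; qe <- nq - al$a_start + 1L
      ss <- al$b_end; se <- al$b_start
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = query_id, subject_id = subject_id,
      percent_identity = round(100 * ident, 2),
      alignment_length = len, mismatches = al$mismatches,
      gap_opens = al$gap_opens, query_start = qs, query_end = qe,
      subject_start = ss, subject_end = se,
      e_value = evalue(score, nq, db_len, params),
      bit_score = round((params$karlin_lambda * score -
                           log(params$karlin_K)) / log(2), 1),
      strand = strand, score = score, stringsAsFactors = FALSE)
  }
  for (al in align_oriented(query, subject, idx, params)) collect(al, "+")
  if (params$both_strands) {
    for (al in align_oriented(revcomp(query), subject, idx, params)) {
      collect(al, "-")
    }
  }
  if (length(rows) == 0) return(empty_alignments())
  df <- do.call(rbind, rows)
  df <- df[order(-df$score, df$query_start, df$subject_start), ,
           drop = FALSE]
  # merge overlapping alignments of the pair: keep the highest-scoring of
  # any set overlapping on both query and subject
  keep <- rep(TRUE, nrow(df))
  slo <- pmin(df$subject_start, df$subject_end)
  shi <- pmax(df$subject_start, df$subject_end)
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(df)) > i)
    if (length(j) == 0) next
    ovq <- df$query_start[j] <= df$query_end[i] &
      df$query_end[j] >= df$query_start[i]
    ovs <- slo[j] <= shi[i] & shi[j] >= slo[i]
    keep[j[ovq & ovs]] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Align many queries against many subjects
#'
#' Convenience wrapper building one seed index per subject and reusing it
#' across queries. The e-value database length is the total subject length.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param params an [aligner_params()] object.
#' @return combined alignment data frame (see [align()]).
#' @export
align_many <- function(queries, subjects, params = aligner_params()) {
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  db_len <- sum(nchar(subjects))
  out <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    idx <- seed_index(subjects[[s]], params$word_size)
    res <- vector("list", length(queries))
    for (q in seq_along(queries)) {
      if (nchar(queries[[q]]) < params$word_size) next
      res[[q]] <- align_indexed(queries[[q]], subjects[[s]], idx, params,
                                names(queries)[q], names(subjects)[s],
                                db_len)
    }
    out[[s]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_alignments() else res
}

#' Karlin-Altschul e-value for an ungapped nucleotide score
#'
#' `E = K * m * n * exp(-lambda * S)` with `S` the raw alignment score in
#' match units, `m` the query length and `n` the database length. Strictly
#' decreasing in `S`, linear in `m * n`.
#'
#' @param score raw alignment score.
#' @param query_len,db_len positive sequence lengths.
#' @param params an [aligner_params()] carrying `karlin_K`, `karlin_lambda`.
#' @return the expected number of chance alignments scoring >= `score`.
#' @export
evalue <- function(score, query_len, db_len, params = aligner_params()) {
  if (any(query_len <= 0) || any(db_len <= 0)) {
    stop("sequence lengths must be positive")
  }
  params$karlin_K * query_len * db_len *
    exp(-params$karlin_lambda * score)
}

#' Best-hit reduction of an alignment table
#'
#' One row per query: highest bit score, ties broken by higher percent
#' identity, then lexicographic subject id.
#'
#' @param alignments alignment data frame.
#' @return one-row-per-query data frame.
#' @export
best_hits <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  ord <- order(alignments$query_id, -alignments$bit_score,
               -alignments$percent_identity, alignments$subject_id)
  df <- alignments[ord, , drop = FALSE]
  df <- df[!duplicated(df$query_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
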