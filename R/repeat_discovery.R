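#' Overlap graph of survey reads
#'
#' An undirected edge joins two reads when some suffix/prefix or
#' containment layout (either relative orientation) gives an overlap of at
#' least `min_overlap_bp` bases that is anchored by an exact shared word of
#' `min_overlap_bp` bases at `overlap_identity` (default 1: a 14-base run
#' of perfect identity, the classic assembler minimum-match rule) and
#' whose full overlap region reaches `region_identity` (default 0.90, the
#' pipeline's standard similarity threshold). The region filter rejects
#' chance word collisions -- between unrelated reads, and spurious offsets
#' suggested by repeated words within a family -- while letting reads from
#' copies of a diverged family chain; at `region_identity = 1` the whole
#' overlap must be exact.
#'
#' Candidate offsets are generated from shared exact words of
#' `min_overlap_bp`, which is complete for `overlap_identity = 1` (any
#' qualifying overlap contains such a word by definition); identities
#' below 1 would need degenerate seeding and are not supported.
#'
#' @param reads named character vector (uppercase ACGTN).
#' @param min_overlap_bp minimum overlap / anchor word length (default 14).
#' @param overlap_identity identity of the anchoring word (only 1.0, exact,
#'   is supported).
#' @param region_identity minimum identity of the full overlap region
#'   (default 0.90).
#' @return data frame of edges: i, j (read indices with i < j), read_i,
#'   read_j, orientation (`same`/`opposite`), offset (start of the oriented
#'   j-read in i-forward coordinates), overlap_len.
#' @export
overlap_graph <- function(reads, min_overlap_bp = 14,
                          overlap_identity = 1.0, region_identity = 0.90) {
  stopifnot(!is.null(names(reads)), min_overlap_bp >= 1,
            region_identity >= 0, region_identity <= 1)
  if (overlap_identity != 1) {
    stop("only overlap_identity = 1 (exact anchor words) is supported")
  }
  k <- as.integer(min_overlap_bp)
  empty <- data.frame(i = integer(), j = integer(), read_i = character(),
                      read_j = character(), orientation = character(),
                      offset = integer(), overlap_len = integer(),
                      stringsAsFactors = FALSE)
  if (length(reads) < 2) return(empty)
  edges <- overlap_edges_cpp(unname(reads), unname(revcomp(reads)), k,
                             region_identity)
  if (nrow(edges) == 0) return(empty)
  edges$read_i <- names(reads)[edges$i]
  edges$read_j <- names(reads)[edges$j]
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  edges[, c("i", "j", "read_i", "read_j", "orientation", "offset",
            "overlap_len")]
}

#' Cluster reads and call family consensi
#'
#' Connected components of the overlap graph with at least
#' `min_cluster_size` reads (default 3, the Lander-Waterman significance
#' threshold) become repeat clusters. Within a component, reads are laid
#' out greedily: strongest overlaps first assign each read an orientation
#' and offset relative to the component root (the longest read); edges that
#' contradict an existing placement are simply not used. The consensus is
#' then assembled in two steps: a draft template is tiled from the oriented
#' reads in layout order, with every junction located by local alignment
#' (fixed offsets drift by a base across indel-bearing reads, so junctions
#' must be re-anchored), and all member reads are realigned to the draft to
#' vote a per-column majority consensus, with columns supported by fewer
#' than 2 reads trimmed from both ends.
#'
#' @param edges edge data frame from [overlap_graph()].
#' @param reads the read vector the graph was built from.
#' @param min_cluster_size minimum reported component size.
#' @return list with `clusters` (data frame: cluster_id, n_reads,
#'   length_bp, consensus) and `members` (data frame: cluster_id, read_id,
#'   orientation, layout_pos).
#' @export
cluster_and_consensus <- function(edges, reads, min_cluster_size = 3) {
  empty <- list(
    clusters = data.frame(cluster_id = character(), n_reads = integer(),
                          length_bp = integer(), consensus = character(),
                          stringsAsFactors = FALSE),
    members = data.frame(cluster_id = character(), read_id = character(),
                         orientation = character(), layout_pos = integer(),
                         stringsAsFactors = FALSE))
  if (nrow(edges) == 0) return(empty)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j), directed = FALSE,
    vertices = data.frame(name = seq_along(reads)))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_cluster_size)
  if (length(keep) == 0) return(empty)
  rc <- revcomp(reads)
  lens <- nchar(reads)
  clusters <- list()
  members <- list()
  cl_num <- 0L
  for (cid in keep) {
    nodes <- which(comp$membership == cid)
    sub <- edges[edges$i %in% nodes & edges$j %in% nodes, , drop = FALSE]
    sub <- sub[order(-sub$overlap_len), , drop = FALSE]
    root <- nodes[which.max(lens[nodes])]
    orient <- setNames(rep(NA_character_, length(nodes)),
                       as.character(nodes))
    pos <- setNames(rep(NA_integer_, length(nodes)), as.character(nodes))
    orient[as.character(root)] <- "F"
    pos[as.character(root)] <- 0L
    # place reads by repeatedly applying the strongest edge with exactly
    # one placed endpoint
    repeat {
      placed <- names(orient)[!is.na(orient)]
      usable <- which(xor(as.character(sub$i) %in% placed,
                          as.character(sub$j) %in% placed))
      if (length(usable) == 0) break
      e <- sub[usable[1], ]
      i <- as.character(e$i); j <- as.character(e$j)
      li <- lens[e$i]; lj <- lens[e$j]
      if (i %in% placed) {
        # edge frame: i forward, j oriented by e$orientation at e$offset
        if (orient[i] == "F") {
          oj <- if (e$orientation == "same") "F" else "R"
          pj <- pos[i] + e$offset
        } else {
          oj <- if (e$orientation == "same") "R" else "F"
          pj <- pos[i] + li - (e$offset + lj)
        }
        orient[j] <- oj; pos[j] <- pj
      } else {
        if (orient[j] == "F" && e$orientation == "same") {
          orient[i] <- "F"; pos[i] <- pos[j] - e$offset
        } else if (orient[j] == "R" && e$orientation == "same") {
          orient[i] <- "R"; pos[i] <- pos[j] - (li - (e$offset + lj))
        } else if (orient[j] == "F") { # opposite: i must be R
          orient[i] <- "R"; pos[i] <- pos[j] - (li - (e$offset + lj))
        } else {
          orient[i] <- "F"; pos[i] <- pos[j] - e$offset
        }
      }
    }
    done <- !is.na(orient)
    if (sum(done) < min_cluster_size) next
    nodes_p <- as.integer(names(orient)[done])
    o <- orient[done]
    p <- pos[done]
    p <- p - min(p)
    # the layout fixes orientations and the left-to-right order; exact
    # junctions come from local alignment, because indel-bearing reads make
    # fixed offsets drift by a base or two across a chain
    ord2 <- order(p)
    oriented <- vapply(seq_along(nodes_p), function(t) {
      if (o[t] == "F") reads[[nodes_p[t]]] else rc[[nodes_p[t]]]
    }, character(1))
    draft <- tile_template(oriented[ord2])
    cons <- polish_consensus(draft, oriented)
    if (nchar(cons) == 0) next
    cons <- strsplit(cons, "", fixed = TRUE)[[1]]
    cl_num <- cl_num + 1L
    cl_id <- sprintf("C%04d", cl_num)
    clusters[[cl_num]] <- data.frame(
      cluster_id = cl_id, n_reads = length(nodes_p),
      length_bp = length(cons), consensus = paste0(cons, collapse = ""),
      stringsAsFactors = FALSE)
    members[[cl_num]] <- data.frame(
      cluster_id = cl_id, read_id = names(reads)[nodes_p],
      orientation = unname(o), layout_pos = unname(p),
      stringsAsFactors = FALSE)
  }
  if (cl_num == 0) return(empty)
  list(clusters = do.call(rbind, clusters),
       members = do.call(rbind, members))
}

# Build a draft template by walking oriented reads in layout order and
# splicing each one in at the junction its local alignment to the template
# tail dictates. The template is a mosaic of real read sequence, so every
# junction is locally exact even when fixed layout offsets have drifted
# over indel-bearing reads. Reads that are contained in (or do not extend)
# the template are skipped; they still vote during polishing.
tile_template <- function(oriented_reads, params = aligner_params()) {
  template <- oriented_reads[1]
  for (s in oriented_reads[-1]) {
    tail_len <- min(nchar(template), nchar(s) + 50L)
    tail_start <- nchar(template) - tail_len + 1L
    tl <- substring(template, tail_start)
    al <- sw_align_cpp(s, tl, 100L * params$match, 100L * params$mismatch,
                      params$gap_open, params$gap_extend)
    if (al$score <= 0 || al$matches < 14) next
    if (al$a_end >= nchar(s)) next # contained: nothing to extend
    # require the alignment to reach (close to) the template end
    if (al$b_end < tail_len - 2) next
    template <- paste0(substring(template, 1,
                                 tail_start + al$b_end - 1L),
                       substring(s, al$a_end + 1L))
  }
  template
}

# One polish pass over a draft consensus: each oriented member read is
# locally aligned to the draft and votes per draft column; the majority
# base is re-called and columns supported by < 2 reads are trimmed from
# both ends. Reads the greedy layout had shifted out of register realign
# with gaps and vote in the right columns.
polish_consensus <- function(draft, oriented_reads,
                             params = aligner_params()) {
  L <- nchar(draft)
  counts <- matrix(0L, nrow = 4, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in oriented_reads) {
    al <- sw_align_cpp(s, draft, 100L * params$match,
                       100L * params$mismatch, params$gap_open,
                       params$gap_extend)
    if (al$score <= 0) next
    qa <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
    sa <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
    ci <- al$b_start
    for (k in seq_along(sa)) {
      if (sa[k] != "-") {
        b <- match(qa[k], c("A", "C", "G", "T"))
        if (!is.na(b)) counts[b, ci] <- counts[b, ci] + 1L
        ci <- ci + 1L
      }
    }
  }
  support <- colSums(counts)
  good <- which(support >= 2)
  if (length(good) == 0) return("")
  sel <- seq(min(good), max(good))
  cons <- rownames(counts)[max.col(t(counts[, sel, drop = FALSE]),
                                   ties.method = "first")]
  cons[support[sel] == 0] <- "N"
  paste0(cons, collapse = "")
}

#' Lander-Waterman significance of a k-read cluster
#'
#' Null hypothesis: the clustered locus is single-copy. `p_null` is the
#' probability that, dropping `n_reads` reads uniformly on a single-copy
#' genome of `genome_bp`, some set of >= k reads is mutually chained by
#' overlaps of at least `min_overlap_bp`. Estimated by Monte Carlo and also
#' via a closed-form island-statistics approximation (reads chain when
#' consecutive starts are closer than L - m; islands of >= k reads follow a
#' geometric tail, Poissonised over island starts).
#'
#' @param k cluster size in reads.
#' @param n_reads number of reads dropped on the null genome (if missing,
#'   derived as `coverage * genome_bp / mean_read_bp`).
#' @param genome_bp null genome size.
#' @param mean_read_bp mean read length L.
#' @param min_overlap_bp assembly overlap threshold m.
#' @param coverage survey coverage fraction c (used only when `n_reads` is
#'   missing).
#' @param n_sim Monte-Carlo replicates (>= 100).
#' @param seed RNG seed for the Monte-Carlo draw.
#' @return list with k, p_null (Monte Carlo), p_null_closed, se_mc,
#'   p_multicopy = 1 - p_null.
#' @export
cluster_significance <- function(k, n_reads = NULL, genome_bp,
                                 mean_read_bp = 229, min_overlap_bp = 14,
                                 coverage = NULL, n_sim = 1000,
                                 seed = 1L) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  stopifnot(k >= 1, genome_bp > 0, mean_read_bp > 0)
  if (is.null(n_reads)) {
    if (is.null(coverage)) stop("supply n_reads or coverage")
    n_reads <- round(coverage * genome_bp / mean_read_bp)
  }
  L <- mean_read_bp
  Tm <- L - min_overlap_bp
  closed <- if (k == 1) 1 else {
    a <- n_reads / genome_bp
    q <- 1 - exp(-a * Tm)
    mu <- n_reads * (1 - q) * q^(k - 1)
    1 - exp(-mu)
  }
  set.seed(seed)
  hits <- logical(n_sim)
  if (k == 1) {
    hits <- rep(n_reads >= 1, n_sim)
  } else {
    for (s in seq_len(n_sim)) {
      starts <- sort(runif(n_reads, 0, genome_bp))
      chained <- diff(starts) <= Tm
      r <- rle(chained)
      hits[s] <- any(r$values & r$lengths >= (k - 1))
    }
  }
  p_mc <- mean(hits)
  list(k = k, p_null = p_mc, p_null_closed = closed,
       se_mc = sqrt(p_mc * (1 - p_mc) / n_sim), p_multicopy = 1 - p_mc)
}

# Parse the class code from a repeat-library identifier of the documented
# grammar CLASS|family|... .
library_class <- function(ids) {
  code <- vapply(strsplit(ids, "|", fixed = TRUE), `[[`, character(1), 1)
  ok <- code %in% REPEAT_CLASSES
  if (!all(ok)) {
    warning("library identifiers without a parseable class code: ",
            paste(unique(ids[!ok]), collapse = ", "))
    code[!ok] <- "unclassified"
  }
  code
}

#' Classify clusters against a repeat library
#'
#' The class of a cluster is the class code of its best library hit (by bit
#' score) with e-value at or below the cutoff; clusters with no qualifying
#' hit are `unannotated`. Library identifiers follow the grammar
#' `CLASS|family|...`; identifiers without a recognised class code classify
#' as `unclassified` with a warning.
#'
#' @param clusters cluster data frame (cluster_id, consensus, ...).
#' @param repeat_library named character vector of class-coded library
#'   sequences.
#' @param evalue_cutoff e-value gate (default 1e-6).
#' @param params aligner parameters.
#' @return `clusters` with repeat_class, best_hit_id, best_hit_evalue
#'   columns added, plus a `composition` attribute (per-class counts).
#' @export
classify_clusters <- function(clusters, repeat_library,
                              evalue_cutoff = 1e-6,
                              params = aligner_params()) {
  cons <- setNames(clusters$consensus, clusters$cluster_id)
  aln <- align_many(cons, repeat_library, params)
  aln <- aln[aln$e_value <= evalue_cutoff, , drop = FALSE]
  best <- best_hits(aln)
  m <- match(clusters$cluster_id, best$query_id)
  clusters$best_hit_id <- best$subject_id[m]
  clusters$best_hit_evalue <- best$e_value[m]
  cls <- rep("unannotated", nrow(clusters))
  if (any(!is.na(m))) {
    cls[!is.na(m)] <- library_class(best$subject_id[m[!is.na(m)]])
  }
  clusters$repeat_class <- cls
  comp <- as.data.frame(table(repeat_class = clusters$repeat_class),
                        stringsAsFactors = FALSE)
  names(comp)[2] <- "n_clusters"
  attr(clusters, "composition") <- comp
  clusters
}

#' Partition clusters into known and novel
#'
#' A cluster is novel when it has no alignment to the reference set with
#' e-value at or below the cutoff.
#'
#' @param clusters cluster data frame with consensus sequences.
#' @param reference_set named character vector of reference sequences.
#' @param evalue_cutoff e-value gate (default 1e-6).
#' @param params aligner parameters.
#' @return list: known (cluster ids), novel (cluster ids), counts.
#' @export
novelty_screen <- function(clusters, reference_set, evalue_cutoff = 1e-6,
                           params = aligner_params()) {
  stopifnot(length(reference_set) > 0)
  cons <- setNames(clusters$consensus, clusters$cluster_id)
  aln <- align_many(cons, reference_set, params)
  aln <- aln[aln$e_value <= evalue_cutoff, , drop = FALSE]
  known <- intersect(clusters$cluster_id, unique(aln$query_id))
  novel <- setdiff(clusters$cluster_id, known)
  list(known = known, novel = novel,
       counts = c(known = length(known), novel = length(novel)))
}
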