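#' Mine rDNA-matching survey reads
#'
#' Selects reads with an alignment to any rDNA reference at or above
#' `min_identity`. Per-anchor hit counts are reported alongside the union
#' (a read may match one or both anchors).
#'
#' @param reads named character vector of survey reads.
#' @param rdna_refs named character vector of rDNA reference sequences.
#' @param min_identity minimum fractional identity (default 0.90).
#' @param params aligner parameters.
#' @return list: `reads` (the matching subset of `reads`), `n` (count),
#'   `per_anchor` (named hit counts).
#' @export
mine_rdna_reads <- function(reads, rdna_refs, min_identity = 0.90,
                            params = aligner_params()) {
  stopifnot(length(rdna_refs) > 0, !is.null(names(rdna_refs)))
  aln <- align_many(reads, rdna_refs, params)
  aln <- aln[aln$percent_identity >= 100 * min_identity, , drop = FALSE]
  per_anchor <- vapply(names(rdna_refs), function(a) {
    length(unique(aln$query_id[aln$subject_id == a]))
  }, integer(1))
  sel <- unique(aln$query_id)
  list(reads = reads[names(reads) %in% sel], n = length(sel),
       per_anchor = per_anchor)
}

# Best full local alignment of seq against the anchor over both strands,
# via the dynamic-programming kernel directly (anchors are short, so no
# seeding is needed and the traceback strings are retained).
anchor_align <- function(seq, anchor, params) {
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    al <- sw_align_cpp(s, anchor, 100L * params$match,
                       100L * params$mismatch, params$gap_open,
                       params$gap_extend)
    if (al$score > 0 && (is.null(best) || al$score > best$score)) {
      best <- al
      best$strand <- strand
    }
  }
  best
}

#' Build a reference-anchored alignment of mined rDNA reads
#'
#' Each read (and each non-anchor reference) is placed by its best local
#' alignment to the designated anchor reference; gaps are propagated so all
#' rows share one column set. Sequences whose best alignment is shorter
#' than `min_overlap` or below `min_identity` are dropped, with reasons
#' recorded in the `dropped` element.
#'
#' Matrix cells hold `A/C/G/T/N`, `-` (gap) or `.` (position not covered by
#' the row's alignment). Columns carry anchor coordinates (0-based;
#' insertion columns get the half-open position of the anchor gap they sit
#' in, offset by -0.5).
#'
#' @param mined_reads named character vector of rDNA-matching reads.
#' @param refs named character vector of reference sequences; the anchor
#'   must be among them.
#' @param anchor name of the anchor reference (default: first).
#' @param min_overlap minimum alignment length to keep a row (default 50).
#' @param min_identity minimum fractional identity to keep a row
#'   (default 0.80).
#' @param params aligner parameters (scores reused by the kernel).
#' @return object of class `its_alignment`: list with `mat` (character
#'   matrix), `ids`, `origin` (`read`/`reference`), `col_anchor`, `anchor`,
#'   `dropped`.
#' @export
build_its_alignment <- function(mined_reads, refs,
                                anchor = names(refs)[1], min_overlap = 50,
                                min_identity = 0.80,
                                params = aligner_params()) {
  stopifnot(anchor %in% names(refs))
  anchor_seq <- refs[[anchor]]
  la <- nchar(anchor_seq)
  seqs <- c(refs[names(refs) != anchor], mined_reads)
  origin <- c(rep("reference", sum(names(refs) != anchor)),
              rep("read", length(mined_reads)))
  rows <- list()
  inserts <- list() # per row: named list anchor_gap_pos -> inserted string
  kept_ids <- character(0)
  kept_origin <- character(0)
  dropped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (s in seq_along(seqs)) {
    id <- names(seqs)[s]
    al <- anchor_align(seqs[[s]], anchor_seq, params)
    if (is.null(al)) {
      dropped <- rbind(dropped, data.frame(id = id, reason = "no alignment",
                                           stringsAsFactors = FALSE))
      next
    }
    len <- al$length
    ident <- al$matches / len
    if (len < min_overlap || ident < min_identity) {
      dropped <- rbind(dropped, data.frame(
        id = id, reason = sprintf("gate failed (length %d, identity %.3f)",
                                  len, ident), stringsAsFactors = FALSE))
      next
    }
    row <- rep(".", la)
    ins <- list()
    qa <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
    sa <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
    bi <- al$b_start # 1-based next anchor position
    for (k in seq_along(sa)) {
      if (sa[k] != "-") {
        row[bi] <- qa[k]
        bi <- bi + 1L
      } else {
        key <- as.character(bi) # insertion before anchor position bi
        ins[[key]] <- paste0(ins[[key]] %||% "", qa[k])
      }
    }
    rows[[length(rows) + 1L]] <- row
    inserts[[length(inserts) + 1L]] <- ins
    kept_ids <- c(kept_ids, id)
    kept_origin <- c(kept_origin, origin[s])
  }
  # the anchor itself is a row covering everything
  rows <- c(list(strsplit(anchor_seq, "", fixed = TRUE)[[1]]), rows)
  inserts <- c(list(list()), inserts)
  kept_ids <- c(anchor, kept_ids)
  kept_origin <- c("reference", kept_origin)
  if (length(rows) < 2) {
    stop("empty alignment: no sequence passed the overlap/identity gate")
  }
  # global insertion column widths per anchor gap
  gaps <- sort(unique(as.integer(unlist(lapply(inserts, names)))))
  gap_w <- vapply(gaps, function(g) {
    max(vapply(inserts, function(i)
      nchar(i[[as.character(g)]] %||% ""), integer(1)))
  }, integer(1))
  ncol_tot <- la + sum(gap_w)
  mat <- matrix(".", nrow = length(rows), ncol = ncol_tot)
  col_anchor <- numeric(ncol_tot)
  ci <- 1L
  for (ai in seq_len(la)) {
    gi <- match(ai, gaps)
    if (!is.na(gi)) {
      w <- gap_w[gi]
      for (r in seq_along(rows)) {
        insstr <- inserts[[r]][[as.character(ai)]] %||% ""
        covered <- rows[[r]][ai] != "." &&
          (ai == 1 || rows[[r]][ai - 1] != ".")
        fill <- if (nzchar(insstr)) {
          c(strsplit(insstr, "", fixed = TRUE)[[1]],
            rep("-", w - nchar(insstr)))
        } else if (covered) rep("-", w) else rep(".", w)
        mat[r, ci:(ci + w - 1L)] <- fill
      }
      col_anchor[ci:(ci + w - 1L)] <- ai - 1 - 0.5
      ci <- ci + w
    }
    for (r in seq_along(rows)) mat[r, ci] <- rows[[r]][ai]
    col_anchor[ci] <- ai - 1
    ci <- ci + 1L
  }
  structure(list(mat = mat, ids = kept_ids, origin = kept_origin,
                 col_anchor = col_anchor, anchor = anchor,
                 dropped = dropped),
            class = "its_alignment")
}

#' Trim an anchored alignment to a diagnostic block
#'
#' Truncates to `region` (anchor-relative, 0-based half-open), drops rows
#' that do not fully span the region (any uncovered cell) or that contain
#' `N` within it, and removes columns gapped in strictly more than
#' `gap_column_threshold` of the retained rows (columns at exactly the
#' threshold are kept). The operation is idempotent.
#'
#' @param aln an `its_alignment` or `its_block`.
#' @param region numeric length-2, anchor-relative 0-based half-open.
#' @param gap_column_threshold gap-column removal threshold (default 0.95,
#'   strict >).
#' @return object of class `its_block` (same structure as the input, with
#'   `region` recorded).
#' @export
trim_block <- function(aln, region, gap_column_threshold = 0.95) {
  stopifnot(inherits(aln, c("its_alignment", "its_block")),
            length(region) == 2, region[1] < region[2])
  anchor_len <- max(aln$col_anchor) + 1
  if (region[2] - region[1] > anchor_len) {
    stop("region (", region[2] - region[1], " bp) is longer than the ",
         "alignment (", anchor_len, " anchor positions)")
  }
  keep_col <- aln$col_anchor >= region[1] - 0.5 &
    aln$col_anchor < region[2] - 0.5
  if (!any(keep_col)) stop("region outside anchor coordinates")
  mat <- aln$mat[, keep_col, drop = FALSE]
  span <- !apply(mat == ".", 1, any) & !apply(mat == "N", 1, any)
  mat <- mat[span, , drop = FALSE]
  if (nrow(mat) == 0) stop("no row fully spans the region")
  gap_frac <- colMeans(mat == "-")
  keep2 <- gap_frac <= gap_column_threshold
  structure(list(mat = mat[, keep2, drop = FALSE],
                 ids = aln$ids[span], origin = aln$origin[span],
                 col_anchor = aln$col_anchor[keep_col][keep2],
                 anchor = aln$anchor, region = as.numeric(region)),
            class = "its_block")
}

#' Classify reads to the nearest parental haplotype
#'
#' Substitution distance from each read row to each haplotype row is
#' counted over columns where both are ungapped; each read is assigned to
#' the strict minimum-distance haplotype, or `ambiguous` on ties.
#'
#' @param block an `its_block`.
#' @param haplotype_ids row ids of the (>= 2) haplotype references.
#' @return list: `calls` (data frame: read_id, assigned_haplotype,
#'   distance_to_best, distance_to_second), `tallies` (named counts per
#'   haplotype plus `ambiguous`).
#' @export
classify_parentage <- function(block, haplotype_ids) {
  stopifnot(inherits(block, "its_block"), length(haplotype_ids) >= 2)
  hi <- match(haplotype_ids, block$ids)
  if (any(is.na(hi))) {
    stop("haplotype(s) not present in block: ",
         paste(haplotype_ids[is.na(hi)], collapse = ", "))
  }
  haps <- block$mat[hi, , drop = FALSE]
  if (length(haplotype_ids) == 2 && all(haps[1, ] == haps[2, ])) {
    stop("haplotypes are identical within the block: no discriminating ",
         "sites")
  }
  reads <- setdiff(which(block$origin == "read"), hi)
  calls <- data.frame(read_id = block$ids[reads],
                      assigned_haplotype = rep(NA_character_,
                                               length(reads)),
                      distance_to_best = rep(NA_integer_, length(reads)),
                      distance_to_second = rep(NA_integer_, length(reads)),
                      stringsAsFactors = FALSE)
  for (r in seq_along(reads)) {
    row <- block$mat[reads[r], ]
    d <- vapply(seq_along(hi), function(h) {
      hap <- haps[h, ]
      shared <- row != "-" & hap != "-"
      sum(row[shared] != hap[shared])
    }, integer(1))
    ord <- order(d)
    calls$distance_to_best[r] <- d[ord[1]]
    calls$distance_to_second[r] <- d[ord[2]]
    calls$assigned_haplotype[r] <-
      if (d[ord[1]] == d[ord[2]]) "ambiguous" else haplotype_ids[ord[1]]
  }
  tallies <- setNames(integer(length(haplotype_ids) + 1),
                      c(haplotype_ids, "ambiguous"))
  tb <- table(calls$assigned_haplotype)
  tallies[names(tb)] <- as.integer(tb)
  list(calls = calls, tallies = tallies)
}

nexus_label <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.|-]", x), paste0("'", gsub("'", "''", x), "'"),
         x)
}

#' Write an ITS block as a NEXUS DATA file
#'
#' Emits a minimal NEXUS file (`ntax`, `nchar`, `datatype=DNA`, `gap=-`,
#' `missing=?`) suitable for external phylogenetic software. Labels with
#' characters outside `[A-Za-z0-9_.|-]` are quoted. Uncovered cells (`.`)
#' are written as `?`.
#'
#' @param block an `its_block` (or `its_alignment`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(block, path) {
  stopifnot(nrow(block$mat) > 0)
  seqs <- apply(block$mat, 1, paste0, collapse = "")
  seqs <- chartr(".", "?", seqs)
  labs <- nexus_label(block$ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs),
                       ncol(block$mat)),
               "  FORMAT DATATYPE=DNA GAP=- MISSING=?;", "  MATRIX"), con)
  writeLines(sprintf("    %s  %s", format(labs), seqs), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Read a NEXUS DATA file written by [write_nexus()]
#'
#' @param path path to the NEXUS file.
#' @return list: `mat` (character matrix, `?` restored to `.`), `ids`.
#' @export
read_nexus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || toupper(trimws(lines[1])) != "#NEXUS") {
    stop("not a NEXUS file: ", path)
  }
  dim_line <- grep("DIMENSIONS", lines, ignore.case = TRUE, value = TRUE)[1]
  ntax <- as.integer(sub(".*NTAX=([0-9]+).*", "\\1", dim_line,
                         ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR=([0-9]+).*", "\\1", dim_line,
                           ignore.case = TRUE))
  mstart <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)[1]
  if (is.na(mstart)) stop("no MATRIX block in ", path)
  ids <- character(ntax)
  seqs <- character(ntax)
  r <- 0L
  for (ln in lines[(mstart + 1):length(lines)]) {
    t <- trimws(ln)
    if (t == ";" || toupper(t) == "END;") break
    if (!nzchar(t)) next
    r <- r + 1L
    if (startsWith(t, "'")) {
      m <- regmatches(t, regexec("^'((?:[^']|'')*)'\\s+(\\S+)$", t))[[1]]
      if (length(m) != 3) stop("malformed quoted label at NEXUS row ", r)
      ids[r] <- gsub("''", "'", m[2])
      seqs[r] <- m[3]
    } else {
      parts <- strsplit(t, "\\s+")[[1]]
      ids[r] <- parts[1]
      seqs[r] <- parts[length(parts)]
    }
  }
  if (r != ntax) stop("NEXUS matrix has ", r, " rows, expected ", ntax)
  if (any(nchar(seqs) != nchar_)) {
    stop("NEXUS row length disagrees with NCHAR")
  }
  mat <- do.call(rbind, strsplit(chartr("?", ".", seqs), "", fixed = TRUE))
  rownames(mat) <- NULL
  list(mat = mat, ids = ids)
}
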