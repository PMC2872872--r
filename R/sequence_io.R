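#' Read a FASTA file
#'
#' Strict FASTA reader for survey-scale nucleotide data. Sequences are
#' uppercased, `U` is mapped to `T`, and anything outside `A/C/G/T/N` is a
#' parse error carrying the file name and line number. Duplicate identifiers
#' and empty files are also errors: silent coercion hides upstream problems
#' in survey pipelines.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; names are the identifiers
#'   (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA parse error at ", path, ":1: expected '>' header")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier '", ids[duplicated(ids)][1], "' in ",
         path)
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste0(x, collapse = ""), character(1))
  # headers with no sequence lines
  if (length(seqs) < length(ids)) {
    missing <- setdiff(as.character(seq_along(ids)), names(seqs))
    stop("FASTA record '", ids[as.integer(missing[1])], "' in ", path,
         " has no sequence")
  }
  seqs <- seqs[as.character(seq_along(ids))]
  seqs <- chartr("acgtun", "ACGTTN", seqs)
  seqs <- chartr("U", "T", seqs)
  bad <- which(!is_dna(seqs))
  if (length(bad) > 0) {
    line <- which(hdr)[bad[1]]
    stop("non-IUPAC nucleotide character in record '", ids[bad[1]],
         "' of ", path, " (record starting at line ", line, ")")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param wrap line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Qualities are parsed but discarded (the survey pipeline is quality-blind;
#' the simulator writes constant dummy qualities).
#'
#' @param path path to a FASTQ file.
#' @return named character vector of sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty FASTQ file: ", path)
  if (length(lines) %% 4 != 0) {
    stop("FASTQ parse error in ", path, ": line count ", length(lines),
         " is not a multiple of 4")
  }
  i <- seq(1L, length(lines), by = 4L)
  bad <- i[!startsWith(lines[i], "@")]
  if (length(bad) > 0) {
    stop("FASTQ parse error at ", path, ":", bad[1], ": expected '@' header")
  }
  ids <- sub("\\s.*$", "", sub("^@", "", lines[i]))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTQ identifier '", ids[duplicated(ids)][1], "' in ",
         path)
  }
  seqs <- toupper(lines[i + 1L])
  seqs <- chartr("U", "T", seqs)
  badseq <- which(!is_dna(seqs))
  if (length(badseq) > 0) {
    stop("non-IUPAC nucleotide character at ", path, ":", i[badseq[1]] + 1L)
  }
  setNames(seqs, ids)
}

#' Write sequences as FASTQ with dummy qualities
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param quality_char single character used for every base quality.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  stopifnot(!is.null(names(seqs)))
  out <- character(4L * length(seqs))
  out[seq(1, length(out), 4)] <- paste0("@", names(seqs))
  out[seq(2, length(out), 4)] <- as.character(seqs)
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <-
    vapply(nchar(seqs), function(n) strrep(quality_char, n), character(1))
  writeLines(out, path)
  invisible(path)
}

ALN_COLS <- c("query_id", "subject_id", "percent_identity",
              "alignment_length", "mismatches", "gap_opens",
              "query_start", "query_end", "subject_start", "subject_end",
              "e_value", "bit_score")

#' Read a 12-column tabular alignment file
#'
#' The dialect is the common tab-separated alignment table: query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end (1-based inclusive; subject coordinates are
#' swapped for minus-strand alignments), e-value and bit score. A `strand`
#' column is derived from the subject coordinate order.
#'
#' @param path path to the tab-separated file.
#' @return data frame with the 12 dialect columns plus `strand`.
#' @export
read_alignment_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_alignments())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stop("alignment table parse error at ", path, ":", i, ": expected 12 ",
         "tab-separated columns, found ", nf[i])
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    query_start = as.integer(m[, 7]), query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]), subject_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  df$strand <- ifelse(df$subject_start > df$subject_end, "-", "+")
  df
}

#' Write alignments in the 12-column tabular dialect
#'
#' @param alignments data frame as produced by [align()] or
#'   [read_alignment_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(alignments, path) {
  stopifnot(all(ALN_COLS %in% names(alignments)))
  df <- alignments[, ALN_COLS]
  df$e_value <- formatC(df$e_value, format = "g", digits = 3)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

empty_alignments <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   percent_identity = numeric(),
                   alignment_length = integer(), mismatches = integer(),
                   gap_opens = integer(), query_start = integer(),
                   query_end = integer(), subject_start = integer(),
                   subject_end = integer(), e_value = numeric(),
                   bit_score = numeric(), strand = character(),
                   stringsAsFactors = FALSE)
  df$score <- numeric()
  df
}

#' Read and write planted-feature truth tables
#'
#' Six-column BED-style TSV: family_id, repeat_class, start (0-based),
#' end (exclusive), copy_index, source_haplotype (`.` for none).
#'
#' @param truth data frame as emitted by [simulate_genome()].
#' @param path file path.
#' @return `read_truth_table`: the truth data frame; `write_truth_table`:
#'   `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  df <- truth
  df$source_haplotype[is.na(df$source_haplotype)] <- "."
  write.table(df[, c("family_id", "repeat_class", "start", "end",
                     "copy_index", "source_haplotype")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("family_id", "repeat_class", "start", "end",
                                 "copy_index", "source_haplotype"))
  df$source_haplotype[df$source_haplotype == "."] <- NA_character_
  df
}

#' Read a YAML run configuration
#'
#' @param path path to a YAML file.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  yaml::read_yaml(path)
}
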