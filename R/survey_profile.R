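# Rounding conventions are pinned per quantity: the printed figures of a
# survey report are only reproducible under one specific rule each, so each
# function applies (and documents) its own.

trunc_decimals <- function(x, digits) trunc(x * 10^digits) / 10^digits

signif2 <- function(x) signif(x, 2)

#' Basic read-set statistics
#'
#' GC fraction counts G+C over A+C+G+T; `N` bases are excluded from both
#' numerator and denominator (but do count toward lengths).
#'
#' @param reads character vector of read sequences.
#' @return list with count, total_bp, mean_length_bp, gc_fraction.
#' @export
read_stats <- function(reads) {
  if (length(reads) == 0) stop("empty read set")
  lens <- nchar(reads)
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(unname(reads)), c("A", "C", "G", "T"))
  acgt <- sum(counts)
  gc <- sum(counts[, c("C", "G")])
  list(count = length(reads), total_bp = sum(lens),
       mean_length_bp = sum(lens) / length(reads),
       gc_fraction = if (acgt > 0) gc / acgt else NA_real_)
}

#' Genome size from flow-cytometry DNA content
#'
#' Converts measured DNA contents in picograms to genome size using a fixed
#' Mbp-per-pg constant (default 980), averaging over measurements. The
#' total is additionally reported rounded to the nearest 0.5 Gbp and the
#' per-haploid size to two significant figures, the conventions under which
#' survey-report figures are printed.
#'
#' @param pg_values measured DNA contents (pg), e.g. 3C values for a
#'   triploid.
#' @param mbp_per_pg conversion constant (default 980 Mbp/pg).
#' @param ploidy number of component genomes (default 3).
#' @return list with total_gbp_raw, total_gbp (nearest 0.5),
#'   per_haploid_gbp_raw, per_haploid_gbp (2 significant figures).
#' @export
genome_size_from_pg <- function(pg_values, mbp_per_pg = 980, ploidy = 3) {
  if (length(pg_values) == 0) stop("no pg measurements supplied")
  stopifnot(all(pg_values > 0), ploidy >= 1)
  total <- mean(pg_values) * mbp_per_pg / 1000
  list(total_gbp_raw = total, total_gbp = round(total * 2) / 2,
       per_haploid_gbp_raw = total / ploidy,
       per_haploid_gbp = signif2(total / ploidy))
}

#' Survey coverage fraction
#'
#' @param total_read_bp total sequenced bases.
#' @param effective_genome_bp effective genome size.
#' @return list with `coverage` (fraction) and `percent`.
#' @export
coverage_estimate <- function(total_read_bp, effective_genome_bp) {
  if (effective_genome_bp <= 0) stop("effective genome size must be > 0")
  if (total_read_bp < 0) stop("total read bp must be >= 0")
  c_frac <- total_read_bp / effective_genome_bp
  list(coverage = c_frac, percent = 100 * c_frac)
}

#' Screen reads against organellar (or other contaminant) references
#'
#' A read counts once per reference if it has any alignment with e-value at
#' or below the cutoff. Percentages are truncated (not rounded) to two
#' decimals, the convention under which printed contamination figures are
#' reproducible from their read counts.
#'
#' @param reads named character vector of reads.
#' @param organelle_refs named character vector of reference sequences.
#' @param evalue_cutoff e-value gate (default 1e-6).
#' @param params aligner parameters.
#' @return data frame: reference, hit_count, percent.
#' @export
contamination_screen <- function(reads, organelle_refs,
                                 evalue_cutoff = 1e-6,
                                 params = aligner_params()) {
  stopifnot(length(organelle_refs) > 0)
  aln <- align_many(reads, organelle_refs, params)
  aln <- aln[aln$e_value <= evalue_cutoff, , drop = FALSE]
  hits <- vapply(names(organelle_refs), function(ref) {
    length(unique(aln$query_id[aln$subject_id == ref]))
  }, integer(1))
  contamination_percent(hits, length(reads),
                        reference = names(organelle_refs))
}

#' @rdname contamination_screen
#' @param hit_count integer vector of per-reference read hit counts.
#' @param total_reads total number of reads screened.
#' @param reference reference labels.
#' @export
contamination_percent <- function(hit_count, total_reads,
                                  reference = names(hit_count)) {
  data.frame(reference = reference %||% as.character(seq_along(hit_count)),
             hit_count = as.integer(hit_count),
             percent = trunc_decimals(100 * hit_count / total_reads, 2),
             stringsAsFactors = FALSE)
}

#' Best-hit identity histogram
#'
#' Each read contributes its single best alignment (highest bit score, ties
#' broken by identity). Bin heights are fractions of all reads, so the bins
#' sum to the matched-read fraction (at most 1).
#'
#' @param alignments alignment data frame.
#' @param total_reads total number of reads surveyed (the denominator).
#' @param bin_width identity bin width in percentage points (default 1).
#' @param range identity range covered by the bins.
#' @return data frame: bin_low, bin_high, fraction.
#' @export
identity_histogram <- function(alignments, total_reads, bin_width = 1,
                               range = c(75, 100)) {
  if (nrow(alignments) == 0) {
    return(data.frame(bin_low = numeric(), bin_high = numeric(),
                      fraction = numeric()))
  }
  best <- best_hits(alignments)
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  bin <- cut(best$percent_identity, breaks = breaks, include.lowest = TRUE,
             right = FALSE)
  # put exact 100% identities into the last bin
  bin[best$percent_identity >= range[2]] <- levels(bin)[length(levels(bin))]
  tab <- table(bin)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             fraction = as.numeric(tab) / total_reads,
             stringsAsFactors = FALSE)
}

#' Select gene-space survey reads
#'
#' Coding-sequence references that themselves match the repeat library (at
#' the e-value cutoff) are removed first; reads whose best hit against the
#' filtered references falls inside the identity window (inclusive at both
#' edges, exclusive of everything outside, including 100%) are selected as
#' likely single-copy gene-space reads.
#'
#' @param reads named character vector of reads.
#' @param cds_set named character vector of coding reference sequences.
#' @param repeat_library named character vector of repeat sequences (may be
#'   empty).
#' @param identity_window inclusive identity window, default `c(94, 99)`.
#' @param evalue_cutoff repeat-filter e-value gate.
#' @param params aligner parameters.
#' @return list: `reads` (selected read ids), `fraction` (of all reads),
#'   `filtered_cds` (retained reference ids), `n_repeat_cds` (removed).
#' @export
gene_space_reads <- function(reads, cds_set, repeat_library = character(0),
                             identity_window = c(94, 99),
                             evalue_cutoff = 1e-6,
                             params = aligner_params()) {
  stopifnot(length(cds_set) > 0)
  repeat_cds <- character(0)
  if (length(repeat_library) > 0) {
    flt <- align_many(cds_set, repeat_library, params)
    repeat_cds <- unique(flt$query_id[flt$e_value <= evalue_cutoff])
  }
  kept <- setdiff(names(cds_set), repeat_cds)
  if (length(kept) == 0) {
    stop("no coding references remain after repeat filtering")
  }
  aln <- align_many(reads, cds_set[kept], params)
  best <- best_hits(aln)
  sel <- best$query_id[best$percent_identity >= identity_window[1] &
                         best$percent_identity <= identity_window[2]]
  list(reads = sel, fraction = length(sel) / length(reads),
       filtered_cds = kept, n_repeat_cds = length(repeat_cds))
}

#' Exon-space fraction of coding-matching survey sequence
#'
#' Fraction of read sequence expected to lie within exons among reads that
#' match coding references: `E / (E + L - 2m)` for mean exon length `E`,
#' mean read length `L` and minimum exon overlap `m` required for a
#' full-length match. Monotonically decreasing in `L`, increasing in `m`.
#'
#' @param mean_exon_bp mean exon length E (default 250).
#' @param mean_read_bp mean read length L (default 229).
#' @param min_overlap_bp minimum exon overlap m (default 50).
#' @return list: `fraction`, `percent` (rounded to nearest integer).
#' @export
exon_space_fraction <- function(mean_exon_bp = 250, mean_read_bp = 229,
                                min_overlap_bp = 50) {
  stopifnot(mean_exon_bp > 0, mean_read_bp > 0, min_overlap_bp >= 0)
  den <- mean_exon_bp + mean_read_bp - 2 * min_overlap_bp
  if (den <= 0) stop("degenerate geometry: E + L - 2m must be positive")
  f <- mean_exon_bp / den
  list(fraction = f, percent = round(100 * f))
}

#' Gene-content chain from the coding read fraction
#'
#' Multiplies the fraction of reads matching coding references by the
#' exon-space fraction to give the genomic coding fraction (reported as a
#' percentage rounded to one decimal, the printed convention), converts to
#' coding bp over the effective genome, divides by the mean coding length
#' per gene for total loci, and reports loci per component genome rounded
#' to the nearest 1,000. The rounded coding percentage feeds the downstream
#' products, which is what makes the printed chain internally consistent.
#'
#' @param coding_read_fraction fraction of survey reads in the gene-space
#'   identity window.
#' @param effective_genome_bp effective genome size G.
#' @param mean_exon_bp,mean_read_bp,min_overlap_bp see
#'   [exon_space_fraction()].
#' @param mean_cds_bp coding bp per gene (default 1500).
#' @param n_subgenomes component genomes (default 3).
#' @return list: coding_fraction_raw, coding_percent, coding_bp,
#'   loci_total, loci_per_subgenome.
#' @export
gene_content_estimate <- function(coding_read_fraction, effective_genome_bp,
                                  mean_exon_bp = 250, mean_read_bp = 229,
                                  min_overlap_bp = 50, mean_cds_bp = 1500,
                                  n_subgenomes = 3) {
  stopifnot(coding_read_fraction >= 0, coding_read_fraction <= 1)
  if (is.null(effective_genome_bp) || is.na(effective_genome_bp)) {
    stop("effective genome size is required")
  }
  esf <- exon_space_fraction(mean_exon_bp, mean_read_bp, min_overlap_bp)
  raw <- coding_read_fraction * esf$fraction
  pct <- round(100 * raw, 1)
  coding_bp <- pct / 100 * effective_genome_bp
  loci <- coding_bp / mean_cds_bp
  list(coding_fraction_raw = raw, coding_percent = pct,
       coding_bp = coding_bp, loci_total = loci,
       loci_per_subgenome = round(loci / n_subgenomes / 1000) * 1000)
}
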