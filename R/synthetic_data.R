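#' Specify a repeat family for genome simulation
#'
#' A family is a master unit sequence replicated `copy_number` times, each
#' copy independently diverged from the master by per-base substitutions at
#' rate `intra_family_divergence` (substitutions only, so planted unit
#' lengths are exact). Centromeric and telomeric families form tandem
#' arrays; all other classes are dispersed.
#'
#' @param family_id identifier.
#' @param repeat_class one of `r paste(REPEAT_CLASSES, collapse = ", ")`.
#' @param unit_length_bp unit length (>= 50).
#' @param copy_number copies per genome (>= 1).
#' @param intra_family_divergence per-base substitution rate in `[0, 0.1]`.
#' @param tandem logical; default follows the class.
#' @return an object of class `repeat_family_spec`.
#' @export
repeat_family_spec <- function(family_id, repeat_class, unit_length_bp,
                               copy_number, intra_family_divergence = 0,
                               tandem = repeat_class %in%
                                 c("centromeric_tandem", "telomere")) {
  repeat_class <- match.arg(repeat_class, REPEAT_CLASSES)
  stopifnot(unit_length_bp >= 50, copy_number >= 1,
            intra_family_divergence >= 0, intra_family_divergence <= 0.1)
  structure(list(family_id = as.character(family_id),
                 repeat_class = repeat_class,
                 unit_length_bp = as.integer(unit_length_bp),
                 copy_number = as.integer(copy_number),
                 intra_family_divergence = intra_family_divergence,
                 tandem = isTRUE(tandem)),
            class = "repeat_family_spec")
}

#' Specify a synthetic genome
#'
#' The genome is i.i.d. background sequence at `gc` GC fraction into which
#' repeat-family copies, genes (exon/intron mosaics) and, when
#' `its_haplotypes` is given, two-haplotype rDNA arrays are planted at
#' random non-overlapping positions.
#'
#' @param genome_size_bp total genome size G.
#' @param families list of [repeat_family_spec()] objects.
#' @param gene_count number of planted genes (exon mosaics).
#' @param mean_exon_bp mean exon length E (default 250).
#' @param mean_cds_bp mean coding length per gene (default 1500).
#' @param intron_bp intron length between planted exons.
#' @param its_haplotypes optional named character vector of exactly two
#'   sequences (>= 150 bp, differing at >= 3 sites) carried by rDNA arrays.
#' @param gc background GC fraction (default 0.44).
#' @param rng_seed integer seed; the same spec always yields the same
#'   genome.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(genome_size_bp, families = list(), gene_count = 0,
                        mean_exon_bp = 250, mean_cds_bp = 1500,
                        intron_bp = 200, its_haplotypes = NULL, gc = 0.44,
                        rng_seed = 1L) {
  stopifnot(genome_size_bp > 0, gene_count >= 0, mean_exon_bp > 0,
            mean_cds_bp > 0)
  if (!is.null(its_haplotypes)) {
    stopifnot(length(its_haplotypes) == 2, !is.null(names(its_haplotypes)))
    if (any(nchar(its_haplotypes) < 150)) {
      stop("ITS haplotypes must be at least 150 bp")
    }
    if (nchar(its_haplotypes[1]) == nchar(its_haplotypes[2])) {
      d <- hamming(its_haplotypes[[1]], its_haplotypes[[2]])
      if (d < 3) stop("ITS haplotypes must differ at >= 3 sites")
    }
  }
  structure(list(genome_size_bp = as.numeric(genome_size_bp),
                 families = families, gene_count = as.integer(gene_count),
                 mean_exon_bp = as.integer(mean_exon_bp),
                 mean_cds_bp = as.integer(mean_cds_bp),
                 intron_bp = as.integer(intron_bp),
                 its_haplotypes = its_haplotypes, gc = gc,
                 rng_seed = as.integer(rng_seed)),
            class = "genome_spec")
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' 454-style read profile
#'
#' @param mean_length_bp mean read length L (default 229).
#' @param length_sd_bp read length standard deviation.
#' @param substitution_rate per-base substitution error rate.
#' @param homopolymer_indel_rate per-run indel rate multiplier; within a
#'   homopolymer run the indel probability is this rate times the run
#'   length, emulating pyrosequencing flow miscalls.
#' @param coverage_fraction target coverage c in (0, 1].
#' @return an object of class `read_profile`.
#' @export
read_profile <- function(mean_length_bp = 229, length_sd_bp = 40,
                         substitution_rate = 0.005,
                         homopolymer_indel_rate = 0.002,
                         coverage_fraction = 0.012) {
  stopifnot(mean_length_bp > 0, length_sd_bp >= 0,
            substitution_rate >= 0, substitution_rate <= 0.05,
            homopolymer_indel_rate >= 0, homopolymer_indel_rate <= 0.05,
            coverage_fraction > 0, coverage_fraction <= 1)
  structure(list(mean_length_bp = mean_length_bp,
                 length_sd_bp = length_sd_bp,
                 substitution_rate = substitution_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 coverage_fraction = coverage_fraction),
            class = "read_profile")
}

#' Small-RNA production profile
#'
#' Signatures are generated per repeat family at a class-specific expected
#' rate per copy per kilobase; realised counts are Poisson. The default
#' rates order classes as observed in grass sRNA surveys (rDNA highest,
#' MITEs intermediate, high-copy retrotransposons lowest per kb); they are
#' free parameters of the simulator, not estimates from any dataset.
#'
#' @param length_range inclusive signature length range within `[18, 32]`.
#' @param fraction_24nt fraction of signatures 24 nt long (default 0.65).
#' @param per_copy_rate_by_class named numeric: expected signatures per
#'   copy per kb of unit sequence for each repeat class.
#' @param library_labels tissue library names sampled uniformly.
#' @return an object of class `srna_profile`.
#' @export
srna_profile <- function(length_range = c(18L, 32L), fraction_24nt = 0.65,
                         per_copy_rate_by_class = c(
                           rDNA = 8, MITE = 4, centromeric_tandem = 2,
                           transposon = 2, retrotransposon = 1,
                           telomere = 0.5, unclassified = 1),
                         library_labels = c("leaf", "inflorescence",
                                            "rhizome")) {
  stopifnot(length(length_range) == 2, length_range[1] >= 18,
            length_range[2] <= 32, length_range[1] <= length_range[2],
            fraction_24nt >= 0, fraction_24nt <= 1,
            all(per_copy_rate_by_class >= 0))
  structure(list(length_range = as.integer(length_range),
                 fraction_24nt = fraction_24nt,
                 per_copy_rate_by_class = per_copy_rate_by_class,
                 library_labels = library_labels),
            class = "srna_profile")
}

# Mutate every copy of a master independently at per-base rate d.
diverge_copies <- function(master, n, d) {
  if (d <= 0) return(rep(master, n))
  vapply(seq_len(n), function(i) mutate_seq(master, d), character(1))
}

#' Simulate a genome with planted repeats, genes and rDNA haplotypes
#'
#' Deterministic given the spec (seeded from `spec$rng_seed`). Every planted
#' feature is enumerated in the returned truth table with 0-based half-open
#' coordinates. rDNA units carry one of the two ITS haplotypes verbatim
#' (family divergence is applied to the flanking unit sequence only, so the
#' diagnostic region stays haplotype-faithful); both haplotypes are
#' guaranteed to appear.
#'
#' @param spec a [genome_spec()].
#' @return list with elements `genome` (single string), `truth` (data frame:
#'   family_id, repeat_class, start, end, copy_index, source_haplotype) and
#'   `masters` (named character vector of family master sequences).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$rng_seed)
  G <- spec$genome_size_bp
  fam_bp <- vapply(spec$families, function(f)
    as.numeric(f$copy_number) * f$unit_length_bp, numeric(1))
  gene_n_exons <- max(1L, round(spec$mean_cds_bp / spec$mean_exon_bp))
  gene_bp <- spec$gene_count *
    (gene_n_exons * spec$mean_exon_bp + (gene_n_exons - 1) * spec$intron_bp)
  cum <- cumsum(c(fam_bp, genes = gene_bp))
  if (length(cum) > 0 && max(cum) > G) {
    over <- which(cum > G)[1]
    nm <- if (over > length(spec$families)) "planted genes" else
      spec$families[[over]]$family_id
    stop("packing error: planted features exceed genome size at '", nm, "'")
  }

  chunks <- list()   # each: list(seq, truth = df or NULL)
  masters <- character(0)
  for (f in spec$families) {
    is_rdna <- f$repeat_class == "rDNA" && !is.null(spec$its_haplotypes)
    if (is_rdna) {
      haps <- spec$its_haplotypes
      hl <- nchar(haps[[1]])
      if (f$unit_length_bp < hl + 20) {
        stop("rDNA unit of '", f$family_id,
             "' too short to carry the ITS haplotype")
      }
      flank1 <- random_dna(10, spec$gc)
      flank2 <- random_dna(f$unit_length_bp - hl - 10, spec$gc)
      master <- paste0(flank1, haps[[1]], flank2)
      hap_choice <- c(1L, 2L,
                      sample(1:2, f$copy_number - 2L, replace = TRUE))
      hap_choice <- hap_choice[seq_len(f$copy_number)]
      copies <- vapply(hap_choice, function(h) {
        paste0(mutate_seq(flank1, f$intra_family_divergence), haps[[h]],
               mutate_seq(flank2, f$intra_family_divergence))
      }, character(1))
      hap_names <- names(haps)[hap_choice]
    } else {
      master <- random_dna(f$unit_length_bp, spec$gc)
      copies <- diverge_copies(master, f$copy_number,
                               f$intra_family_divergence)
      hap_names <- rep(NA_character_, f$copy_number)
    }
    masters[f$family_id] <- master
    tr <- data.frame(family_id = f$family_id,
                     repeat_class = f$repeat_class,
                     start = NA_real_, end = NA_real_,
                     copy_index = seq_len(f$copy_number),
                     source_haplotype = hap_names,
                     stringsAsFactors = FALSE)
    if (f$tandem) {
      # one array chunk; internal offsets are multiples of the unit length
      tr$offset <- (tr$copy_index - 1) * f$unit_length_bp
      tr$len <- f$unit_length_bp
      chunks[[length(chunks) + 1L]] <-
        list(seq = paste0(copies, collapse = ""), truth = tr)
    } else {
      for (i in seq_len(f$copy_number)) {
        tri <- tr[i, , drop = FALSE]
        tri$offset <- 0; tri$len <- f$unit_length_bp
        chunks[[length(chunks) + 1L]] <- list(seq = copies[i], truth = tri)
      }
    }
  }
  if (spec$gene_count > 0) {
    for (g in seq_len(spec$gene_count)) {
      exons <- replicate(gene_n_exons, random_dna(spec$mean_exon_bp,
                                                  spec$gc))
      introns <- replicate(max(gene_n_exons - 1, 0),
                           random_dna(spec$intron_bp, spec$gc))
      parts <- character(0)
      offs <- integer(gene_n_exons)
      pos <- 0L
      for (e in seq_len(gene_n_exons)) {
        offs[e] <- pos
        parts <- c(parts, exons[e])
        pos <- pos + spec$mean_exon_bp
        if (e < gene_n_exons) {
          parts <- c(parts, introns[e])
          pos <- pos + spec$intron_bp
        }
      }
      tr <- data.frame(family_id = sprintf("gene%04d", g),
                       repeat_class = "exon", start = NA_real_,
                       end = NA_real_, copy_index = seq_len(gene_n_exons),
                       source_haplotype = NA_character_,
                       offset = offs, len = spec$mean_exon_bp,
                       stringsAsFactors = FALSE)
      chunks[[length(chunks) + 1L]] <-
        list(seq = paste0(parts, collapse = ""), truth = tr)
    }
  }

  feat_bp <- sum(vapply(chunks, function(ch) nchar(ch$seq), numeric(1)))
  bg_bp <- G - feat_bp
  ord <- if (length(chunks) > 1) sample(length(chunks)) else
    seq_along(chunks)
  n_gap <- length(chunks) + 1L
  gap_len <- if (bg_bp > 0) {
    as.vector(rmultinom(1, bg_bp, rep(1, n_gap)))
  } else rep(0L, n_gap)

  pieces <- character(2L * length(chunks) + 1L)
  truth <- vector("list", length(chunks))
  pos <- 0
  pi <- 1L
  for (i in seq_along(ord)) {
    pieces[pi] <- random_dna(gap_len[i], spec$gc)
    pos <- pos + gap_len[i]
    pi <- pi + 1L
    ch <- chunks[[ord[i]]]
    if (!is.null(ch$truth)) {
      tr <- ch$truth
      tr$start <- pos + tr$offset
      tr$end <- tr$start + tr$len
      tr$offset <- NULL
      tr$len <- NULL
      truth[[i]] <- tr
    }
    pieces[pi] <- ch$seq
    pos <- pos + nchar(ch$seq)
    pi <- pi + 1L
  }
  pieces[pi] <- random_dna(gap_len[n_gap], spec$gc)
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(family_id = character(), repeat_class = character(),
                        start = numeric(), end = numeric(),
                        copy_index = integer(),
                        source_haplotype = character(),
                        stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = paste0(pieces, collapse = ""), truth = truth,
       masters = masters)
}

# Apply homopolymer-scaled indels: each run of identical bases suffers an
# insertion (base duplicated) or deletion with probability rate * run_length,
# capped at 0.5, at most once per run.
apply_homopolymer_indels <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  r <- charToRaw(seq)
  runs <- rle(as.integer(r))
  p <- pmin(rate * runs$lengths, 0.5)
  hit <- runif(length(p)) < p
  if (!any(hit)) return(seq)
  ins <- runif(sum(hit)) < 0.5
  newlen <- runs$lengths
  newlen[hit] <- newlen[hit] + ifelse(ins, 1L, -1L)
  newlen <- pmax(newlen, 0L)
  rawToChar(as.raw(rep(runs$values, newlen)))
}

#' Simulate survey reads from a genome
#'
#' Uniform read starts over both strands; read count is chosen so that the
#' total read bases approximate `coverage_fraction * G`. Substitution errors
#' and homopolymer-scaled indels follow the profile. Read names encode the
#' true origin as `r<i>|<family>|<copy>|<start0>|<strand>` (family `bg`,
#' copy 0 for background reads; a read is attributed to the planted feature
#' it overlaps most), so downstream recovery tests can be label-based.
#'
#' @param genome genome string (or the list returned by
#'   [simulate_genome()]).
#' @param profile a [read_profile()].
#' @param seed integer seed.
#' @param truth optional truth table used for name annotation.
#' @return named character vector of read sequences.
#' @export
simulate_survey_reads <- function(genome, profile, seed = 1L,
                                  truth = NULL) {
  stopifnot(inherits(profile, "read_profile"))
  if (is.list(genome)) {
    if (is.null(truth)) truth <- genome$truth
    genome <- genome$genome
  }
  G <- nchar(genome)
  if (G == 0) stop("empty genome")
  set.seed(seed)
  L <- profile$mean_length_bp
  c_frac <- profile$coverage_fraction
  if (c_frac * G < L) {
    stop("coverage underflow: coverage_fraction * genome size (",
         round(c_frac * G), " bp) is below one read length (", L, " bp)")
  }
  n <- round(c_frac * G / L)
  len <- if (profile$length_sd_bp > 0) {
    pmax(30L, pmin(as.integer(round(rnorm(n, L, profile$length_sd_bp))),
                   G))
  } else rep(as.integer(L), n)
  start0 <- floor(runif(n) * (G - len + 1)) # 0-based
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(genome, start0 + 1, start0 + len)
  neg <- strand == "-"
  seqs[neg] <- revcomp(seqs[neg])
  if (profile$substitution_rate > 0) {
    seqs <- vapply(seqs, mutate_seq, character(1),
                   rate = profile$substitution_rate, USE.NAMES = FALSE)
  }
  if (profile$homopolymer_indel_rate > 0) {
    seqs <- vapply(seqs, apply_homopolymer_indels, character(1),
                   rate = profile$homopolymer_indel_rate,
                   USE.NAMES = FALSE)
  }
  fam <- rep("bg", n)
  copy <- rep(0L, n)
  if (!is.null(truth) && nrow(truth) > 0) {
    q <- IRanges::IRanges(start = start0 + 1, end = start0 + len)
    s <- IRanges::IRanges(start = truth$start + 1, end = truth$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
      ord <- order(qh, -w)
      first <- !duplicated(qh[ord])
      qi <- qh[ord][first]
      si <- sh[ord][first]
      fam[qi] <- truth$family_id[si]
      copy[qi] <- truth$copy_index[si]
    }
  }
  names(seqs) <- sprintf("r%06d|%s|%d|%d|%s", seq_len(n), fam, copy,
                         start0, strand)
  seqs
}

#' Parse provenance-encoded read names
#'
#' @param ids character vector of read names produced by
#'   [simulate_survey_reads()].
#' @return data frame with read_id, family_id, copy_index, start, strand.
#' @export
parse_read_names <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  stopifnot(all(lengths(parts) == 5))
  m <- do.call(rbind, parts)
  data.frame(read_id = ids, family_id = m[, 2],
             copy_index = as.integer(m[, 3]), start = as.numeric(m[, 4]),
             strand = m[, 5], stringsAsFactors = FALSE)
}

#' Simulate small-RNA signatures from planted features
#'
#' The generative model: the expected signature count of a family is its
#' class rate (per copy per kb) times copy number times unit kilobases;
#' realised counts are Poisson. Each signature is a genomic substring of a
#' planted copy (either strand), so it carries that copy's divergence.
#' Signature lengths are 24 nt with probability `fraction_24nt`, otherwise
#' uniform over the rest of the length range.
#'
#' @param truth truth table from [simulate_genome()].
#' @param genome genome string (or the [simulate_genome()] list).
#' @param profile an [srna_profile()].
#' @param seed integer seed.
#' @return data frame: signature_id (encoding `s<i>|<family>|<copy>`),
#'   sequence, length, abundance, library_label.
#' @export
simulate_srna <- function(truth, genome, profile, seed = 1L) {
  stopifnot(inherits(profile, "srna_profile"))
  if (is.list(genome)) genome <- genome$genome
  set.seed(seed)
  empty <- data.frame(signature_id = character(), sequence = character(),
                      length = integer(), abundance = integer(),
                      library_label = character(), stringsAsFactors = FALSE)
  rates <- profile$per_copy_rate_by_class
  feat <- truth[truth$repeat_class %in% names(rates), , drop = FALSE]
  if (nrow(feat) == 0 || all(rates[unique(feat$repeat_class)] == 0)) {
    warning("no small-RNA production: all class rates are zero or no ",
            "eligible features")
    return(empty)
  }
  feat$rate <- rates[feat$repeat_class]
  feat$len <- feat$end - feat$start
  # expected count per planted copy = rate * len/1000; family totals then
  # equal rate * copy_number * unit_kb
  lam <- feat$rate * feat$len / 1000
  counts <- rpois(nrow(feat), lam)
  tot <- sum(counts)
  if (tot == 0) {
    warning("no small-RNA signatures realised (all Poisson counts zero)")
    return(empty)
  }
  idx <- rep(seq_len(nrow(feat)), counts)
  lr <- profile$length_range
  pool <- setdiff(seq(lr[1], lr[2]), 24L)
  has24 <- 24L >= lr[1] && 24L <= lr[2]
  lens <- rep(if (has24) 24L else pool[1], tot)
  if (length(pool) > 0 && (!has24 || profile$fraction_24nt < 1)) {
    other <- if (has24) runif(tot) >= profile$fraction_24nt else
      rep(TRUE, tot)
    lens[other] <- pool[sample.int(length(pool), sum(other),
                                   replace = TRUE)]
  }
  lens <- as.integer(lens)
  lens <- pmin(lens, feat$len[idx])
  start0 <- feat$start[idx] + floor(runif(tot) * (feat$len[idx] - lens + 1))
  seqs <- substring(genome, start0 + 1, start0 + lens)
  neg <- runif(tot) < 0.5
  seqs[neg] <- revcomp(seqs[neg])
  data.frame(
    signature_id = sprintf("s%06d|%s|%d", seq_len(tot), feat$family_id[idx],
                           feat$copy_index[idx]),
    sequence = seqs, length = lens, abundance = 1L,
    library_label = sample(profile$library_labels, tot, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Extract the planted coding sequences from a simulated genome
#'
#' Concatenates the planted exons of each gene, giving the reference
#' "CDS set" used by the gene-space analysis.
#'
#' @param sim the list returned by [simulate_genome()].
#' @return named character vector of coding sequences.
#' @export
truth_cds_set <- function(sim) {
  ex <- sim$truth[sim$truth$repeat_class == "exon", , drop = FALSE]
  if (nrow(ex) == 0) return(setNames(character(0), character(0)))
  ex <- ex[order(ex$family_id, ex$copy_index), ]
  seqs <- substring(sim$genome, ex$start + 1, ex$end)
  vapply(split(seqs, ex$family_id), paste0, character(1), collapse = "")
}
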