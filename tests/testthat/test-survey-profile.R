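test_that("read statistics count bases and GC correctly", {
  st <- read_stats(c("ACGT", "AACC"))
  expect_equal(st$count, 2)
  expect_equal(st$total_bp, 8)
  expect_equal(st$mean_length_bp, 4)
  expect_equal(st$gc_fraction, 0.5)
  # all-N reads count toward lengths but not GC
  st2 <- read_stats(c("GGCC", "NNNN"))
  expect_equal(st2$total_bp, 8)
  expect_equal(st2$gc_fraction, 1)
  expect_error(read_stats(character(0)), "empty")
})

test_that("genome size conversion reproduces printed figures", {
  gs <- genome_size_from_pg(c(7.60, 7.95))
  expect_equal(gs$total_gbp_raw, mean(c(7.60, 7.95)) * 0.98)
  expect_equal(gs$total_gbp, 7.5)
  expect_equal(gs$per_haploid_gbp, 2.5)
  expect_equal(genome_size_from_pg(1, ploidy = 1)$total_gbp_raw, 0.98)
  # linear in the measured contents
  a <- genome_size_from_pg(c(2, 3))
  b <- genome_size_from_pg(c(4, 6))
  expect_equal(b$total_gbp_raw, 2 * a$total_gbp_raw)
  expect_error(genome_size_from_pg(numeric(0)), "no pg")
})

test_that("coverage estimate is a simple ratio with guards", {
  expect_equal(coverage_estimate(84e6, 7.5e9)$coverage, 0.0112)
  expect_equal(coverage_estimate(5e6, 5e6)$coverage, 1)
  expect_equal(coverage_estimate(0, 5e6)$coverage, 0)
  expect_error(coverage_estimate(1, 0), "> 0")
})

test_that("contamination percentages are truncated, not rounded", {
  cp <- contamination_percent(c(chloroplast = 901L), 366448L)
  expect_equal(cp$percent, 0.24) # 0.2458... truncates to 0.24
  expect_equal(contamination_percent(c(x = 0L), 1000L)$percent, 0)
  expect_equal(contamination_percent(c(x = 999L), 100000L)$percent, 0.99)
})

test_that("contamination screen recovers planted organelle reads", {
  set.seed(21)
  genome <- random_dna(2e5, 0.44)
  organelle <- c(chloroplast = random_dna(5000, 0.4))
  prof <- read_profile(coverage_fraction = 0.25)
  reads <- simulate_survey_reads(genome, prof, seed = 22)
  org_reads <- simulate_survey_reads(organelle[[1]],
                                     read_profile(coverage_fraction = 0.5),
                                     seed = 23)
  names(org_reads) <- sub("^r", "org", names(org_reads))
  all_reads <- c(reads, org_reads)
  scr <- contamination_screen(all_reads, organelle)
  aln <- align_many(all_reads, organelle)
  hit_ids <- unique(aln$query_id[aln$e_value <= 1e-6])
  planted <- names(org_reads)
  expect_gte(sum(planted %in% hit_ids) / length(planted), 0.95)
  false_pos <- setdiff(hit_ids, planted)
  expect_lte(length(false_pos) / length(reads), 0.0005)
  expect_equal(scr$hit_count,
               length(unique(aln$query_id[aln$e_value <= 1e-6])))
})

test_that("identity histograms place best hits in the right bins", {
  aln <- data.frame(query_id = c("a", "b"), subject_id = "s",
                    percent_identity = c(100, 100),
                    bit_score = c(100, 90), stringsAsFactors = FALSE)
  h <- identity_histogram(aln, total_reads = 2)
  expect_equal(sum(h$fraction), 1)
  expect_equal(h$fraction[h$bin_low == 99], 1)
  empty <- identity_histogram(empty_aln <- aln[0, ], total_reads = 10)
  expect_equal(nrow(empty), 0)
})

test_that("histogram mode tracks a fixed substitution rate", {
  set.seed(24)
  ref <- c(ref = random_dna(2000, 0.5))
  reads <- vapply(1:100, function(i) {
    s <- sample.int(1800, 1)
    mutate_positions(substr(ref[[1]], s, s + 199), sample.int(200, 10))
  }, character(1))
  names(reads) <- sprintf("m%03d", 1:100)
  aln <- align_many(reads, ref)
  h <- identity_histogram(aln, total_reads = 100)
  mode_bin <- h$bin_low[which.max(h$fraction)]
  expect_lte(abs(mode_bin - 95), 1)
  # mass conservation: fractions sum to the matched-read fraction
  expect_equal(sum(h$fraction),
               length(unique(aln$query_id)) / 100)
})

test_that("exon-space fraction reproduces the printed arithmetic", {
  esf <- exon_space_fraction(250, 229, 50)
  expect_equal(esf$fraction, 250 / 379, tolerance = 1e-12)
  expect_equal(esf$percent, 66)
  expect_equal(exon_space_fraction(250, 100, 50)$fraction, 1)
  # decreasing in read length, increasing in the minimum overlap
  expect_gt(exon_space_fraction(250, 200, 50)$fraction,
            exon_space_fraction(250, 300, 50)$fraction)
  expect_gt(exon_space_fraction(250, 229, 60)$fraction,
            exon_space_fraction(250, 229, 40)$fraction)
  expect_error(exon_space_fraction(100, 50, 100), "degenerate")
})

test_that("exon-space fraction approximates a placement simulation", {
  # read placement over an exon/intron mosaic with 150-bp introns (short
  # grass-like introns; the closed form overstates the exonic fraction
  # for long-intron geometries)
  set.seed(25)
  E <- 250; L <- 229; m <- 50; intron <- 150
  n_ex <- 40
  starts <- (0:(n_ex - 1)) * (E + intron)
  glen <- n_ex * (E + intron)
  rs <- floor(runif(2e5) * (glen - L))
  ov_tot <- numeric(length(rs))
  maxov <- numeric(length(rs))
  for (s in starts) {
    o <- pmin(rs + L, s + E) - pmax(rs, s)
    o[o < 0] <- 0
    ov_tot <- ov_tot + o
    maxov <- pmax(maxov, o)
  }
  sel <- maxov >= m
  mc <- sum(ov_tot[sel]) / (sum(sel) * L)
  expect_lte(abs(mc - exon_space_fraction(E, L, m)$fraction), 0.02)
})

test_that("gene-content chain reproduces the printed survey figures", {
  est <- gene_content_estimate(0.034, 7.5e9)
  expect_equal(est$coding_percent, 2.2)
  expect_equal(est$coding_bp, 165e6)
  expect_equal(est$loci_total, 110000)
  expect_equal(est$loci_per_subgenome, 37000)
  zero <- gene_content_estimate(0, 7.5e9)
  expect_equal(zero$coding_bp, 0)
  expect_equal(zero$loci_per_subgenome, 0)
  dbl <- gene_content_estimate(0.034, 15e9)
  expect_equal(dbl$coding_bp, 2 * est$coding_bp)
  expect_equal(dbl$loci_total, 2 * est$loci_total)
  expect_equal(dbl$coding_percent, est$coding_percent)
})

test_that("gene-space window is inclusive and repeat-filtered", {
  set.seed(26)
  cds <- c(gene1 = random_dna(600, 0.5), gene2 = random_dna(600, 0.5),
           repgene = random_dna(600, 0.5))
  lib <- c("retrotransposon|fam9|x" = cds[["repgene"]])
  # read identical to a clean cds: 100% identity, outside [94, 99]
  perfect <- c(p1 = substr(cds[["gene1"]], 100, 328))
  # read at ~96%: inside the window
  ninety6 <- c(n1 = mutate_positions(substr(cds[["gene2"]], 100, 328),
                                     sample(229, 9)))
  # read matching only the repeat-flagged cds
  repread <- c(rp = substr(cds[["repgene"]], 100, 328))
  res <- gene_space_reads(c(perfect, ninety6, repread), cds, lib)
  expect_identical(res$reads, "n1")
  expect_equal(res$n_repeat_cds, 1)
  expect_false("repgene" %in% res$filtered_cds)
  expect_error(gene_space_reads(perfect, cds["repgene"], lib),
               "repeat filtering")
})

test_that("gene-space selection tracks the planted genic read fraction", {
  # genome with planted genes; the coding reference is a 4%-diverged
  # relative (sister-species CDS), so genic reads land in the 94-99%
  # identity window
  spec <- genome_spec(4e5, gene_count = 40, rng_seed = 27)
  sim <- simulate_genome(spec)
  set.seed(28)
  cds_rel <- vapply(truth_cds_set(sim), mutate_seq, character(1),
                    rate = 0.03)
  reads <- simulate_survey_reads(sim,
                                 read_profile(coverage_fraction = 0.15),
                                 seed = 29)
  res <- gene_space_reads(reads, cds_rel, character(0))
  # oracle: reads overlapping a planted exon by >= 50 bp (the minimum
  # exon overlap of the gene-content model)
  pr <- parse_read_names(names(reads))
  ex <- sim$truth[sim$truth$repeat_class == "exon", ]
  q <- IRanges::IRanges(pr$start + 1, pr$start + nchar(reads))
  s <- IRanges::IRanges(ex$start + 1, ex$end)
  ov <- IRanges::findOverlaps(q, s, minoverlap = 50)
  truth_frac <- length(unique(S4Vectors::from(ov))) / length(reads)
  expect_lte(abs(res$fraction - truth_frac) / truth_frac, 0.2)
})
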