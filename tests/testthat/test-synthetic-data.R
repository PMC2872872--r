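test_that("genome simulation is deterministic given the spec", {
  fams <- list(repeat_family_spec("f1", "MITE", 300, 20, 0.01))
  spec <- genome_spec(50000, fams, gene_count = 2, rng_seed = 9)
  a <- simulate_genome(spec)
  b <- simulate_genome(spec)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
})

test_that("planted copies are conserved exactly at zero divergence", {
  fams <- list(repeat_family_spec("f1", "retrotransposon", 1000, 100, 0))
  sim <- simulate_genome(genome_spec(500000, fams, rng_seed = 2))
  tr <- sim$truth[sim$truth$family_id == "f1", ]
  expect_equal(nrow(tr), 100)
  expect_true(all(tr$end - tr$start == 1000))
  copies <- substring(sim$genome, tr$start + 1, tr$end)
  expect_true(all(copies == sim$masters[["f1"]]))
  expect_true(all(tr$start >= 0 & tr$end <= 500000))
})

test_that("copy divergence follows the binomial substitution model", {
  d <- 0.02
  fams <- list(repeat_family_spec("f1", "transposon", 1000, 100, d))
  sim <- simulate_genome(genome_spec(500000, fams, rng_seed = 3))
  tr <- sim$truth[sim$truth$family_id == "f1", ]
  copies <- substring(sim$genome, tr$start + 1, tr$end)
  master <- sim$masters[["f1"]]
  dist <- vapply(copies, function(s)
    sum(charToRaw(s) != charToRaw(master)), numeric(1))
  # mean Hamming distance ~ Binomial(1000, 0.02): mean 20,
  # sd of the mean over 100 copies = sqrt(1000 * .02 * .98 / 100)
  expect_lt(abs(mean(dist) - 1000 * d),
            3 * sqrt(1000 * d * (1 - d) / 100))
})

test_that("tandem arrays are contiguous and infeasible packing errors", {
  fams <- list(repeat_family_spec("cen", "centromeric_tandem", 200, 50,
                                  0))
  sim <- simulate_genome(genome_spec(50000, fams, rng_seed = 4))
  tr <- sim$truth
  expect_true(all(diff(tr$start) == 200))
  big <- list(repeat_family_spec("huge", "MITE", 1000, 100, 0))
  expect_error(simulate_genome(genome_spec(50000, big, rng_seed = 1)),
               "packing error.*huge")
})

test_that("error-free reads are exact genomic substrings", {
  set.seed(1)
  genome <- random_dna(23000, 0.44)
  prof <- read_profile(mean_length_bp = 230, length_sd_bp = 0,
                       substitution_rate = 0, homopolymer_indel_rate = 0,
                       coverage_fraction = 0.1)
  reads <- simulate_survey_reads(genome, prof, seed = 5)
  expect_equal(length(reads), 10)
  pr <- parse_read_names(names(reads))
  for (i in seq_along(reads)) {
    s <- substr(genome, pr$start[i] + 1, pr$start[i] + nchar(reads[i]))
    expect_identical(unname(reads[i]),
                     if (pr$strand[i] == "+") s else revcomp(s))
  }
})

test_that("read totals conserve the requested coverage", {
  set.seed(2)
  genome <- random_dna(1e6, 0.44)
  reads <- simulate_survey_reads(genome,
                                 read_profile(coverage_fraction = 0.012),
                                 seed = 6)
  expect_lt(abs(sum(nchar(reads)) - 12000) / 12000, 0.05)
  expect_error(
    simulate_survey_reads(random_dna(1000, 0.5),
                          read_profile(coverage_fraction = 0.012),
                          seed = 1),
    "underflow")
})

test_that("per-base depth is Poisson and strands are balanced", {
  set.seed(3)
  G <- 2.3e6
  genome <- random_dna(G, 0.44)
  prof <- read_profile(substitution_rate = 0, homopolymer_indel_rate = 0,
                       coverage_fraction = 1)
  reads <- simulate_survey_reads(genome, prof, seed = 7)
  pr <- parse_read_names(names(reads))
  expect_gt(length(reads), 1e4)
  frac_plus <- mean(pr$strand == "+")
  expect_lt(abs(frac_plus - 0.5), 0.03)
  # depth at positions spaced a read length apart (independent draws)
  pos <- seq(1000, G - 1000, by = 500)
  lens <- nchar(reads)
  cover <- vapply(pos, function(p)
    sum(pr$start < p & pr$start + lens >= p), numeric(1))
  lambda <- 1 # coverage fraction
  breaks <- c(-0.5, 0.5, 1.5, 2.5, Inf)
  obs <- table(cut(cover, breaks))
  p_exp <- c(dpois(0:2, lambda), 1 - ppois(2, lambda))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = p_exp))
  expect_gt(gof$p.value, 0.01)
})

test_that("small-RNA counts scale with copy number at fixed class rate", {
  fams <- list(repeat_family_spec("a", "MITE", 300, 100, 0),
               repeat_family_spec("b", "MITE", 300, 200, 0))
  sim <- simulate_genome(genome_spec(300000, fams, rng_seed = 8))
  prof <- srna_profile(per_copy_rate_by_class = c(MITE = 4))
  sig <- simulate_srna(sim$truth, sim$genome, prof, seed = 9)
  fam <- vapply(strsplit(sig$signature_id, "|", fixed = TRUE), `[[`,
                character(1), 2)
  n <- table(fam)
  lam <- c(a = 4 * 100 * 0.3, b = 4 * 200 * 0.3)
  # log count ratio within a 99% Poisson band of log 2
  expect_lt(abs(log(n[["b"]] / n[["a"]]) - log(2)),
            2.58 * sqrt(1 / lam[["a"]] + 1 / lam[["b"]]))
  # each signature is a genomic substring of its source copy
  tr <- sim$truth
  copy <- vapply(strsplit(sig$signature_id, "|", fixed = TRUE), `[[`,
                 character(1), 3)
  for (i in seq_len(min(nrow(sig), 50))) {
    row <- tr[tr$family_id == fam[i] & tr$copy_index == as.integer(copy[i]), ]
    region <- substr(sim$genome, row$start + 1, row$end)
    hit <- grepl(sig$sequence[i], region, fixed = TRUE) ||
      grepl(revcomp(sig$sequence[i]), region, fixed = TRUE)
    expect_true(hit)
  }
})

test_that("signature lengths follow the profile", {
  fams <- list(repeat_family_spec("a", "rDNA", 500, 50, 0))
  sim <- simulate_genome(genome_spec(100000, fams, rng_seed = 10))
  all24 <- simulate_srna(sim$truth, sim$genome,
                         srna_profile(fraction_24nt = 1,
                                      per_copy_rate_by_class = c(rDNA = 5)),
                         seed = 11)
  expect_true(all(all24$length == 24))
  expect_true(all(nchar(all24$sequence) == 24))
  mixed <- simulate_srna(sim$truth, sim$genome,
                         srna_profile(fraction_24nt = 0.65,
                                      per_copy_rate_by_class = c(rDNA = 20)),
                         seed = 12)
  expect_true(all(mixed$length >= 18 & mixed$length <= 32))
  f24 <- mean(mixed$length == 24)
  expect_lt(abs(f24 - 0.65), 3 * sqrt(0.65 * 0.35 / nrow(mixed)))
  expect_warning(
    none <- simulate_srna(sim$truth, sim$genome,
                          srna_profile(per_copy_rate_by_class = c(rDNA = 0)),
                          seed = 13),
    "zero")
  expect_equal(nrow(none), 0)
})

test_that("planted genes expose their coding sequences", {
  spec <- genome_spec(100000, gene_count = 3, rng_seed = 14)
  sim <- simulate_genome(spec)
  cds <- truth_cds_set(sim)
  expect_length(cds, 3)
  expect_true(all(nchar(cds) == 6 * 250)) # 1500 bp in 250-bp exons
})
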