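# Shared fixture: an rDNA tandem array carrying two ITS haplotypes.
make_rdna_sim <- function(seed = 81, copies = 60, unit = 600,
                          n_diff = 5) {
  set.seed(seed)
  hapA <- random_dna(200, 0.5)
  hapB <- mutate_positions(hapA, round(seq(20, 190, length.out = n_diff)))
  haps <- c(hapA = hapA, hapB = hapB)
  fam <- list(repeat_family_spec("rdna1", "rDNA", unit, copies, 0.004))
  sim <- simulate_genome(genome_spec(1e5, fam, its_haplotypes = haps,
                                     rng_seed = seed))
  list(sim = sim, haps = haps,
       anchor = c(anchor = sim$masters[["rdna1"]]))
}

test_that("rDNA mining selects matching reads with high sensitivity", {
  fx <- make_rdna_sim()
  reads <- simulate_survey_reads(fx$sim,
                                 read_profile(coverage_fraction = 0.3),
                                 seed = 82)
  mined <- mine_rdna_reads(reads, fx$anchor)
  # oracle: reads overlapping the rDNA array by >= 50 bp (shorter overlaps
  # fall below the aligner's reporting threshold by construction)
  pr <- parse_read_names(names(reads))
  tr <- fx$sim$truth
  q <- IRanges::IRanges(pr$start + 1, pr$start + nchar(reads))
  s <- IRanges::IRanges(tr$start + 1, tr$end)
  ov <- IRanges::findOverlaps(q, s, minoverlap = 50)
  truth_rdna <- names(reads)[unique(S4Vectors::from(ov))]
  expect_gte(sum(truth_rdna %in% names(mined$reads)) / length(truth_rdna),
             0.95)
  expect_equal(mined$per_anchor[["anchor"]], mined$n)
  # an unrelated read is rejected
  set.seed(83)
  stray <- c(stray = random_dna(229, 0.5))
  expect_equal(mine_rdna_reads(stray, fx$anchor)$n, 0)
})

test_that("anchored alignments reproduce the anchor and its variants", {
  set.seed(84)
  anchor <- c(anc = random_dna(400, 0.5))
  # two clean reads tiling the anchor
  tiles <- c(r1 = substr(anchor[[1]], 1, 220),
             r2 = substr(anchor[[1]], 181, 400))
  aln <- build_its_alignment(tiles, anchor)
  expect_equal(ncol(aln$mat), 400) # no insertions
  anc_row <- aln$mat[match("anc", aln$ids), ]
  for (r in c("r1", "r2")) {
    row <- aln$mat[match(r, aln$ids), ]
    covered <- row != "."
    expect_true(all(row[covered] == anc_row[covered]))
  }
  # a read with one substitution yields exactly one variant column
  mut <- c(m1 = mutate_positions(substr(anchor[[1]], 50, 280), 100))
  aln2 <- build_its_alignment(mut, anchor)
  row <- aln2$mat[match("m1", aln2$ids), ]
  anc2 <- aln2$mat[match("anc", aln2$ids), ]
  covered <- row != "."
  expect_equal(sum(row[covered] != anc2[covered]), 1)
  # rows failing the gate are dropped with a reason
  set.seed(85)
  junk <- c(j = random_dna(229, 0.5))
  expect_error(build_its_alignment(junk, anchor), "gate")
})

test_that("block trimming is strict at the gap threshold and idempotent", {
  # hand-built alignment: 20 rows x 10 anchor columns, plus one insertion
  # column gapped in 19/20 rows (95%, kept) and one gapped in 20/20
  n <- 20
  mat <- matrix("A", n, 12)
  col_anchor <- c(0, 1, 2, 3, 3.5, 4, 5, 5.5, 6, 7, 8, 9)
  mat[, 5] <- c(rep("-", n - 1), "C")   # 95% gapped: kept (strict >)
  mat[, 8] <- rep("-", n)               # 100% gapped: removed
  aln <- structure(list(mat = mat, ids = sprintf("r%02d", 1:n),
                        origin = c("reference", rep("read", n - 1)),
                        col_anchor = col_anchor, anchor = "r01",
                        dropped = NULL),
                   class = "its_alignment")
  blk <- trim_block(aln, region = c(0, 10))
  expect_true(3.5 %in% blk$col_anchor)    # 95% column kept
  expect_false(5.5 %in% blk$col_anchor)   # 100% column removed
  blk2 <- trim_block(blk, region = c(0, 10))
  expect_identical(blk2$mat, blk$mat)
  expect_identical(blk2$col_anchor, blk$col_anchor)
  # gap-free alignments trim to the region slice
  clean <- structure(list(mat = matrix("G", 4, 10), ids = paste0("s", 1:4),
                          origin = rep("read", 4), col_anchor = 0:9,
                          anchor = "x", dropped = NULL),
                     class = "its_alignment")
  blk3 <- trim_block(clean, region = c(2, 7))
  expect_equal(ncol(blk3$mat), 5)
  expect_equal(blk3$col_anchor, 2:6)
  expect_error(trim_block(clean, region = c(0, 50)), "longer")
})

test_that("rows with uncovered cells or N are dropped from blocks", {
  mat <- rbind(rep("A", 6),
               c("A", "A", ".", "A", "A", "A"),
               c("A", "N", "A", "A", "A", "A"),
               rep("A", 6))
  aln <- structure(list(mat = mat, ids = c("ref", "partial", "noisy",
                                           "good"),
                        origin = c("reference", "read", "read", "read"),
                        col_anchor = 0:5, anchor = "ref", dropped = NULL),
                   class = "its_alignment")
  blk <- trim_block(aln, region = c(0, 6))
  expect_setequal(blk$ids, c("ref", "good"))
})

test_that("parentage calls go to the strict nearest haplotype", {
  mat <- rbind(
    c("A", "C", "G", "T", "A", "C"),  # hapA
    c("A", "C", "G", "T", "G", "T"),  # hapB (differs at cols 5, 6)
    c("A", "C", "G", "T", "A", "C"),  # read identical to hapA
    c("A", "C", "G", "T", "G", "T"),  # read identical to hapB
    c("A", "C", "G", "T", "A", "T"))  # equidistant
  blk <- structure(list(mat = mat,
                        ids = c("hapA", "hapB", "ra", "rb", "rtie"),
                        origin = c("reference", "reference", "read",
                                   "read", "read"),
                        col_anchor = 0:5, anchor = "hapA",
                        region = c(0, 6)),
                   class = "its_block")
  res <- classify_parentage(blk, c("hapA", "hapB"))
  calls <- setNames(res$calls$assigned_haplotype, res$calls$read_id)
  expect_identical(calls[["ra"]], "hapA")
  expect_identical(res$calls$distance_to_best[res$calls$read_id == "ra"],
                   0L)
  expect_identical(calls[["rb"]], "hapB")
  expect_identical(calls[["rtie"]], "ambiguous")
  expect_equal(unname(res$tallies),
               c(1L, 1L, 1L))
  # identical haplotypes are rejected
  same <- blk
  same$mat[2, ] <- same$mat[1, ]
  expect_error(classify_parentage(same, c("hapA", "hapB")),
               "discriminating")
})

test_that("classification ignores row order and agreeing columns", {
  fx <- make_rdna_sim(seed = 86)
  reads <- simulate_survey_reads(fx$sim,
                                 read_profile(mean_length_bp = 400,
                                              length_sd_bp = 20,
                                              coverage_fraction = 0.5),
                                 seed = 87)
  mined <- mine_rdna_reads(reads, fx$anchor)
  refs <- c(fx$anchor,
            hapA = paste0(substr(fx$anchor, 1, 10), fx$haps[["hapA"]]),
            hapB = paste0(substr(fx$anchor, 1, 10), fx$haps[["hapB"]]))
  aln <- build_its_alignment(mined$reads, refs)
  blk <- trim_block(aln, region = c(10, 160))
  res <- classify_parentage(blk, c("hapA", "hapB"))
  # row order invariance
  perm <- sample(nrow(blk$mat))
  blk2 <- blk
  blk2$mat <- blk$mat[perm, , drop = FALSE]
  blk2$ids <- blk$ids[perm]
  blk2$origin <- blk$origin[perm]
  res2 <- classify_parentage(blk2, c("hapA", "hapB"))
  m <- match(res$calls$read_id, res2$calls$read_id)
  expect_identical(res$calls$assigned_haplotype,
                   res2$calls$assigned_haplotype[m])
  # agreement with the planted source haplotypes
  pr <- parse_read_names(res$calls$read_id)
  tr <- fx$sim$truth
  src <- tr$source_haplotype[match(paste(pr$family_id, pr$copy_index),
                                   paste(tr$family_id, tr$copy_index))]
  ok <- res$calls$assigned_haplotype == src
  expect_gte(mean(ok), 0.9)
})

test_that("NEXUS export round-trips through the package reader", {
  set.seed(88)
  mat <- matrix(sample(c("A", "C", "G", "T", "-"), 3 * 150,
                       replace = TRUE), nrow = 3)
  blk <- structure(list(mat = mat,
                        ids = c("read one", "M.sinensis|AB1", "plain"),
                        origin = rep("read", 3), col_anchor = 0:149,
                        anchor = "x", region = c(0, 150)),
                   class = "its_block")
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus(blk, path)
  txt <- readLines(path)
  expect_true(any(grepl("NTAX=3 NCHAR=150", txt)))
  expect_true(any(grepl("'read one'", txt)))
  back <- read_nexus(path)
  expect_identical(back$ids, blk$ids)
  expect_identical(back$mat, unname(blk$mat))
})
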