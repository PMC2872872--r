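test_that("signature mapping honours the one-mismatch full-length rule", {
  set.seed(71)
  target <- c(t1 = random_dna(500, 0.5))
  sig_exact <- substr(target[[1]], 101, 124)
  sig_2mm <- mutate_positions(sig_exact, c(5, 20))
  sigs <- data.frame(signature_id = c("e", "m2"),
                     sequence = c(sig_exact, sig_2mm),
                     stringsAsFactors = FALSE)
  hits <- map_srna(sigs, target)
  expect_true(any(hits$signature_id == "e" & hits$position == 100 &
                    hits$mismatches == 0))
  expect_false("m2" %in% hits$signature_id)
  # reverse-complement placements are reported on the forward strand
  rc <- data.frame(signature_id = "r", sequence = revcomp(sig_exact),
                   stringsAsFactors = FALSE)
  hrc <- map_srna(rc, target)
  expect_true(any(hrc$position == 100 & hrc$strand == "-"))
  # out-of-range lengths are skipped with a warning
  bad <- data.frame(signature_id = "b", sequence = strrep("A", 40),
                    stringsAsFactors = FALSE)
  expect_warning(none <- map_srna(bad, target), "18-32")
  expect_equal(nrow(none), 0)
})

test_that("signature mapping equals the exhaustive-scan oracle", {
  set.seed(72)
  targets <- c(t1 = random_dna(300, 0.5), t2 = random_dna(250, 0.4))
  sigs <- character(100)
  for (i in 1:100) {
    l <- sample(18:32, 1)
    if (i <= 60) { # planted, with 0-2 mutations
      t <- sample(1:2, 1)
      p <- sample.int(nchar(targets[t]) - l, 1)
      s <- substr(targets[[t]], p, p + l - 1)
      nmut <- sample(0:2, 1)
      if (nmut > 0) s <- mutate_positions(s, sample.int(l, nmut))
      if (runif(1) < 0.5) s <- revcomp(s)
      sigs[i] <- s
    } else {
      sigs[i] <- random_dna(l, 0.5)
    }
  }
  df <- data.frame(signature_id = sprintf("s%03d", 1:100), sequence = sigs,
                   stringsAsFactors = FALSE)
  hits <- map_srna(df, targets)
  got <- hits[order(match(hits$signature_id, df$signature_id),
                    match(hits$target_id, names(targets)),
                    hits$position, hits$strand), ]
  want <- oracle_srna_scan(sigs, unname(targets))
  expect_equal(nrow(got), nrow(want))
  expect_equal(match(got$signature_id, df$signature_id), want$sig)
  expect_equal(match(got$target_id, names(targets)), want$target)
  expect_equal(got$position, want$position)
  expect_equal(got$strand, want$strand)
})

test_that("TPQ normalisation scales and conserves totals", {
  expect_equal(tpq_normalize(1, 250000), 1)
  expect_equal(tpq_normalize(100, 1e6), 25)
  expect_error(tpq_normalize(1, 0), "positive")
  # conservation under partitioning
  set.seed(73)
  counts <- rpois(20, 50)
  total <- 4e5
  expect_equal(sum(tpq_normalize(counts, total)),
               250000 * sum(counts) / total)
})

test_that("per-kilobase rates follow their definition", {
  expect_equal(per_kb_rate(100, 100, 1000), 1)
  expect_equal(per_kb_rate(0, 50, 2000), 0)
  expect_error(per_kb_rate(10, 0, 1000), "zero genomic kb")
})

test_that("binned aggregation conserves per-cluster sums", {
  clusters <- data.frame(
    cluster_id = c("a", "b", "c"),
    repeat_class = c("MITE", "MITE", "retrotransposon"),
    copy_number = c(30, 130, 260), length_bp = c(1000, 1000, 2000),
    stringsAsFactors = FALSE)
  sigs <- data.frame(signature_id = c("s1", "s2", "s3"),
                     abundance = c(2L, 3L, 5L), length = c(24L, 24L, 21L),
                     stringsAsFactors = FALSE)
  hits <- data.frame(signature_id = c("s1", "s2", "s3", "s3"),
                     target_id = c("a", "b", "c", "a"),
                     position = 0L, strand = "+", mismatches = 0L,
                     stringsAsFactors = FALSE)
  b <- bin_and_aggregate(clusters, hits, sigs, bin_width = 100)
  # single-cluster bins reproduce the per-cluster rate
  row_a <- b[b$bin_min == 0, ]
  expect_equal(row_a$matched_count, 2 + 5) # s1 + multi-hit s3
  expect_equal(row_a$rate_per_kb,
               per_kb_rate(7, clusters$copy_number[1],
                           clusters$length_bp[1]))
  # aggregation totals equal per-cluster sums
  expect_equal(sum(b$matched_count), 2 + 3 + 5 + 5)
  expect_equal(sum(b$genomic_kb),
               sum(clusters$copy_number * clusters$length_bp / 1000))
  # empty bins are omitted
  expect_false(any(b$bin_min == 300))
  # 24-nt filtering drops the 21-mer
  b24 <- bin_and_aggregate(clusters, hits, sigs, bin_width = 100,
                           only_24nt = TRUE)
  expect_equal(sum(b24$matched_count), 2 + 3)
})

test_that("linearity statistics hit their closed-form cases", {
  binned <- data.frame(repeat_class = "MITE", bin_min = c(0, 100, 200),
                       bin_max = c(100, 200, 300), n_clusters = 1,
                       matched_count = c(0, 100, 200) * 3 + 60,
                       genomic_kb = 10, stringsAsFactors = FALSE)
  ls <- linearity_stats(binned)
  expect_equal(ls$r_squared, 1)
  flat <- binned
  flat$matched_count <- 50
  lf <- linearity_stats(flat)
  expect_equal(lf$chi_square_p, 1)
  expect_error(linearity_stats(binned[1:2, ]), "3")
})

test_that("per-kb rate has no copy-number trend under proportionality", {
  set.seed(74)
  n <- 60
  cn <- round(runif(n, 20, 800))
  len <- 1000
  rate <- 0.08 # signatures per copy per kb
  counts <- rpois(n, rate * cn * len / 1000)
  rates <- per_kb_rate(counts, cn, len)
  fit <- summary(lm(rates ~ cn))
  expect_gt(fit$coefficients["cn", "Pr(>|t|)"], 0.05)
})

test_that("class shares split multi-class signatures evenly", {
  clusters <- data.frame(cluster_id = c("a", "b"),
                         repeat_class = c("MITE", "rDNA"),
                         stringsAsFactors = FALSE)
  sigs <- data.frame(signature_id = c("s1", "s2"), abundance = c(4L, 2L),
                     stringsAsFactors = FALSE)
  one <- data.frame(signature_id = "s1", target_id = "a",
                    stringsAsFactors = FALSE)
  cs1 <- class_share(one, sigs, clusters)
  expect_equal(cs1$percent, 100)
  both <- data.frame(signature_id = c("s1", "s1"),
                     target_id = c("a", "b"), stringsAsFactors = FALSE)
  cs2 <- class_share(both, sigs, clusters)
  expect_equal(sort(cs2$percent), c(50, 50))
  expect_equal(sum(cs2$abundance), 4)
})

test_that("size distributions weight by abundance", {
  sigs <- data.frame(signature_id = c("a", "b", "c"),
                     length = c(24L, 24L, 21L), abundance = c(5L, 5L, 10L),
                     stringsAsFactors = FALSE)
  sd <- size_distribution(sigs)
  expect_equal(sd$fraction[sd$length == 24], 0.5)
  expect_equal(sum(sd$fraction), 1)
})
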