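#!/usr/bin/env Rscript
# Build the synthetic survey that the downstream analyses consume: a
# repeat-rich genome (dispersed retrotransposon/transposon families, a MITE
# family, a centromeric tandem array and a two-haplotype rDNA array, plus
# protein-coding genes), 454-style survey reads at 1.2% coverage, and
# small-RNA signatures. Everything is seeded, and the planted truth is
# written alongside for the recovery checks in later steps.

suppressPackageStartupMessages(library(repeatsurveyr))
dir.create("results", showWarnings = FALSE)

set.seed(2025)
hapA <- random_dna(200, 0.5)
hapB <- mutate_positions(hapA, round(seq(20, 190, length.out = 5)))
haps <- c(sacchariflorus = hapA, sinensis = hapB)

families <- c(
  lapply(1:4, function(i)
    repeat_family_spec(sprintf("retro%02d", i), "retrotransposon", 4000,
                       c(100, 250, 500, 1000)[i], 0.01)),
  lapply(1:2, function(i)
    repeat_family_spec(sprintf("dnatr%02d", i), "transposon", 2500,
                       c(80, 200)[i], 0.01)),
  list(repeat_family_spec("mite01", "MITE", 400, 800, 0.005),
       repeat_family_spec("cen01", "centromeric_tandem", 500, 2000, 0.01),
       repeat_family_spec("rdna01", "rDNA", 600, 150, 0.004)),
  lapply(1:6, function(i)
    repeat_family_spec(sprintf("rare%02d", i), "transposon", 3000, 8,
                       0.01)))

spec <- genome_spec(2e7, families, gene_count = 50,
                    its_haplotypes = haps, rng_seed = 2025)
sim <- simulate_genome(spec)
reads <- simulate_survey_reads(sim, read_profile(coverage_fraction = 0.012),
                               seed = 2026)
sigs <- simulate_srna(sim$truth, sim$genome, srna_profile(), seed = 2027)

write_fasta(sim$masters, "results/family_masters.fasta")
write_fastq(reads, "results/survey_reads.fastq")
write_truth_table(sim$truth, "results/truth.bed")
write_fasta(setNames(sigs$sequence, sigs$signature_id),
            "results/srna_signatures.fasta")
write.table(sigs, "results/srna_signatures.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_fasta(haps, "results/its_haplotypes.fasta")
write_fasta(truth_cds_set(sim), "results/planted_cds.fasta")

rep_bp <- sum(with(subset(sim$truth, repeat_class != "exon"), end - start))
cat(sprintf("genome: %d bp; %d planted features; repeat fraction %.1f%%\n",
            nchar(sim$genome), nrow(sim$truth), 100 * rep_bp / 2e7))
cat(sprintf("reads: %d (%.0f bp, %.2f%% coverage); sRNA signatures: %d\n",
            length(reads), sum(nchar(reads)),
            100 * sum(nchar(reads)) / 2e7, nrow(sigs)))
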