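#!/usr/bin/env Rscript
# Survey-level statistics: read-set summary, genome size from flow
# cytometry, coverage, the exon-space/gene-content arithmetic, and a
# contamination screen against a synthetic organellar reference.

suppressPackageStartupMessages(library(repeatsurveyr))
reads <- read_fastq("results/survey_reads.fastq")

st <- read_stats(reads)
cat(sprintf("reads: %d, total %.0f bp, mean %.0f bp, GC %.1f%%\n",
            st$count, st$total_bp, st$mean_length_bp,
            100 * st$gc_fraction))

gs <- genome_size_from_pg(c(7.60, 7.95))
cat(sprintf("flow-cytometry genome size: %.2f Gbp raw -> %.1f Gbp (%.1f Gbp per haploid genome)\n",
            gs$total_gbp_raw, gs$total_gbp, gs$per_haploid_gbp))

cov <- coverage_estimate(st$total_bp, 2e7)
cat(sprintf("survey coverage of the 20-Mbp synthetic genome: %.2f%%\n",
            cov$percent))

# gene-content chain at the survey's canonical parameters
esf <- exon_space_fraction(250, 229, 50)
est <- gene_content_estimate(0.034, 7.5e9)
chain <- data.frame(
  quantity = c("exon_space_percent", "coding_percent", "coding_mbp",
               "loci_total", "loci_per_subgenome"),
  value = c(esf$percent, est$coding_percent, est$coding_bp / 1e6,
            est$loci_total, est$loci_per_subgenome))
write.table(chain, "results/gene_content_chain.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("exon space %.0f%%; coding %.1f%% = %.0f Mbp = %.0f loci (%.0f per subgenome)\n",
            esf$percent, est$coding_percent, est$coding_bp / 1e6,
            est$loci_total, est$loci_per_subgenome))

# contamination screen against a synthetic chloroplast reference
set.seed(2028)
organelle <- c(chloroplast_synthetic = random_dna(20000, 0.38))
scr <- contamination_screen(reads[1:500], organelle)
write.table(scr, "results/contamination.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("chloroplast screen (500 reads): %d hits (%.2f%%)\n",
            scr$hit_count, scr$percent))
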