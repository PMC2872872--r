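#!/usr/bin/env Rscript
# Read-depth copy number: align survey reads to the cluster consensi,
# convert counts to copy numbers and genome fractions, rank the most
# abundant repeats, and measure the fraction of reads matching the repeat
# catalogue.

suppressPackageStartupMessages(library(repeatsurveyr))
reads <- read_fastq("results/survey_reads.fastq")
cons <- read_fasta("results/cluster_consensi.fasta")
ann <- read.delim("results/clusters.tsv", stringsAsFactors = FALSE)

cov <- sum(nchar(reads)) / 2e7
aln <- align_many(reads, cons, aligner_params(min_identity = 0.9))
N <- vapply(names(cons), function(cid)
  length(unique(aln$query_id[aln$subject_id == cid])), integer(1))
ann$copy_number <- estimate_copy_number(N[ann$cluster_id],
                                        nchar(cons)[ann$cluster_id],
                                        229, cov)
gf <- genome_fraction(ann$copy_number, ann$length_bp, 2e7)
ann$genome_fraction <- gf$fraction
ann$genome_percent <- gf$percent

top <- top_repeats_table(ann, n = 10)
write.table(top[, c("rank", "cluster_id", "length_bp", "copy_number",
                    "genome_percent", "repeat_class", "best_hit_id")],
            "results/top_repeats.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("ten most abundant repeat clusters:\n")
print(top[, c("rank", "cluster_id", "copy_number", "genome_percent",
              "repeat_class")], row.names = FALSE)

frac <- fraction_reads_in_repeats(reads, cons)
cat(sprintf("%.0f%% of survey reads match the de novo repeat catalogue\n",
            100 * frac$fraction))
write.table(ann[, setdiff(names(ann), "consensus")],
            "results/cluster_copy_numbers.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
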