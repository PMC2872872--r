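#!/usr/bin/env Rscript
# De novo repeat discovery by non-cognate assembly: overlap-cluster the
# survey reads, call consensi, test cluster significance under the
# single-copy null, classify clusters against a class-coded library built
# from the planted family masters, and screen for novelty.

suppressPackageStartupMessages(library(repeatsurveyr))
reads <- read_fastq("results/survey_reads.fastq")
masters <- read_fasta("results/family_masters.fasta")
truth <- read_truth_table("results/truth.bed")

g <- overlap_graph(reads)
cl <- cluster_and_consensus(g, reads)
cat(sprintf("%d overlap edges -> %d clusters of >= 3 reads (largest: %d reads)\n",
            nrow(g), nrow(cl$clusters), max(cl$clusters$n_reads)))

sig <- cluster_significance(k = 3, n_reads = length(reads),
                            genome_bp = 2e7, n_sim = 2000, seed = 2029)
cat(sprintf("P(>=3 reads chain at a single-copy locus | null): %.3f (closed form %.3f); P(multi-copy) = %.3f\n",
            sig$p_null, sig$p_null_closed, sig$p_multicopy))

# class-coded library from the true masters (the role the plant repeat
# database plays on real data)
classes <- truth$repeat_class[match(names(masters), truth$family_id)]
lib <- masters[!is.na(classes) & classes != "exon"]
names(lib) <- sprintf("%s|%s|synthetic",
                      classes[!is.na(classes) & classes != "exon"],
                      names(lib))
ann <- classify_clusters(cl$clusters, lib)
print(attr(ann, "composition"))

# novelty: against a reference missing the MITE and rDNA families
ref <- lib[!grepl("^(MITE|rDNA)", names(lib))]
nov <- novelty_screen(ann, ref)
cat(sprintf("novelty screen: %d known, %d novel clusters\n",
            nov$counts[["known"]], nov$counts[["novel"]]))

write_fasta(setNames(ann$consensus, ann$cluster_id),
            "results/cluster_consensi.fasta")
write.table(ann[, setdiff(names(ann), "consensus")],
            "results/clusters.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(cl$members, "results/cluster_members.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
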