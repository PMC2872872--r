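#!/usr/bin/env Rscript
# Small-RNA quantification: map signatures to the repeat clusters with at
# most one mismatch over the full signature, normalise to TPQ and per-kb
# rates, bin by copy number and test the linearity of production against
# copy number across bin widths.

suppressPackageStartupMessages(library(repeatsurveyr))
sigs <- read.delim("results/srna_signatures.tsv", stringsAsFactors = FALSE)
cons <- read_fasta("results/cluster_consensi.fasta")
ann <- read.delim("results/cluster_copy_numbers.tsv",
                  stringsAsFactors = FALSE)

hits <- map_srna(sigs, cons)
cat(sprintf("%d of %d signatures match a repeat cluster (TPQ %.0f)\n",
            length(unique(hits$signature_id)), nrow(sigs),
            tpq_normalize(length(unique(hits$signature_id)), nrow(sigs))))

sd <- size_distribution(sigs)
cat(sprintf("24-nt share of signatures: %.0f%%\n",
            100 * sd$fraction[sd$length == 24]))
write.table(sd, "results/srna_sizes.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cs <- class_share(hits, sigs, ann)
write.table(cs, "results/srna_class_share.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(cs, row.names = FALSE)

for (bw in c(25, 50, 100, 200)) {
  binned <- bin_and_aggregate(ann, hits, sigs, bin_width = bw)
  ls <- linearity_stats(binned)
  cat(sprintf("bin width %3d: %d bins, R^2 = %.2f, chi-square p = %.2g\n",
              bw, ls$n_bins, ls$r_squared, ls$chi_square_p))
  if (bw == 100) {
    write.table(binned, "results/srna_binned_rates.tsv", sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
}
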