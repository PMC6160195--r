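#!/usr/bin/env Rscript
# Euclidean-distance genome scan: per-SNP pooled nucleotide-frequency
# distance, squared, loess-fitted per chromosome, thresholded at the
# genome-wide median + 3 population SDs of the fitted values, and condensed
# into candidate regions. The per-SNP track written here is the plot data
# for the classic ED Manhattan panel.

suppressPackageStartupMessages(library(bsamapr))

snps <- read_variants("results/filter/filtered.vcf")
scores <- smooth_scan(compute_ed(snps))
thr <- ed_threshold(scores$fitted)
regions <- call_regions(scores, thr)

cat("SNPs scanned:", nrow(scores), "\n")
cat(sprintf("Threshold: median %.4f + %g x SD %.4f = %.4f\n",
            thr$median, thr$sd_multiplier, thr$sd, thr$value))
cat("Candidate regions:\n")
print(as.data.frame(regions), row.names = FALSE)

dir.create("results/ed", showWarnings = FALSE, recursive = TRUE)
write.table(scores, "results/ed/ed_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(regions, "results/ed/ed_regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (nrow(regions) > 0) write_bed(regions, "results/ed/ed_regions.bed")
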