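#!/usr/bin/env Rscript
# Simulate the F2 bulk-sequencing experiment the downstream analyses
# consume: 383 plants, one incompletely dominant locus on Chr10, bulks of
# 37 high- and 18 zero-phenotype plants, pooled reads at the study's mean
# depths, plus a 5% spike-in of filter-violating records so the quality
# filter has something to do. Everything is written under results/sim/.

suppressPackageStartupMessages(library(bsamapr))

cfg <- sim_config(violation_fraction = 0.05, seed = 17)
design <- select_bulks(simulate_f2(cfg))
sim <- simulate_reads(design, dir = "results/sim")

cat("Simulated", nrow(sim$records), "SNPs on", cfg$n_chromosomes,
    "chromosomes;", nrow(sim$genes), "gene models\n")
cat("Causal locus:", sim$causal$chrom, "at", sim$causal$pos, "bp\n")
cat("High bulk phenotype range:",
    paste(round(range(design$phenotypes[design$high_bulk]), 2), collapse = " - "),
    "mg/100 g; low bulk all", unique(design$phenotypes[design$low_bulk]), "\n")
cat("Injected filter violations:", sum(sim$truth$injected != "none"), "\n")
cat("Outputs: results/sim/{variants.vcf, genes.gff3, truth.tsv, config.json}\n")
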