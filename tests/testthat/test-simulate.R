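small_cfg <- function(...) {
  sim_config(n_chromosomes = 2, snps_per_chromosome = 60,
             causal_chrom = "Chr02", causal_pos = 25e6, ...)
}

test_that("zero map length gives purely parental chromosomes", {
  cfg <- small_cfg(map_length_morgans = 0, n_f2 = 100, seed = 5)
  d <- simulate_f2(cfg)
  for (chr in c("Chr01", "Chr02")) {
    g <- d$genotypes[, d$snps$chrom == chr]
    expect_true(all(apply(g, 1, function(x) length(unique(x)) == 1)))
  }
})

test_that("causal genotype frequencies are 1:2:1 in a large F2", {
  cfg <- small_cfg(n_f2 = 4000, seed = 11)
  d <- simulate_f2(cfg)
  g <- d$genotypes[, d$causal$snp_index]
  freq <- tabulate(g + 1, 3) / length(g)
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / length(g))
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 2.5 * se))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_cfg(violation_fraction = 0.1, seed = 21)
  s1 <- simulate_reads(select_bulks(simulate_f2(cfg)))
  s2 <- simulate_reads(select_bulks(simulate_f2(cfg)))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_reads(select_bulks(simulate_f2(cfg)), dir = d1)
  simulate_reads(select_bulks(simulate_f2(cfg)), dir = d2)
  expect_identical(readLines(file.path(d1, "variants.vcf")),
                   readLines(file.path(d2, "variants.vcf")))
})

test_that("bulk selection follows the floor-then-top rule", {
  cfg <- small_cfg(seed = 31)
  d <- select_bulks(simulate_f2(cfg))
  expect_length(d$high_bulk, 37)
  expect_length(d$low_bulk, 18)
  expect_length(intersect(d$high_bulk, d$low_bulk), 0)
  expect_true(all(d$phenotypes[d$high_bulk] >= 0.90))
  expect_true(all(d$phenotypes[d$low_bulk] == 0))
  # the zero-phenotype bulk is homozygous low at the causal locus
  expect_true(all(d$genotypes[d$low_bulk, d$causal$snp_index] == 0))
})

test_that("high-bulk selection fails loudly when no plant qualifies", {
  cfg <- small_cfg(effect_size = 0, noise_sd = 1e-9, seed = 3)
  d <- simulate_f2(cfg)
  expect_error(select_bulks(d), "shortfall")
})

test_that("pool read frequencies concentrate on the truth at high depth", {
  cfg <- small_cfg(mean_depth_h = 1e5, mean_depth_n = 1e5,
                   error_rate = 0, seed = 13)
  sim <- simulate_reads(select_bulks(simulate_f2(cfg)))
  alt_frac <- function(role) {
    m <- as.matrix(sim$records[, paste(role, BASES, sep = "_")])
    m[cbind(seq_len(nrow(m)), match(sim$records$alt, BASES))] / rowSums(m)
  }
  expect_true(all(abs(alt_frac("pool_high") - sim$truth$freq_high_pool) < 0.01))
  expect_true(all(abs(alt_frac("pool_low") - sim$truth$freq_low_pool) < 0.01))
})

test_that("injected violations are rejected at the configured rate", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 500,
                    causal_chrom = NA, violation_fraction = 0.1, seed = 17)
  sim <- simulate_reads(select_bulks(simulate_f2(cfg)))
  n <- nrow(sim$records)
  res <- filter_snps(sim$records,
                     filter_criteria(require_pool_difference = FALSE,
                                     require_recessive_consistency = FALSE))
  rejected <- sum(res$tally$count)
  expect_equal(rejected, sum(sim$truth$injected != "none"))
  sigma <- sqrt(n * 0.1 * 0.9)
  expect_lt(abs(rejected - 0.1 * n), 3 * sigma)
})

test_that("simulated datasets round trip through the VCF reader", {
  cfg <- small_cfg(error_rate = 0, seed = 23)
  sim <- simulate_reads(select_bulks(simulate_f2(cfg)))
  dir <- withr::local_tempdir()
  write_variants(sim$records, file.path(dir, "v.vcf"))
  back <- read_variants(file.path(dir, "v.vcf"))
  expect_equal(as.data.frame(back), as.data.frame(sim$records),
               ignore_attr = TRUE)
})

test_that("unlinked chromosomes show no systematic delta", {
  cfg <- small_cfg(seed = 29)
  sim <- simulate_reads(select_bulks(simulate_f2(cfg)))
  idx <- compute_snp_index(partition_depths(sim$records))
  off <- idx$delta[idx$chrom == "Chr01"]
  se <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off)), 3 * se + 0.05)
  # and the causal locus is strongly shifted
  at_causal <- idx$delta[idx$chrom == "Chr02"][
    which.min(abs(idx$pos[idx$chrom == "Chr02"] - 25e6))]
  expect_gt(at_causal, 0.5)
})

test_that("the pH-differential assay computes c3g equivalents", {
  expect_equal(anthocyanin_concentration(0.2, 0.2, 0, 0), 0)
  got <- anthocyanin_concentration(0.5, dilution_factor = 10)
  expect_equal(got, 0.5 * 449.2 * 10 * 1000 / 26900, tolerance = 1e-12)
  expect_equal(round(got, 2), 83.49)
  # linear in the dilution factor
  expect_equal(anthocyanin_concentration(0.3, dilution_factor = 4),
               2 * anthocyanin_concentration(0.3, dilution_factor = 2))
  expect_warning(zero <- anthocyanin_concentration(0.1, a520_ph45 = 0.3),
                 "clamped")
  expect_equal(zero, 0)
  expect_error(anthocyanin_concentration(0.5, extinction_coefficient = 0))
  expect_error(anthocyanin_concentration(0.5, path_length_cm = 0))
})
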