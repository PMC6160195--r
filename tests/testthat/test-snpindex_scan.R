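partition_of <- function(n_np, h_np, n_hp, h_hp) {
  tibble::tibble(chrom = "Chr01", pos = 1L,
                 allele_low = "A", allele_high = "G",
                 n_np = n_np, h_np = h_np, n_hp = n_hp, h_hp = h_hp,
                 unassigned_low = 0, unassigned_high = 0)
}

test_that("pool depths partition by parental origin", {
  rec <- random_records(1, seed = 1)
  rec$ref <- "A"; rec$alt <- "G"
  rec[1, paste0("parent_low_", BASES)] <- list(20, 0, 0, 0)
  rec[1, paste0("parent_high_", BASES)] <- list(0, 0, 20, 0)
  rec[1, paste0("pool_low_", BASES)] <- list(40, 0, 0, 0)
  rec[1, paste0("pool_high_", BASES)] <- list(10, 0, 30, 0)
  p <- partition_depths(rec)
  expect_equal(c(p$n_np, p$h_np, p$n_hp, p$h_hp), c(40, 0, 10, 30))

  # a third-nucleotide read is excluded and tallied as unassigned
  rec$pool_high_T <- 2
  p <- partition_depths(rec)
  expect_equal(c(p$n_hp, p$h_hp), c(10, 30))
  expect_equal(p$unassigned_high, 2)
})

test_that("partition sums reconcile with pool depths on random fixtures", {
  rec <- random_records(300, seed = 8)
  p <- suppressMessages(partition_depths(rec))
  depth_low <- rowSums(rec[match(p$pos, rec$pos), paste0("pool_low_", BASES)])
  depth_high <- rowSums(rec[match(p$pos, rec$pos), paste0("pool_high_", BASES)])
  expect_equal(p$n_np + p$h_np + p$unassigned_low, unname(depth_low))
  expect_equal(p$n_hp + p$h_hp + p$unassigned_high, unname(depth_high))
})

test_that("uninformative records (parents sharing an allele) are dropped", {
  rec <- random_records(1, seed = 1)
  for (role in c("parent_low", "parent_high")) {
    rec[1, paste(role, BASES, sep = "_")] <- list(20, 0, 0, 0)
  }
  expect_message(p <- partition_depths(rec), "uninformative")
  expect_equal(nrow(p), 0)
})

test_that("SNP-index conventions behave as documented", {
  balanced <- compute_snp_index(partition_of(15, 15, 20, 20))
  expect_equal(c(balanced$index_h, balanced$index_n, balanced$delta),
               c(0.5, 0.5, 0))

  # fully selected causal extreme
  extreme <- partition_of(40, 0, 0, 40)
  expect_equal(compute_snp_index(extreme, "unified")$delta, 1)
  expect_equal(compute_snp_index(extreme, "literal")$delta, 0)
})

test_that("infinite-depth delta at a dominant causal locus is 2/3", {
  # Enumerate F2 genotypes 1:2:1 under full dominance; the high bulk is all
  # trait-positive plants (het:high-hom = 2:1), the low bulk all trait-null.
  f2 <- c(low_hom = 1, het = 2, high_hom = 1) / 4
  positive <- f2[c("het", "high_hom")] / sum(f2[c("het", "high_hom")])
  freq_high_pool <- positive[["het"]] * 0.5 + positive[["high_hom"]] * 1
  expect_equal(freq_high_pool, 2 / 3)
  depth <- 3e6
  p <- partition_of(n_np = depth, h_np = 0,
                    n_hp = depth * (1 - freq_high_pool),
                    h_hp = depth * freq_high_pool)
  idx <- compute_snp_index(p)
  expect_equal(idx$index_h, 2 / 3)
  expect_equal(idx$index_n, 0)
  expect_equal(idx$delta, 2 / 3)
})

test_that("unified delta negates under pool-label exchange", {
  p <- partition_of(30, 10, 5, 35)
  swapped <- partition_of(5, 35, 30, 10)
  expect_equal(compute_snp_index(swapped)$delta, -compute_snp_index(p)$delta)
})

windowed_frame <- function(delta, chrom = "Chr01") {
  tibble::tibble(chrom = chrom, pos = seq_along(delta) * 1000L,
                 index_h = delta, index_n = 0, delta = delta,
                 depth_h = 34, depth_n = 46, window_delta = NA_real_)
}

test_that("window averaging reproduces hand arithmetic and the oracle", {
  const <- window_average(windowed_frame(rep(0.3, 30)), window_spec(10, 1))
  expect_equal(const$window_delta, rep(0.3, 30))

  steps <- window_average(windowed_frame(c(0, 0, 1, 1)), window_spec(2, 1))
  expect_equal(steps$window_delta, c(0, 0.5, 1, 1))

  set.seed(77)
  x <- rnorm(1000)
  got <- window_average(windowed_frame(x), window_spec(400, 1))
  expect_equal(got$window_delta, oracle_window_mean(x, 400))

  # window of 1 is the identity
  ident <- window_average(windowed_frame(x[1:50]), window_spec(1, 1))
  expect_equal(ident$window_delta, x[1:50])
})

test_that("short chromosomes collapse to one whole-chromosome window", {
  expect_warning(
    out <- window_average(windowed_frame(c(0.2, 0.4, 0.6)), window_spec(400, 1)),
    "whole-chromosome")
  expect_equal(out$window_delta, rep(0.4, 3))
})

test_that("null confidence bounds are symmetric, centred and cover", {
  cc <- confidence_config(replicates = 20000, seed = 99)
  th <- confidence_thresholds(cc, data.frame(depth_h = 34, depth_n = 46))
  snp99 <- th[th$scope == "snp" & th$level == 0.99, ]
  # symmetry within Monte-Carlo error
  expect_lt(abs(snp99$lower + snp99$upper), 0.03)

  # held-out coverage at each level
  set.seed(1234)
  fresh <- bsamapr:::.null_delta(50000, 34, 46, 37, 18)
  for (l in c(0.90, 0.95, 0.99)) {
    b <- th[th$scope == "snp" & th$level == l, ]
    covered <- mean(fresh >= b$lower & fresh <= b$upper)
    expect_lt(abs(covered - l), 0.01)
  }
})

test_that("confidence bounds shrink as depth grows", {
  cc <- confidence_config(replicates = 20000, seed = 7)
  grid <- data.frame(depth_h = c(5, 40, 400), depth_n = c(5, 40, 400))
  th <- confidence_thresholds(cc, grid)
  up <- th[th$scope == "snp" & th$level == 0.99, ]
  up <- up[order(up$depth_h), ]
  expect_true(all(diff(up$upper) < 0.005))

  # large depth and bulk: bounds concentrate near 0
  cc_big <- confidence_config(replicates = 20000, bulk_size_h = 5000,
                              bulk_size_n = 5000, seed = 7)
  th_big <- confidence_thresholds(cc_big, data.frame(depth_h = 1e5, depth_n = 1e5))
  big99 <- th_big[th_big$scope == "snp" & th_big$level == 0.99, ]
  expect_lt(big99$upper, 0.05)
  expect_gt(big99$lower, -0.05)
})

test_that("region calling from window deltas uses the two-sided bounds", {
  expect_equal(nrow(call_regions_snpindex(
    windowed_frame(numeric(0)),
    confidence_thresholds(confidence_config(replicates = 1000, window_snps = 5),
                          data.frame(depth_h = 34, depth_n = 46)))), 0)

  cc <- confidence_config(replicates = 5000, window_snps = 5, seed = 3)
  th <- confidence_thresholds(cc, data.frame(depth_h = 34, depth_n = 46))
  x <- c(rep(0, 20), rep(0.9, 10), rep(0, 20), rep(-0.9, 5), rep(0, 5))
  df <- window_average(windowed_frame(x), window_spec(5, 1))
  reg <- call_regions_snpindex(df, th, level = 0.99)
  expect_gte(nrow(reg), 2)
  expect_true(any(reg$direction == 1) && any(reg$direction == -1))
  # every SNP inside a region exceeds its bound
  b <- lookup_bounds(df, th, 0.99)
  for (i in seq_len(nrow(reg))) {
    inside <- b$pos >= reg$start[i] & b$pos <= reg$end[i]
    expect_true(all(b$window_delta[inside] > b$upper[inside] |
                      b$window_delta[inside] < b$lower[inside]))
  }
})
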