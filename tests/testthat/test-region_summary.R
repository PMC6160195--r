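test_that("published interval sizes are reproduced exactly", {
  pub <- published_regions()
  expect_equal(region_length_mb(pub$start, pub$end), pub$size_mb)
})

test_that("published summary totals are reproduced", {
  si <- summarize_regions(published_regions("snp_index"))
  tot <- si[si$chrom == "Total", ]
  expect_equal(tot$length_mb, 14.10)
  expect_equal(tot$n_genes, 126L)
  expect_equal(tot$n_snps, 1674L)

  ed <- summarize_regions(published_regions("ed"))
  tot <- ed[ed$chrom == "Total", ]
  expect_equal(tot$n_genes, 437L)
  expect_equal(tot$n_snps, 6268L)

  chr05 <- published_regions("ed")
  chr05 <- chr05[chr05$chrom == "Chr05", ]
  s <- summarize_regions(chr05)
  expect_equal(s$length_mb[s$chrom == "Total"], 80.12)
  expect_equal(s$n_genes[s$chrom == "Total"], 270L)
})

test_that("the two scans' published regions intersect to the nested set", {
  ed <- published_regions("ed")
  si <- published_regions("snp_index")
  final <- intersect_regions(ed[ed$chrom == "Chr10", ], si)
  expect_equal(nrow(final), 3)
  expect_equal(final$start, si$start)
  expect_equal(final$end, si$end)
  expect_true(all(final$source == "final"))
})

test_that("intersection is commutative, idempotent and oracle-consistent", {
  mk <- function(seed, n) {
    set.seed(seed)
    start <- sort(sample.int(1e6, n))
    out <- tibble::tibble(chrom = sample(c("Chr01", "Chr02"), n, TRUE),
                          start = start,
                          end = start + sample.int(5e4, n))
    # keep each set internally disjoint per chromosome
    out <- out[order(out$chrom, out$start), ]
    keep <- unlist(lapply(split(seq_len(n), out$chrom), function(i) {
      ok <- logical(length(i)); last_end <- -1
      for (k in seq_along(i)) {
        if (out$start[i[k]] > last_end) { ok[k] <- TRUE; last_end <- out$end[i[k]] }
      }
      i[ok]
    }))
    out[sort(keep), ]
  }
  for (seed in 1:5) {
    a <- mk(seed, 40); b <- mk(seed + 50, 40)
    ab <- intersect_regions(a, b)
    ba <- intersect_regions(b, a)
    expect_equal(ab[, c("chrom", "start", "end")], ba[, c("chrom", "start", "end")])
    want <- oracle_intersect(a, b)
    expect_equal(as.data.frame(ab[, c("chrom", "start", "end")]), want,
                 ignore_attr = TRUE)
    # idempotent: intersecting with itself returns the set
    aa <- intersect_regions(a, a)
    expect_equal(as.data.frame(aa[, c("chrom", "start", "end")]),
                 as.data.frame(a[, c("chrom", "start", "end")]),
                 ignore_attr = TRUE)
    expect_lte(sum(ab$end - ab$start), min(sum(a$end - a$start),
                                           sum(b$end - b$start)))
  }
  # disjoint inputs give the empty set
  expect_equal(nrow(intersect_regions(
    tibble::tibble(chrom = "Chr01", start = 1L, end = 10L),
    tibble::tibble(chrom = "Chr01", start = 20L, end = 30L))), 0)
})

test_that("gene counting uses inclusive any-overlap and matches the oracle", {
  region <- tibble::tibble(chrom = "Chr01", start = 100L, end = 200L)
  expect_equal(count_genes(region, random_genes(0)), 0L)
  # gene starting exactly at the region end is counted
  abutting <- tibble::tibble(gene_id = "g", chrom = "Chr01",
                             start = 200L, end = 300L, strand = "+")
  expect_equal(count_genes(region, abutting), 1L)
  # containment mode excludes it
  expect_equal(count_genes(region, abutting, mode = "containment"), 0L)

  for (seed in 1:5) {
    genes <- random_genes(100, seed = seed)
    set.seed(seed)
    start <- sort(sample.int(9e5, 10))
    regions <- tibble::tibble(chrom = sample(c("Chr01", "Chr02"), 10, TRUE),
                              start = start, end = start + 5e4)
    expect_equal(count_genes(regions, genes),
                 as.integer(oracle_count_genes(regions, genes)))
    # order invariance and monotonicity under region growth
    expect_equal(count_genes(regions, genes[sample(100), ]),
                 count_genes(regions, genes))
    grown <- regions; grown$end <- grown$end + 1e5
    expect_true(all(count_genes(grown, genes) >= count_genes(regions, genes)))
  }
})

test_that("summary totals equal column sums", {
  regions <- tibble::tibble(chrom = c("Chr01", "Chr01", "Chr02"),
                            start = c(10L, 5e6L, 100L),
                            end = c(2e6L, 9e6L, 3e6L))
  genes <- random_genes(60, seed = 4, span = 8e6)
  snps <- tibble::tibble(chrom = sample(c("Chr01", "Chr02"), 500, TRUE),
                         pos = sample.int(1e7, 500))
  s <- summarize_regions(regions, genes = genes, snps = snps)
  body <- s[s$chrom != "Total", ]
  tot <- s[s$chrom == "Total", ]
  expect_equal(tot$n_genes, sum(body$n_genes))
  expect_equal(tot$n_snps, sum(body$n_snps))
  expect_equal(tot$length_mb, round(sum(body$length_mb), 2))
  expect_equal(body$n_snps, count_snps(regions, snps))
})

test_that("BED export is 0-based half-open and round trips", {
  regions <- tibble::tibble(chrom = "Chr01", start = 101L, end = 200L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(regions, path)
  raw <- read.delim(path, header = FALSE)
  expect_equal(c(raw$V2, raw$V3), c(100L, 200L))
  back <- read_bed(path)
  expect_equal(c(back$start, back$end), c(101L, 200L))
})
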