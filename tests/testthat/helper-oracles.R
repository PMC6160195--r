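# Independent brute-force oracles. These deliberately use naive loops and
# plain arithmetic, not the package's code paths.

BASES <- c("A", "C", "G", "T")

# Euclidean distance between two pools' nucleotide frequency vectors.
oracle_ed <- function(counts_low, counts_high) {
  fl <- counts_low / sum(counts_low)
  fh <- counts_high / sum(counts_high)
  sqrt(sum((fl - fh)^2))
}

# Left-aligned truncated sliding mean, one value per start index.
oracle_window_mean <- function(x, w) {
  n <- length(x)
  sapply(seq_len(n), function(i) mean(x[i:min(i + w - 1, n)]))
}

# Run-length region scanner: consecutive above-threshold SNPs, split when
# adjacent positions are more than max_gap apart.
oracle_regions <- function(chrom, pos, above, max_gap) {
  out <- NULL
  for (chr in unique(chrom)) {
    p <- pos[chrom == chr]
    a <- above[chrom == chr]
    i <- 1
    while (i <= length(p)) {
      if (!a[i]) { i <- i + 1; next }
      j <- i
      while (j + 1 <= length(p) && a[j + 1] && p[j + 1] - p[j] <= max_gap) j <- j + 1
      out <- rbind(out, data.frame(chrom = chr, start = p[i], end = p[j],
                                   n_snps = j - i + 1))
      i <- j + 1
    }
  }
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0)))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

# All-pairs interval intersection.
oracle_intersect <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      s <- max(a$start[i], b$start[j])
      e <- min(a$end[i], b$end[j])
      if (s <= e) out <- rbind(out, data.frame(chrom = a$chrom[i],
                                               start = s, end = e))
    }
  }
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-pairs gene overlap count (1-based inclusive).
oracle_count_genes <- function(regions, genes) {
  sapply(seq_len(nrow(regions)), function(i) {
    sum(genes$chrom == regions$chrom[i] &
          genes$start <= regions$end[i] &
          genes$end >= regions$start[i])
  })
}

# All-pairs nearest-gene location classifier.
oracle_annotate <- function(pos, chrom, genes, flank) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return("intergenic")
  if (any(g$start <= pos & pos <= g$end)) return("genic_unclassified")
  d <- ifelse(pos < g$start, g$start - pos, pos - g$end)
  best <- which(d == min(d))
  best <- best[which.min(g$start[best])]
  if (d[best] > flank) return("intergenic")
  strand <- if (g$strand[best] %in% c("+", "-")) g$strand[best] else "+"
  before <- pos < g$start[best]
  if (before == (strand == "+")) "upstream" else "downstream"
}

# A random record table with counts in caller-consistent form (all reads on
# the listed REF/ALT alleles), exercising a range of depths and frequencies.
random_records <- function(n, seed = 1) {
  set.seed(seed)
  ref <- sample(BASES, n, replace = TRUE)
  alt <- sapply(ref, function(b) sample(setdiff(BASES, b), 1))
  rec <- tibble::tibble(
    chrom = sample(c("Chr01", "Chr02"), n, replace = TRUE),
    pos = 0L, id = sprintf("r%04d", seq_len(n)), ref = ref, alt = alt
  )
  for (role in c("parent_low", "parent_high", "pool_high", "pool_low")) {
    m <- matrix(0, n, 4, dimnames = list(NULL, paste(role, BASES, sep = "_")))
    depth <- rpois(n, 30) + 1
    f <- switch(role, parent_low = 0, parent_high = 1, runif(n))
    a <- rbinom(n, depth, f)
    m[cbind(seq_len(n), match(alt, BASES))] <- a
    m[cbind(seq_len(n), match(ref, BASES))] <- depth - a
    rec <- dplyr::bind_cols(rec, tibble::as_tibble(m))
  }
  rec$gt_parent_low <- paste(ref, ref, sep = "/")
  rec$gt_parent_high <- paste(alt, alt, sep = "/")
  rec$annotation_class <- NA_character_
  rec <- rec[order(rec$chrom), ]
  rec$pos <- ave(seq_len(n), rec$chrom, FUN = function(i) {
    sort(sample.int(1e6, length(i)))
  })
  rec
}

# Random gene-model table.
random_genes <- function(n, chroms = c("Chr01", "Chr02"), seed = 1,
                         span = 1e6) {
  set.seed(seed)
  start <- sample.int(span, n)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample(500:20000, n, replace = TRUE),
    strand = sample(c("+", "-", "*"), n, replace = TRUE)
  )
}
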