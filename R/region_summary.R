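.regions_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(regions$start, regions$end)
  )
}

#' Intersect two candidate-region sets
#'
#' Standard per-chromosome interval intersection of the two scans' candidate
#' regions (1-based inclusive coordinates); empty overlaps are dropped. The
#' intersection of the two scans is the terminal rule of the pipeline: only
#' intervals flagged by both the ED and the SNP-index scan survive.
#'
#' @param a,b Region tibbles (`chrom`, `start`, `end`), each internally
#'   disjoint and sorted.
#' @return Region tibble with `source = "final"`.
#' @export
intersect_regions <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), source = character(0)))
  }
  gr <- GenomicRanges::intersect(.regions_gr(a), .regions_gr(b),
                                 ignore.strand = TRUE)
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    source = rep("final", length(gr))
  )
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Interval size in megabases
#'
#' `(end - start) / 1e6`, rounded half-away-from-zero to 2 decimals. Note
#' the span convention is `end - start` (not `end - start + 1`).
#'
#' @param start,end 1-based region bounds (vectors); a single-SNP region
#'   (`start == end`) has size 0.
#' @return Numeric vector of interval sizes in Mb.
#' @export
region_length_mb <- function(start, end) {
  stopifnot(all(start <= end))
  round_half_away((end - start) / 1e6, 2)
}

#' Count gene models overlapping each region
#'
#' @param regions Region tibble.
#' @param genes Gene-model table ([read_gene_models()] schema).
#' @param mode `"overlap"` (default): any 1-bp overlap counts, so a gene
#'   whose start equals the region end is counted. `"containment"`: only
#'   genes fully inside the region.
#' @return Integer vector, one count per region.
#' @export
count_genes <- function(regions, genes, mode = c("overlap", "containment")) {
  mode <- match.arg(mode)
  if (nrow(regions) == 0L) return(integer(0))
  if (nrow(genes) == 0L) return(rep(0L, nrow(regions)))
  gr_g <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end)
  )
  gr_r <- .regions_gr(regions)
  if (mode == "overlap") {
    n <- GenomicRanges::countOverlaps(gr_r, gr_g, ignore.strand = TRUE)
  } else {
    # containment: gene fully within the region
    ov <- GenomicRanges::findOverlaps(gr_g, gr_r, type = "within",
                                      ignore.strand = TRUE)
    tab <- table(factor(S4Vectors::subjectHits(ov),
                        levels = seq_len(nrow(regions))))
    n <- as.integer(tab)
  }
  as.integer(n)
}

#' Count SNPs inside each region
#' @param regions Region tibble.
#' @param snps Table with `chrom` and `pos` (e.g. filtered SNP records).
#' @return Integer vector, one count per region (bounds inclusive).
#' @export
count_snps <- function(regions, snps) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(snps$chrom == regions$chrom[i] &
          snps$pos >= regions$start[i] & snps$pos <= regions$end[i])
  }, integer(1))
}

#' Summarize candidate regions (interval size, genes, SNPs) with totals
#'
#' One row per region with `length_mb` recomputed from the bounds via
#' [region_length_mb()], `n_genes` and `n_snps` recomputed when `genes` /
#' `snps` are supplied (otherwise existing columns are kept), plus a totals
#' row summing lengths, gene counts and SNP counts.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, optionally
#'   `n_genes`, `n_snps`, `source`).
#' @param genes Optional gene-model table; triggers recount.
#' @param snps Optional SNP table (`chrom`, `pos`); triggers recount.
#' @param add_total Append the totals row (default TRUE).
#' @return Tibble `chrom`, `start`, `end`, `length_mb`, `n_genes`,
#'   `n_snps`, `source`; totals row has `chrom = "Total"` and NA bounds.
#' @export
summarize_regions <- function(regions, genes = NULL, snps = NULL,
                              add_total = TRUE) {
  out <- tibble::tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    length_mb = region_length_mb(regions$start, regions$end),
    n_genes = if (!is.null(genes)) count_genes(regions, genes)
              else if ("n_genes" %in% names(regions)) regions$n_genes
              else NA_integer_,
    n_snps = if (!is.null(snps)) count_snps(regions, snps)
             else if ("n_snps" %in% names(regions)) regions$n_snps
             else NA_integer_,
    source = if ("source" %in% names(regions)) regions$source else "final"
  )
  if (add_total && nrow(out) > 0) {
    total <- tibble::tibble(
      chrom = "Total", start = NA_integer_, end = NA_integer_,
      length_mb = round_half_away(sum(out$length_mb), 2),
      n_genes = if (all(is.na(out$n_genes))) NA_integer_ else sum(out$n_genes),
      n_snps = if (all(is.na(out$n_snps))) NA_integer_ else sum(out$n_snps),
      source = out$source[1]
    )
    out <- dplyr::bind_rows(out, total)
  }
  out
}

#' Write regions as BED (0-based half-open)
#' @param regions Region tibble (1-based inclusive bounds).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into the 1-based region model
#' @param path BED path (chrom, start, end in the first three columns).
#' @param source Value for the `source` column.
#' @return Region tibble with 1-based inclusive bounds.
#' @export
read_bed <- function(path, source = "imported") {
  bed <- utils::read.delim(path, header = FALSE)
  tibble::tibble(chrom = as.character(bed[[1]]),
                 start = as.integer(bed[[2]]) + 1L,
                 end = as.integer(bed[[3]]),
                 source = source)
}
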