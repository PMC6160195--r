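#' Annotate SNP location relative to gene models
#'
#' Classifies each SNP as `genic_*`, `upstream`, `downstream` or
#' `intergenic`. A position inside a gene span keeps any codon-level class
#' already present on the record (`genic_synonymous` / `genic_nonsynonymous`,
#' accepted from input annotation) and is otherwise `genic_unclassified`.
#' A non-genic position within `flank` bp of its nearest gene is `upstream`
#' if it lies on that gene's 5' side and `downstream` on the 3' side
#' (strand-aware; unknown strand is treated as `+`). Everything else is
#' `intergenic`. When several genes are equally near, the gene with the
#' lower start coordinate wins.
#'
#' Implementation note: nearest genes are found per chromosome from the
#' sorted gene ends (left neighbours) and sorted gene starts (right
#' neighbours), so nested or overlapping gene models are handled without an
#' all-pairs scan.
#'
#' @param records SNP record table.
#' @param genes Gene-model table ([read_gene_models()] schema).
#' @param flank Flanking distance in bp defining upstream/downstream
#'   (default 5000).
#' @return `records` with `annotation_class` filled in.
#' @export
annotate_location <- function(records, genes, flank = 5000) {
  stopifnot(flank > 0)
  n <- nrow(records)
  if (n == 0L) return(records)
  cls <- records$annotation_class
  out <- rep(NA_character_, n)

  unknown <- setdiff(unique(records$chrom), unique(genes$chrom))
  if (length(unknown) > 0 && nrow(genes) > 0) {
    warning("no gene models for chromosome(s): ",
            paste(unknown, collapse = ", "), "; classified intergenic")
  }

  for (chr in unique(records$chrom)) {
    ri <- which(records$chrom == chr)
    pos <- records$pos[ri]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0L) {
      out[ri] <- "intergenic"
      next
    }

    # Genic: inside any gene span.
    gr_g <- IRanges::IRanges(g$start, g$end)
    ov <- IRanges::overlapsAny(IRanges::IRanges(pos, pos), gr_g)
    keep <- !is.na(cls[ri]) & cls[ri] %in% c("genic_synonymous", "genic_nonsynonymous")
    out[ri[ov]] <- ifelse(keep[ov], cls[ri][ov], "genic_unclassified")

    todo <- which(!ov)
    if (length(todo) == 0L) next
    p <- pos[todo]

    # Left neighbour: gene with the maximal end < pos (ties -> lower start).
    oe <- order(g$end, g$start)
    ends_sorted <- g$end[oe]
    idx_l <- findInterval(p - 1L, ends_sorted)   # last end <= p - 1
    left_dist <- ifelse(idx_l >= 1L, p - ends_sorted[pmax(idx_l, 1L)], Inf)
    left_gene <- ifelse(idx_l >= 1L, oe[pmax(idx_l, 1L)], NA_integer_)
    # among genes sharing that end, prefer the lower start
    if (any(idx_l >= 1L)) {
      for (j in which(idx_l >= 1L)) {
        e <- ends_sorted[idx_l[j]]
        cand <- which(g$end == e)
        left_gene[j] <- cand[which.min(g$start[cand])]
      }
    }

    # Right neighbour: gene with the minimal start > pos (ties -> lower start,
    # i.e. the start value itself; among equal starts any is equivalent for
    # distance, pick the first after ordering by start).
    os <- order(g$start, g$end)
    starts_sorted <- g$start[os]
    idx_r <- findInterval(p, starts_sorted) + 1L # first start > p
    right_dist <- ifelse(idx_r <= nrow(g), starts_sorted[pmin(idx_r, nrow(g))] - p, Inf)
    right_gene <- ifelse(idx_r <= nrow(g), os[pmin(idx_r, nrow(g))], NA_integer_)

    use_left <- left_dist < right_dist |
      (left_dist == right_dist & !is.na(left_gene) & !is.na(right_gene) &
         g$start[pmax(left_gene, 1L)] <= g$start[pmax(right_gene, 1L)])
    nearest <- ifelse(use_left, left_gene, right_gene)
    dist <- pmin(left_dist, right_dist)

    lab <- rep("intergenic", length(todo))
    within <- is.finite(dist) & dist <= flank
    if (any(within)) {
      gi <- nearest[within]
      strand <- g$strand[gi]
      strand[!strand %in% c("+", "-")] <- "+"
      snp_left_of_gene <- !use_left[within]   # SNP precedes gene start
      lab[within] <- ifelse(
        snp_left_of_gene,
        ifelse(strand == "+", "upstream", "downstream"),
        ifelse(strand == "+", "downstream", "upstream")
      )
    }
    out[ri[todo]] <- lab
  }
  records$annotation_class <- out
  records
}
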