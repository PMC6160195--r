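#' Read a multi-sample VCF into the SNP record table
#'
#' Parses a VCF with per-sample `AD` (allele depth) fields and decomposes the
#' allele depths of the four mapped samples into per-nucleotide read counts.
#' Alleles that are not single nucleotides (indels, `*`) contribute no
#' counts. Records lacking a usable `AD` entry for a role are retained with
#' zero counts for that sample, with a warning.
#'
#' @param path Path to a VCF (v4.x) file, plain or bgzipped.
#' @param sample_map Named character vector mapping the roles
#'   `parent_low`, `parent_high`, `pool_high`, `pool_low` to sample names in
#'   the VCF header.
#' @return A tibble with one row per variant, sorted by `(chrom, pos)`:
#'   `chrom`, `pos`, `id`, `ref`, `alt` (comma-separated alternates), sixteen
#'   count columns `<role>_<base>`, called parent genotypes
#'   `gt_parent_low`/`gt_parent_high` (nucleotide form, e.g. `"A/A"`), and
#'   `annotation_class` (NA until [annotate_location()] fills it).
#' @seealso [write_variants()], [filter_snps()]
#' @export
read_variants <- function(path, sample_map = default_sample_map()) {
  stopifnot(all(.roles %in% names(sample_map)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) {
    return(empty_records())
  }
  samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(unname(sample_map[.roles]), samples)
  if (length(missing) > 0) {
    stop("sample(s) not present in VCF header: ",
         paste(missing, collapse = ", "),
         " (roles: ",
         paste(names(sample_map)[sample_map %in% missing], collapse = ", "),
         ")")
  }

  fix <- vcfR::getFIX(vcf)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) NULL)

  n <- nrow(fix)
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  alt[is.na(alt)] <- ""
  allele_list <- mapply(function(r, a) {
    c(r, if (nzchar(a)) strsplit(a, ",", fixed = TRUE)[[1]] else character(0))
  }, ref, alt, SIMPLIFY = FALSE, USE.NAMES = FALSE)

  counts <- matrix(0, nrow = n, ncol = 16,
                   dimnames = list(NULL, unlist(lapply(.roles, .count_cols))))
  bad_ad <- 0L
  for (role in .roles) {
    sm <- sample_map[[role]]
    ad_s <- ad[, sm]
    for (i in seq_len(n)) {
      entry <- ad_s[i]
      if (is.na(entry) || entry == "." || !nzchar(entry)) {
        bad_ad <- bad_ad + 1L
        next
      }
      depths <- suppressWarnings(as.integer(strsplit(entry, ",", fixed = TRUE)[[1]]))
      alleles <- allele_list[[i]]
      if (anyNA(depths) || length(depths) != length(alleles)) {
        bad_ad <- bad_ad + 1L
        next
      }
      for (k in seq_along(alleles)) {
        b <- alleles[k]
        if (b %in% .bases) {
          col <- paste(role, b, sep = "_")
          counts[i, col] <- counts[i, col] + depths[k]
        }
      }
    }
  }
  if (bad_ad > 0) {
    warning(bad_ad, " sample AD entr", if (bad_ad == 1) "y" else "ies",
            " missing or malformed; counts set to zero")
  }

  gt_base <- function(role) {
    if (is.null(gt)) return(rep(NA_character_, n))
    g <- gt[, sample_map[[role]]]
    vapply(seq_len(n), function(i) {
      gi <- g[i]
      if (is.na(gi) || gi %in% c(".", "./.", ".|.")) return(NA_character_)
      idx <- suppressWarnings(as.integer(strsplit(gi, "[/|]")[[1]]))
      if (anyNA(idx)) return(NA_character_)
      alleles <- allele_list[[i]]
      if (any(idx + 1L > length(alleles))) return(NA_character_)
      paste(alleles[idx + 1L], collapse = "/")
    }, character(1))
  }

  out <- tibble::tibble(
    chrom = chrom, pos = pos,
    id = as.character(fix[, "ID"]),
    ref = ref, alt = alt
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  out$gt_parent_low <- gt_base("parent_low")
  out$gt_parent_high <- gt_base("parent_high")
  out$annotation_class <- NA_character_
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Default sample-role mapping
#'
#' The study design this package targets: a recessive trait-null parent
#' (`Z5`), a high-trait parent (`Z6`) and the two phenotypic-extreme F2
#' pools (`H-pool`, `N-pool`).
#' @return Named character vector of sample names keyed by role.
#' @export
default_sample_map <- function() {
  c(parent_low = "Z5", parent_high = "Z6",
    pool_high = "H-pool", pool_low = "N-pool")
}

#' An empty SNP record table with the full schema
#' @return Zero-row tibble with the columns [read_variants()] produces.
#' @export
empty_records <- function() {
  counts <- stats::setNames(
    rep(list(numeric(0)), 16),
    unlist(lapply(.roles, .count_cols))
  )
  tibble::tibble(
    chrom = character(0), pos = integer(0), id = character(0),
    ref = character(0), alt = character(0),
    !!!counts,
    gt_parent_low = character(0), gt_parent_high = character(0),
    annotation_class = character(0)
  )
}

#' Write SNP records back to a VCF file
#'
#' Emits plain-text VCFv4.2 with `GT:AD` sample fields. Allele depths are
#' written for the REF and ALT alleles listed on each record; read counts on
#' nucleotides that are not listed alleles cannot be represented in `AD` and
#' are dropped with a warning (as a variant caller would).
#'
#' @param records SNP record table as produced by [read_variants()].
#' @param path Output file path.
#' @param sample_map Role-to-sample-name mapping used for the header columns.
#' @return `path`, invisibly.
#' @export
write_variants <- function(records, path, sample_map = default_sample_map()) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamapr",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", unname(sample_map[.roles])), collapse = "\t")
  )
  n <- nrow(records)
  if (n == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  alt_chr <- ifelse(is.na(records$alt) | !nzchar(records$alt), "", records$alt)
  allele_list <- mapply(function(r, a) {
    c(r, if (nzchar(a)) strsplit(a, ",", fixed = TRUE)[[1]] else character(0))
  }, records$ref, alt_chr, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  count_mats <- lapply(.roles, function(role) {
    m <- as.matrix(records[, .count_cols(role)])
    colnames(m) <- .bases
    m
  })
  names(count_mats) <- .roles

  gt_num <- function(gt, i) {
    if (is.na(gt)) return("./.")
    idx <- match(strsplit(gt, "/", fixed = TRUE)[[1]], allele_list[[i]]) - 1L
    if (anyNA(idx)) "./." else paste(idx, collapse = "/")
  }
  dropped <- 0
  sample_cols <- lapply(.roles, function(role) {
    m <- count_mats[[role]]
    vapply(seq_len(n), function(i) {
      alleles <- allele_list[[i]]
      ad <- rep(0, length(alleles))
      known <- alleles %in% .bases
      ad[known] <- m[i, alleles[known]]
      dropped <<- dropped + sum(m[i, ]) - sum(ad)
      gtv <- switch(role,
                    parent_low = gt_num(records$gt_parent_low[i], i),
                    parent_high = gt_num(records$gt_parent_high[i], i),
                    "./.")
      paste0(gtv, ":", paste(as.integer(ad), collapse = ","))
    }, character(1))
  })
  if (dropped > 0) {
    warning(dropped, " reads on unlisted nucleotides dropped when writing AD")
  }
  lines <- do.call(paste, c(
    list(records$chrom, records$pos, records$id, records$ref,
         ifelse(nzchar(alt_chr), alt_chr, "."),
         ".", "PASS", ".", "GT:AD"),
    sample_cols, sep = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 track and keeps `gene` features, returning the minimal
#' gene-model table used for location annotation and region gene counts.
#'
#' @param path GFF3 file.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (`"+"`, `"-"` or `"*"` for unknown).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(seq_along(gr))
  tibble::tibble(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write gene models to GFF3
#' @param genes Gene-model table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
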