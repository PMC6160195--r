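#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end scan: input paths (or
#' an in-memory simulated dataset), the sample-role map, filter criteria,
#' smoothing, windowing and confidence settings.
#'
#' @param vcf Path to the input VCF (ignored when `dataset` is given).
#' @param gff Optional path to a GFF3 gene track.
#' @param outdir Output directory for all stage outputs.
#' @param dataset Optional in-memory dataset from [simulate_reads()]
#'   (fields `records`, `genes`); takes precedence over `vcf`/`gff`.
#' @param sample_map Role-to-sample mapping for the VCF.
#' @param criteria [filter_criteria()]. The pool-difference rule is off by
#'   default here: on idealized pooled reads it rejects the unlinked
#'   background the confidence thresholds assume (see the methods
#'   vignette); enable it for caller-produced genotype data.
#' @param smoothing [smoothing_config()].
#' @param windows [window_spec()].
#' @param confidence [confidence_config()].
#' @param convention SNP-index convention, `"unified"` or `"literal"`.
#' @param level Confidence level for region calling (default 0.99).
#' @param max_gap Maximum bp between consecutive in-region SNPs.
#' @param seed Seed recorded in the summary and used for the confidence
#'   simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf = NULL, gff = NULL, outdir = tempfile("bsarun"),
                            dataset = NULL,
                            sample_map = default_sample_map(),
                            criteria = filter_criteria(require_pool_difference = FALSE),
                            smoothing = smoothing_config(),
                            windows = window_spec(),
                            confidence = confidence_config(),
                            convention = c("unified", "literal"),
                            level = 0.99, max_gap = 1e6, seed = 1L) {
  structure(list(vcf = vcf, gff = gff, outdir = outdir, dataset = dataset,
                 sample_map = sample_map, criteria = criteria,
                 smoothing = smoothing, windows = windows,
                 confidence = confidence,
                 convention = match.arg(convention),
                 level = level, max_gap = max_gap, seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full bulked-segregant scan end to end
#'
#' Stages: load (or take the simulated) variants -> quality filter -> ED
#' scan (statistic, loess fit, median+k*SD threshold, regions) -> SNP-index
#' scan (depth partition, indices, sliding windows, Monte-Carlo bounds,
#' regions) -> intersection and summary. Every stage logs its input/output
#' record counts, writes TSV/BED outputs under `config$outdir` (per-SNP
#' scan tracks double as plot data), and a machine-readable `summary.json`
#' holds thresholds, regions and totals. A stage failure aborts with the
#' stage named; outputs of completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- load ------------------------------------------------------------
  records <- stage("load", {
    if (!is.null(config$dataset)) config$dataset$records
    else read_variants(config$vcf, config$sample_map)
  })
  genes <- stage("load", {
    if (!is.null(config$dataset)) config$dataset$genes
    else if (!is.null(config$gff)) read_gene_models(config$gff)
    else NULL
  })
  message("load: ", nrow(records), " variant records",
          if (!is.null(genes)) paste0(", ", nrow(genes), " gene models"))

  # -- filter ----------------------------------------------------------
  filt <- stage("filter", filter_snps(records, config$criteria))
  .write_tsv(filt$tally, file.path(outdir, "rejection_report.tsv"))
  stage("filter", write_variants(filt$passed, file.path(outdir, "filtered.vcf"),
                                 config$sample_map))
  message("filter: ", nrow(filt$passed), " of ", nrow(records),
          " records pass")
  snps <- filt$passed

  empty_summary <- function(reason) {
    summary <- list(seed = config$seed, n_input = nrow(records),
                    n_filtered = nrow(snps), warning = reason,
                    ed = NULL, snp_index = NULL, final_regions = list(),
                    totals = list(length_mb = 0, n_genes = 0, n_snps = 0))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    warning(reason)
    invisible(summary)
  }
  if (nrow(snps) == 0L) {
    return(empty_summary("no records passed the quality filters"))
  }

  # -- ED scan ----------------------------------------------------------
  ed <- stage("ed", {
    scores <- compute_ed(snps)
    scores <- smooth_scan(scores, config$smoothing)
    thr <- ed_threshold(scores$fitted, config$smoothing)
    regions <- call_regions(scores, thr, config$max_gap)
    list(scores = scores, threshold = thr, regions = regions)
  })
  .write_tsv(ed$scores, file.path(outdir, "ed_scan.tsv"))
  .write_tsv(ed$regions, file.path(outdir, "ed_regions.tsv"))
  if (nrow(ed$regions) > 0) write_bed(ed$regions, file.path(outdir, "ed_regions.bed"))
  message("ed: threshold ", signif(ed$threshold$value, 4), ", ",
          nrow(ed$regions), " region(s)")

  # -- SNP-index scan ----------------------------------------------------
  si <- stage("snpindex", {
    part <- partition_depths(snps)
    idx <- compute_snp_index(part, config$convention)
    idx <- window_average(idx, config$windows)
    conf <- config$confidence
    conf$seed <- config$seed
    conf$window_snps <- config$windows$window_snps
    grid <- make_depth_grid(idx$depth_h, idx$depth_n)
    thresholds <- confidence_thresholds(conf, grid, scopes = "snp")
    regions <- call_regions_snpindex(idx, thresholds, config$level,
                                     max_gap = config$max_gap)
    track <- idx
    for (l in conf$levels) {
      b <- lookup_bounds(idx, thresholds, l)
      track[[sprintf("bound%02.0f_lower", 100 * l)]] <- b$lower
      track[[sprintf("bound%02.0f_upper", 100 * l)]] <- b$upper
    }
    list(track = track, thresholds = thresholds, regions = regions)
  })
  .write_tsv(si$track, file.path(outdir, "snpindex_scan.tsv"))
  .write_tsv(si$thresholds, file.path(outdir, "confidence_thresholds.tsv"))
  .write_tsv(si$regions, file.path(outdir, "snpindex_regions.tsv"))
  if (nrow(si$regions) > 0) write_bed(si$regions, file.path(outdir, "snpindex_regions.bed"))
  message("snpindex: ", nrow(si$regions), " region(s) at level ", config$level)

  # -- regions ----------------------------------------------------------
  final <- stage("regions", intersect_regions(ed$regions, si$regions))
  final_summary <- stage("regions", {
    if (nrow(final) > 0) summarize_regions(final, genes = genes, snps = snps)
    else tibble::tibble(chrom = character(0), start = integer(0),
                        end = integer(0), length_mb = numeric(0),
                        n_genes = integer(0), n_snps = integer(0),
                        source = character(0))
  })
  .write_tsv(final_summary, file.path(outdir, "final_regions.tsv"))
  if (nrow(final) > 0) write_bed(final, file.path(outdir, "final_regions.bed"))
  message("regions: ", nrow(final), " final region(s)")

  # -- report -----------------------------------------------------------
  region_rows <- function(df) {
    if (nrow(df) == 0L) return(list())
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  body <- final_summary[final_summary$chrom != "Total", , drop = FALSE]
  totals <- final_summary[final_summary$chrom == "Total", , drop = FALSE]
  summary <- list(
    seed = config$seed,
    convention = config$convention,
    n_input = nrow(records),
    n_filtered = nrow(snps),
    rejections = stats::setNames(as.list(filt$tally$count), filt$tally$rule),
    ed = list(threshold = ed$threshold, regions = region_rows(ed$regions)),
    snp_index = list(level = config$level,
                     regions = region_rows(si$regions)),
    final_regions = region_rows(body),
    totals = if (nrow(totals) == 1L) {
      list(length_mb = totals$length_mb,
           n_genes = if (is.na(totals$n_genes)) NULL else totals$n_genes,
           n_snps = if (is.na(totals$n_snps)) NULL else totals$n_snps)
    } else list(length_mb = 0, n_genes = 0, n_snps = 0)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
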