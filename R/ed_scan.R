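#' Euclidean-distance association statistic per SNP
#'
#' For each SNP, the four nucleotide read frequencies are computed in each
#' pool and the statistic is the Euclidean distance between the two pools'
#' frequency vectors:
#' \deqn{ED = \sqrt{\sum_{b \in \{A,C,G,T\}} (f_b^{low} - f_b^{high})^2}}
#' Squaring (`ed2`) suppresses background noise and amplifies large
#' divergences; the squared series is what the downstream smoothing and
#' threshold operate on by default. For a biallelic site
#' \eqn{0 \le ED \le \sqrt{2}}.
#'
#' @param records SNP record table; both pools must have depth > 0. Records
#'   with a zero-depth pool are skipped with a warning (they should have
#'   been removed by the depth filter).
#' @return Tibble `chrom`, `pos`, `ed`, `ed2`, `fitted` (NA until
#'   [smooth_scan()]).
#' @export
compute_ed <- function(records) {
  mh <- as.matrix(records[, .count_cols("pool_high")])
  ml <- as.matrix(records[, .count_cols("pool_low")])
  dh <- rowSums(mh)
  dl <- rowSums(ml)
  ok <- dh > 0 & dl > 0
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with zero pool depth skipped")
  }
  fh <- mh[ok, , drop = FALSE] / dh[ok]
  fl <- ml[ok, , drop = FALSE] / dl[ok]
  ed <- sqrt(rowSums((fl - fh)^2))
  tibble::tibble(
    chrom = records$chrom[ok], pos = records$pos[ok],
    ed = ed, ed2 = ed^2, fitted = NA_real_
  )
}

#' Smoothing configuration for the ED genome scan
#'
#' @param span Loess span as a fraction of the points on each chromosome
#'   (default 0.3).
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @param sd_multiplier Threshold multiplier: the significance threshold is
#'   the genome-wide median of the fitted values plus `sd_multiplier`
#'   standard deviations (default 3).
#' @param stat Which series to smooth and threshold: `"ed2"` (default) or
#'   `"ed"`.
#' @return A `smoothing_config` list.
#' @export
smoothing_config <- function(span = 0.3, degree = 2, sd_multiplier = 3,
                             stat = c("ed2", "ed")) {
  stopifnot(span > 0, span <= 1, degree %in% c(1, 2), sd_multiplier > 0)
  structure(list(span = span, degree = degree,
                 sd_multiplier = sd_multiplier, stat = match.arg(stat)),
            class = "smoothing_config")
}

#' Loess-smooth an association scan along each chromosome
#'
#' Fits `stat ~ pos` by loess independently per chromosome and stores the
#' fitted value at every SNP. Chromosomes with fewer than 10 SNPs are left
#' unsmoothed (fitted = raw statistic) with a warning.
#'
#' @param scores Output of [compute_ed()]; positions must be strictly
#'   increasing within each chromosome.
#' @param config A [smoothing_config()].
#' @return `scores` with the `fitted` column filled.
#' @export
smooth_scan <- function(scores, config = smoothing_config()) {
  stopifnot(inherits(config, "smoothing_config"))
  stat <- scores[[config$stat]]
  fitted <- rep(NA_real_, nrow(scores))
  for (chr in unique(scores$chrom)) {
    idx <- which(scores$chrom == chr)
    stopifnot(!is.unsorted(scores$pos[idx], strictly = TRUE))
    if (length(idx) < 10L) {
      warning("chromosome ", chr, " has < 10 SNPs; fitted set to raw values")
      fitted[idx] <- stat[idx]
      next
    }
    fit <- stats::loess(
      y ~ x,
      data = data.frame(x = scores$pos[idx], y = stat[idx]),
      span = config$span, degree = config$degree,
      family = "gaussian",
      control = stats::loess.control(surface = "direct")
    )
    fitted[idx] <- stats::predict(fit, data.frame(x = scores$pos[idx]))
  }
  scores$fitted <- fitted
  scores
}

#' Genome-wide significance threshold for the smoothed ED scan
#'
#' The threshold is the median of all loess-fitted values, genome-wide,
#' plus `sd_multiplier` population standard deviations (SD computed with
#' divisor n). It is derived from the data at run time, never a constant of
#' the method.
#'
#' @param fitted Numeric vector of fitted values over all chromosomes
#'   (length >= 2).
#' @param config A [smoothing_config()] supplying `sd_multiplier`.
#' @return List with `method`, `value`, `median`, `sd`, `sd_multiplier`.
#' @export
ed_threshold <- function(fitted, config = smoothing_config()) {
  stopifnot(length(fitted) >= 2, all(is.finite(fitted)))
  med <- stats::median(fitted)
  s <- pop_sd(fitted)
  list(method = "median_plus_k_sd",
       value = med + config$sd_multiplier * s,
       median = med, sd = s, sd_multiplier = config$sd_multiplier)
}

# Shared run extractor: maximal groups of above-threshold SNPs that are
# consecutive in SNP order (no below-threshold SNP between) and whose
# consecutive positions are <= max_gap apart.
.call_runs <- function(chrom, pos, above, max_gap) {
  out <- list()
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    p <- pos[idx]
    a <- above[idx]
    hit <- which(a)
    if (length(hit) == 0L) next
    new_run <- c(TRUE, diff(hit) > 1L | diff(p[hit]) > max_gap)
    grp <- cumsum(new_run)
    for (gid in unique(grp)) {
      run <- hit[grp == gid]
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chr, start = p[run[1]], end = p[run[length(run)]],
        n_snps = length(run)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), n_snps = integer(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Call candidate regions from a smoothed scan
#'
#' Extracts maximal runs of consecutive SNPs whose fitted value exceeds the
#' threshold; a run is split where two consecutive above-threshold SNPs are
#' more than `max_gap` bp apart. Region bounds are the positions of the
#' first and last SNP of the run (region coordinates are SNP-anchored).
#'
#' @param scores Smoothed scan ([smooth_scan()] output), sorted by position
#'   within chromosome.
#' @param threshold An [ed_threshold()] result (or a bare number).
#' @param max_gap Maximum bp between consecutive in-region SNPs (default 1e6).
#' @return Region tibble `chrom`, `start`, `end`, `n_snps`, `source = "ed"`.
#' @export
call_regions <- function(scores, threshold, max_gap = 1e6) {
  thr <- if (is.list(threshold)) threshold$value else threshold
  regions <- .call_runs(scores$chrom, scores$pos, scores$fitted > thr, max_gap)
  regions$source <- rep("ed", nrow(regions))
  regions
}
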