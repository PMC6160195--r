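#' Partition pool read depths by parental origin
#'
#' At each biallelic SNP where the parents are fixed for different
#' nucleotides, every pool read is assigned to the parent whose allele it
#' matches. Reads carrying any other nucleotide are dropped and tallied as
#' unassigned. Records where a parent cannot be called (zero depth) or the
#' two parents share their consensus allele are uninformative and dropped
#' with a message.
#'
#' @param records Filtered SNP record table.
#' @return Tibble `chrom`, `pos`, `allele_low` (parent-low allele),
#'   `allele_high`, `n_np`/`h_np` (low-pool reads matching the low/high
#'   parent), `n_hp`/`h_hp` (high-pool reads matching the low/high parent),
#'   `unassigned_low`, `unassigned_high`.
#' @export
partition_depths <- function(records) {
  n <- nrow(records)
  if (n == 0L) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          allele_low = character(0), allele_high = character(0),
                          n_np = numeric(0), h_np = numeric(0),
                          n_hp = numeric(0), h_hp = numeric(0),
                          unassigned_low = numeric(0), unassigned_high = numeric(0)))
  }
  consensus <- function(role) {
    m <- as.matrix(records[, .count_cols(role)])
    ok <- rowSums(m) > 0
    idx <- max.col(m, ties.method = "first")
    ifelse(ok, .bases[idx], NA_character_)
  }
  a_low <- consensus("parent_low")
  a_high <- consensus("parent_high")
  informative <- !is.na(a_low) & !is.na(a_high) & a_low != a_high
  if (any(!informative)) {
    message(sum(!informative), " uninformative record(s) dropped ",
            "(parents share an allele or cannot be called)")
  }
  r <- records[informative, , drop = FALSE]
  a_low <- a_low[informative]
  a_high <- a_high[informative]
  pick <- function(role, allele) {
    m <- as.matrix(r[, .count_cols(role)])
    m[cbind(seq_len(nrow(m)), match(allele, .bases))]
  }
  n_np <- pick("pool_low", a_low)
  h_np <- pick("pool_low", a_high)
  n_hp <- pick("pool_high", a_low)
  h_hp <- pick("pool_high", a_high)
  tibble::tibble(
    chrom = r$chrom, pos = r$pos,
    allele_low = a_low, allele_high = a_high,
    n_np = n_np, h_np = h_np, n_hp = n_hp, h_hp = h_hp,
    unassigned_low = .sample_depth(r, "pool_low") - n_np - h_np,
    unassigned_high = .sample_depth(r, "pool_high") - n_hp - h_hp
  )
}

#' Per-pool SNP-index and delta SNP-index
#'
#' Under the default `unified` convention both indices are the fraction of
#' reads derived from the high parent, the standard QTL-seq convention:
#' `index_h = h_hp / (h_hp + n_hp)`, `index_n = h_np / (n_np + h_np)`, and
#' `delta = index_h - index_n`, so `delta` approaches 1 at a locus where the
#' high bulk is fixed for the high-parent allele and the low bulk for the
#' low-parent allele. The `literal` convention instead counts
#' low-parent reads in the low pool (`index_n = n_np / (n_np + h_np)`),
#' which makes the two indices asymmetric (delta is then 0 at a fully
#' selected locus); it is provided for comparability only.
#'
#' @param partition Output of [partition_depths()]. Records with a
#'   zero-depth pool partition are skipped with a warning.
#' @param convention `"unified"` (default) or `"literal"`.
#' @return Tibble `chrom`, `pos`, `index_h`, `index_n`, `delta`,
#'   `depth_h`, `depth_n`, `window_delta` (NA until [window_average()]).
#' @export
compute_snp_index <- function(partition, convention = c("unified", "literal")) {
  convention <- match.arg(convention)
  depth_n <- partition$n_np + partition$h_np
  depth_h <- partition$n_hp + partition$h_hp
  ok <- depth_n > 0 & depth_h > 0
  if (any(!ok)) warning(sum(!ok), " record(s) with an empty pool partition skipped")
  p <- partition[ok, , drop = FALSE]
  index_h <- p$h_hp / (p$h_hp + p$n_hp)
  index_n <- if (convention == "unified") {
    p$h_np / (p$n_np + p$h_np)
  } else {
    p$n_np / (p$n_np + p$h_np)
  }
  tibble::tibble(
    chrom = p$chrom, pos = p$pos,
    index_h = index_h, index_n = index_n,
    delta = index_h - index_n,
    depth_h = depth_h[ok], depth_n = depth_n[ok],
    window_delta = NA_real_
  )
}

#' Sliding-window specification
#' @param window_snps SNPs per window (default 400).
#' @param step_snps Window step in SNPs (default 1).
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_snps = 400, step_snps = 1) {
  stopifnot(window_snps >= 1, step_snps >= 1, step_snps <= window_snps)
  structure(list(window_snps = window_snps, step_snps = step_snps),
            class = "window_spec")
}

# Left-aligned rolling mean over windows of w SNPs starting every `step`
# SNPs, truncated at the chromosome end; SNP i reports the window it starts
# (with step > 1, the most recent started window).
.window_mean <- function(x, w, step) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  starts <- seq(1L, n, by = step)
  ends <- pmin(starts + w - 1L, n)
  vals <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  vals[findInterval(seq_len(n), starts)]
}

#' Window-average SNP-index tracks along each chromosome
#'
#' Computes the arithmetic mean of `delta` (and of the two pool indices)
#' over sliding windows of `window_snps` SNPs advanced by `step_snps`,
#' independently per chromosome. Final windows are truncated at the
#' chromosome end. A chromosome with fewer SNPs than one window becomes a
#' single whole-chromosome window, with a warning.
#'
#' @param records [compute_snp_index()] output, sorted by position within
#'   chromosome.
#' @param spec A [window_spec()].
#' @return `records` with `window_delta`, `window_index_h`,
#'   `window_index_n` filled.
#' @export
window_average <- function(records, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  wd <- wih <- win <- rep(NA_real_, nrow(records))
  for (chr in unique(records$chrom)) {
    idx <- which(records$chrom == chr)
    stopifnot(!is.unsorted(records$pos[idx]))
    w <- spec$window_snps
    if (length(idx) < w) {
      warning("chromosome ", chr, " has ", length(idx), " SNPs < window of ",
              w, "; using one whole-chromosome window")
      wd[idx] <- mean(records$delta[idx])
      wih[idx] <- mean(records$index_h[idx])
      win[idx] <- mean(records$index_n[idx])
      next
    }
    wd[idx] <- .window_mean(records$delta[idx], w, spec$step_snps)
    wih[idx] <- .window_mean(records$index_h[idx], w, spec$step_snps)
    win[idx] <- .window_mean(records$index_n[idx], w, spec$step_snps)
  }
  records$window_delta <- wd
  records$window_index_h <- wih
  records$window_index_n <- win
  records
}

#' Monte-Carlo confidence configuration for the null delta SNP-index
#'
#' @param levels Two-sided confidence levels (default 0.90, 0.95, 0.99).
#' @param replicates Null draws per depth pair (default 10000, minimum 1000).
#' @param bulk_size_h,bulk_size_n Individuals per bulk (defaults 37 and 18).
#' @param window_snps Window size used for window-scope bounds (default 400).
#' @param seed RNG seed for the simulation.
#' @return A `confidence_config` list.
#' @export
confidence_config <- function(levels = c(0.90, 0.95, 0.99),
                              replicates = 10000,
                              bulk_size_h = 37, bulk_size_n = 18,
                              window_snps = 400, seed = 1L) {
  stopifnot(all(levels > 0 & levels < 1), replicates >= 1000,
            bulk_size_h >= 1, bulk_size_n >= 1)
  structure(list(levels = levels, replicates = replicates,
                 bulk_size_h = bulk_size_h, bulk_size_n = bulk_size_n,
                 window_snps = window_snps, seed = as.integer(seed)),
            class = "confidence_config")
}

# One matrix of null delta draws at a fixed depth pair: two-stage sampling —
# each bulk's high-parent allele frequency from 2*N sampled chromosomes at
# probability 1/2, then read counts binomially at the given depth.
.null_delta <- function(n, depth_h, depth_n, bulk_h, bulk_n) {
  fh <- stats::rbinom(n, 2L * bulk_h, 0.5) / (2 * bulk_h)
  fn <- stats::rbinom(n, 2L * bulk_n, 0.5) / (2 * bulk_n)
  ih <- stats::rbinom(n, depth_h, fh) / depth_h
  in_ <- stats::rbinom(n, depth_n, fn) / depth_n
  ih - in_
}

#' Simulated null confidence bounds for the delta SNP-index
#'
#' For each pool-depth pair, draws `replicates` null (no-QTL) deltas by
#' two-stage sampling — bulk allele frequency from the finite bulk, then
#' binomial read counts at the fixed depth — and returns empirical two-sided
#' quantile bounds at each confidence level. Two scopes are produced:
#' `"snp"` bounds on a single-SNP delta, and `"window"` bounds on the mean
#' of `window_snps` *independent* null deltas. Window members on a real
#' chromosome are correlated through linkage, so the `"window"` bounds are
#' only valid for unlinked SNPs; region calling defaults to the `"snp"`
#' scope (see [call_regions_snpindex()]).
#'
#' @param config A [confidence_config()].
#' @param depth_pairs Data frame with columns `depth_h`, `depth_n` (one row
#'   per depth pair to simulate), e.g. from [make_depth_grid()].
#' @param scopes Which bound scopes to simulate; window-scope bounds cost
#'   `window_snps` times more draws, so callers that only apply per-SNP
#'   bounds can restrict to `"snp"`.
#' @return Tibble `depth_h`, `depth_n`, `level`, `scope`, `lower`, `upper`.
#' @export
confidence_thresholds <- function(config = confidence_config(),
                                  depth_pairs,
                                  scopes = c("snp", "window")) {
  stopifnot(inherits(config, "confidence_config"),
            all(c("depth_h", "depth_n") %in% names(depth_pairs)),
            all(scopes %in% c("snp", "window")), length(scopes) >= 1)
  set.seed(config$seed)
  probs <- function(l) c((1 - l) / 2, (1 + l) / 2)
  out <- vector("list", nrow(depth_pairs))
  for (i in seq_len(nrow(depth_pairs))) {
    dh <- depth_pairs$depth_h[i]
    dn <- depth_pairs$depth_n[i]
    draws <- list()
    if ("snp" %in% scopes) {
      draws$snp <- .null_delta(config$replicates, dh, dn,
                               config$bulk_size_h, config$bulk_size_n)
    }
    if ("window" %in% scopes) {
      w <- config$window_snps
      draws$window <- colMeans(matrix(
        .null_delta(config$replicates * w, dh, dn,
                    config$bulk_size_h, config$bulk_size_n),
        nrow = w))
    }
    rows <- lapply(config$levels, function(l) {
      dplyr::bind_rows(lapply(names(draws), function(sc) {
        q <- stats::quantile(draws[[sc]], probs(l), names = FALSE, type = 7)
        tibble::tibble(depth_h = dh, depth_n = dn, level = l,
                       scope = sc, lower = q[1], upper = q[2])
      }))
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

#' Build a depth grid for threshold simulation
#'
#' Log-spaced depth values spanning the observed per-pool depths, crossed
#' into pairs; thresholds are simulated once per pair and each SNP later
#' looks up its nearest pair (log scale).
#'
#' @param depth_h,depth_n Observed per-SNP depths for the two pools.
#' @param n_points Grid points per pool axis (default 4).
#' @return Data frame `depth_h`, `depth_n` with one row per pair.
#' @export
make_depth_grid <- function(depth_h, depth_n, n_points = 4) {
  axis <- function(d) {
    d <- d[d > 0]
    lo <- max(1, min(d))
    hi <- max(d)
    unique(round(exp(seq(log(lo), log(hi), length.out = n_points))))
  }
  expand.grid(depth_h = axis(depth_h), depth_n = axis(depth_n),
              KEEP.OUT.ATTRS = FALSE)
}

# Nearest grid pair (log scale) for each SNP's depth pair.
.nearest_pair <- function(depth_h, depth_n, pairs) {
  vapply(seq_along(depth_h), function(i) {
    d <- (log(depth_h[i]) - log(pairs$depth_h))^2 +
      (log(depth_n[i]) - log(pairs$depth_n))^2
    which.min(d)
  }, integer(1))
}

#' Look up per-SNP confidence bounds
#'
#' @param records Windowed SNP-index table ([window_average()] output).
#' @param thresholds [confidence_thresholds()] output.
#' @param level Confidence level to extract.
#' @param scope `"snp"` (default) or `"window"`.
#' @return `records` with `lower` and `upper` bound columns for `level`.
#' @export
lookup_bounds <- function(records, thresholds, level = 0.99,
                          scope = c("snp", "window")) {
  scope <- match.arg(scope)
  th <- thresholds[thresholds$scope == scope &
                     abs(thresholds$level - level) < 1e-9, , drop = FALSE]
  if (nrow(th) == 0L) stop("no thresholds at level ", level, " scope ", scope)
  pairs <- unique(th[, c("depth_h", "depth_n")])
  idx <- .nearest_pair(records$depth_h, records$depth_n, pairs)
  key_th <- paste(th$depth_h, th$depth_n)
  key_rec <- paste(pairs$depth_h[idx], pairs$depth_n[idx])
  m <- match(key_rec, key_th)
  records$lower <- th$lower[m]
  records$upper <- th$upper[m]
  records
}

#' Call candidate regions from the windowed delta SNP-index
#'
#' A SNP is above threshold when its window-averaged delta falls outside the
#' two-sided null bound at its (nearest-grid) depth pair. Runs are extracted
#' and merged exactly as in [call_regions()]. By default the per-SNP
#' (`scope = "snp"`) bound is applied to the window average — conservative
#' for unlinked windows and calibrated for fully linked ones — because the
#' iid window-mean bound is anti-conservative when window members are in
#' linkage (see the methods vignette).
#'
#' Regions are reported with the sign of the window delta (`direction`):
#' positive means linkage to the high-trait parent allele.
#'
#' @param records Windowed SNP-index table.
#' @param thresholds [confidence_thresholds()] output.
#' @param level Confidence level (default 0.99).
#' @param scope Bound scope, `"snp"` (default) or `"window"`.
#' @param max_gap Maximum bp between consecutive in-region SNPs (default 1e6).
#' @return Region tibble `chrom`, `start`, `end`, `n_snps`, `source =
#'   "snp_index"`, `direction`.
#' @export
call_regions_snpindex <- function(records, thresholds, level = 0.99,
                                  scope = c("snp", "window"), max_gap = 1e6) {
  scope <- match.arg(scope)
  rec <- lookup_bounds(records, thresholds, level, scope)
  above <- rec$window_delta > rec$upper | rec$window_delta < rec$lower
  regions <- .call_runs(rec$chrom, rec$pos, above, max_gap)
  regions$source <- rep("snp_index", nrow(regions))
  if (nrow(regions) > 0) {
    regions$direction <- vapply(seq_len(nrow(regions)), function(i) {
      sel <- rec$chrom == regions$chrom[i] &
        rec$pos >= regions$start[i] & rec$pos <= regions$end[i]
      as.numeric(sign(mean(rec$window_delta[sel])))
    }, numeric(1))
  } else {
    regions$direction <- numeric(0)
  }
  regions
}
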