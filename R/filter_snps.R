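#' High-quality SNP filter criteria
#'
#' The four-rule filter applied before association scans, in fixed order:
#' multi-allelic sites are excluded; sites with read depth below
#' `min_depth_per_sample` in any of the four samples are omitted; sites where
#' the two pools have identical called genotypes are eliminated; and sites
#' where a pool carries an allele observed in neither parent (above the noise
#' floor) are excluded.
#'
#' A pool "genotype" here is the set of nucleotides whose within-pool read
#' frequency exceeds `noise_floor` — pools are mixtures, so exact count
#' equality would be meaningless.
#'
#' @param min_depth_per_sample Read-depth floor applied to each of the four
#'   samples independently (default 4).
#' @param require_biallelic Apply the multi-allelic exclusion rule.
#' @param require_pool_difference Apply the identical-pool-genotypes rule.
#' @param require_recessive_consistency Require every pool allele above the
#'   noise floor to be present in at least one parent.
#' @param noise_floor Frequency above which a nucleotide counts as observed
#'   in a sample (default 0.1).
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(min_depth_per_sample = 4,
                            require_biallelic = TRUE,
                            require_pool_difference = TRUE,
                            require_recessive_consistency = TRUE,
                            noise_floor = 0.1) {
  stopifnot(min_depth_per_sample >= 0, noise_floor >= 0, noise_floor < 1)
  structure(
    list(min_depth_per_sample = min_depth_per_sample,
         require_biallelic = require_biallelic,
         require_pool_difference = require_pool_difference,
         require_recessive_consistency = require_recessive_consistency,
         noise_floor = noise_floor),
    class = "filter_criteria"
  )
}

# Set of nucleotides with frequency > floor in one sample (list of vectors).
.observed_bases <- function(records, role, floor) {
  m <- as.matrix(records[, .count_cols(role)])
  depth <- rowSums(m)
  freq <- m / ifelse(depth > 0, depth, 1)
  lapply(seq_len(nrow(m)), function(i) .bases[freq[i, ] > floor])
}

#' Filter SNP records to the high-quality set
#'
#' Applies the four rules of [filter_criteria()] in order and partitions
#' rejected records by the first rule they fail.
#'
#' @param records SNP record table ([read_variants()] schema).
#' @param criteria A [filter_criteria()] object.
#' @return A list with `passed` (subset of `records`, order preserved) and
#'   `tally`, a tibble with columns `rule` and `count` over the four rules
#'   `multiallelic`, `low_depth`, `identical_genotypes`,
#'   `recessive_inconsistent`. `nrow(passed) + sum(tally$count) ==
#'   nrow(records)` always holds.
#' @export
filter_snps <- function(records, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  rules <- c("multiallelic", "low_depth", "identical_genotypes",
             "recessive_inconsistent")
  n <- nrow(records)
  if (n == 0L) {
    return(list(passed = records,
                tally = tibble::tibble(rule = rules, count = rep(0L, 4))))
  }
  floor <- criteria$noise_floor
  obs <- lapply(.roles, .observed_bases, records = records, floor = floor)
  names(obs) <- .roles

  fail <- rep(NA_character_, n)

  # Rule 1: multi-allelic — >2 nucleotides above the floor across all four
  # samples, or a record carrying more than one ALT allele.
  if (criteria$require_biallelic) {
    n_alt <- vapply(records$alt, function(a) {
      if (is.na(a) || !nzchar(a)) 0L else length(strsplit(a, ",", fixed = TRUE)[[1]])
    }, integer(1), USE.NAMES = FALSE)
    n_obs <- vapply(seq_len(n), function(i) {
      length(unique(unlist(lapply(obs, `[[`, i))))
    }, integer(1))
    fail[is.na(fail) & (n_alt > 1L | n_obs > 2L)] <- "multiallelic"
  }

  # Rule 2: depth < floor in any one of the four samples.
  if (criteria$min_depth_per_sample > 0) {
    depths <- vapply(.roles, .sample_depth, numeric(n), records = records)
    if (n == 1L) depths <- matrix(depths, nrow = 1)
    low <- apply(depths, 1, min) < criteria$min_depth_per_sample
    fail[is.na(fail) & low] <- "low_depth"
  }

  # Rule 3: identical called pool genotypes (sets of above-floor nucleotides).
  if (criteria$require_pool_difference) {
    same <- vapply(seq_len(n), function(i) {
      setequal(obs$pool_high[[i]], obs$pool_low[[i]])
    }, logical(1))
    fail[is.na(fail) & same] <- "identical_genotypes"
  }

  # Rule 4: a pool allele above the floor present in neither parent.
  if (criteria$require_recessive_consistency) {
    bad <- vapply(seq_len(n), function(i) {
      pool_alleles <- union(obs$pool_high[[i]], obs$pool_low[[i]])
      parent_alleles <- union(obs$parent_low[[i]], obs$parent_high[[i]])
      length(setdiff(pool_alleles, parent_alleles)) > 0
    }, logical(1))
    fail[is.na(fail) & bad] <- "recessive_inconsistent"
  }

  tally <- tibble::tibble(
    rule = rules,
    count = unname(vapply(rules, function(r) sum(fail == r, na.rm = TRUE),
                          integer(1)))
  )
  list(passed = records[is.na(fail), , drop = FALSE], tally = tally)
}

#' Write the per-rule rejection report
#' @param tally Tally tibble from [filter_snps()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(tally, path) {
  utils::write.table(tally, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
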