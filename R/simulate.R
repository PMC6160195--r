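#' Simulation configuration for an F2 bulk-sequencing experiment
#'
#' Defaults emulate the study design the package targets: an F2 of 383
#' plants from a cross between a trait-null (recessive) and a high-trait
#' inbred, one major incompletely dominant locus, tail-selected bulks of 37
#' (high) and 18 (zero-phenotype) plants, and pooled sequencing at mean
#' depths of 33.83x (high pool), 45.74x (low pool), 25.77x and 23.45x
#' (low/high parent). Chromosome length defaults to 50 Mb so that the mean
#' marker spacing (0.2 Mb at 250 SNPs) stays well below the 1 Mb region
#' merge gap, as in the densely markered data the method expects.
#'
#' @param n_chromosomes Number of chromosomes (default 12).
#' @param chrom_length_bp Physical length per chromosome (default 50 Mb).
#' @param n_f2 F2 population size (default 383).
#' @param snps_per_chromosome SNPs simulated per chromosome (default 250).
#' @param causal_chrom,causal_pos The causal locus; set `causal_chrom = NA`
#'   for a no-QTL (null) genome, in which case bulks are drawn at random.
#' @param dominance Degree of dominance h of the high allele on phenotype,
#'   in `[0, 1]` (default 0.75, incomplete dominance).
#' @param effect_size Mean phenotype of the high homozygote, mg/100 g
#'   (default 6).
#' @param noise_sd Phenotypic noise SD, mg/100 g (default 0.8).
#' @param bulk_high_n,bulk_low_n Bulk sizes (defaults 37 and 18).
#' @param bulk_high_floor Minimum phenotype to qualify for the high bulk
#'   (default 0.90 mg/100 g).
#' @param mean_depth_h,mean_depth_n,mean_depth_parent_low,mean_depth_parent_high
#'   Mean Poisson sequencing depths per sample.
#' @param error_rate Per-read sequencing error probability (default 0.001).
#' @param violation_fraction Fraction of records corrupted into
#'   filter-failing form (half multi-allelic, half low-depth; default 0).
#' @param genes_per_chromosome Random gene models per chromosome (default 30).
#' @param map_length_morgans Genetic map length per chromosome (default 1;
#'   Haldane model, no interference).
#' @param seed RNG seed; the whole generator is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 12,
                       chrom_length_bp = 50e6,
                       n_f2 = 383,
                       snps_per_chromosome = 250,
                       causal_chrom = "Chr10",
                       causal_pos = 30e6,
                       dominance = 0.75,
                       effect_size = 6,
                       noise_sd = 0.8,
                       bulk_high_n = 37,
                       bulk_low_n = 18,
                       bulk_high_floor = 0.90,
                       mean_depth_h = 33.83,
                       mean_depth_n = 45.74,
                       mean_depth_parent_low = 25.77,
                       mean_depth_parent_high = 23.45,
                       error_rate = 0.001,
                       violation_fraction = 0,
                       genes_per_chromosome = 30,
                       map_length_morgans = 1,
                       seed = 1L) {
  stopifnot(bulk_high_n + bulk_low_n <= n_f2,
            mean_depth_h > 0, mean_depth_n > 0,
            error_rate >= 0, error_rate < 0.1,
            dominance >= 0, dominance <= 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (!is.na(causal_chrom)) {
    if (causal_pos < 1 || causal_pos > chrom_length_bp) {
      stop("causal_pos ", causal_pos, " outside chromosome of length ",
           chrom_length_bp)
    }
  }
  structure(cfg, class = "sim_config")
}

.chrom_names <- function(n) sprintf("Chr%02d", seq_len(n))

# One F2 gamete per chromosome: Haldane crossovers (Poisson count, uniform
# breakpoints), returning the 0/1 parental haplotype at each SNP position.
.gamete <- function(pos, chrom_len, morgans) {
  start <- stats::rbinom(1L, 1L, 0.5)
  k <- stats::rpois(1L, morgans)
  if (k == 0L) return(rep(start, length(pos)))
  bp <- sort(stats::runif(k, 0, chrom_len))
  (start + findInterval(pos, bp)) %% 2L
}

#' Simulate an F2 population with one major incompletely dominant locus
#'
#' Each plant receives two independent Haldane gametes per chromosome;
#' genotype dosage at a SNP is the number of high-parent alleles (0/1/2).
#' Phenotype is 0 exactly for the low-homozygote class at the causal locus
#' (recessive null), `effect_size * dominance` for heterozygotes and
#' `effect_size` for high homozygotes, plus Gaussian noise truncated at 0.
#' With `causal_chrom = NA` no locus affects phenotype (phenotypes are NA
#' and bulks are later drawn at random).
#'
#' @param config A [sim_config()].
#' @return A `bulk_design` list: `snps` (tibble `chrom`, `pos`),
#'   `genotypes` (n_f2 x n_snps dosage matrix), `phenotypes`, `causal`
#'   (list `chrom`, `pos`, `snp_index` or NULL), `config`.
#' @export
simulate_f2 <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- .chrom_names(config$n_chromosomes)
  snps <- dplyr::bind_rows(lapply(chroms, function(chr) {
    pos <- sort(sample.int(config$chrom_length_bp, config$snps_per_chromosome))
    tibble::tibble(chrom = chr, pos = pos)
  }))
  causal <- NULL
  if (!is.na(config$causal_chrom)) {
    stopifnot(config$causal_chrom %in% chroms)
    on_chr <- which(snps$chrom == config$causal_chrom)
    nearest <- on_chr[which.min(abs(snps$pos[on_chr] - config$causal_pos))]
    snps$pos[nearest] <- as.integer(config$causal_pos)
    snps <- dplyr::arrange(snps, .data$chrom, .data$pos)
    causal <- list(chrom = config$causal_chrom,
                   pos = as.integer(config$causal_pos),
                   snp_index = which(snps$chrom == config$causal_chrom &
                                       snps$pos == config$causal_pos)[1])
  }

  n_snps <- nrow(snps)
  geno <- matrix(0L, nrow = config$n_f2, ncol = n_snps)
  for (chr in chroms) {
    cols <- which(snps$chrom == chr)
    pos <- snps$pos[cols]
    for (i in seq_len(config$n_f2)) {
      g1 <- .gamete(pos, config$chrom_length_bp, config$map_length_morgans)
      g2 <- .gamete(pos, config$chrom_length_bp, config$map_length_morgans)
      geno[i, cols] <- g1 + g2
    }
  }

  pheno <- rep(NA_real_, config$n_f2)
  if (!is.null(causal)) {
    g <- geno[, causal$snp_index]
    mu <- c(0, config$dominance * config$effect_size, config$effect_size)[g + 1L]
    pheno <- pmax(0, mu + stats::rnorm(config$n_f2, 0, config$noise_sd))
    pheno[g == 0L] <- 0
  }

  structure(list(snps = snps, genotypes = geno, phenotypes = pheno,
                 causal = causal, config = config),
            class = "bulk_design")
}

#' Select the phenotypic-extreme bulks
#'
#' High bulk: the `bulk_high_n` highest-phenotype plants among those at or
#' above `bulk_high_floor`. Low bulk: the first `bulk_low_n` plants (by
#' index) with phenotype exactly 0 (the measurable-trait-free class). Ties
#' are broken by plant index. For a null design (no causal locus) both
#' bulks are disjoint random samples.
#'
#' @param design A [simulate_f2()] result.
#' @return `design` with `high_bulk` and `low_bulk` index vectors added.
#' @export
select_bulks <- function(design) {
  stopifnot(inherits(design, "bulk_design"))
  cfg <- design$config
  if (is.null(design$causal)) {
    set.seed(cfg$seed + 1L)
    picks <- sample.int(cfg$n_f2, cfg$bulk_high_n + cfg$bulk_low_n)
    design$high_bulk <- sort(picks[seq_len(cfg$bulk_high_n)])
    design$low_bulk <- sort(picks[-seq_len(cfg$bulk_high_n)])
    return(design)
  }
  ph <- design$phenotypes
  eligible <- which(ph >= cfg$bulk_high_floor)
  if (length(eligible) < cfg$bulk_high_n) {
    stop("only ", length(eligible), " plants at or above the high-bulk floor (",
         cfg$bulk_high_floor, "); need ", cfg$bulk_high_n,
         " (shortfall ", cfg$bulk_high_n - length(eligible), ")")
  }
  ord <- eligible[order(-ph[eligible], eligible)]
  design$high_bulk <- sort(ord[seq_len(cfg$bulk_high_n)])
  zeros <- which(ph == 0)
  if (length(zeros) < cfg$bulk_low_n) {
    stop("only ", length(zeros), " zero-phenotype plants; need ",
         cfg$bulk_low_n, " (shortfall ", cfg$bulk_low_n - length(zeros), ")")
  }
  design$low_bulk <- zeros[seq_len(cfg$bulk_low_n)]
  design
}

# Split `origin` reads of a true base into per-base counts with sequencing
# error `e` (errors uniform over the other three bases). Vectorized.
.reads_with_error <- function(origin, true_base, e) {
  n <- length(origin)
  correct <- stats::rbinom(n, origin, 1 - e)
  err <- origin - correct
  e1 <- stats::rbinom(n, err, 1 / 3)
  e2 <- stats::rbinom(n, err - e1, 1 / 2)
  e3 <- err - e1 - e2
  counts <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, .bases))
  others <- t(vapply(true_base, function(b) setdiff(.bases, b), character(3)))
  counts[cbind(seq_len(n), match(true_base, .bases))] <- correct
  counts[cbind(seq_len(n), match(others[, 1], .bases))] <-
    counts[cbind(seq_len(n), match(others[, 1], .bases))] + e1
  counts[cbind(seq_len(n), match(others[, 2], .bases))] <-
    counts[cbind(seq_len(n), match(others[, 2], .bases))] + e2
  counts[cbind(seq_len(n), match(others[, 3], .bases))] <-
    counts[cbind(seq_len(n), match(others[, 3], .bases))] + e3
  counts
}

#' Simulate pooled sequencing reads and write the dataset
#'
#' Converts a bulked design into a multi-sample SNP record table (and
#' optionally VCF + GFF3 + truth TSV on disk). Per SNP: each pool's
#' high-allele frequency is the mean allele dosage over its bulk members
#' divided by 2; per-sample depth is Poisson at the configured mean; reads
#' are drawn binomially from allele origin and then perturbed by uniform
#' sequencing error. Parents are sequenced as fixed homozygotes. A
#' configurable fraction of records is corrupted to fail the quality
#' filters (half multi-allelic, half low-depth) for filter testing. Random
#' gene models are placed uniformly per chromosome.
#'
#' @param design A [select_bulks()] result.
#' @param dir Optional output directory; when given, writes `variants.vcf`,
#'   `genes.gff3`, `truth.tsv` and `config.json`.
#' @return List: `records` (the [read_variants()] schema), `genes`,
#'   `truth` (per-SNP true pool frequencies and injected violations),
#'   `causal`, `design`.
#' @export
simulate_reads <- function(design, dir = NULL) {
  stopifnot(inherits(design, "bulk_design"),
            !is.null(design$high_bulk), !is.null(design$low_bulk))
  cfg <- design$config
  set.seed(cfg$seed + 2L)
  snps <- design$snps
  n <- nrow(snps)

  # Allele dosage -> pool frequencies of the high-parent allele.
  freq_h <- colMeans(design$genotypes[design$high_bulk, , drop = FALSE]) / 2
  freq_n <- colMeans(design$genotypes[design$low_bulk, , drop = FALSE]) / 2

  ref_base <- sample(.bases, n, replace = TRUE)
  alt_base <- vapply(ref_base, function(b) sample(setdiff(.bases, b), 1),
                     character(1), USE.NAMES = FALSE)

  sample_pool <- function(mean_depth, freq) {
    depth <- stats::rpois(n, mean_depth)
    alt_origin <- stats::rbinom(n, depth, freq)
    .reads_with_error(alt_origin, alt_base, cfg$error_rate) +
      .reads_with_error(depth - alt_origin, ref_base, cfg$error_rate)
  }
  counts <- list(
    parent_low = sample_pool(cfg$mean_depth_parent_low, 0),
    parent_high = sample_pool(cfg$mean_depth_parent_high, 1),
    pool_high = sample_pool(cfg$mean_depth_h, freq_h),
    pool_low = sample_pool(cfg$mean_depth_n, freq_n)
  )

  # Inject filter-violating records.
  injected <- rep("none", n)
  if (cfg$violation_fraction > 0) {
    hit <- which(stats::runif(n) < cfg$violation_fraction)
    kind <- sample(c("multiallelic", "low_depth"), length(hit), replace = TRUE)
    injected[hit] <- kind
    for (j in seq_along(hit)) {
      i <- hit[j]
      if (kind[j] == "multiallelic") {
        third <- setdiff(.bases, c(ref_base[i], alt_base[i]))[1]
        dep <- sum(counts$pool_high[i, ])
        counts$pool_high[i, third] <- max(4, round(0.3 * max(dep, 10)))
      } else {
        keep <- counts$pool_low[i, ]
        tot <- sum(keep)
        if (tot > 0) counts$pool_low[i, ] <- floor(keep * 3 / tot)
      }
    }
  }

  rec <- tibble::tibble(
    chrom = snps$chrom, pos = snps$pos,
    id = sprintf("snp_%06d", seq_len(n)),
    ref = ref_base,
    alt = ifelse(injected == "multiallelic",
                 paste(alt_base,
                       vapply(seq_len(n), function(i)
                         setdiff(.bases, c(ref_base[i], alt_base[i]))[1],
                         character(1)),
                       sep = ","),
                 alt_base)
  )
  for (role in .roles) {
    m <- counts[[role]]
    colnames(m) <- .count_cols(role)
    rec <- dplyr::bind_cols(rec, tibble::as_tibble(m))
  }
  rec$gt_parent_low <- paste(ref_base, ref_base, sep = "/")
  rec$gt_parent_high <- paste(alt_base, alt_base, sep = "/")
  rec$annotation_class <- NA_character_

  genes <- dplyr::bind_rows(lapply(.chrom_names(cfg$n_chromosomes), function(chr) {
    start <- sort(sample.int(cfg$chrom_length_bp - 6000L, cfg$genes_per_chromosome))
    len <- round(stats::runif(cfg$genes_per_chromosome, 1000, 5000))
    tibble::tibble(
      gene_id = sprintf("gene_%s_%03d", chr, seq_len(cfg$genes_per_chromosome)),
      chrom = chr, start = start, end = start + len,
      strand = sample(c("+", "-"), cfg$genes_per_chromosome, replace = TRUE)
    )
  }))

  truth <- tibble::tibble(
    chrom = snps$chrom, pos = snps$pos,
    freq_high_pool = freq_h, freq_low_pool = freq_n,
    injected = injected
  )

  out <- list(records = rec, genes = genes, truth = truth,
              causal = design$causal, design = design)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_variants(rec, file.path(dir, "variants.vcf"))
    write_gene_models(genes, file.path(dir, "genes.gff3"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg_out <- cfg
    class(cfg_out) <- NULL
    jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Deterministic fixture with known per-rule filter violations
#'
#' Builds a record table in which every record either passes all four
#' quality filters or fails exactly one known rule (and is constructed to
#' fail no earlier rule), together with the expected rejection tally. Used
#' to verify the filter accounting exactly.
#'
#' @param n_clean,n_multiallelic,n_low_depth,n_identical,n_inconsistent
#'   Number of records of each kind.
#' @return List `records`, `expected_tally` (tibble `rule`, `count`).
#' @export
make_filter_fixture <- function(n_clean = 2, n_multiallelic = 1,
                                n_low_depth = 1, n_identical = 1,
                                n_inconsistent = 1) {
  blank <- function() {
    counts <- stats::setNames(rep(list(0), 16),
                              unlist(lapply(.roles, .count_cols)))
    tibble::tibble(chrom = "Chr01", pos = 0L, id = ".", ref = "A", alt = "G",
                   !!!counts,
                   gt_parent_low = "A/A", gt_parent_high = "G/G",
                   annotation_class = NA_character_)
  }
  set_counts <- function(rec, role, a = 0, c = 0, g = 0, t = 0) {
    rec[, .count_cols(role)] <- as.list(c(a, c, g, t))
    rec
  }
  mk <- function(kind, i) {
    r <- blank()
    r$id <- paste0(kind, "_", i)
    r <- set_counts(r, "parent_low", a = 20)
    r <- set_counts(r, "parent_high", g = 20)
    r <- set_counts(r, "pool_low", a = 40)
    r <- set_counts(r, "pool_high", a = 10, g = 30)
    if (kind == "multiallelic") {
      r$alt <- "G,T"
      r <- set_counts(r, "pool_high", a = 10, g = 20, t = 10)
    } else if (kind == "low_depth") {
      r <- set_counts(r, "pool_low", a = 3)
    } else if (kind == "identical") {
      r <- set_counts(r, "pool_low", a = 20, g = 20)
      r <- set_counts(r, "pool_high", a = 20, g = 20)
    } else if (kind == "inconsistent") {
      # both parents A: two observed bases total (A, T), pool carries T
      r$alt <- "T"
      r$gt_parent_high <- "A/A"
      r <- set_counts(r, "parent_high", a = 20)
      r <- set_counts(r, "pool_low", a = 40)
      r <- set_counts(r, "pool_high", a = 25, t = 15)
    }
    r
  }
  kinds <- c(rep("clean", n_clean), rep("multiallelic", n_multiallelic),
             rep("low_depth", n_low_depth), rep("identical", n_identical),
             rep("inconsistent", n_inconsistent))
  records <- dplyr::bind_rows(mapply(mk, kinds, seq_along(kinds),
                                     SIMPLIFY = FALSE))
  records$pos <- seq_len(nrow(records)) * 100L
  list(
    records = records,
    expected_tally = tibble::tibble(
      rule = c("multiallelic", "low_depth", "identical_genotypes",
               "recessive_inconsistent"),
      count = c(n_multiallelic, n_low_depth, n_identical, n_inconsistent)
    )
  )
}
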