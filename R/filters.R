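#' Configuration of the seven-criterion SNP filtering cascade
#'
#' Defaults reproduce a strict genotyping-by-sequencing filtering protocol:
#' biallelic sites only; per-genotype depth in `[5, 200]` and genotype
#' quality at least 20 (failing genotypes are set to missing, as in the
#' VCFtools `--minDP`/`--minGQ` semantics); site called in at least 80% of
#' individuals; minor allele frequency at least 0.02 over called genotypes
#' (inclusive); observed heterozygosity strictly below 0.5 (paralog guard);
#' and all SNPs discarded on any scaffold ("genomic locus") carrying more
#' than nine surviving SNPs (sequencing/genotyping-error guard).
#'
#' @param min_alleles,max_alleles allele-count window (biallelic by default)
#' @param min_dp,max_dp per-genotype depth window
#' @param min_gq minimum per-genotype quality
#' @param max_missing_fraction maximum fraction of missing genotypes per site
#' @param min_maf minimum minor allele frequency (ties kept)
#' @param max_hobs per-site observed-heterozygosity bound (strict `<`)
#' @param max_snps_per_locus scaffold-level SNP-count bound (strict: loci
#'   with more SNPs are discarded entirely)
#' @return an object of class `filter_config`
#' @export
filter_config <- function(min_alleles = 2, max_alleles = 2, min_dp = 5,
                          max_dp = 200, min_gq = 20,
                          max_missing_fraction = 0.2, min_maf = 0.02,
                          max_hobs = 0.5, max_snps_per_locus = 9) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_maf >= 0, min_maf <= 1, max_hobs >= 0, max_hobs <= 1,
            min_dp <= max_dp, min_alleles <= max_alleles,
            max_snps_per_locus >= 1)
  structure(as.list(environment()), class = "filter_config")
}

#' Apply the SNP filtering cascade
#'
#' Criteria are applied in a fixed order: (1) biallelic sites; (2) genotypes
#' with DP outside the window set to missing; (3) genotypes with GQ below the
#' bound set to missing; (4) site presence (called fraction); (5) minor
#' allele frequency over called genotypes; (6) observed heterozygosity
#' strictly below the bound; (7) discard every SNP on scaffolds carrying
#' more than `max_snps_per_locus` survivors of criteria 1-6. Genotype-level
#' masking (2, 3) deliberately precedes the site-level tests (4-6), which
#' therefore see the masked data. The cascade is idempotent.
#'
#' @param records a [variant_set()] carrying DP and GQ
#' @param config a [filter_config()]
#' @return list with `records` (the filtered [variant_set()]) and `report`
#'   (data.frame: criterion, sites in, sites out, genotypes masked)
#' @export
apply_filters <- function(records, config = filter_config()) {
  stopifnot(inherits(records, "variant_set"),
            inherits(config, "filter_config"))
  if (is.null(records$dp) || is.null(records$gq)) {
    stop("records are missing DP/GQ fields; the cascade needs both")
  }
  report <- data.frame(criterion = character(0), n_in = integer(0),
                       n_out = integer(0), genotypes_masked = integer(0))
  log_step <- function(name, n_in, n_out, masked = 0L) {
    report[nrow(report) + 1L, ] <<- list(name, n_in, n_out, as.integer(masked))
  }

  # 1: biallelic
  n_alt <- ifelse(records$alt == ".", 0L,
                  vapply(strsplit(records$alt, ","), length, integer(1)))
  n_alleles <- 1L + n_alt
  keep <- n_alleles >= config$min_alleles & n_alleles <= config$max_alleles
  log_step("biallelic", .n_sites(records), sum(keep))
  records <- .subset_sites(records, keep)

  # 2: depth window (genotype-level masking)
  bad_dp <- !is.na(records$gt) &
    (records$dp < config$min_dp | records$dp > config$max_dp)
  records$gt[bad_dp] <- NA_integer_
  log_step("depth_mask", .n_sites(records), .n_sites(records), sum(bad_dp))

  # 3: genotype quality (genotype-level masking)
  bad_gq <- !is.na(records$gt) & records$gq < config$min_gq
  records$gt[bad_gq] <- NA_integer_
  log_step("gq_mask", .n_sites(records), .n_sites(records), sum(bad_gq))

  # 4: presence
  called <- rowMeans(!is.na(records$gt))
  keep <- called >= 1 - config$max_missing_fraction
  log_step("presence", .n_sites(records), sum(keep))
  records <- .subset_sites(records, keep)

  # 5: minor allele frequency over called genotypes (inclusive threshold)
  n_called <- rowSums(!is.na(records$gt))
  p <- rowSums(records$gt, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p, 1 - p)
  keep <- n_called > 0 & maf >= config$min_maf
  log_step("maf", .n_sites(records), sum(keep))
  records <- .subset_sites(records, keep)

  # 6: observed heterozygosity (strict <)
  hobs <- rowSums(records$gt == 1L, na.rm = TRUE) /
    pmax(1L, rowSums(!is.na(records$gt)))
  keep <- hobs < config$max_hobs
  log_step("hobs", .n_sites(records), sum(keep))
  records <- .subset_sites(records, keep)

  # 7: scaffolds with too many surviving SNPs
  per_scaffold <- table(records$chrom)
  bad_scaffolds <- names(per_scaffold)[per_scaffold > config$max_snps_per_locus]
  keep <- !records$chrom %in% bad_scaffolds
  log_step("snps_per_locus", .n_sites(records), sum(keep))
  records <- .subset_sites(records, keep)

  list(records = records, report = report)
}

#' Retain one SNP per scaffold
#'
#' Reduces linkage-disequilibrium bias for structure-type analyses by
#' keeping exactly one SNP per scaffold: the first by position (default) or
#' a seeded random choice.
#'
#' @param records a [variant_set()]
#' @param method `"first"` or `"random"`
#' @param rng_seed integer seed used by the random method
#' @return the pruned [variant_set()]
#' @export
select_one_snp_per_locus <- function(records, method = c("first", "random"),
                                     rng_seed = NULL) {
  stopifnot(inherits(records, "variant_set"))
  method <- match.arg(method)
  idx <- seq_along(records$chrom)
  keep <- with_seed(rng_seed, {
    vapply(split(idx, records$chrom), function(i) {
      if (method == "first") i[which.min(records$pos[i])]
      else if (length(i) == 1L) i
      else sample(i, 1L)
    }, integer(1))
  })
  .subset_sites(records, sort(unname(keep)))
}
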