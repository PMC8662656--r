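#' Per-site variant records with genotype, depth and quality matrices
#'
#' The filtering cascade operates on this container: one row per SNP site
#' (scaffold, 1-based position, ref/alt alleles) and per-sample matrices of
#' genotypes (`{0, 1, 2, NA}`), read depth (`DP`) and phred-scaled genotype
#' quality (`GQ`). `alt` holds a comma-separated allele list so that
#' multi-allelic records survive the round trip to VCF and can be rejected by
#' the biallelic filter.
#'
#' @param chrom,pos,ref,alt per-site vectors
#' @param gt,dp,gq sites x samples matrices; `dp`/`gq` may be `NULL` when the
#'   source VCF lacks them (the filter cascade then refuses to run)
#' @param samples sample names
#' @return an object of class `variant_set`
#' @export
variant_set <- function(chrom, pos, ref, alt, gt, dp = NULL, gq = NULL,
                        samples = colnames(gt)) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  L <- length(chrom)
  stopifnot(length(pos) == L, length(ref) == L, length(alt) == L,
            nrow(gt) == L)
  if (is.null(samples)) samples <- paste0("sample_", seq_len(ncol(gt)))
  for (m in list(dp, gq)) {
    if (!is.null(m)) stopifnot(all(dim(m) == dim(gt)))
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 gt = gt, dp = dp, gq = gq,
                 samples = as.character(samples)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", length(x$pos), "sites x", length(x$samples),
      "samples\n")
  cat("scaffolds:", length(unique(x$chrom)),
      "| DP:", !is.null(x$dp), "| GQ:", !is.null(x$gq), "\n")
  invisible(x)
}

.n_sites <- function(vs) length(vs$pos)

.subset_sites <- function(vs, keep) {
  variant_set(vs$chrom[keep], vs$pos[keep], vs$ref[keep], vs$alt[keep],
              vs$gt[keep, , drop = FALSE],
              if (!is.null(vs$dp)) vs$dp[keep, , drop = FALSE],
              if (!is.null(vs$gq)) vs$gq[keep, , drop = FALSE],
              vs$samples)
}

#' Decorate simulated genotypes with GBS-like depth, quality and missingness
#'
#' Emulates reduced-representation (genotyping-by-sequencing) noise on a
#' clean simulated genotype matrix so the filtering cascade can be exercised
#' end to end. Per genotype: read depth `DP` is drawn from a negative
#' binomial with mean `depth_mean` and dispersion `dp_size`; genotype quality
#' is the documented deterministic function
#' `GQ = min(99, round(gq_scale * DP * (0.7 if heterozygous else 1)))`,
#' increasing in depth and lower for heterozygous calls (whose two alleles
#' must both be sampled among the reads); genotypes are dropped to missing
#' independently at `missing_rate`, and a genotype with `DP = 0` is always
#' missing.
#'
#' @param genotypes a [genotype_matrix()]
#' @param depth_mean mean read depth (> 0)
#' @param dp_size negative-binomial size (dispersion) parameter
#' @param gq_scale slope of the GQ model in phred units per read
#' @param missing_rate genotype dropout probability in `[0, 1)`
#' @param rng_seed integer seed or `NULL`
#' @param snps_per_scaffold if > 1, consecutive loci are grouped onto shared
#'   scaffolds with consecutive positions, emulating multi-SNP GBS loci
#' @return a [variant_set()] with DP and GQ
#' @export
add_gbs_noise <- function(genotypes, depth_mean = 10, dp_size = 5,
                          gq_scale = 3, missing_rate = 0.05, rng_seed = NULL,
                          snps_per_scaffold = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"), depth_mean > 0,
            missing_rate >= 0, missing_rate < 1)
  gt <- t(genotypes$gt)                       # sites x individuals
  L <- nrow(gt)
  n <- ncol(gt)
  chrom <- genotypes$chrom
  pos <- genotypes$pos
  if (snps_per_scaffold > 1L) {
    idx <- (seq_len(L) - 1L) %/% as.integer(snps_per_scaffold)
    chrom <- sprintf("scaffold_%06d", idx + 1L)
    pos <- as.integer((seq_len(L) - 1L) %% as.integer(snps_per_scaffold) * 50L + 101L)
  }
  with_seed(rng_seed, {
    dp <- matrix(as.integer(rnbinom(L * n, mu = depth_mean, size = dp_size)),
                 L, n)
    het <- !is.na(gt) & gt == 1L
    gq <- matrix(pmin(99L, as.integer(round(gq_scale * dp * ifelse(het, 0.7, 1)))),
                 L, n)
    drop <- matrix(runif(L * n) < missing_rate, L, n) | dp == 0L
    gt[drop] <- NA_integer_
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    variant_set(chrom, pos, ref, unname(alt), gt, dp, gq,
                samples = genotypes$sample_id)
  })
}

#' Convert variant records plus a population map to a genotype matrix
#'
#' @param records a [variant_set()]
#' @param popmap data.frame with columns `sample_id`, `group` (see
#'   [read_popmap()]); samples absent from the map are dropped
#' @return a [genotype_matrix()]
#' @export
as_genotype_matrix <- function(records, popmap) {
  stopifnot(inherits(records, "variant_set"),
            all(c("sample_id", "group") %in% names(popmap)))
  keep <- match(popmap$sample_id, records$samples)
  if (anyNA(keep)) {
    stop("samples in popmap missing from records: ",
         paste(popmap$sample_id[is.na(keep)], collapse = ", "))
  }
  genotype_matrix(t(records$gt[, keep, drop = FALSE]),
                  group = popmap$group, sample_id = popmap$sample_id,
                  chrom = records$chrom, pos = records$pos)
}
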