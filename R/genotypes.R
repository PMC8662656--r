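#' Diploid genotype matrix with group labels
#'
#' The central genotype container: individuals x SNP loci, entries counting
#' copies of the derived/alternate allele (0, 1, 2 or `NA` for missing),
#' with a scaffold id and 1-based position per locus and a genetic-group
#' label per individual.
#'
#' @param gt integer matrix, individuals x loci, entries in `{0, 1, 2, NA}`
#' @param group character vector of group labels, one per individual
#' @param sample_id individual identifiers (default constructed from groups)
#' @param chrom scaffold ids per locus (default one scaffold per locus)
#' @param pos 1-based positions per locus
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(gt, group, sample_id = NULL, chrom = NULL,
                            pos = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (!all(gt %in% c(0L, 1L, 2L, NA))) {
    stop("genotype entries must be 0, 1, 2 or NA")
  }
  n <- nrow(gt)
  L <- ncol(gt)
  group <- as.character(group)
  stopifnot(length(group) == n)
  if (is.null(sample_id)) {
    sample_id <- paste0(group, "_", stats::ave(seq_len(n), group, FUN = seq_along))
  }
  if (is.null(chrom)) chrom <- sprintf("scaffold_%06d", seq_len(L))
  if (is.null(pos)) pos <- rep(1L, L)
  stopifnot(length(sample_id) == n, length(chrom) == L, length(pos) == L)
  structure(list(gt = gt, sample_id = as.character(sample_id), group = group,
                 chrom = as.character(chrom), pos = as.integer(pos)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$gt), "individuals x", ncol(x$gt), "loci\n")
  print(table(x$group))
  miss <- mean(is.na(x$gt))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$gt)

#' Simulate derived-allele indicators for a single locus
#'
#' Builds one coalescent genealogy of all sampled lineages under the
#' piecewise-constant multi-population model implied by `params`, places one
#' mutation uniformly at random on the total branch length, and returns the
#' per-lineage derived-allele indicator. The locus is always segregating in
#' the pooled sample.
#'
#' @param params a [scenario_params()] object
#' @param lineage_counts named haploid lineage counts for `JR`, `OH`, `KK`,
#'   `OT` (groups may be 0, total at least 2)
#' @param rng_seed integer seed or `NULL`
#' @return integer 0/1 vector, one entry per lineage, ordered by group block
#' @export
simulate_locus <- function(params, lineage_counts, rng_seed = NULL) {
  stopifnot(inherits(params, "scenario_params"))
  nl <- .lineage_vector(lineage_counts)
  sc <- .scenario_events(params)
  with_seed(rng_seed,
    as.integer(sim_loci_cpp(c(nl, 0L), sc$sizes0, sc$events, 1L)))
}

# simulate lineage-level derived indicators, optionally redrawing loci whose
# pooled minor-allele frequency falls below an ascertainment threshold
.sim_lineages <- function(nl, sc, n_loci, min_maf = NULL) {
  lin <- sim_loci_cpp(c(nl, 0L), sc$sizes0, sc$events, as.integer(n_loci))
  if (!is.null(min_maf) && min_maf > 0) {
    repeat {
      p <- colMeans(lin)
      bad <- which(pmin(p, 1 - p) < min_maf)
      if (!length(bad)) break
      lin[, bad] <- sim_loci_cpp(c(nl, 0L), sc$sizes0, sc$events,
                                 length(bad))
    }
  }
  lin
}

.lineage_vector <- function(lineage_counts) {
  nl <- setNames(integer(4), .group_names)
  lineage_counts <- unlist(lineage_counts)
  if (is.null(names(lineage_counts))) {
    if (length(lineage_counts) > 4) stop("at most 4 groups")
    nl[seq_along(lineage_counts)] <- as.integer(lineage_counts)
  } else {
    bad <- setdiff(names(lineage_counts), .group_names)
    if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
    nl[names(lineage_counts)] <- as.integer(lineage_counts)
  }
  if (sum(nl) < 2) stop("need at least 2 lineages in total")
  nl
}

#' Simulate a multi-locus SNP genotype dataset under a demographic scenario
#'
#' Loci are independent; each is generated by one coalescent genealogy with a
#' single segregating mutation (see [simulate_locus()]). Diploid genotypes
#' are formed by pairing consecutive lineages within each group
#' (Hardy-Weinberg within demes). With `min_maf` set, loci whose pooled
#' minor-allele frequency falls below the threshold are redrawn, emulating a
#' minor-allele-frequency ascertainment of the observed SNP panel.
#'
#' @param params a [scenario_params()] object
#' @param config a [sample_config()] of diploid sample sizes
#' @param n_loci number of SNP loci
#' @param rng_seed integer seed or `NULL`
#' @param min_maf optional pooled minor-allele-frequency ascertainment
#'   threshold (default `NULL`: no conditioning)
#' @return a [genotype_matrix()] with no missing entries
#' @export
simulate_dataset <- function(params, config = sample_config(), n_loci,
                             rng_seed = NULL, min_maf = NULL) {
  stopifnot(inherits(params, "scenario_params"), n_loci >= 1)
  nl <- .lineage_vector(2L * unclass(config))
  sc <- .scenario_events(params)
  with_seed(rng_seed, {
    lin <- .sim_lineages(nl, sc, n_loci, min_maf)
    gt <- lin[seq(1, nrow(lin), by = 2), , drop = FALSE] +
      lin[seq(2, nrow(lin), by = 2), , drop = FALSE]
    group <- rep(names(nl), nl %/% 2L)
    genotype_matrix(gt, group)
  })
}

#' Simulate a single panmictic population
#'
#' Convenience wrapper for null-model checks: one population of constant
#' diploid size, every locus ascertained as segregating in the sample.
#'
#' @param n_ind diploid sample size
#' @param n_loci number of loci
#' @param N diploid effective size
#' @param rng_seed integer seed or `NULL`
#' @param group label assigned to all individuals
#' @return a [genotype_matrix()]
#' @export
simulate_panmictic <- function(n_ind, n_loci, N, rng_seed = NULL,
                               group = "POP") {
  stopifnot(n_ind >= 2, n_loci >= 1, N >= 1)
  with_seed(rng_seed, {
    lin <- sim_loci_cpp(2L * as.integer(n_ind), as.numeric(N),
                        matrix(numeric(0), 0, 4), as.integer(n_loci))
    gt <- lin[seq(1, nrow(lin), by = 2), , drop = FALSE] +
      lin[seq(2, nrow(lin), by = 2), , drop = FALSE]
    genotype_matrix(gt, rep(group, n_ind))
  })
}

#' Write a genotype matrix as TSV
#'
#' @param genotypes a [genotype_matrix()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genotype_tsv <- function(genotypes, path) {
  df <- data.frame(sample_id = genotypes$sample_id, group = genotypes$group,
                   genotypes$gt, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0(genotypes$chrom, ":", genotypes$pos)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a two-column population map (sample_id, group)
#'
#' @param genotypes a [genotype_matrix()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_popmap <- function(genotypes, path) {
  write.table(data.frame(genotypes$sample_id, genotypes$group), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column population map
#'
#' @param path TSV with columns sample_id, group (no header)
#' @return data.frame with columns `sample_id`, `group`
#' @export
read_popmap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample_id", "group"),
                   colClasses = "character")
  df
}
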