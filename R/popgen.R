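# Per-group, per-locus counts from a genotype matrix: called diploids,
# alternate-allele copies, heterozygote counts.
.group_counts <- function(genotypes, group) {
  rows <- genotypes$group == group
  if (!any(rows)) stop("no individuals in group ", group)
  g <- genotypes$gt[rows, , drop = FALSE]
  called <- colSums(!is.na(g))
  list(n = called,
       alt = colSums(g, na.rm = TRUE),
       het = colSums(g == 1L, na.rm = TRUE))
}

# Weir & Cockerham (1984) variance components for two populations at every
# locus, vectorized. Inputs are per-locus called sample sizes, alternate
# allele frequencies and heterozygote fractions.
.wc_components <- function(na_, pa, ha, nb, pb, hb) {
  nbar <- (na_ + nb) / 2
  nc <- 2 * nbar - (na_^2 + nb^2) / (2 * nbar)
  pbar <- (na_ * pa + nb * pb) / (2 * nbar)
  s2 <- (na_ * (pa - pbar)^2 + nb * (pb - pbar)^2) / nbar
  hbar <- (na_ * ha + nb * hb) / (2 * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  list(a = a, b = b, c = c_, pbar = pbar)
}

#' Per-group summary genetic statistics
#'
#' For each group and each of its variant sites (sites with at least two
#' called genotypes in the group), with `p` the alternate-allele frequency
#' over called genotypes and `n_c` the called diploids:
#' `H_exp = 2p(1-p)`; `H_obs` = heterozygote fraction;
#' `pi = 2p(1-p) * 2n_c / (2n_c - 1)` (unbiased pairwise-difference
#' correction); `F_IS = 1 - H_obs/H_exp` where `H_exp > 0`, else 0. Group
#' values are means over the group's variant sites. `poly` counts sites
#' polymorphic within the group and `private` counts SNPs segregating in
#' this group only.
#'
#' @param genotypes a [genotype_matrix()]
#' @return data.frame, one row per group: `group`, `n`, `variant`, `poly`,
#'   `private`, `H_exp`, `H_obs`, `pi`, `F_IS`
#' @export
group_summary <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  groups <- unique(genotypes$group)
  if (any(table(genotypes$group) < 2)) {
    stop("every group needs at least 2 individuals")
  }
  counts <- lapply(groups, function(g) .group_counts(genotypes, g))
  names(counts) <- groups
  poly_mat <- matrix(unlist(lapply(groups, function(g) {
    ct <- counts[[g]]
    p <- ct$alt / (2 * ct$n)
    ct$n >= 2 & !is.na(p) & p > 0 & p < 1
  })), ncol = length(groups), dimnames = list(NULL, groups))
  out <- lapply(groups, function(g) {
    ct <- counts[[g]]
    variant <- ct$n >= 2
    n_c <- ct$n[variant]
    p <- ct$alt[variant] / (2 * n_c)
    hexp <- 2 * p * (1 - p)
    hobs <- ct$het[variant] / n_c
    pi_site <- hexp * (2 * n_c) / (2 * n_c - 1)
    fis <- ifelse(hexp > 0, 1 - hobs / hexp, 0)
    others <- poly_mat[variant, setdiff(groups, g), drop = FALSE]
    private <- sum(poly_mat[variant, g] & rowSums(others) == 0)
    data.frame(group = g, n = sum(genotypes$group == g),
               variant = sum(variant), poly = sum(poly_mat[variant, g]),
               private = private, H_exp = mean(hexp), H_obs = mean(hobs),
               pi = mean(pi_site), F_IS = mean(fis))
  })
  do.call(rbind, out)
}

# multi-locus WC84 theta for a fixed split of individuals; gt/het/called are
# loci x individuals transposed views used by the permutation loop
.theta_from_split <- function(called, alt, het, in_a) {
  ca <- called %*% in_a
  cb <- called %*% (1 - in_a)
  aa <- alt %*% in_a
  ab <- alt %*% (1 - in_a)
  ha <- het %*% in_a
  hb <- het %*% (1 - in_a)
  ok <- ca >= 2 & cb >= 2
  w <- .wc_components(ca[ok], aa[ok] / (2 * ca[ok]), ha[ok] / ca[ok],
                      cb[ok], ab[ok] / (2 * cb[ok]), hb[ok] / cb[ok])
  denom <- sum(w$a + w$b + w$c)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  sum(w$a) / denom
}

#' Pairwise multi-locus F_ST with a permutation test
#'
#' Weir & Cockerham (1984) theta per locus, combined as the ratio of summed
#' variance components over loci (ratio of averages). Significance is
#' assessed by shuffling individuals between the two groups;
#' `p = (1 + #\{permuted theta >= observed\}) / (n_perm + 1)`. Loci need at
#' least two called genotypes in each group to contribute. When no locus
#' segregates in the pair the estimate is undefined (`NA` with status
#' `"undefined"`), not zero.
#'
#' @param genotypes a [genotype_matrix()]
#' @param group_a,group_b group labels
#' @param n_perm number of permutations (0 skips the test)
#' @param rng_seed integer seed or `NULL`
#' @return an object of class `fst_result`: `estimate`, `p_value`,
#'   `n_perm`, `status`
#' @export
pairwise_fst <- function(genotypes, group_a, group_b, n_perm = 10000,
                         rng_seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  rows <- genotypes$group %in% c(group_a, group_b)
  if (sum(genotypes$group == group_a) < 2 ||
      sum(genotypes$group == group_b) < 2) {
    stop("both groups need at least 2 individuals")
  }
  g <- genotypes$gt[rows, , drop = FALSE]
  grp <- genotypes$group[rows]
  called <- t(!is.na(g)) * 1
  alt <- t(g)
  alt[is.na(alt)] <- 0
  het <- t(!is.na(g) & g == 1L) * 1
  in_a <- as.numeric(grp == group_a)

  # segregating in the pooled pair at all?
  pooled_alt <- rowSums(alt)
  pooled_n <- rowSums(called)
  seg <- any(pooled_n >= 2 & pooled_alt > 0 & pooled_alt < 2 * pooled_n)
  obs <- .theta_from_split(called, alt, het, in_a)
  if (!seg || is.na(obs)) {
    return(structure(list(estimate = NA_real_, p_value = NA_real_,
                          n_perm = 0L, status = "undefined"),
                     class = "fst_result"))
  }
  p_value <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(rng_seed, {
      vapply(seq_len(n_perm), function(i) {
        .theta_from_split(called, alt, het, sample(in_a))
      }, numeric(1))
    })
    p_value <- (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1)
  }
  structure(list(estimate = obs, p_value = p_value,
                 n_perm = as.integer(n_perm), status = "ok"),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("WC84 multi-locus F_ST = %s (p = %s, %d permutations, %s)\n",
              format(x$estimate, digits = 4), format(x$p_value, digits = 4),
              x$n_perm, x$status))
  invisible(x)
}

#' Pairwise F_ST matrix over all groups
#'
#' @param genotypes a [genotype_matrix()]
#' @param n_perm permutations per pair (0 skips the tests)
#' @param rng_seed integer seed or `NULL`
#' @return list with `fst` (symmetric matrix) and `p_value` (matrix)
#' @export
fst_matrix <- function(genotypes, n_perm = 0, rng_seed = NULL) {
  groups <- unique(genotypes$group)
  k <- length(groups)
  est <- p <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  seeds <- seq_len(k * k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- pairwise_fst(genotypes, groups[i], groups[j], n_perm = n_perm,
                        rng_seed = if (is.null(rng_seed)) NULL else
                          derive_seed(rng_seed, paste0(groups[i], groups[j])))
      est[i, j] <- est[j, i] <- r$estimate
      p[i, j] <- p[j, i] <- r$p_value
    }
  }
  list(fst = est, p_value = p)
}

#' Nei's (1972) standard genetic distance between two groups
#'
#' Per biallelic locus with alternate-allele frequencies `p_x`, `p_y` over
#' called genotypes: `J_x = p_x^2 + (1-p_x)^2`, `J_xy = p_x p_y +
#' (1-p_x)(1-p_y)`, `D = -ln(J_xy / sqrt(J_x J_y))`. Loci fixed for opposite
#' alleles give an infinite distance; these are excluded from the mean and
#' counted separately.
#'
#' @param genotypes a [genotype_matrix()]
#' @param group_a,group_b group labels
#' @return list with `per_locus` distances, `mean` over finite loci,
#'   `n_infinite`, and `n_loci` used
#' @export
nei_distance <- function(genotypes, group_a, group_b) {
  ca <- .group_counts(genotypes, group_a)
  cb <- .group_counts(genotypes, group_b)
  ok <- ca$n >= 1 & cb$n >= 1
  px <- ca$alt[ok] / (2 * ca$n[ok])
  py <- cb$alt[ok] / (2 * cb$n[ok])
  jx <- px^2 + (1 - px)^2
  jy <- py^2 + (1 - py)^2
  jxy <- px * py + (1 - px) * (1 - py)
  d <- -log(jxy / sqrt(jx * jy))
  d[jxy == 0] <- Inf
  list(per_locus = d, mean = mean(d[is.finite(d)]),
       n_infinite = sum(is.infinite(d)), n_loci = length(d))
}

#' Principal components analysis of genotypes
#'
#' Missing entries are imputed to the per-site mean; monomorphic sites are
#' excluded; each site is standardized by its mean `2p` and by
#' `sqrt(2p(1-p))`, and the individual x individual covariance is
#' eigendecomposed. Coordinates are reproducible up to sign.
#'
#' @param genotypes a [genotype_matrix()]
#' @param n_components number of components to return
#' @return list with `eigenvalues`, `varprop`, and `coords`
#'   (individuals x components, rownames = sample ids)
#' @export
genotype_pca <- function(genotypes, n_components = 10) {
  g <- genotypes$gt
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0                     # mean imputation after centering
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  cv <- tcrossprod(x) / ncol(x)
  e <- eigen(cv, symmetric = TRUE)
  k <- min(n_components, nrow(cv) - 1)
  ev <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(coords) <- genotypes$sample_id
  colnames(coords) <- paste0("PC", seq_len(k))
  list(eigenvalues = ev[seq_len(k)], varprop = ev[seq_len(k)] / sum(ev),
       coords = coords)
}
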