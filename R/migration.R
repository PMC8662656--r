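#' Directional relative migration between genetic groups (migrant-pool G_ST)
#'
#' For every pair of groups a hypothetical migrant pool is formed with
#' allele frequencies equal to the unweighted mean of the pair's per-locus
#' frequencies. Nei's multi-locus G_ST (subpopulation and total
#' heterozygosities averaged over loci before the ratio) is computed between
#' each member of the pair and the pool; a population that resembles the
#' pool more closely receives more immigrants, so the differentiation
#' between group `a` and the pool quantifies migration into `a` from `b`.
#' Each directional differentiation is converted to an effective migration
#' value through the island-model relation `Nm = (1/G_ST - 1)/4` and the
#' whole matrix is divided by its maximum, yielding relative migration in
#' `[0, 1]`.
#'
#' @param genotypes a [genotype_matrix()] with at least two groups of at
#'   least two individuals each
#' @return a `migration_matrix`: square matrix, rows = source group,
#'   columns = target group, `NA` on the diagonal and for pairs without
#'   shared polymorphic loci (flagged in `attr(, "undefined_pairs")`)
#' @export
relative_migration <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  groups <- unique(genotypes$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(table(genotypes$group) < 2)) {
    stop("every group needs at least 2 individuals")
  }
  counts <- lapply(groups, function(g) .group_counts(genotypes, g))
  names(counts) <- groups
  k <- length(groups)
  nm <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  undefined <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ca <- counts[[i]]
      cb <- counts[[j]]
      ok <- ca$n >= 1 & cb$n >= 1
      pa <- ca$alt[ok] / (2 * ca$n[ok])
      pb <- cb$alt[ok] / (2 * cb$n[ok])
      poly <- (pa > 0 & pa < 1) | (pb > 0 & pb < 1) | (pa != pb)
      if (!any(poly)) {
        undefined <- c(undefined, paste(groups[i], groups[j], sep = "-"))
        next
      }
      pa <- pa[poly]
      pb <- pb[poly]
      pool <- (pa + pb) / 2
      gst <- function(p, q) {
        hs <- mean((2 * p * (1 - p) + 2 * q * (1 - q)) / 2)
        pm <- (p + q) / 2
        ht <- mean(2 * pm * (1 - pm))
        if (ht <= 0) return(NaN)
        max((ht - hs) / ht, 1e-12)
      }
      g_a <- gst(pa, pool)              # differentiation of a from the pool
      g_b <- gst(pb, pool)
      nm[groups[j], groups[i]] <- (1 / g_a - 1) / 4   # migration b -> a
      nm[groups[i], groups[j]] <- (1 / g_b - 1) / 4   # migration a -> b
    }
  }
  if (any(is.finite(nm))) nm <- nm / max(nm, na.rm = TRUE)
  structure(nm, class = c("migration_matrix", "matrix"),
            undefined_pairs = undefined)
}

#' @export
print.migration_matrix <- function(x, threshold = NULL, ...) {
  cat("relative migration (row = source, column = target)\n")
  m <- unclass(x)
  attr(m, "undefined_pairs") <- NULL
  print(round(m, 3))
  if (!is.null(threshold)) {
    weak <- which(m < threshold, arr.ind = TRUE)
    if (nrow(weak)) {
      cat("limited gene flow (<", threshold, "):",
          paste(rownames(m)[weak[, 1]], "->", colnames(m)[weak[, 2]],
                collapse = ", "), "\n")
    }
  }
  up <- attr(x, "undefined_pairs")
  if (length(up)) cat("undefined pairs:", paste(up, collapse = ", "), "\n")
  invisible(x)
}
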