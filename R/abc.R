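# Summary-statistic vector used for ABC. Per group: proportion of loci with
# zero within-group gene diversity; mean and variance of gene diversity over
# loci with nonzero diversity; mean gene diversity over all loci. Per group
# pair: mean and variance of per-locus WC84 theta over loci polymorphic in
# the pooled pair ("nonzero" loci; negative theta counts as nonzero); the
# proportion of per-locus Nei distances equal to zero; and the mean Nei
# distance over all (finite) loci. For four groups the vector has
# 4*4 + 6*4 = 40 entries in a fixed order.

.stat_names <- function(groups) {
  per_group <- as.vector(outer(c("gd_p0", "gd_mnz", "gd_vnz", "gd_mean"),
                               groups, function(s, g) paste(g, s, sep = "_")))
  pairs <- combn(groups, 2)
  per_pair <- as.vector(apply(pairs, 2, function(pr) {
    paste(paste(pr, collapse = "."),
          c("fst_mnz", "fst_vnz", "nei_p0", "nei_mean"), sep = "_")
  }))
  c(per_group, per_pair)
}

.var0 <- function(x) if (length(x) < 2) 0 else var(x)

# counts: list per group of list(n, alt, het) as from .group_counts
.stats_from_counts <- function(counts, groups) {
  out <- numeric(0)
  freqs <- lapply(groups, function(g) {
    ct <- counts[[g]]
    ct$alt / (2 * ct$n)
  })
  names(freqs) <- groups
  for (g in groups) {
    p <- freqs[[g]]
    gd <- 2 * p * (1 - p)
    nz <- gd[gd > 0]
    out <- c(out, mean(gd == 0),
             if (length(nz)) mean(nz) else 0,
             .var0(nz),
             mean(gd))
  }
  pairs <- combn(groups, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    ca <- counts[[a]]
    cb <- counts[[b]]
    pa <- freqs[[a]]
    pb <- freqs[[b]]
    w <- .wc_components(ca$n, pa, ca$het / ca$n, cb$n, pb, cb$het / cb$n)
    theta <- w$a / (w$a + w$b + w$c)
    poly_pair <- w$pbar > 0 & w$pbar < 1
    nz <- theta[poly_pair & is.finite(theta)]
    jx <- pa^2 + (1 - pa)^2
    jy <- pb^2 + (1 - pb)^2
    jxy <- pa * pb + (1 - pa) * (1 - pb)
    d <- -log(jxy / sqrt(jx * jy))
    d[jxy == 0] <- Inf
    out <- c(out, if (length(nz)) mean(nz) else 0, .var0(nz),
             mean(d < 1e-12), mean(d[is.finite(d)]))
  }
  setNames(out, .stat_names(groups))
}

#' ABC summary statistics of a genotype dataset
#'
#' @param genotypes a [genotype_matrix()] (at least two groups)
#' @param groups group ordering (default: order of appearance)
#' @return named numeric vector (40 entries for four groups)
#' @export
summary_stats <- function(genotypes, groups = unique(genotypes$group)) {
  stopifnot(inherits(genotypes, "genotype_matrix"), length(groups) >= 2)
  counts <- lapply(groups, function(g) .group_counts(genotypes, g))
  names(counts) <- groups
  .stats_from_counts(counts, groups)
}

#' Build an ABC reference table
#'
#' Each row is one simulation: a scenario id (cycled so the scenario prior
#' is uniform), a parameter draw from the priors, and the summary-statistic
#' vector of a dataset simulated under that draw. Per-statistic standard
#' deviations over the table are stored as normalization constants;
#' zero-variance statistics are dropped from distance computations and
#' recorded.
#'
#' @param priors a [prior_spec()]
#' @param scenarios integer vector of scenario ids
#' @param config a [sample_config()]
#' @param n_sims number of simulations
#' @param n_loci SNP loci per simulated dataset
#' @param rng_seed integer seed or `NULL`
#' @param min_maf optional pooled minor-allele-frequency ascertainment
#'   applied to every simulated locus, matching an ascertainment applied to
#'   the observed data (default `NULL`: none)
#' @param progress print progress every this many rows (0 = quiet)
#' @return an object of class `reference_table`
#' @export
build_reference_table <- function(priors, scenarios = 1:3,
                                  config = sample_config(), n_sims, n_loci,
                                  rng_seed = NULL, min_maf = NULL,
                                  progress = 0) {
  stopifnot(n_sims >= 1, n_loci >= 1)
  scen <- rep_len(as.integer(scenarios), n_sims)
  groups <- names(config)
  nl <- 2L * unclass(config)
  param_mat <- matrix(NA_real_, n_sims, length(.all_param_names),
                      dimnames = list(NULL, .all_param_names))
  stat_mat <- matrix(NA_real_, n_sims, length(.stat_names(groups)),
                     dimnames = list(NULL, .stat_names(groups)))
  grp_index <- rep(groups, unclass(config))
  with_seed(rng_seed, {
    for (i in seq_len(n_sims)) {
      params <- draw_scenario_params(priors, scen[i])
      sc <- .scenario_events(params)
      lin <- .sim_lineages(.lineage_vector(nl), sc, n_loci, min_maf)
      gt <- lin[seq(1, nrow(lin), by = 2), , drop = FALSE] +
        lin[seq(2, nrow(lin), by = 2), , drop = FALSE]
      counts <- lapply(groups, function(g) {
        rows <- grp_index == g
        gg <- gt[rows, , drop = FALSE]
        list(n = rep(sum(rows), n_loci), alt = colSums(gg),
             het = colSums(gg == 1L))
      })
      names(counts) <- groups
      param_mat[i, names(params$values)] <- params$values
      stat_mat[i, ] <- .stats_from_counts(counts, groups)
      if (progress > 0 && i %% progress == 0) {
        message("reference table: ", i, "/", n_sims)
      }
    }
  })
  stat_sd <- apply(stat_mat, 2, sd)
  dropped <- colnames(stat_mat)[!is.finite(stat_sd) | stat_sd == 0]
  structure(list(scenario = scen, params = param_mat, stats = stat_mat,
                 stat_sd = stat_sd, dropped = dropped, priors = priors,
                 config = config, n_loci = n_loci, min_maf = min_maf),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("ABC reference table:", nrow(x$stats), "simulations x",
      ncol(x$stats), "summary statistics;", x$n_loci, "loci per dataset\n")
  print(table(scenario = x$scenario))
  if (length(x$dropped)) {
    cat("dropped (zero-variance) statistics:",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a reference table as TSV plus a JSON sidecar
#'
#' @param table a `reference_table`
#' @param path base path; writes `<path>.tsv` and `<path>.json`
#' @return `path`, invisibly
#' @export
write_reference_table <- function(table, path) {
  df <- data.frame(scenario = table$scenario, table$params, table$stats,
                   check.names = FALSE)
  write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(stat_sd = as.list(table$stat_sd), dropped = table$dropped,
               n_loci = table$n_loci, config = as.list(unclass(table$config)),
               prior_bounds = table$priors$bounds)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  df <- read.table(paste0(path, ".tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pm <- as.matrix(df[, .all_param_names])
  sm <- as.matrix(df[, setdiff(colnames(df), c("scenario", .all_param_names))])
  structure(list(scenario = df$scenario, params = pm, stats = sm,
                 stat_sd = unlist(meta$stat_sd), dropped = meta$dropped %||% character(0),
                 priors = prior_spec(meta$prior_bounds),
                 config = do.call(sample_config, as.list(meta$config)),
                 n_loci = meta$n_loci),
            class = "reference_table")
}

# normalized distances of every table row from the observed statistics
.abc_distances <- function(table, observed) {
  keep <- setdiff(colnames(table$stats), table$dropped)
  z <- sweep(table$stats[, keep, drop = FALSE], 2, table$stat_sd[keep], "/")
  zo <- observed[keep] / table$stat_sd[keep]
  sqrt(rowSums(sweep(z, 2, zo)^2))
}

#' Scenario posterior probabilities: direct (rejection) method
#'
#' Euclidean distance on per-statistic-normalized summaries; the posterior
#' probability of each scenario is its share among the `n_closest` rows
#' (ties at the cutoff broken by row index). 95% confidence intervals use
#' the normal-approximation binomial interval, clipped to `[0, 1]`.
#'
#' @param table a `reference_table`
#' @param observed summary-statistic vector of the observed dataset
#' @param n_closest number of retained simulations
#' @return an `abc_model_choice` data.frame: scenario, pp, lo, hi
#' @export
posterior_prob_direct <- function(table, observed, n_closest = 500) {
  stopifnot(nrow(table$stats) >= n_closest)
  d <- .abc_distances(table, observed)
  sel <- order(d)[seq_len(n_closest)]          # order() breaks ties by index
  scen <- sort(unique(table$scenario))
  pp <- vapply(scen, function(s) mean(table$scenario[sel] == s), numeric(1))
  se <- sqrt(pp * (1 - pp) / n_closest)
  res <- data.frame(scenario = scen, pp = pp,
                    lo = pmax(0, pp - 1.96 * se),
                    hi = pmin(1, pp + 1.96 * se))
  structure(res, class = c("abc_model_choice", "data.frame"),
            method = "direct")
}

#' Scenario posterior probabilities: logistic-regression method
#'
#' Weighted multinomial logistic regression of the scenario label on the
#' normalized summary statistics over the closest fraction of the table
#' (Epanechnikov weights in distance), evaluated at the observed statistics.
#' Confidence intervals come from the fitted coefficient covariance by the
#' delta method. Complete separation is handled by clipping fitted
#' probabilities into `[1e-6, 1 - 1e-6]` and renormalizing (flagged). If the
#' retained subset contains a single scenario the direct method on the same
#' subset is returned with a warning.
#'
#' @param table a `reference_table`
#' @param observed summary-statistic vector
#' @param closest_fraction fraction of the table retained
#' @return an `abc_model_choice` data.frame: scenario, pp, lo, hi
#' @export
posterior_prob_logistic <- function(table, observed, closest_fraction = 0.01) {
  n_sel <- max(2L, ceiling(closest_fraction * nrow(table$stats)))
  d <- .abc_distances(table, observed)
  sel <- order(d)[seq_len(n_sel)]
  dsel <- d[sel]
  scen_all <- sort(unique(table$scenario))
  if (length(unique(table$scenario[sel])) < 2) {
    warning("retained subset contains a single scenario; ",
            "falling back to the direct method")
    res <- posterior_prob_direct(table, observed, n_closest = n_sel)
    attr(res, "method") <- "direct-fallback"
    return(res)
  }
  dmax <- max(dsel)
  w <- if (dmax > 0) 1 - (dsel / dmax)^2 else rep(1, n_sel)
  w[w <= 0] <- min(w[w > 0]) / 2        # keep boundary rows in the fit
  keep <- setdiff(colnames(table$stats), table$dropped)
  x <- sweep(table$stats[sel, keep, drop = FALSE], 2, table$stat_sd[keep], "/")
  x <- sweep(x, 2, observed[keep] / table$stat_sd[keep])
  lab <- droplevels(factor(table$scenario[sel], levels = scen_all))
  dat <- data.frame(.scen = lab, x, check.names = FALSE)
  fit <- nnet::multinom(.scen ~ ., data = dat, weights = w, trace = FALSE,
                        maxit = 500, MaxNWts = 5000)
  present <- levels(droplevels(lab))
  # probabilities at the observed point (all centered covariates zero)
  co <- coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1)
  eta <- c(0, co[, 1])                  # intercepts; reference class first
  pr <- exp(eta - max(eta))
  pr <- pr / sum(pr)
  # delta-method variance from the intercept block of vcov
  np <- ncol(co)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- rep(NA_real_, length(pr))
  if (!is.null(vc)) {
    int_idx <- seq(1, by = np, length.out = nrow(co))
    vint <- vc[int_idx, int_idx, drop = FALSE]
    for (k in seq_along(pr)) {
      grad <- vapply(seq_len(nrow(co)), function(j) {
        pj <- pr[j + 1]
        pr[k] * ((k == j + 1) - pj)
      }, numeric(1))
      se[k] <- sqrt(drop(t(grad) %*% vint %*% grad))
    }
  }
  flagged <- any(pr < 1e-6 | pr > 1 - 1e-6)
  pr <- pmin(pmax(pr, 1e-6), 1 - 1e-6)
  pr <- pr / sum(pr)
  pp <- setNames(numeric(length(scen_all)), scen_all)
  sev <- setNames(rep(0, length(scen_all)), scen_all)
  pp[present] <- pr
  sev[present] <- ifelse(is.na(se), 0, se)
  res <- data.frame(scenario = scen_all, pp = unname(pp),
                    lo = pmax(0, unname(pp) - 1.96 * unname(sev)),
                    hi = pmin(1, unname(pp) + 1.96 * unname(sev)))
  structure(res, class = c("abc_model_choice", "data.frame"),
            method = "logistic", separation = flagged)
}

#' Posterior distributions of the demographic parameters
#'
#' Local-linear regression adjustment in the style of Beaumont et al.: the
#' closest `closest_fraction` of the whole table (taken among the rows of
#' the chosen scenario) is retained with Epanechnikov weights in normalized
#' distance; each parameter is logit-transformed to its prior bounds,
#' regressed on the normalized statistics, adjusted to the observed point,
#' back-transformed, and summarized by weighted median, mean and 5%/95%
#' quantiles. A singular regression design falls back to unadjusted
#' weighted rejection quantiles (flagged via `adjusted = FALSE`).
#'
#' @param table a `reference_table`
#' @param observed summary-statistic vector
#' @param scenario_id scenario whose parameters are estimated
#' @param closest_fraction fraction of the table defining the neighborhood
#' @return a `param_posterior`: `summary` data.frame (parameter, median,
#'   mean, q5, q95), adjusted `draws`, `weights`, `adjusted` flag
#' @export
estimate_parameters <- function(table, observed, scenario_id,
                                closest_fraction = 0.01) {
  rows <- which(table$scenario == scenario_id)
  if (!length(rows)) stop("no rows for scenario ", scenario_id)
  n_sel <- min(length(rows), max(2L, ceiling(closest_fraction * nrow(table$stats))))
  d <- .abc_distances(table, observed)[rows]
  sel <- rows[order(d)[seq_len(n_sel)]]
  dsel <- sort(d)[seq_len(n_sel)]
  dmax <- max(dsel)
  w <- if (dmax > 0) 1 - (dsel / dmax)^2 else rep(1, n_sel)
  w[w <= 0] <- min(w[w > 0]) / 2
  keep <- setdiff(colnames(table$stats), table$dropped)
  x <- sweep(table$stats[sel, keep, drop = FALSE], 2, table$stat_sd[keep], "/")
  x <- sweep(x, 2, observed[keep] / table$stat_sd[keep])

  pnames <- scenario_param_names(scenario_id)
  bounds <- table$priors$bounds
  theta <- table$params[sel, pnames, drop = FALSE]
  z <- theta
  degenerate <- logical(length(pnames))
  names(degenerate) <- pnames
  for (p in pnames) {
    b <- bounds[[p]]
    if (b[1] == b[2]) {
      degenerate[p] <- TRUE
      z[, p] <- 0
    } else {
      f <- pmin(pmax((theta[, p] - b[1]) / (b[2] - b[1]), 1e-8), 1 - 1e-8)
      z[, p] <- qlogis(f)
    }
  }

  adjusted <- TRUE
  zadj <- z
  design <- cbind(1, x)
  fit <- tryCatch({
    wd <- design * sqrt(w)
    qrd <- qr(wd)
    if (qrd$rank < ncol(design)) stop("singular design")
    beta <- qr.coef(qrd, z * sqrt(w))
    beta[is.na(beta)] <- 0
    z - x %*% beta[-1, , drop = FALSE]
  }, error = function(e) NULL)
  if (is.null(fit)) {
    adjusted <- FALSE
  } else {
    zadj <- fit
  }

  draws <- zadj
  for (p in pnames) {
    b <- bounds[[p]]
    draws[, p] <- if (degenerate[p]) b[1] else b[1] + plogis(zadj[, p]) * (b[2] - b[1])
  }
  summ <- do.call(rbind, lapply(pnames, function(p) {
    q <- wquantile(draws[, p], w, c(0.05, 0.5, 0.95))
    data.frame(parameter = p, median = q[2],
               mean = weighted.mean(draws[, p], w), q5 = q[1], q95 = q[3])
  }))
  rownames(summ) <- summ$parameter
  structure(list(summary = summ, draws = draws, weights = w,
                 scenario_id = as.integer(scenario_id), adjusted = adjusted),
            class = "param_posterior")
}

#' @export
print.param_posterior <- function(x, ...) {
  cat("parameter posterior (scenario", x$scenario_id,
      if (x$adjusted) "| local-linear adjusted" else "| rejection only", ")\n")
  print(transform(x$summary, median = signif(median, 4),
                  mean = signif(mean, 4), q5 = signif(q5, 4),
                  q95 = signif(q95, 4)), row.names = FALSE)
  invisible(x)
}

#' Resample joint parameter draws from a posterior
#'
#' Rows of the adjusted posterior sample are resampled with their weights;
#' draws violating the scenario's ordering or founder constraints (possible
#' after regression adjustment) are rejected.
#'
#' @param post a `param_posterior`
#' @param n number of draws
#' @param rng_seed integer seed or `NULL`
#' @return list of [scenario_params()] objects
#' @export
posterior_param_draws <- function(post, n, rng_seed = NULL) {
  with_seed(rng_seed, {
    out <- vector("list", n)
    got <- 0L
    tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > 200L * n) stop("could not draw valid posterior parameters")
      i <- sample.int(nrow(post$draws), 1, prob = post$weights)
      p <- tryCatch(scenario_params(post$scenario_id, post$draws[i, ]),
                    error = function(e) NULL)
      if (!is.null(p)) {
        got <- got + 1L
        out[[got]] <- p
      }
    }
    out
  })
}

#' Simulate summary statistics at fixed parameter values
#'
#' @param params_list list of [scenario_params()]
#' @param config a [sample_config()]
#' @param n_loci loci per dataset
#' @param rng_seed integer seed or `NULL`
#' @param min_maf optional ascertainment threshold as in
#'   [build_reference_table()]
#' @return matrix of summary-statistic vectors, one row per parameter set
#' @export
simulate_stats <- function(params_list, config = sample_config(), n_loci,
                           rng_seed = NULL, min_maf = NULL) {
  with_seed(rng_seed, {
    t(vapply(params_list, function(p) {
      summary_stats(simulate_dataset(p, config, n_loci, min_maf = min_maf))
    }, numeric(length(.stat_names(names(config))))))
  })
}

#' PCA model checking of an ABC fit
#'
#' Projects the observed summary statistics into the principal-component
#' space of statistics simulated from the prior (reference-table rows of the
#' chosen scenario) and from the posterior, and flags whether the observed
#' point lies inside the simulated cloud: its Mahalanobis distance in the
#' first two components must not exceed the 99th percentile of the simulated
#' points' distances.
#'
#' @param table a `reference_table`
#' @param post a `param_posterior` for the chosen scenario
#' @param observed summary-statistic vector
#' @param config a [sample_config()]
#' @param n_prior,n_posterior number of prior/posterior statistic vectors
#' @param rng_seed integer seed or `NULL`
#' @return list: `inside` flag, `obs_score`, `scores`, `source`
#'   (prior/posterior), `distance`, `threshold`
#' @export
abc_model_check <- function(table, post, observed, config = table$config,
                            n_prior = 100, n_posterior = 100,
                            rng_seed = NULL) {
  rows <- which(table$scenario == post$scenario_id)
  stopifnot(length(rows) >= n_prior)
  with_seed(rng_seed, {
    prior_stats <- table$stats[sample(rows, n_prior), , drop = FALSE]
    draws <- posterior_param_draws(post, n_posterior)
    post_stats <- simulate_stats(draws, config, table$n_loci,
                                 min_maf = table$min_maf)
    model_check_pca(prior_stats, post_stats, observed)
  })
}

#' @rdname abc_model_check
#' @param prior_stats,posterior_stats matrices of simulated summary
#'   statistics (rows = simulations)
#' @export
model_check_pca <- function(prior_stats, posterior_stats, observed) {
  sims <- rbind(prior_stats, posterior_stats)
  src <- rep(c("prior", "posterior"), c(nrow(prior_stats),
                                        nrow(posterior_stats)))
  sds <- apply(sims, 2, sd)
  keep <- is.finite(sds) & sds > 0
  pc <- prcomp(sims[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1:2, drop = FALSE]
  obs <- (observed[keep] - pc$center) / pc$scale
  obs_score <- drop(obs %*% pc$rotation[, 1:2])
  sdev2 <- pc$sdev[1:2]^2
  d_sims <- sqrt(rowSums(sweep(scores^2, 2, sdev2, "/")))
  d_obs <- sqrt(sum(obs_score^2 / sdev2))
  thr <- quantile(d_sims, 0.99)
  list(inside = d_obs <= thr, obs_score = obs_score, scores = scores,
       source = src, distance = d_obs, threshold = unname(thr))
}
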