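# direct, independent evaluation of the summary statistics from per-group
# allele frequencies, used as the oracle for summary_stats()
direct_stats <- function(gm, groups) {
  freq <- function(g, l) {
    x <- gm$gt[gm$group == g, l]
    mean(x, na.rm = TRUE) / 2
  }
  hline <- function(g) {
    vapply(seq_len(ncol(gm$gt)), function(l) {
      p <- freq(g, l)
      2 * p * (1 - p)
    }, numeric(1))
  }
  out <- c()
  for (g in groups) {
    gd <- hline(g)
    nz <- gd[gd > 0]
    out <- c(out, mean(gd == 0), if (length(nz)) mean(nz) else 0,
             if (length(nz) >= 2) var(nz) else 0, mean(gd))
  }
  for (k in seq_len(ncol(combn(groups, 2)))) {
    pr <- combn(groups, 2)[, k]
    th <- vapply(seq_len(ncol(gm$gt)), function(l) {
      ga <- gm$gt[gm$group == pr[1], l]
      gb <- gm$gt[gm$group == pr[2], l]
      n <- c(length(ga), length(gb))
      p <- c(mean(ga) / 2, mean(gb) / 2)
      h <- c(mean(ga == 1), mean(gb == 1))
      nbar <- mean(n)
      nc <- 2 * nbar - sum(n^2) / (2 * nbar)
      pbar <- sum(n * p) / (2 * nbar)
      s2 <- sum(n * (p - pbar)^2) / nbar
      hbar <- sum(n * h) / (2 * nbar)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      c(a / (a + b + cc), pbar)
    }, numeric(2))
    nz <- th[1, th[2, ] > 0 & th[2, ] < 1]
    nz <- nz[is.finite(nz)]
    pa <- vapply(seq_len(ncol(gm$gt)), function(l) freq(pr[1], l), numeric(1))
    pb <- vapply(seq_len(ncol(gm$gt)), function(l) freq(pr[2], l), numeric(1))
    jx <- pa^2 + (1 - pa)^2
    jy <- pb^2 + (1 - pb)^2
    jxy <- pa * pb + (1 - pa) * (1 - pb)
    d <- -log(jxy / sqrt(jx * jy))
    d[jxy == 0] <- Inf
    out <- c(out, if (length(nz)) mean(nz) else 0,
             if (length(nz) >= 2) var(nz) else 0,
             mean(d < 1e-12), mean(d[is.finite(d)]))
  }
  out
}

test_that("summary statistics match a direct per-formula evaluation", {
  gm <- gm_from_groups(
    A = list(c(0L, 1L, 2L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L, 1L, 0L),
             c(0L, 2L, 0L, 0L, 2L, 0L)),
    B = list(c(2L, 0L, 0L, 1L, 1L, 0L), c(2L, 1L, 0L, 1L, 0L, 0L),
             c(1L, 0L, 0L, 0L, 0L, 0L)),
    C = list(c(0L, 0L, 2L, 2L, 1L, 0L), c(0L, 0L, 2L, 2L, 2L, 0L),
             c(0L, 1L, 2L, 2L, 2L, 0L)),
    D = list(c(0L, 0L, 0L, 0L, 0L, 2L), c(0L, 0L, 0L, 0L, 1L, 2L),
             c(0L, 0L, 0L, 0L, 0L, 2L)))
  s <- summary_stats(gm, groups = c("A", "B", "C", "D"))
  expect_length(s, 40)
  expect_equal(unname(s), direct_stats(gm, c("A", "B", "C", "D")),
               tolerance = 1e-12)
})

test_that("degenerate group compositions produce the documented encodings", {
  gm <- gm_from_groups(A = list(rep(0L, 4), rep(0L, 4)),
                       B = list(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L)))
  s <- summary_stats(gm, groups = c("A", "B"))
  expect_equal(unname(s["A_gd_p0"]), 1)    # monomorphic everywhere
  expect_equal(unname(s["A_gd_mnz"]), 0)   # masked as 0 when no nonzero loci
  g <- simulate_panmictic(10, 100, 20000, rng_seed = 91)
  gm2 <- genotype_matrix(rbind(g$gt, g$gt), rep(c("X", "Y"), each = 10))
  s2 <- summary_stats(gm2, groups = c("X", "Y"))
  expect_equal(unname(s2["X.Y_nei_p0"]), 1)
  expect_lt(abs(unname(s2["X.Y_fst_mnz"])), 0.2)  # near zero for clones
})

test_that("the reference table stratifies scenarios and is reproducible", {
  pr <- prior_spec()
  tab <- build_reference_table(pr, 1:3, sample_config(3, 3, 3, 3),
                               n_sims = 9, n_loci = 10, rng_seed = 92)
  expect_identical(as.integer(table(tab$scenario)), rep(3L, 3))
  tab2 <- build_reference_table(pr, 1:3, sample_config(3, 3, 3, 3),
                                n_sims = 9, n_loci = 10, rng_seed = 92)
  expect_identical(tab$stats, tab2$stats)
  expect_identical(tab$params, tab2$params)
})

test_that("reference-table serialization round-trips", {
  tab <- build_reference_table(prior_spec(), 1:3, sample_config(3, 3, 3, 3),
                               n_sims = 12, n_loci = 10, rng_seed = 93)
  base <- file.path(withr::local_tempdir(), "reftab")
  write_reference_table(tab, base)
  back <- read_reference_table(base)
  expect_equal(back$stats, tab$stats, tolerance = 1e-8)
  expect_equal(back$params, tab$params, tolerance = 1e-8)
  expect_identical(back$scenario, tab$scenario)
})

test_that("table parameter marginals recover the constrained prior", {
  # under iid uniform times with ordering enforced by rejection, TA is the
  # maximum of k iid uniforms: CDF ((x - a)/(b - a))^k, k = 4 for scenario 1
  # and 5 for scenarios 2 and 3
  tab <- build_reference_table(prior_spec(), 1:3, sample_config(2, 2, 2, 2),
                               n_sims = 1500, n_loci = 4, rng_seed = 94)
  for (sid in 1:3) {
    k <- if (sid == 1) 4 else 5
    ta <- tab$params[tab$scenario == sid, "TA"]
    cdf <- function(x) pmin(pmax((x - 10) / (1e5 - 10), 0), 1)^k
    ks <- suppressWarnings(stats::ks.test(ta, cdf))
    expect_gt(ks$p.value, 0.01)
  }
})

# a hand-built reference table with well-separated scenario clouds
toy_table <- function(n_per = 200, sep = 8, sd_stats = 1, seed = 95) {
  set.seed(seed)
  scen <- rep(1:3, each = n_per)
  centers <- rbind(rep(0, 6), rep(sep, 6), rep(-sep, 6))
  stats <- centers[scen, ] + matrix(rnorm(3 * n_per * 6, 0, sd_stats),
                                    ncol = 6)
  colnames(stats) <- paste0("s", 1:6)
  pr <- prior_spec()
  pn <- names(pr$bounds)
  params <- vapply(pn, function(p) {
    b <- pr$bounds[[p]]
    runif(3 * n_per, b[1] + 0.01 * diff(b), b[2] - 0.01 * diff(b))
  }, numeric(3 * n_per))
  structure(list(scenario = scen, params = params, stats = stats,
                 stat_sd = apply(stats, 2, sd), dropped = character(0),
                 priors = prior_spec(), config = sample_config(2, 2, 2, 2),
                 n_loci = 10),
            class = "reference_table")
}

test_that("degenerate symmetric tables give uniform posterior probabilities", {
  tab <- toy_table(sep = 0)
  obs <- rep(0, 6)
  names(obs) <- paste0("s", 1:6)
  d <- posterior_prob_direct(tab, obs, n_closest = 300)
  expect_equal(sum(d$pp), 1, tolerance = 1e-6)
  expect_true(all(abs(d$pp - 1 / 3) < 0.12))
  l <- posterior_prob_logistic(tab, obs, closest_fraction = 0.5)
  expect_equal(sum(l$pp), 1, tolerance = 1e-6)
  expect_true(all(abs(l$pp - 1 / 3) < 0.12))
})

test_that("well-separated scenarios are identified with near-certainty", {
  tab <- toy_table(sep = 8)
  obs <- setNames(rep(-8, 6), paste0("s", 1:6))     # deep inside scenario 3
  d <- posterior_prob_direct(tab, obs, n_closest = 100)
  expect_equal(d$pp[d$scenario == 3], 1, tolerance = 1e-6)
  l <- posterior_prob_logistic(tab, obs, closest_fraction = 0.4)
  expect_gte(l$pp[l$scenario == 3], 0.99)
  expect_equal(sum(l$pp), 1, tolerance = 1e-6)
})

test_that("direct posterior probabilities absorb uniform statistic rescaling", {
  tab <- toy_table(sep = 2)
  obs <- setNames(rep(1, 6), paste0("s", 1:6))
  d1 <- posterior_prob_direct(tab, obs, n_closest = 150)
  tab2 <- tab
  tab2$stats <- tab$stats * 37
  tab2$stat_sd <- apply(tab2$stats, 2, sd)
  d2 <- posterior_prob_direct(tab2, obs * 37, n_closest = 150)
  expect_equal(d1$pp, d2$pp, tolerance = 1e-12)
})

test_that("an observed table row pulls its own parameters back (locality)", {
  tab <- toy_table(n_per = 200, sep = 6)
  target <- tab$params[1, ]
  # place eight exact copies of row 1 in the table
  for (i in 2:8) {
    tab$stats[i, ] <- tab$stats[1, ]
    tab$params[i, ] <- target
  }
  obs <- setNames(tab$stats[1, ], paste0("s", 1:6))
  post <- estimate_parameters(tab, obs, 1, closest_fraction = 10 / 600)
  est <- post$summary[scenario_param_names(1), "median"]
  truth <- target[scenario_param_names(1)]
  expect_true(all(abs(est - truth) / truth < 0.05))
})

test_that("degenerate priors collapse the posterior to the constant", {
  pr <- prior_spec(bounds = list(N_KKP = c(650, 650)))
  tab <- build_reference_table(pr, 1, sample_config(3, 3, 3, 3),
                               n_sims = 250, n_loci = 25, rng_seed = 96)
  obs <- summary_stats(simulate_dataset(scenario1_truth(),
                                        sample_config(3, 3, 3, 3), 25,
                                        rng_seed = 97),
                       groups = names(sample_config()))
  post <- estimate_parameters(tab, obs, 1, closest_fraction = 0.2)
  row <- post$summary["N_KKP", ]
  expect_identical(unname(unlist(row[c("median", "mean", "q5", "q95")])),
                   rep(650, 4))
})

test_that("posterior probabilities always sum to one on real tables", {
  tab <- build_reference_table(prior_spec(), 1:3, sample_config(3, 3, 3, 3),
                               n_sims = 300, n_loci = 30, rng_seed = 98)
  for (seed in 1:3) {
    obs <- summary_stats(simulate_dataset(scenario1_truth(),
                                          sample_config(3, 3, 3, 3), 30,
                                          rng_seed = 100 + seed),
                         groups = names(sample_config()))
    d <- posterior_prob_direct(tab, obs, n_closest = 50)
    l <- posterior_prob_logistic(tab, obs, closest_fraction = 0.2)
    expect_equal(sum(d$pp), 1, tolerance = 1e-6)
    expect_equal(sum(l$pp), 1, tolerance = 1e-6)
    expect_true(all(d$lo >= 0 & d$hi <= 1))
    expect_true(all(l$lo >= 0 & l$hi <= 1))
  }
})

test_that("model-check PCA flags self-generated data in and outliers out", {
  set.seed(99)
  prior_stats <- matrix(rnorm(200 * 12), 200, 12)
  post_stats <- matrix(rnorm(200 * 12), 200, 12)
  colnames(prior_stats) <- colnames(post_stats) <- paste0("s", 1:12)
  inside <- vapply(1:100, function(i) {
    obs <- setNames(rnorm(12), paste0("s", 1:12))
    model_check_pca(prior_stats, post_stats, obs)$inside
  }, logical(1))
  expect_gte(mean(inside), 0.95)
  far <- setNames(c(10, rnorm(11)), paste0("s", 1:12))
  expect_false(model_check_pca(prior_stats, post_stats, far)$inside)
})
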