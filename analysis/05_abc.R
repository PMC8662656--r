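#!/usr/bin/env Rscript
# Demographic inference by ABC at desk scale: a reference table over the
# three competing scenarios, scenario choice by the direct (rejection) and
# logistic-regression methods, posterior parameter distributions for the
# winning scenario, and a PCA model check of the fit.

library(bathypop)

popmap <- read_popmap("results/popmap.tsv")
gm <- as_genotype_matrix(read_vcf("results/filtered.vcf"), popmap)
config <- sample_config()
observed <- summary_stats(gm, groups = names(config))

# the observed SNPs passed a minor-allele-frequency >= 0.02 filter, so the
# reference simulations carry the same ascertainment
message("building the reference table (6,000 simulations x 300 loci)...")
table <- build_reference_table(prior_spec(), scenarios = 1:3,
                               config = config, n_sims = 6000,
                               n_loci = 300, min_maf = 0.02,
                               rng_seed = derive_seed(1, "abc_table"))
write_reference_table(table, "results/reference_table")

direct <- posterior_prob_direct(table, observed, n_closest = 500)
logist <- posterior_prob_logistic(table, observed, closest_fraction = 0.05)
cat("direct method:\n"); print(direct)
cat("logistic-regression method:\n"); print(logist)
write.table(rbind(cbind(method = "direct", as.data.frame(direct)),
                  cbind(method = "logistic", as.data.frame(logist))),
            "results/abc_model_choice.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

best <- direct$scenario[which.max(direct$pp)]
cat("best-supported scenario:", best, "\n")
post <- estimate_parameters(table, observed, scenario_id = best,
                            closest_fraction = 0.05)
print(post)
write.table(post$summary, "results/abc_params.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

check <- abc_model_check(table, post, observed, config = config,
                         n_prior = 150, n_posterior = 100,
                         rng_seed = derive_seed(1, "abc_check"))
cat(sprintf("model check: observed %s the simulated cloud (PC1-2 distance %.2f, 99%% threshold %.2f)\n",
            if (check$inside) "inside" else "OUTSIDE", check$distance,
            check$threshold))
write.table(data.frame(source = c(check$source, "observed"),
                       rbind(check$scores, check$obs_score)),
            "results/abc_model_check.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
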