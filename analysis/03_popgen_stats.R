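#!/usr/bin/env Rscript
# Population-genetic statistics of the filtered dataset: per-group summary
# (diversity, inbreeding, private SNPs), pairwise WC84 F_ST with permutation
# significance, and a genotype PCA on the LD-pruned SNP set.

library(bathypop)

popmap <- read_popmap("results/popmap.tsv")
gm <- as_genotype_matrix(read_vcf("results/filtered.vcf"), popmap)

gs <- group_summary(gm)
print(gs, digits = 3)
write.table(gs, "results/group_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fm <- fst_matrix(gm, n_perm = 1000, rng_seed = derive_seed(1, "fst"))
cat("pairwise WC84 F_ST:\n")
print(round(fm$fst, 4))
write.table(fm$fst, "results/fst_matrix.tsv", sep = "\t", quote = FALSE)
write.table(fm$p_value, "results/fst_pvalues.tsv", sep = "\t", quote = FALSE)

gm_pruned <- as_genotype_matrix(read_vcf("results/filtered_pruned.vcf"),
                                popmap)
pca <- genotype_pca(gm_pruned, n_components = 4)
cat("variance explained by PC1-4:",
    round(100 * pca$varprop, 1), "%\n")
write.table(data.frame(sample_id = rownames(pca$coords),
                       group = gm_pruned$group, pca$coords),
            "results/pca_coords.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
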