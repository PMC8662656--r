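#!/usr/bin/env Rscript
# Directional relative migration between the genetic groups from the
# migrant-pool G_ST method; coefficients below 0.3 are conventionally
# displayed as limited gene flow.

library(bathypop)

popmap <- read_popmap("results/popmap.tsv")
gm <- as_genotype_matrix(read_vcf("results/filtered.vcf"), popmap)

mig <- relative_migration(gm)
print(mig, threshold = 0.3)
write.table(unclass(mig), "results/migration.tsv", sep = "\t", quote = FALSE)
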