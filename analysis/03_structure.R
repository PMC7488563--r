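#!/usr/bin/env Rscript
# Population-structure diagnostics on the filtered, LD-pruned SNP set:
# genotype PCA and one-level AMOVA with 1000 label permutations.

suppressPackageStartupMessages(library(sweepscan))

dat <- "results/data"
res <- read_vcf(file.path(dat, "cohort.vcf"),
                file.path(dat, "cohort.popmap.tsv"))
gm <- res$genotypes
kept <- utils::read.table(file.path(dat, "pruned_sites.tsv"),
                          header = TRUE, sep = "\t")
idx <- match(paste(kept$chrom, kept$pos),
             paste(gm$sites$chrom, gm$sites$pos))

pc <- pca_genotypes(gm, sites = idx)
coords <- data.frame(sample = rownames(pc$coordinates),
                     population = unname(gm$popmap),
                     pc$coordinates[, 1:4])
utils::write.table(coords, "results/pca_coordinates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("PC1 + PC2 explain %.1f%% of the genotypic variance\n",
            100 * sum(pc$variance_explained[1:2])))

gm_pruned <- subset_sites(gm, idx)
am <- amova(gm_pruned, n_perm = 1000, seed = 7)
print(am)
utils::write.table(
  data.frame(sigma2_among = am$sigma_among,
             sigma2_within = am$sigma_within, phi_st = am$phi_st,
             p_value = am$p_value, n_perm = am$n_perm),
  "results/amova.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
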