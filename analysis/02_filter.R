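#!/usr/bin/env Rscript
# Variant hard filtering on the synthetic cohort: quantile outlier cuts
# on the caller annotations (FS top 5%; rank sums and DP 2.5% per tail;
# MQ < 30), clustered-SNP removal (> 5 SNPs per 20 bp), and an
# LD-pruned SNP subset (r2 <= 0.1 in 50-SNP windows) for the structure
# analyses.

suppressPackageStartupMessages(library(sweepscan))

dat <- "results/data"
res <- read_vcf(file.path(dat, "cohort.vcf"),
                file.path(dat, "cohort.popmap.tsv"))
gm <- res$genotypes
cat("loaded", ncol(gm$calls), "SNPs;",
    res$log[["indel_removed"]], "indels and",
    res$log[["multiallelic_removed"]], "multi-allelic records dropped\n")

ann <- utils::read.table(file.path(dat, "annotations.tsv"), header = TRUE,
                         sep = "\t")
stopifnot(all(ann$pos == gm$sites$pos))
gm$sites <- cbind(gm$sites, ann[, !(names(ann) %in% c("chrom", "pos"))])

hard <- apply_hard_filters(gm)
utils::write.table(hard$report, "results/filter_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("hard filters removed",
    ncol(gm$calls) - ncol(hard$genotypes$calls), "SNPs; realized",
    "thresholds in results/filter_report.tsv\n")

gm2 <- filter_clustered_snps(hard$genotypes)
cat("clustered-SNP rule removed",
    ncol(hard$genotypes$calls) - ncol(gm2$calls), "SNPs\n")

pruned <- ld_prune(gm2)
cat("LD pruning kept", length(pruned), "of", ncol(gm2$calls),
    "SNPs for the structure analyses\n")

write_vcf(gm2, file.path(dat, "cohort.filtered.vcf"))
# site keys so the scan stages can subset the *phased* cohort panel
utils::write.table(gm2$sites[, c("chrom", "pos")],
                   file.path(dat, "kept_sites.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(gm2$sites[pruned, c("chrom", "pos")],
                   file.path(dat, "pruned_sites.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
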