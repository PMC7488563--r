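#!/usr/bin/env Rscript
# Runs of homozygosity: PLINK-style detection (50-SNP windows, <= 3 het,
# <= 3 missing, >= 500 kb), per-sample F_ROH with Tukey group
# comparison, and population ROH hotspots (> 50% sample sharing).

suppressPackageStartupMessages(library(sweepscan))

dat <- "results/data"
res <- read_vcf(file.path(dat, "cohort.vcf"),
                file.path(dat, "cohort.popmap.tsv"))
gm <- res$genotypes
lens <- with(utils::read.table(file.path(dat, "chrom_lengths.tsv"),
                               header = TRUE, sep = "\t"),
             stats::setNames(length_bp, chrom))

run <- run_roh(list(genotypes = gm,
                    config = list(chrom_lengths = lens)))
utils::write.table(run$segments, "results/roh_segments.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(run$froh, "results/froh.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(run$summary, "results/froh_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
if (nrow(run$hotspots))
  write_bed(data.frame(chrom = run$hotspots$chrom,
                       start = run$hotspots$start,
                       end = run$hotspots$end,
                       name = run$hotspots$population),
            "results/roh_hotspots.bed")
utils::write.table(run$hotspots, "results/roh_hotspots.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("ROH segments:", nrow(run$segments), "\n")
print(run$summary)
cg <- compare_groups(run$froh, gm$popmap)
cat("Tukey letters:",
    paste(names(cg$letters), cg$letters, sep = "=", collapse = "  "),
    "\n")
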