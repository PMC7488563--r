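#!/usr/bin/env Rscript
# Build the synthetic study cohort: four populations of 12 diploids on a
# 5 x 10-Mb genome, Balding-Nichols divergence F = 0.05, with known
# injected signals -- two hard sweeps (one private to pop1, one to pop3)
# and elevated autozygosity in pop3 (the "dairy-like" population).
# Everything downstream reads the files this script writes.

suppressPackageStartupMessages(library(sweepscan))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
set.seed(NULL)

cfg <- sim_config(
  n_pops = 4, n_per_pop = 12,
  chrom_lengths = stats::setNames(rep(1e7, 5), paste0("chr", 1:5)),
  fst_target = 0.05,
  sweep_specs = data.frame(
    pop = c("pop1", "pop3"), chrom = c("chr2", "chr4"),
    position = c(5.025e6, 3.025e6), final_freq = 0.95,
    core_halflength = 2e5),
  roh_specs = data.frame(pop = "pop3", target_fraction = 0.14,
                         tract_mean_bp = 2e6),
  seed = 20260921)
sim <- simulate_neutral(cfg)

# one deliberately shared autozygous tract (chr4:2.7-4.0 Mb) in 8 of 12
# pop3 samples: a ground-truth ROH hotspot that also overlaps the chr4
# sweep, so the hotspot x sweep intersection stage has known signal
shared <- c(chrom = "chr4", start = 2.7e6, end = 4.0e6)
pop3 <- unique(sim$panel$sample[
  sim$panel$popmap[sim$panel$sample] == "pop3"])[1:8]
idx <- which(sim$panel$sites$chrom == shared["chrom"] &
               sim$panel$sites$pos > as.numeric(shared["start"]) &
               sim$panel$sites$pos <= as.numeric(shared["end"]))
for (smp in pop3) {
  rows <- which(sim$panel$sample == smp)
  sim$panel$hap[rows[2], idx] <- sim$panel$hap[rows[1], idx]
  sim$truth$tracts <- rbind(sim$truth$tracts,
                            data.frame(sample = smp,
                                       chrom = unname(shared["chrom"]),
                                       start = as.numeric(shared["start"]),
                                       end = as.numeric(shared["end"])))
}
sim$genotypes <- genotypes_from_panel(sim$panel)

write_vcf(sim$panel, file.path(out, "cohort.vcf"))
writeLines(paste(names(sim$genotypes$popmap), sim$genotypes$popmap,
                 sep = "\t"), file.path(out, "cohort.popmap.tsv"))
utils::write.table(
  data.frame(chrom = names(cfg$chrom_lengths),
             length_bp = as.integer(cfg$chrom_lengths)),
  file.path(out, "chrom_lengths.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

truth_sweeps <- data.frame(
  chrom = sim$truth$sweeps$chrom,
  start = (sim$truth$sweeps$pos - 1) %/% 50000 * 50000,
  end = ((sim$truth$sweeps$pos - 1) %/% 50000 + 1) * 50000,
  name = paste0("sweep_", sim$truth$sweeps$pop))
write_bed(truth_sweeps, file.path(out, "truth_sweeps.bed"))
write_bed(data.frame(chrom = sim$truth$tracts$chrom,
                     start = sim$truth$tracts$start,
                     end = sim$truth$tracts$end,
                     name = sim$truth$tracts$sample),
          file.path(out, "truth_tracts.bed"))

ann <- simulate_annotation_table(ncol(sim$genotypes$calls),
                                 seed = 20260922)
utils::write.table(cbind(sim$genotypes$sites[, c("chrom", "pos")], ann),
                   file.path(out, "annotations.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("cohort:", nrow(sim$genotypes$calls), "samples,",
    ncol(sim$genotypes$calls), "SNPs on",
    length(cfg$chrom_lengths), "chromosomes\n")
cat("injected:", nrow(sim$truth$sweeps), "sweeps,",
    nrow(sim$truth$tracts), "autozygous tracts\n")
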