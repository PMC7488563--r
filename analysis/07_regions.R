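#!/usr/bin/env Rscript
# Shared signals and annotation: intersect the called sweep regions
# (within and cross runs) with the ROH hotspots, and annotate all sweep
# regions against a feature table (here: the injected truth intervals,
# standing in for a gene/QTL track) with nearest-feature distances.

suppressPackageStartupMessages(library(sweepscan))

within <- read_features("results/within_regions.bed", "bed",
                        source = "within")
cross <- read_features("results/cross_regions.bed", "bed",
                       source = "cross")
hotspots <- utils::read.table("results/roh_hotspots.tsv", header = TRUE,
                              sep = "\t")

shared <- rbind(
  intersect_sweeps_hotspots(within, hotspots),
  intersect_sweeps_hotspots(cross, hotspots))
utils::write.table(shared, "results/sweeps_x_hotspots.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("sweep x hotspot shared intervals:", nrow(shared), "\n")

features <- read_features("results/data/truth_sweeps.bed", "bed",
                          source = "truth")
sweeps <- rbind(within, cross)
ov <- overlap_features(sweeps, features)
nr <- nearest_features(sweeps, features, max_distance_bp = 2.5e5)
report <- data.frame(
  chrom = sweeps$chrom, start = sweeps$start, end = sweeps$end,
  source = sweeps$source,
  overlapping = vapply(seq_len(nrow(sweeps)), function(i)
    paste(ov$s_name[ov$query == i], collapse = ","), ""),
  nearest = vapply(seq_len(nrow(sweeps)), function(i) {
    j <- nr$query == i & nr$distance_bp > 0
    if (any(j)) sprintf("%s (%d bp)", nr$s_name[j][1],
                        as.integer(nr$distance_bp[j][1])) else ""
  }, ""))
utils::write.table(report, "results/region_annotation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("annotated", nrow(report), "regions;",
    sum(report$overlapping != ""), "overlap a truth interval\n")
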