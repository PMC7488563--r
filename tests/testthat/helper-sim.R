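# Small fixture builders shared across test files.

# haplotype panel straight from a 0/1 matrix on one chromosome
make_panel <- function(hap, pos = NULL, pop = "p1") {
  hap <- as.matrix(hap)
  n_hap <- nrow(hap)
  stopifnot(n_hap %% 2 == 0)
  if (is.null(pos)) pos <- seq_len(ncol(hap)) * 1000L
  samples <- paste0("s", seq_len(n_hap / 2))
  rownames(hap) <- as.vector(rbind(paste0(samples, "_1"),
                                   paste0(samples, "_2")))
  pops <- rep_len(pop, length(samples))
  sites <- data.frame(chrom = "chr1", pos = as.integer(pos), ref = "A",
                      alt = "G", ancestral = "A",
                      stringsAsFactors = FALSE)
  haplotype_panel(hap, sites, setNames(pops, samples))
}

# genotype matrix from a calls matrix (samples x sites)
make_gm <- function(calls, pos = NULL, pop = NULL, chrom = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", ncol(calls))
  if (is.null(pop)) pop <- rep("p1", nrow(calls))
  sites <- data.frame(chrom = chrom, pos = as.integer(pos), ref = "A",
                      alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, setNames(pop, rownames(calls)))
}

# random feature table for interval tests (0-based half-open)
random_features <- function(n, chroms = c("chr1", "chr2"),
                            max_pos = 1e5, max_len = 5e3) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             name = paste0("f", seq_len(n)), stringsAsFactors = FALSE)
}
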