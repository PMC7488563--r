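test_that("VCF reading keeps biallelic SNPs only and encodes genotypes", {
  vcf <- file.path(tempdir(), "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sA", "sB", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0|0\t0|1",      # indel
    "chr1\t300\t.\tC\tT,G\t.\tPASS\t.\tGT\t0|1\t0|2",     # triallelic
    "chr1\t400\t.\tG\tC\t.\tPASS\t.\tGT\t.|.\t0|1",
    "chr1\t500\t.\tT\tA\t.\tPASS\t.\tGT\t1|0\t0|0"),
    vcf)
  pm <- file.path(tempdir(), "toy.popmap")
  writeLines(c("sA\tpopX", "sB\tpopX"), pm)

  res <- read_vcf(vcf, pm)
  expect_equal(ncol(res$genotypes$calls), 3L)
  expect_equal(unname(res$log), c(1L, 1L))
  expect_equal(res$genotypes$sites$pos, c(100L, 400L, 500L))
  expect_equal(unname(res$genotypes$calls["sA", ]), c(1L, NA, 1L))
  expect_equal(unname(res$genotypes$calls["sB", ]), c(2L, 1L, 0L))
  # a missing genotype leaves no complete phased panel
  expect_null(res$haplotypes)

  # fully phased, complete records give haplotypes: 0|1 -> (0, 1)
  vcf2 <- file.path(tempdir(), "toy_phased.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sA", "sB", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t500\t.\tT\tA\t.\tPASS\t.\tGT\t1|0\t0|0"), vcf2)
  res2 <- read_vcf(vcf2, pm)
  expect_false(is.null(res2$haplotypes))
  expect_equal(unname(res2$haplotypes$hap[c("sA_1", "sA_2"), 1]),
               c(0L, 1L))
  expect_equal(unname(res2$haplotypes$hap[c("sA_1", "sA_2"), 2]),
               c(1L, 0L))
})

test_that("reading errors name missing popmap samples", {
  vcf <- file.path(tempdir(), "toy2.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sA", "sB", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1"), vcf)
  pm <- file.path(tempdir(), "toy2.popmap")
  writeLines("sA\tpopX", pm)
  expect_error(read_vcf(vcf, pm), "sB")
})

test_that("simulator VCF round-trips calls, positions and popmap", {
  sim <- simulate_neutral(sim_config(n_pops = 2, n_per_pop = 4,
                                     chrom_lengths = c(chr1 = 2e5),
                                     seed = 7))
  vcf <- file.path(tempdir(), "rt.vcf")
  pm <- file.path(tempdir(), "rt.popmap")
  write_vcf(sim$panel, vcf)
  writeLines(paste(names(sim$genotypes$popmap), sim$genotypes$popmap,
                   sep = "\t"), pm)
  back <- read_vcf(vcf, pm)
  expect_identical(unname(back$genotypes$calls),
                   unname(sim$genotypes$calls))
  expect_identical(back$genotypes$sites$pos, sim$genotypes$sites$pos)
  expect_identical(back$genotypes$popmap, sim$genotypes$popmap)
  expect_identical(unname(back$haplotypes$hap), unname(sim$panel$hap))
  # unphased writing round-trips the calls too
  write_vcf(sim$genotypes, vcf)
  back2 <- read_vcf(vcf, pm)
  expect_identical(unname(back2$genotypes$calls),
                   unname(sim$genotypes$calls))
  expect_null(back2$haplotypes)
})

test_that("quantile hard filters remove exact tail counts on continuous data", {
  ann <- simulate_annotation_table(10000, seed = 11)
  calls <- matrix(0L, 2, 10000,
                  dimnames = list(c("a", "b"), NULL))
  sites <- data.frame(chrom = "chr1", pos = seq_len(10000), ref = "A",
                      alt = "G", ann)
  gm <- genotype_matrix(calls, sites, c(a = "p", b = "p"))
  res <- apply_hard_filters(gm)
  rep <- res$report
  expect_equal(rep$removed[rep$filter == "FS"], 500L)
  expect_equal(rep$removed[rep$filter == "DP"], 500L)
  expect_equal(rep$removed[rep$filter == "BaseQRankSum"], 500L)
  # re-applying with frozen thresholds changes nothing
  res2 <- apply_hard_filters(res$genotypes, thresholds = rep)
  expect_equal(sum(res2$report$removed), 0L)
  expect_equal(ncol(res2$genotypes$calls), ncol(res$genotypes$calls))
})

test_that("threshold boundaries are strict and degenerate columns inert", {
  calls <- matrix(0L, 2, 3, dimnames = list(c("a", "b"), NULL))
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A",
                      alt = "G", MQ = c(29.9, 30, 31),
                      DP = c(100, 100, 100))
  gm <- genotype_matrix(calls, sites, c(a = "p", b = "p"))
  res <- apply_hard_filters(gm)
  expect_equal(res$genotypes$sites$MQ, c(30, 31))      # 29.9 < 30 removed
  expect_equal(res$report$removed[res$report$filter == "DP"], 0L)
})

test_that("clustered-SNP filter matches its definition at the boundary", {
  gm6 <- make_gm(matrix(0L, 2, 6), pos = 100:105)
  expect_equal(ncol(filter_clustered_snps(gm6)$calls), 0L)
  gm5 <- make_gm(matrix(0L, 2, 5), pos = c(100L, 104L, 108L, 112L, 119L))
  expect_equal(ncol(filter_clustered_snps(gm5)$calls), 5L)
})

test_that("clustered-SNP filter equals the all-windows oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(200:1000, 1)
    pos <- sort(sample.int(n * 12, n))
    gm <- make_gm(matrix(0L, 2, n), pos = pos)
    kept <- filter_clustered_snps(gm)$sites$pos
    drop <- oracle_clustered(rep("chr1", n), pos)
    expect_identical(kept, pos[!drop])
  }
})

test_that("LD pruning breaks duplicated pairs and keeps independents", {
  set.seed(3)
  base <- matrix(sample(0:2, 30 * 10, replace = TRUE), 30, 10)
  dup <- cbind(base[, 1:5], base[, 3], base[, 6:10])  # col 6 duplicates col 3
  gm <- make_gm(dup)
  kept <- ld_prune(gm)
  expect_true(3 %in% kept)
  expect_false(6 %in% kept)   # the later of the identical pair goes

  # mutually independent sites (verified directly) are all retained
  set.seed(4)
  X <- matrix(rbinom(200 * 20, 2, 0.5), 200, 20)
  r2 <- stats::cor(X)^2
  expect_lte(max(r2[upper.tri(r2)]), 0.1)  # fixture really is independent
  expect_equal(ld_prune(make_gm(X)), 1:20)
})

test_that("a lone SNP on a chromosome is retained by pruning", {
  gm <- make_gm(matrix(c(0L, 1L, 2L, 1L), 4, 1))
  expect_equal(ld_prune(gm), 1L)
})
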