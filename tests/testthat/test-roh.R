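# a diploid genotype vector with a homozygous tract between two
# heterozygosity-rich flanks
tract_calls <- function(pos, tract) {
  g <- sample(c(0L, 1L, 2L), length(pos), replace = TRUE,
              prob = c(0.3, 0.4, 0.3))
  inside <- pos > tract[1] & pos <= tract[2]
  g[inside] <- sample(c(0L, 2L), sum(inside), replace = TRUE)
  g
}

test_that("a homozygous megabase tract yields exactly one segment", {
  set.seed(40)
  pos <- sort(sample.int(3e6, 3000))
  g <- tract_calls(pos, c(1e6, 2e6))
  gm <- make_gm(matrix(g, 1), pos = pos)
  seg <- detect_roh(gm)
  expect_equal(nrow(seg), 1L)
  # the called segment covers the tract's interior SNPs
  expect_lt(abs(seg$start[1] - 1e6), 5e4)
  expect_lt(abs(seg$end[1] - 2e6), 5e4)

  # fully heterozygous individual: nothing
  gm_het <- make_gm(matrix(1L, 1, 3000), pos = pos)
  expect_equal(nrow(detect_roh(gm_het)), 0L)

  # a 400-kb tract fails the 500-kb floor
  g2 <- tract_calls(pos, c(1e6, 1.4e6))
  seg2 <- detect_roh(make_gm(matrix(g2, 1), pos = pos))
  expect_equal(nrow(seg2), 0L)
})

test_that("detect_roh equals the exhaustive scanning-window oracle", {
  params <- roh_params()
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(500:2000, 1)
    pos <- sort(sample.int(4e6, n))
    g <- tract_calls(pos, sort(runif(2, 0, 4e6)))
    g[sample(n, n %/% 50)] <- NA  # sprinkle missing calls
    gm <- make_gm(matrix(g, 1), pos = pos)
    seg <- detect_roh(gm, params)
    orc <- oracle_roh_one(g, pos, params)
    if (is.null(orc)) {
      expect_equal(nrow(seg), 0L)
    } else {
      expect_equal(nrow(seg), nrow(orc))
      expect_equal(seg$start, orc$start)
      expect_equal(seg$end, orc$end)
      expect_equal(seg$n_snps, orc$n_snps)
    }
  }
})

test_that("F_ROH is segment length over genome length", {
  seg <- data.frame(sample = c("a", "a", "b"), chrom = "chr1",
                    start = c(0, 5e8, 0), end = c(2e8, 5.5114e8, 1e8),
                    n_snps = 100L,
                    length_bp = c(2e8, 5.114e7, 1e8))
  tab <- froh(seg, c("a", "b", "c"))
  expect_equal(tab$f_roh[tab$sample == "a"], 0.1)  # 251.14 Mb / 2511.4 Mb
  expect_equal(tab$f_roh[tab$sample == "c"], 0)
  tab2 <- froh(seg, c("a", "b"), l_gen_bp = 1e9)
  expect_equal(tab2$f_roh, c(0.25114, 0.1))
})

test_that("F_ROH recovers injected autozygosity within 0.02", {
  cfg <- sim_config(n_pops = 1, n_per_pop = 4,
                    chrom_lengths = setNames(rep(2e7, 5),
                                             paste0("chr", 1:5)),
                    seed = 41)
  sim <- simulate_neutral(cfg)
  sim <- inject_autozygosity(sim, target_fraction = 0.15,
                             tract_mean_bp = 2e6)
  res <- run_roh(sim)
  expect_true(all(abs(res$froh$f_roh - 0.15) <= 0.02))
})

test_that("per-population F_ROH summaries are correct and order-stable", {
  tab <- data.frame(sample = c("a", "b", "c", "d"),
                    s_roh_bp = 0, f_roh = c(0.1, 0.1, 0.0, 0.2))
  pm <- c(a = "X", b = "X", c = "Y", d = "Y")
  s <- froh_summary(tab, pm)
  expect_equal(s$mean[s$population == "X"], 0.1)
  expect_equal(s$cv_pct[s$population == "X"], 0)
  expect_equal(s$mean[s$population == "Y"], 0.1)
  expect_equal(s$median[s$population == "Y"], 0.1)
  s2 <- froh_summary(tab[4:1, ], pm)
  expect_equal(s[order(s$population), -1], s2[order(s2$population), -1],
               ignore_attr = TRUE)
})

test_that("group comparison letters reflect true separation", {
  # identical data: a single letter everywhere
  tab0 <- data.frame(sample = paste0("s", 1:12), s_roh_bp = 0,
                     f_roh = 0.07)
  pm <- setNames(rep(c("A", "B", "C"), each = 4), paste0("s", 1:12))
  cg0 <- compare_groups(tab0, pm)
  expect_equal(length(unique(cg0$letters)), 1L)

  # a 5-pooled-sd shift separates its group
  set.seed(42)
  x <- rnorm(12, 0.05, 0.01)
  x[9:12] <- x[9:12] + 0.05
  cg1 <- compare_groups(data.frame(sample = paste0("s", 1:12),
                                   s_roh_bp = 0, f_roh = x), pm)
  expect_false(cg1$letters[["C"]] %in% cg1$letters[c("A", "B")])
  expect_true(any(grepl(cg1$letters[["A"]], cg1$letters[["B"]], fixed = TRUE)))

  # equal means share a letter in >= 90% of seeded replicates
  share <- 0L
  for (s in 1:100) {
    set.seed(500 + s)
    y <- rnorm(12, 0.05, 0.01)
    cg <- compare_groups(data.frame(sample = paste0("s", 1:12),
                                    s_roh_bp = 0, f_roh = y), pm)
    lt <- strsplit(unname(cg$letters), "")
    if (length(Reduce(intersect, lt)) > 0) share <- share + 1L
  }
  expect_gte(share, 90L)
})

test_that("hotspots require a strict sharing majority", {
  seg <- do.call(rbind, lapply(1:7, function(i)
    data.frame(sample = paste0("s", i), chrom = "chr1", start = 1e5,
               end = 2e5, n_snps = 100L, length_bp = 1e5)))
  pm <- setNames(rep("P", 12), paste0("s", 1:12))
  hs <- roh_hotspots(seg, pm)
  expect_equal(nrow(hs), 1L)            # 7 of 12 > 50%
  expect_equal(hs$start, 1e5)
  expect_equal(hs$end, 2e5)
  hs6 <- roh_hotspots(seg[1:6, ], pm)
  expect_equal(nrow(hs6), 0L)           # exactly half is not enough
})

test_that("hotspots match the per-position counting oracle and shrink with the threshold", {
  pm <- setNames(rep("P", 10), paste0("s", 1:10))
  for (seed in 1:5) {
    set.seed(seed)
    seg <- do.call(rbind, lapply(1:10, function(i) {
      k <- sample(1:4, 1)
      start <- sort(sample.int(5e4, k))
      data.frame(sample = paste0("s", i), chrom = "chr1", start = start,
                 end = start + sample.int(2e4, k) + 100,
                 n_snps = 50L, length_bp = 1000L)
    }))
    for (sf in c(0.3, 0.5)) {
      hs <- roh_hotspots(seg, pm, share_fraction = sf)
      orc <- oracle_hotspots(seg, 10, sf, 8e4)
      if (is.null(orc)) {
        expect_equal(nrow(hs), 0L)
      } else {
        expect_equal(hs$start, orc$start)
        expect_equal(hs$end, orc$end)
      }
    }
    lo <- roh_hotspots(seg, pm, share_fraction = 0.3)
    hi <- roh_hotspots(seg, pm, share_fraction = 0.6)
    # monotonicity: every high-threshold interval sits inside a low one
    if (nrow(hi)) {
      for (i in seq_len(nrow(hi)))
        expect_true(any(lo$start <= hi$start[i] & lo$end >= hi$end[i]))
    }
  }
})
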