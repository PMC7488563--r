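test_that("EHH matches direct combinatorial values", {
  # 4 haplotypes with extended-haplotype counts {2, 1, 1} at the last
  # site: EHH = C(2,2) / C(4,2) = 1/6
  hap <- rbind(c(1, 0, 0),
               c(1, 0, 0),
               c(1, 0, 1),
               c(1, 1, 0))
  p <- make_panel(hap)
  pr <- ehh(p, 1, "all")
  right <- pr[pr$direction == 1, ]
  expect_equal(right$ehh[2], 1 / 6, tolerance = 1e-12)
  # all pairwise distinct already at site 2's extension to site 3? site2:
  # alleles (0,0,0,1) -> groups {3,1} -> EHH = 3/6
  expect_equal(right$ehh[1], 0.5, tolerance = 1e-12)

  # identical haplotypes keep EHH = 1 everywhere
  same <- matrix(1, 4, 5)
  pr2 <- ehh(make_panel(same), 3, "all")
  expect_true(all(pr2$ehh == 1))

  # n = 4 all pairwise distinct at a site -> EHH = 0
  dist4 <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1))
  pr3 <- ehh(make_panel(dist4), 1, "all")
  expect_equal(pr3$ehh[pr3$direction == 1][2], 0)
})

test_that("EHH profiles agree with a string-grouping oracle and decrease", {
  set.seed(8)
  for (rep in 1:10) {
    hap <- matrix(rbinom(12 * 30, 1, 0.5), 12, 30)
    p <- make_panel(hap)
    focal <- sample(5:25, 1)
    pr <- ehh(p, focal, "all")
    for (dir in c(-1, 1)) {
      side <- pr[pr$direction == dir, ]
      expect_true(all(diff(side$ehh[order(side$distance_cM)]) <= 1e-12))
      for (i in seq_len(nrow(side)))
        expect_equal(side$ehh[i],
                     oracle_ehh_at(hap, 1:12, focal, side$site[i]),
                     tolerance = 1e-12)
    }
  }
})

test_that("iHH integrates EHH with cutoff, gap weighting and truncation", {
  # EHH stays at 1 for 0.1 cM on each side of the focal site, then a
  # breaker site splits the class (EHH 1/3, below a 0.5 cutoff): each
  # side integrates to the 0.1-cM rectangle exactly
  breaker <- c(0, 1, 1, 0)
  hap <- cbind(breaker, matrix(1, 4, 11), breaker)
  pos <- c(40000, seq(50000, 250000, by = 20000), 260000)
  p <- make_panel(hap, pos = pos)
  pr <- ehh(p, 7, "all")  # block middle, pos 150000
  res <- ihh(pr, cutoff = 0.5)
  expect_equal(res$ihh, 0.2, tolerance = 1e-12)
  expect_false(res$unscored)
  # with the default cutoff the breaker trapezoids enter the integral
  res2 <- ihh(pr)
  expect_gt(res2$ihh, 0.2)

  # random panels: R integration of the profile equals the compiled path
  set.seed(9)
  for (rep in 1:10) {
    hap <- matrix(rbinom(16 * 40, 1, 0.5), 16, 40)
    pos <- sort(sample.int(3e6, 40))
    p <- make_panel(hap, pos = pos)
    focal <- sample(10:30, 1)
    pr <- ehh(p, focal, "all")
    r_side <- ihh(pr)
    cpp <- sweepscan:::ihh_cpp(hap, focal - 1L, 0:15, as.numeric(pos),
                               pos / 1e6, 0.05, 2e5, 2e4)
    expect_equal(r_side$ihh, cpp[1], tolerance = 1e-12)
    expect_equal(r_side$unscored, cpp[2] == 1)
    # independent trapezoid oracle, right side only
    right <- pr[pr$direction == 1, ]
    oracle <- oracle_ihh_side(right$ehh, right$distance_cM, right$pos,
                              p$sites$pos[focal])
    left <- pr[pr$direction == -1, ]
    left <- left[rev(seq_len(nrow(left))), ]
    oracle <- oracle + oracle_ihh_side(left$ehh, left$distance_cM,
                                       left$pos, p$sites$pos[focal])
    expect_equal(r_side$ihh, oracle, tolerance = 1e-12)
  }
})

test_that("raw iHS equals the two-class iHH log-ratio computed in R", {
  set.seed(10)
  hap <- matrix(rbinom(20 * 60, 1, 0.5), 20, 60)
  pos <- sort(sample.int(2e6, 60))
  p <- make_panel(hap, pos = pos)
  sc <- ihs_scan(p)
  expect_gt(nrow(sc), 0)
  for (i in seq_len(min(10, nrow(sc)))) {
    focal <- sc$site[i]
    ia <- ihh(ehh(p, focal, "ancestral"))
    id <- ihh(ehh(p, focal, "derived"))
    expect_equal(sc$raw[i], log(ia$ihh / id$ihh), tolerance = 1e-10)
  }
})

test_that("mirror-image haplotype classes give raw iHS of zero", {
  # derived carriers are an exact allele-flip of ancestral carriers:
  # identical partition structure on both sides
  set.seed(12)
  block <- matrix(rbinom(5 * 21, 1, 0.5), 5, 21)
  hap <- rbind(block, 1 - block)
  hap[, 11] <- rep(c(0L, 1L), each = 5)  # focal: 5 ancestral, 5 derived
  p <- make_panel(hap)
  sc <- ihs_scan(p, maf_min = 0.05)
  row <- sc[sc$site == 11, ]
  expect_equal(row$raw, 0, tolerance = 1e-12)
})

test_that("standardized iHS is zero-mean unit-sd within occupied bins", {
  set.seed(11)
  sim <- simulate_neutral(sim_config(n_pops = 1, n_per_pop = 12,
                                     chrom_lengths = c(chr1 = 3e6),
                                     seed = 12))
  sc <- standardize_ihs(ihs_scan(sim$panel))
  bin <- cut(sc$derived_freq, seq(0, 1, length.out = 101),
             include.lowest = TRUE)
  for (b in levels(droplevels(bin))) {
    z <- sc$std[bin == b]
    z <- z[!is.na(z)]
    if (length(z) >= 2) {
      expect_lt(abs(mean(z)), 1e-9)
      expect_lt(abs(sd(z) - 1), 1e-9)
    }
  }
  # permuting row order leaves every std unchanged
  perm <- sample(nrow(sc))
  sc2 <- standardize_ihs(ihs_scan(sim$panel)[perm, ])
  expect_equal(sc2$std, sc$std[perm])
})

test_that("XP-EHH is zero for identical panels and antisymmetric", {
  set.seed(13)
  hap <- matrix(rbinom(12 * 50, 1, 0.5), 12, 50)
  both <- rbind(hap, hap)
  samples <- paste0("s", 1:12)
  rownames(both) <- as.vector(rbind(paste0(samples, "_1"),
                                    paste0(samples, "_2")))
  pos <- sort(sample.int(2e6, 50))
  sites <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                      ancestral = "A", stringsAsFactors = FALSE)
  pm <- setNames(rep(c("pA", "pB"), each = 6), samples)
  p <- haplotype_panel(both, sites, pm)
  sc <- xpehh_scan(p, "pA", "pB")
  expect_true(all(abs(sc$raw) < 1e-12))

  # antisymmetry on a random two-population panel
  sim <- simulate_neutral(sim_config(n_pops = 2, n_per_pop = 8,
                                     chrom_lengths = c(chr1 = 2e6),
                                     seed = 14))
  ab <- xpehh_scan(sim$panel, "pop1", "pop2")
  ba <- xpehh_scan(sim$panel, "pop2", "pop1")
  expect_equal(ab$site, ba$site)
  expect_equal(ab$raw, -ba$raw, tolerance = 1e-12)
})

test_that("haplotype statistics ignore haplotype row order", {
  sim <- simulate_neutral(sim_config(n_pops = 1, n_per_pop = 10,
                                     chrom_lengths = c(chr1 = 2e6),
                                     seed = 15))
  sc1 <- ihs_scan(sim$panel)
  shuf <- sim$panel
  ord <- sample(nrow(shuf$hap))
  shuf$hap <- shuf$hap[ord, ]
  shuf$sample <- shuf$sample[ord]
  sc2 <- ihs_scan(shuf)
  expect_equal(sc1, sc2)
})

test_that("a sweep produces strongly negative iHS and positive XP-EHH", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 16,
                    chrom_lengths = c(chr1 = 4e6),
                    sweep_specs = data.frame(pop = "pop1", chrom = "chr1",
                                             position = 2e6,
                                             final_freq = 0.9,
                                             core_halflength = 3e5),
                    seed = 16)
  sim <- simulate_neutral(cfg)
  s <- sim$truth$sweeps$site[1]
  sc <- ihs_scan(sim$panel, pop = "pop1")
  near <- sc[abs(sc$pos - sim$truth$sweeps$pos[1]) < 5e4, ]
  expect_lt(min(near$raw), -2)  # derived haplotypes much longer

  xp <- xpehh_scan(sim$panel, "pop1", "pop2")
  nearx <- xp[abs(xp$pos - sim$truth$sweeps$pos[1]) < 5e4, ]
  expect_gt(max(nearx$raw), 2)
})
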