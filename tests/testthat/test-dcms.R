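test_that("window averaging is mean-per-window with absolute-first option", {
  w <- make_windows(c(chr1 = 1e5))
  vals <- data.frame(chrom = "chr1", pos = c(10000L, 40000L, 60000L),
                     v = c(1, 3, 5))
  wa <- window_average(vals, w)
  expect_equal(wa$value, c(2, 5))
  expect_equal(wa$support, c(2L, 1L))

  # empty window -> NA
  w3 <- make_windows(c(chr1 = 1.5e5))
  wa3 <- window_average(vals, w3)
  expect_true(is.na(wa3$value[3]))

  # absolute before averaging
  vals2 <- data.frame(chrom = "chr1", pos = c(10000L, 40000L),
                      v = c(-2, 2))
  expect_equal(window_average(vals2, w, abs_first = TRUE)$value[1], 2)
  expect_equal(window_average(vals2, w)$value[1], 0)
})

test_that("skew-normal CDF agrees with numerical integration of the density", {
  for (par in list(c(0, 1, 0), c(1, 2, 3), c(-2, 0.5, -4), c(0, 1, 12))) {
    for (q in c(-2, -0.3, 0, 0.7, 2.5)) {
      num <- stats::integrate(dsn, -Inf, q, xi = par[1], omega = par[2],
                              alpha = par[3], rel.tol = 1e-11)$value
      expect_lt(abs(psn(q, par[1], par[2], par[3]) - num), 1e-8)
    }
  }
  # alpha = 0 reduces to the normal
  expect_equal(psn(1.3, 0, 1, 0), pnorm(1.3), tolerance = 1e-12)
})

test_that("skew-normal MLE recovers parameters and respects shifts", {
  set.seed(30)
  x <- rsn(5000, xi = 0, omega = 1, alpha = 5)
  fit <- fit_skew_normal(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$xi), 0.1)
  expect_lt(abs(fit$omega - 1) / 1, 0.1)
  expect_lt(abs(fit$alpha - 5) / 5, 0.1)

  # symmetric data: the fit collapses to the nested normal.  The shape
  # parameter itself is noisy near 0 (a sample skewness of +/-
  # sqrt(6/n) back-transforms through a cube root), so the limit is
  # checked where it is well-behaved: implied skewness ~ 0 and a fitted
  # CDF indistinguishable from the normal.
  set.seed(31)
  y <- rnorm(5000)
  fity <- fit_skew_normal(y)
  delta <- fity$alpha / sqrt(1 + fity$alpha^2)
  g1 <- (4 - pi) / 2 * (delta * sqrt(2 / pi))^3 /
    (1 - 2 * delta^2 / pi)^1.5
  expect_lt(abs(g1), 0.1)
  qs <- seq(-3, 3, by = 0.25)
  expect_lt(max(abs(psn(qs, fity$xi, fity$omega, fity$alpha) -
                      pnorm(qs))), 0.02)

  # location equivariance
  fit2 <- fit_skew_normal(x + 10)
  expect_equal(fit2$xi - fit$xi, 10, tolerance = 0.02)
  expect_equal(fit2$omega, fit$omega, tolerance = 0.02)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 0.05)

  expect_error(fit_skew_normal(rep(1, 100)), "variance")
})

test_that("empirical p-values are upper-tail, monotone, and rank-reversing", {
  fit <- structure(list(xi = 2, omega = 1.5, alpha = 0,
                        converged = TRUE, method = "mle"),
                   class = "skewnormal_fit")
  expect_equal(empirical_pvalues(fit, 2), 0.5, tolerance = 1e-12)
  v <- seq(-3, 8, length.out = 50)
  p <- empirical_pvalues(fit, v)
  expect_true(all(diff(p) < 0))
  expect_equal(order(p), order(-v))
  expect_true(all(p > 0 & p <= 1))
})

test_that("DCMS weighting matches its analytic structure", {
  set.seed(32)
  p1 <- runif(200)
  # single column: DCMS = -log10 p exactly
  one <- dcms_from_pvalues(cbind(a = p1))
  expect_equal(one$dcms, -log10(p1), tolerance = 1e-12)

  # duplicated column: r = 1, weights 1/2 each, same total
  two <- dcms_from_pvalues(cbind(a = p1, b = p1))
  expect_equal(unname(two$weights), c(0.5, 0.5))
  expect_equal(two$dcms, -log10(p1), tolerance = 1e-12)

  # exactly uncorrelated columns: weights 1 each, DCMS is the sum
  x <- rep(c(1, 1, 2, 2), 50)
  y <- rep(c(1, 2, 1, 2), 50)
  expect_equal(cor(-log10(10^-x), -log10(10^-y)), 0)
  ind <- dcms_from_pvalues(cbind(a = 10^-x, b = 10^-y))
  expect_equal(unname(ind$weights), c(1, 1))
  expect_equal(ind$dcms, x + y, tolerance = 1e-12)

  # constant column is dropped with a warning
  expect_warning(dr <- dcms_from_pvalues(cbind(a = p1, b = rep(0.5, 200))),
                 "constant")
  expect_equal(dr$dcms, -log10(p1), tolerance = 1e-12)
})

test_that("DCMS is invariant to column order and p-preserving rescaling", {
  set.seed(33)
  p <- cbind(a = runif(300), b = runif(300), c = runif(300))
  r1 <- dcms_from_pvalues(p)
  r2 <- dcms_from_pvalues(p[, c(3, 1, 2)])
  expect_equal(r1$dcms, r2$dcms, tolerance = 1e-12)
})

test_that("top-fraction selection uses floor and genomic-order tie-breaks", {
  mk_result <- function(d, chrom = "chr1") {
    structure(list(windows = data.frame(
      chrom = chrom, start = (seq_along(d) - 1) * 5e4,
      end = seq_along(d) * 5e4), dcms = d),
      class = "dcms_result")
  }
  sel <- select_top(mk_result(seq_len(1000)), 0.01)
  expect_equal(sum(sel$selected), 10L)
  expect_true(all(which(sel$selected) > 990))

  sel2 <- select_top(mk_result(seq_len(150)), 0.01)
  expect_equal(sum(sel2$selected), 1L)

  expect_warning(sel3 <- select_top(mk_result(rep(1, 200)), 0.01),
                 "ties")
  expect_equal(which(sel3$selected), 1:2)
})

test_that("region merging joins bookended windows and is idempotent", {
  df <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                   start = c(0, 5e4, 2e5, 0),
                   end = c(5e4, 1e5, 2.5e5, 5e4),
                   dcms = c(3, 7, 5, 4),
                   selected = TRUE)
  reg <- merge_regions(df)
  expect_equal(nrow(reg), 3L)
  expect_equal(reg$start[reg$chrom == "chr1"], c(0, 2e5))
  expect_equal(reg$end[reg$chrom == "chr1"], c(1e5, 2.5e5))
  expect_equal(reg$peak_dcms[1], 7)
  expect_equal(reg$n_windows[1], 2L)

  # merging the merged regions changes nothing
  reg$selected <- TRUE
  reg2 <- merge_regions(data.frame(chrom = reg$chrom, start = reg$start,
                                   end = reg$end, dcms = reg$peak_dcms,
                                   selected = TRUE))
  expect_equal(reg2$start, reg$start)
  expect_equal(reg2$end, reg$end)
})
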