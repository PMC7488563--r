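#' Restrict a genotype matrix to a set of samples or populations
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample IDs to keep, or `NULL`.
#' @param pops population labels to keep, or `NULL`.
#' @return A [genotype_matrix()] with the selected samples.
#' @export
subset_samples <- function(gm, samples = NULL, pops = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- rownames(gm$calls)
  if (!is.null(pops)) keep <- keep[gm$popmap[keep] %in% pops]
  if (!is.null(samples)) keep <- intersect(keep, samples)
  if (!length(keep)) stop("no samples left after subsetting")
  genotype_matrix(gm$calls[keep, , drop = FALSE], gm$sites,
                  gm$popmap[keep])
}

#' Per-site, per-population allele frequencies and weights
#'
#' Frequencies count the alternate (derived, where polarized) allele
#' over non-missing calls only.  Weights are each population's relative
#' non-missing allele count at the site, `c_i = n_i / sum_j n_j`, so the
#' pooled frequency is `pbar = sum_i c_i p_i`.  Populations with zero
#' non-missing calls at a site are excluded there (weights renormalize
#' over the rest).
#'
#' @param gm a [genotype_matrix()].
#' @return An `allele_freq_table`: matrices `p`, `n`, `c` (sites x
#'   populations), vector `pbar`, and `pops`.
#' @export
allele_frequencies <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(unname(gm$popmap))
  S <- ncol(gm$calls)
  p <- n <- matrix(NA_real_, S, length(pops),
                   dimnames = list(NULL, pops))
  for (k in seq_along(pops)) {
    sub <- gm$calls[gm$popmap == pops[k], , drop = FALSE]
    nk <- 2 * colSums(!is.na(sub))
    cnt <- colSums(sub, na.rm = TRUE)
    n[, k] <- nk
    p[, k] <- ifelse(nk > 0, cnt / nk, NA_real_)
  }
  ntot <- rowSums(n)
  cw <- n / ntot
  cw[n == 0] <- 0
  pbar <- rowSums(cw * p, na.rm = TRUE)
  structure(list(p = p, n = n, c = cw, pbar = pbar, pops = pops),
            class = "allele_freq_table")
}

#' Per-site fixation index from the heterozygosity partition
#'
#' `F_ST = (pbar(1-pbar) - sum_i c_i p_i (1-p_i)) / (pbar(1-pbar))`,
#' the share of pooled heterozygosity not explained by within-population
#' heterozygosity.  Sites monomorphic in the pool (`pbar` 0 or 1) are
#' undefined (`NA`) and must be excluded from window means.
#'
#' @param freqs an [allele_frequencies()] table.
#' @return Numeric vector of per-site F_ST in `[0, 1]`, `NA` where
#'   undefined.
#' @export
fst_site <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  het_bar <- freqs$pbar * (1 - freqs$pbar)
  within <- rowSums(freqs$c * freqs$p * (1 - freqs$p), na.rm = TRUE)
  out <- (het_bar - within) / het_bar
  out[het_bar <= 0] <- NA_real_
  out
}

#' Per-site F_ST between one pair of populations
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population labels.
#' @return data.frame `chrom`, `pos`, `fst` (`NA` rows dropped).
#' @export
fst_pair <- function(gm, popA, popB) {
  sub <- subset_samples(gm, pops = c(popA, popB))
  fst <- fst_site(allele_frequencies(sub))
  keep <- !is.na(fst)
  data.frame(chrom = gm$sites$chrom[keep], pos = gm$sites$pos[keep],
             fst = fst[keep], stringsAsFactors = FALSE)
}

#' Background (genome-wide) unfolded site-frequency spectrum
#'
#' Normalized histogram of derived-allele counts `1 .. n-1` over all
#' polarized segregating sites of a population's haplotype panel.
#'
#' @param panel a polarized [haplotype_panel()] (one population).
#' @return A `background_sfs`: haplotype count `n` and probability
#'   vector `prob` over derived counts `1 .. n-1`.
#' @export
background_sfs <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  pol <- if ("polarized" %in% names(panel$sites))
    panel$sites$polarized else !is.na(panel$sites$ancestral)
  n <- nrow(panel$hap)
  counts <- colSums(panel$hap)
  seg <- pol & counts >= 1 & counts <= n - 1
  if (!any(seg)) stop("no polarized segregating sites")
  h <- tabulate(counts[seg], nbins = n - 1)
  structure(list(n = n, prob = h / sum(h)), class = "background_sfs")
}

#' SweepFinder-style composite likelihood ratio scan
#'
#' At each test position x and sweep intensity alpha, a site at
#' recombination distance d (Morgans, from the 1 Mb ~ 1 cM map) escapes
#' the sweep with probability `pe = 1 - exp(-alpha d)`.  Its likelihood
#' is `pe * P_bg(j) + (1 - pe) * P_forced(j)`, where the forced spectrum
#' puts the background mass on derived counts n-1 (hitchhiked derived
#' lineage, weight `sum_k P_bg(k) k/n`) and 1 (escaped derived lineage,
#' weight `sum_k P_bg(k) (1-k/n)`).  The statistic is
#' `CLR(x) = 2 (max_alpha log CL - log CL_background)`, floored at 0
#' (the null is the large-alpha limit of the grid).
#'
#' @param panel a polarized [haplotype_panel()] for one population.
#' @param sfs a [background_sfs()] for the same panel.
#' @param window_bp spacing of test positions; defaults to 50-kb window
#'   centres.
#' @param chrom_lengths optional named chromosome lengths; defaults to
#'   the last window containing a site.
#' @param alpha_grid sweep intensities (per Morgan); default 40
#'   log-spaced values spanning sweep footprints of about 1 kb to 10 Mb.
#' @param radius_bp only sites within this distance of a test position
#'   enter its composite likelihood (farther sites contribute nothing to
#'   the ratio); default 1 Mb.
#' @return data.frame `chrom`, `pos` (test position), `clr`,
#'   `alpha` (maximizer, `NA` when `clr` is 0), `n_sites`.
#' @export
clr_scan <- function(panel, sfs = background_sfs(panel),
                     window_bp = 50000, chrom_lengths = NULL,
                     alpha_grid = NULL, radius_bp = 1e6) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(sfs, "background_sfs"))
  if (is.null(alpha_grid))
    alpha_grid <- exp(seq(log(1e8 / 1e7), log(1e8 / 1e3),
                          length.out = 40))
  n <- sfs$n
  k <- seq_len(n - 1)
  w_high <- sum(sfs$prob * k / n)
  w_low <- sum(sfs$prob * (1 - k / n))

  pol <- if ("polarized" %in% names(panel$sites))
    panel$sites$polarized else !is.na(panel$sites$ancestral)
  counts <- colSums(panel$hap)
  use <- pol & counts >= 1 & counts <= n - 1

  out <- lapply(unique(panel$sites$chrom), function(ch) {
    idx <- which(panel$sites$chrom == ch & use)
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      ceiling(max(panel$sites$pos[panel$sites$chrom == ch]) / window_bp) *
        window_bp
    centers <- seq(window_bp / 2, L, by = window_bp)
    pos <- panel$sites$pos[idx]
    j <- counts[idx]
    bg <- sfs$prob[j]
    forced <- numeric(length(j))
    forced[j == n - 1] <- w_high
    forced[j == 1] <- forced[j == 1] + w_low
    res <- t(vapply(centers, function(x) {
      near <- abs(pos - x) <= radius_bp
      if (!any(near)) return(c(0, NA_real_, 0))
      d <- abs(pos[near] - x) / 1e8  # bp -> Morgans at 1 Mb ~ 1 cM
      b <- bg[near]
      f <- forced[near]
      ll0 <- sum(log(b))
      ll <- vapply(alpha_grid, function(a) {
        pe <- 1 - exp(-a * d)
        sum(log(pe * b + (1 - pe) * f))
      }, 0)
      best <- which.max(ll)
      clr <- 2 * (ll[best] - ll0)
      if (!is.finite(clr) || clr < 0)
        c(0, NA_real_, sum(near))
      else c(clr, alpha_grid[best], sum(near))
    }, numeric(3)))
    data.frame(chrom = ch, pos = centers, clr = res[, 1],
               alpha = res[, 2], n_sites = res[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
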