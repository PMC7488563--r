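.selscan_defaults <- list(cutoff = 0.05, maf_min = 0.05,
                          max_gap_bp = 2e5, gap_scale_bp = 2e4,
                          n_bins = 100L)

.chrom_slice <- function(panel, focal) {
  ch <- panel$sites$chrom[focal]
  idx <- which(panel$sites$chrom == ch)
  list(idx = idx, local = match(focal, idx))
}

#' Extended haplotype homozygosity profile around a focal site
#'
#' EHH at offset d is the probability that two haplotypes drawn without
#' replacement from the carrier class are identical over the interval
#' from the focal site out to d: `sum_h C(c_h, 2) / C(n, 2)` over
#' distinct extended haplotypes.  Computed outward site by site in both
#' directions, within the focal site's chromosome.
#'
#' @param panel a [haplotype_panel()].
#' @param focal site index (column of the panel).
#' @param carrier_class `"all"` haplotypes, or `"ancestral"` /
#'   `"derived"` carriers of the focal alleles (0 / 1 respectively).
#' @param pop optional population label to restrict the panel first.
#' @return An `ehh_profile` data.frame with columns `direction` (-1
#'   left, 0 focal, +1 right), `site`, `pos`, `distance_cM`, `ehh`;
#'   attribute `reached_end` marks sides whose walk hit the chromosome
#'   end.
#' @export
ehh <- function(panel, focal,
                carrier_class = c("all", "ancestral", "derived"),
                pop = NULL) {
  carrier_class <- match.arg(carrier_class)
  if (!is.null(pop)) panel <- subset_pop(panel, pop)
  sl <- .chrom_slice(panel, focal)
  hap <- panel$hap[, sl$idx, drop = FALSE]
  cm <- panel$map_cM[sl$idx]
  members <- switch(carrier_class,
                    all = seq_len(nrow(hap)),
                    ancestral = which(hap[, sl$local] == 0L),
                    derived = which(hap[, sl$local] == 1L))
  if (length(members) < 2L)
    stop("EHH undefined: carrier class '", carrier_class,
         "' has fewer than 2 haplotypes")
  sides <- lapply(c(-1L, 1L), function(dir) {
    pr <- ehh_profile_cpp(hap, sl$local - 1L, members - 1L, cm, dir)
    n <- length(pr$ehh)
    reached <- if (dir < 0) (sl$local - n) == 1L else (sl$local + n) == ncol(hap)
    if (n && pr$ehh[n] == 0) reached <- FALSE
    data.frame(direction = rep(dir, n), site = sl$idx[pr$site],
               pos = panel$sites$pos[sl$idx[pr$site]],
               distance_cM = pr$distance_cM, ehh = pr$ehh,
               reached_end = rep(reached, n))
  })
  out <- rbind(sides[[1]][rev(seq_len(nrow(sides[[1]]))), ],
               data.frame(direction = 0L, site = focal,
                          pos = panel$sites$pos[focal], distance_cM = 0,
                          ehh = 1, reached_end = FALSE),
               sides[[2]])
  rownames(out) <- NULL
  class(out) <- c("ehh_profile", "data.frame")
  out
}

#' Integrated EHH (iHH) from a profile
#'
#' Trapezoidal integral of EHH over genetic distance, both sides summed.
#' The integral is truncated at the first point where EHH drops below
#' `cutoff` (the sub-cutoff trapezoid is excluded) and at physical gaps
#' larger than `max_gap_bp`; gaps above `gap_scale_bp` down-weight their
#' trapezoid by `gap_scale_bp / gap`.  A side whose walk reached the
#' chromosome end with EHH still at or above the cutoff leaves the site
#' unscored.
#'
#' @param profile an [ehh()] profile.
#' @param cutoff EHH truncation level (default 0.05).
#' @param max_gap_bp gap that truncates the integral (default 200 kb).
#' @param gap_scale_bp gap beyond which trapezoids are down-weighted
#'   (default 20 kb).
#' @return List with `ihh` (cM) and `unscored` (logical).
#' @export
ihh <- function(profile, cutoff = 0.05, max_gap_bp = 2e5,
                gap_scale_bp = 2e4) {
  stopifnot(inherits(profile, "ehh_profile"))
  focal <- profile[profile$direction == 0L, ]
  total <- 0
  unscored <- FALSE
  for (dir in c(-1L, 1L)) {
    side <- profile[profile$direction == dir, ]
    if (dir < 0) side <- side[rev(seq_len(nrow(side))), ]
    e_prev <- 1
    x_prev <- 0
    p_prev <- focal$pos
    truncated <- FALSE
    for (i in seq_len(nrow(side))) {
      gap <- abs(side$pos[i] - p_prev)
      if (gap > max_gap_bp) {
        truncated <- TRUE
        break
      }
      if (side$ehh[i] < cutoff) {
        truncated <- TRUE
        break
      }
      w <- if (gap > gap_scale_bp) gap_scale_bp / gap else 1
      total <- total + w * 0.5 * (e_prev + side$ehh[i]) *
        (side$distance_cM[i] - x_prev)
      e_prev <- side$ehh[i]
      x_prev <- side$distance_cM[i]
      p_prev <- side$pos[i]
    }
    if (!truncated &&
        (nrow(side) == 0L || isTRUE(side$reached_end[1])))
      unscored <- TRUE
  }
  list(ihh = total, unscored = unscored)
}

#' Raw iHS scan within one population
#'
#' Per polarized site with minor-allele frequency at least `maf_min`,
#' raw iHS = ln(iHH_ancestral / iHH_derived).  Sites unscored in either
#' class (chromosome-end truncation, zero iHH, or a class smaller than
#' 2) are skipped.
#'
#' @param panel a [haplotype_panel()] coded 1 = derived (see
#'   [polarize_panel()]).
#' @param pop optional population restriction.
#' @param maf_min,cutoff,max_gap_bp,gap_scale_bp selscan-style defaults
#'   (0.05, 0.05, 200 kb, 20 kb).
#' @return data.frame `chrom`, `pos`, `site`, `derived_freq`, `raw`,
#'   with unscored sites removed.
#' @export
ihs_scan <- function(panel, pop = NULL,
                     maf_min = .selscan_defaults$maf_min,
                     cutoff = .selscan_defaults$cutoff,
                     max_gap_bp = .selscan_defaults$max_gap_bp,
                     gap_scale_bp = .selscan_defaults$gap_scale_bp) {
  if (!is.null(pop)) panel <- subset_pop(panel, pop)
  out <- lapply(unique(panel$sites$chrom), function(ch) {
    idx <- which(panel$sites$chrom == ch)
    m <- ihs_scan_cpp(panel$hap[, idx, drop = FALSE],
                      as.numeric(panel$sites$pos[idx]),
                      panel$map_cM[idx], maf_min, cutoff, max_gap_bp,
                      gap_scale_bp)
    keep <- m[, 3] == 1
    data.frame(chrom = ch, pos = panel$sites$pos[idx][keep],
               site = idx[keep], derived_freq = m[keep, 1],
               raw = m[keep, 2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standardize iHS scores within derived-allele-frequency bins
#'
#' Sites are binned by derived-allele frequency into `n_bins`
#' equal-width bins on (0, 1); within each bin
#' `std = (raw - bin mean) / bin sd`.  Bins with fewer than 2 sites or
#' zero spread leave `std` as `NA`.
#'
#' @param scores output of [ihs_scan()].
#' @param n_bins number of frequency bins (default 100).
#' @return `scores` with an added `std` column.
#' @export
standardize_ihs <- function(scores, n_bins = .selscan_defaults$n_bins) {
  br <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(scores$derived_freq, br, include.lowest = TRUE)
  mu <- tapply(scores$raw, bin, mean)
  sdev <- tapply(scores$raw, bin, stats::sd)
  n <- tapply(scores$raw, bin, length)
  std <- (scores$raw - mu[bin]) / sdev[bin]
  std[n[bin] < 2 | !is.finite(std)] <- NA_real_
  scores$std <- as.numeric(std)
  scores
}

#' Raw XP-EHH scan between two populations
#'
#' Per site segregating in the pooled pair, raw XP-EHH =
#' ln(iHH_A / iHH_B), where iHH is integrated EHH over all haplotypes of
#' each population.  Sites unscored in either population are skipped.
#'
#' @param panel a [haplotype_panel()] holding both populations.
#' @param popA,popB population labels; positive scores mean longer
#'   haplotypes in `popA`.
#' @param cutoff,max_gap_bp,gap_scale_bp as in [ihs_scan()].
#' @return data.frame `chrom`, `pos`, `site`, `pooled_freq`, `raw`.
#' @export
xpehh_scan <- function(panel, popA, popB,
                       cutoff = .selscan_defaults$cutoff,
                       max_gap_bp = .selscan_defaults$max_gap_bp,
                       gap_scale_bp = .selscan_defaults$gap_scale_bp) {
  pa <- subset_pop(panel, popA)
  pb <- subset_pop(panel, popB)
  out <- lapply(unique(panel$sites$chrom), function(ch) {
    idx <- which(panel$sites$chrom == ch)
    m <- xpehh_scan_cpp(pa$hap[, idx, drop = FALSE],
                        pb$hap[, idx, drop = FALSE],
                        as.numeric(panel$sites$pos[idx]),
                        panel$map_cM[idx], cutoff, max_gap_bp,
                        gap_scale_bp)
    keep <- m[, 3] == 1
    data.frame(chrom = ch, pos = panel$sites$pos[idx][keep],
               site = idx[keep], pooled_freq = m[keep, 1],
               raw = m[keep, 2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standardize XP-EHH scores genome-wide
#'
#' A single genome-wide bin: `std = (raw - mean) / sd`.
#'
#' @param scores output of [xpehh_scan()].
#' @return `scores` with an added `std` column.
#' @export
standardize_xpehh <- function(scores) {
  scores$std <- as.numeric(scale(scores$raw))
  scores
}
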