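#' Hard-filter configuration
#'
#' Thresholds for the variant-call hard filters.  Quantile cut-offs are
#' recomputed from the data being filtered (an outlier approach), so the
#' realized thresholds are reported rather than hard-coded.
#'
#' @param fs_upper_q upper quantile for the Fisher-strand (FS) cut
#'   (default 0.95: the highest 5% are removed).
#' @param ranksum_tail_q per-tail mass for the two-sided rank-sum and DP
#'   filters (default 0.025: highest and lowest 2.5% removed).
#' @param mq_min fixed mapping-quality floor; sites with MQ strictly
#'   below it are removed (default 30).
#' @param cluster_max_snps,cluster_window_bp clustered-SNP rule: any
#'   `cluster_window_bp`-bp span holding more than `cluster_max_snps`
#'   SNPs is removed wholesale (defaults 5 SNPs / 20 bp).
#' @return A `filter_config` list.
#' @export
filter_config <- function(fs_upper_q = 0.95, ranksum_tail_q = 0.025,
                          mq_min = 30, cluster_max_snps = 5L,
                          cluster_window_bp = 20L) {
  stopifnot(fs_upper_q > 0.5, fs_upper_q < 1,
            ranksum_tail_q > 0, ranksum_tail_q < 0.5,
            cluster_window_bp > 0)
  structure(list(fs_upper_q = fs_upper_q, ranksum_tail_q = ranksum_tail_q,
                 mq_min = mq_min, cluster_max_snps = cluster_max_snps,
                 cluster_window_bp = cluster_window_bp),
            class = "filter_config")
}

#' Apply quantile-based hard filters to caller annotations
#'
#' FS is cut above its empirical upper quantile; BaseQRankSum,
#' MQRankSum, ReadPosRankSum and DP are cut outside their two-sided
#' quantiles; MQ uses the fixed floor.  All comparisons are strict, so a
#' site exactly at a threshold is kept and degenerate (constant) columns
#' remove nothing.  Sites lacking a statistic are exempt from that
#' filter.  Thresholds are linear-interpolation empirical quantiles of
#' the input; pass `thresholds` (a previous report) to freeze them,
#' which makes the filter idempotent.
#'
#' @param gm a [genotype_matrix()] whose `sites` carry annotation
#'   columns.
#' @param cfg a [filter_config()].
#' @param thresholds optional report from a previous run; its threshold
#'   columns are reused instead of recomputing quantiles.
#' @return List with `genotypes` (filtered) and `report` (data.frame:
#'   filter, lower, upper, removed).
#' @export
apply_hard_filters <- function(gm, cfg = filter_config(),
                               thresholds = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$calls) == 0L) stop("empty genotype matrix")
  sites <- gm$sites
  two_sided <- c("BaseQRankSum", "MQRankSum", "ReadPosRankSum", "DP")
  report <- data.frame(filter = character(), lower = numeric(),
                       upper = numeric(), removed = integer(),
                       stringsAsFactors = FALSE)
  fail <- rep(FALSE, nrow(sites))

  get_thr <- function(name, lower, upper) {
    if (!is.null(thresholds)) {
      row <- thresholds[thresholds$filter == name, ]
      if (nrow(row) == 1L) return(c(row$lower, row$upper))
    }
    c(lower, upper)
  }

  one_filter <- function(name, lower_fun, upper_fun) {
    x <- sites[[name]]
    if (is.null(x)) return(NULL)
    if (all(is.na(x))) {
      warning("annotation column ", name, " is all missing; filter skipped")
      return(NULL)
    }
    thr <- get_thr(name, lower_fun(x), upper_fun(x))
    bad <- !is.na(x) & (x < thr[1] | x > thr[2])
    fail <<- fail | bad
    report <<- rbind(report, data.frame(filter = name, lower = thr[1],
                                        upper = thr[2],
                                        removed = sum(bad)))
  }

  one_filter("FS", function(x) -Inf,
             function(x) stats::quantile(x, cfg$fs_upper_q, na.rm = TRUE,
                                         names = FALSE))
  for (f in two_sided)
    one_filter(f,
               function(x) stats::quantile(x, cfg$ranksum_tail_q,
                                           na.rm = TRUE, names = FALSE),
               function(x) stats::quantile(x, 1 - cfg$ranksum_tail_q,
                                           na.rm = TRUE, names = FALSE))
  one_filter("MQ", function(x) cfg$mq_min, function(x) Inf)

  list(genotypes = subset_sites(gm, !fail), report = report)
}

#' Remove clustered SNPs
#'
#' Every SNP lying in any physical span of `window_bp` base pairs that
#' contains strictly more than `max_snps` SNPs is removed.
#'
#' @param gm a [genotype_matrix()] (or [haplotype_panel()]) with sorted
#'   sites.
#' @param max_snps cluster size threshold (strictly greater removes).
#' @param window_bp span width in bp.
#' @return The container with clustered sites removed.
#' @export
filter_clustered_snps <- function(gm, max_snps = 5L, window_bp = 20L) {
  sites <- gm$sites
  drop <- rep(FALSE, nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    p <- sites$pos[idx]
    # rightmost site within window_bp of each left anchor
    j <- findInterval(p + window_bp - 1L, p)
    run <- j - seq_along(p) + 1L
    for (i in which(run > max_snps)) drop[idx[i:j[i]]] <- TRUE
  }
  subset_sites(gm, !drop)
}

#' Greedy LD pruning within sliding SNP windows
#'
#' Within each `window_snps`-wide window (advanced by `step` SNPs along
#' each chromosome), pairs of SNPs with squared genotype correlation
#' above `r2_max` are broken by removing the later-positioned SNP, until
#' no such pair remains.  Monomorphic sites have undefined r2, treated
#' as 0.
#'
#' @param gm a [genotype_matrix()].
#' @param r2_max r-squared ceiling (default 0.1).
#' @param window_snps window width in SNPs (default 50).
#' @param step window advance in SNPs (default 5).
#' @return Integer vector of retained site indices (ascending).
#' @export
ld_prune <- function(gm, r2_max = 0.1, window_snps = 50L, step = 5L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- rep(TRUE, ncol(gm$calls))
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    starts <- seq(1L, max(1L, length(idx) - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      cand <- win[keep[win]]
      if (length(cand) < 2L) next
      r2 <- suppressWarnings(
        stats::cor(gm$calls[, cand, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      alive <- rep(TRUE, length(cand))
      for (a in seq_len(length(cand) - 1L)) {
        if (!alive[a]) next
        for (b in seq(a + 1L, length(cand))) {
          if (alive[b] && r2[a, b] > r2_max) alive[b] <- FALSE
        }
      }
      keep[cand[!alive]] <- FALSE
    }
  }
  which(keep)
}
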