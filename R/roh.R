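#' Parameters for PLINK-style ROH detection
#'
#' @param window_snps scanning-window width in SNPs (default 50).
#' @param min_length_bp minimum run length in bp (default 500 kb).
#' @param max_het_per_window heterozygous calls admitted per scanning
#'   window (default 3).
#' @param max_missing_per_window missing calls admitted per scanning
#'   window (default 3).
#' @param hit_proportion minimum fraction of passing windows covering a
#'   SNP for it to enter a run (PLINK default 0.05).
#' @param min_snps_in_run minimum SNPs per final run (default 50).
#' @return An `roh_params` list.
#' @export
roh_params <- function(window_snps = 50L, min_length_bp = 500000,
                       max_het_per_window = 3L,
                       max_missing_per_window = 3L,
                       hit_proportion = 0.05, min_snps_in_run = 50L) {
  stopifnot(window_snps > 0, min_length_bp > 0, max_het_per_window >= 0,
            max_missing_per_window >= 0, hit_proportion > 0,
            min_snps_in_run >= 1)
  structure(list(window_snps = as.integer(window_snps),
                 min_length_bp = min_length_bp,
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 hit_proportion = hit_proportion,
                 min_snps_in_run = as.integer(min_snps_in_run)),
            class = "roh_params")
}

#' Detect runs of homozygosity (PLINK scanning-window algorithm)
#'
#' For each SNP, the proportion of `window_snps`-wide scanning windows
#' covering it that contain at most `max_het_per_window` heterozygous
#' and `max_missing_per_window` missing calls is computed; SNPs whose
#' proportion reaches `hit_proportion` seed candidate runs, and maximal
#' consecutive stretches of such SNPs are kept as segments when they
#' span at least `min_length_bp` and `min_snps_in_run` SNPs.
#' Chromosomes with fewer SNPs than one window are skipped with a
#' warning.
#'
#' @param gm a [genotype_matrix()].
#' @param params an [roh_params()].
#' @return data.frame of segments: `sample`, `chrom`, `start`, `end`
#'   (0-based half-open), `n_snps`, `length_bp`.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(params, "roh_params"))
  W <- params$window_snps
  segs <- list()
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    S <- length(idx)
    if (S < W) {
      warning("chromosome ", ch, " has fewer than ", W,
              " SNPs; skipped")
      next
    }
    pos <- gm$sites$pos[idx]
    nW <- S - W + 1L
    for (smp in rownames(gm$calls)) {
      g <- gm$calls[smp, idx]
      het <- as.integer(!is.na(g) & g == 1L)
      mis <- as.integer(is.na(g))
      cs_h <- c(0L, cumsum(het))
      cs_m <- c(0L, cumsum(mis))
      w <- seq_len(nW)
      pass <- (cs_h[w + W] - cs_h[w]) <= params$max_het_per_window &
        (cs_m[w + W] - cs_m[w]) <= params$max_missing_per_window
      # windows covering SNP j: starts max(1, j-W+1) .. min(j, nW)
      cp <- c(0L, cumsum(as.integer(pass)))
      j <- seq_len(S)
      lo <- pmax(1L, j - W + 1L)
      hi <- pmin(j, nW)
      npass <- cp[hi + 1L] - cp[lo]
      ncov <- hi - lo + 1L
      hit <- npass / ncov >= params$hit_proportion
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        a <- starts[k]
        b <- ends[k]
        len <- pos[b] - pos[a] + 1L
        if (len >= params$min_length_bp &&
            (b - a + 1L) >= params$min_snps_in_run)
          segs[[length(segs) + 1L]] <-
            data.frame(sample = smp, chrom = ch, start = pos[a] - 1L,
                       end = pos[b], n_snps = b - a + 1L,
                       length_bp = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH = S_ROH / L_GEN`, the genome share covered by runs of
#' homozygosity.  The default `L_GEN` is the 2511.4-Mb autosomal length
#' of the UMD 3.1 cattle assembly; override it with the actual genome
#' length when analysing other (e.g. simulated) data.
#'
#' @param segments a [detect_roh()] table.
#' @param samples all sample IDs (so segment-free samples get 0).
#' @param l_gen_bp genome length covered by SNPs, bp.
#' @return data.frame `sample`, `s_roh_bp`, `f_roh`.
#' @export
froh <- function(segments, samples, l_gen_bp = 2511400000) {
  s <- tapply(segments$length_bp, segments$sample, sum)
  s_roh <- ifelse(samples %in% names(s), as.numeric(s[samples]), 0)
  data.frame(sample = samples, s_roh_bp = s_roh,
             f_roh = s_roh / l_gen_bp, stringsAsFactors = FALSE)
}

#' Per-population descriptive statistics of F_ROH
#'
#' @param tab a [froh()] table.
#' @param popmap named character vector, sample -> population.
#' @return data.frame `population`, `n`, `mean`, `median`, `min`,
#'   `max`, `cv_pct` (100 sd/mean; `NA` when the mean is 0).
#' @export
froh_summary <- function(tab, popmap) {
  pops <- unique(unname(popmap[tab$sample]))
  out <- lapply(pops, function(pp) {
    x <- tab$f_roh[popmap[tab$sample] == pp]
    data.frame(population = pp, n = length(x), mean = mean(x),
               median = stats::median(x), min = min(x), max = max(x),
               cv_pct = if (mean(x) > 0)
                 100 * stats::sd(x) / mean(x) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare F_ROH between populations (ANOVA + Tukey HSD)
#'
#' One-way ANOVA on F_ROH followed by Tukey's honest significant
#' difference test; populations are summarized with a compact letter
#' display (groups sharing a letter do not differ at `alpha`).
#'
#' @param tab a [froh()] table.
#' @param popmap named character vector, sample -> population.
#' @param alpha significance level (default 0.05).
#' @return List with `anova` (the fit), `tukey` (pairwise table) and
#'   `letters` (named character vector per population).
#' @export
compare_groups <- function(tab, popmap, alpha = 0.05) {
  pop <- factor(popmap[tab$sample])
  if (nlevels(pop) < 2) stop("need at least 2 populations")
  if (any(table(pop) < 2)) stop("every population needs >= 2 samples")
  d <- data.frame(f_roh = tab$f_roh, pop = pop)
  if (stats::sd(d$f_roh) == 0) {
    # identical data everywhere: nothing distinguishes the groups
    letters <- stats::setNames(rep("a", nlevels(pop)), levels(pop))
    return(list(anova = NULL, tukey = NULL, letters = letters))
  }
  fit <- stats::aov(f_roh ~ pop, data = d)
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$pop
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(pop = "Tukey"))
  letters <- multcomp::cld(glht_fit, level = alpha)$mcletters$Letters
  list(anova = fit, tukey = as.data.frame(tuk), letters = letters)
}

#' Population ROH hotspots
#'
#' Maximal intervals covered by a run of homozygosity in strictly more
#' than `share_fraction` of a population's samples.
#'
#' @param segments a [detect_roh()] table.
#' @param popmap named character vector, sample -> population (its
#'   names define each population's sample count).
#' @param share_fraction sharing threshold, strict (default 0.5).
#' @return data.frame `population`, `chrom`, `start`, `end` (0-based
#'   half-open), `max_shared` (peak sample count inside the interval).
#' @export
roh_hotspots <- function(segments, popmap, share_fraction = 0.5) {
  out <- list()
  for (pp in unique(unname(popmap))) {
    n <- sum(popmap == pp)
    need <- floor(share_fraction * n) + 1L  # strictly more than the fraction
    seg <- segments[popmap[segments$sample] == pp, , drop = FALSE]
    if (!nrow(seg)) next
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, ]
      ir <- IRanges::IRanges(start = s$start + 1L, end = s$end)
      cov <- IRanges::coverage(ir)
      sl <- IRanges::slice(cov, lower = need)
      if (!length(sl)) next
      vr <- IRanges::ranges(sl)
      peaks <- IRanges::viewMaxs(sl)
      out[[length(out) + 1L]] <-
        data.frame(population = pp, chrom = ch,
                   start = IRanges::start(vr) - 1L,
                   end = IRanges::end(vr),
                   max_shared = as.integer(peaks),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(population = character(), chrom = character(),
                      start = integer(), end = integer(),
                      max_shared = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$population, res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}
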