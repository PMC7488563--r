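# Independent oracles: deliberately naive implementations used only to
# check the package's fast code paths.

# every window of `window_bp` bp that holds > max_snps SNPs marks all of
# its SNPs for removal; enumerate windows anchored at every position
oracle_clustered <- function(chrom, pos, max_snps = 5L, window_bp = 20L) {
  drop <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]
    for (a in unique(p)) {
      inw <- which(p >= a & p <= a + window_bp - 1L)
      if (length(inw) > max_snps) drop[idx[inw]] <- TRUE
    }
  }
  drop
}

# quadratic all-pairs interval overlap on 0-based half-open intervals:
# every (query, subject) pair is examined via direct min/max arithmetic
oracle_overlap <- function(query, subject) {
  hits <- vector("list", nrow(query))
  for (i in seq_len(nrow(query))) {
    ov <- pmin(query$end[i], subject$end) -
      pmax(query$start[i], subject$start)
    j <- which(subject$chrom == query$chrom[i] & ov > 0)
    if (length(j))
      hits[[i]] <- data.frame(query = i, subject = j,
                              overlap_bp = ov[j])
  }
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits))
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = numeric()))
  do.call(rbind, hits)
}

# literal transcription of the printed heterozygosity-partition formula,
# one site at a time
oracle_fst_literal <- function(p, cw) {
  vapply(seq_len(nrow(p)), function(i) {
    pbar <- 0
    for (k in seq_len(ncol(p))) pbar <- pbar + cw[i, k] * p[i, k]
    num <- pbar * (1 - pbar)
    for (k in seq_len(ncol(p)))
      num <- num - cw[i, k] * p[i, k] * (1 - p[i, k])
    num / (pbar * (1 - pbar))
  }, 0)
}

# Hudson-style two-population estimator (ratio of averages), used as the
# calibration oracle for the Balding-Nichols simulator
oracle_fst_hudson <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# exhaustive PLINK-style ROH scan: explicit loops over every scanning
# window and every candidate run
oracle_roh_one <- function(g, pos, params) {
  W <- params$window_snps
  S <- length(g)
  if (S < W) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  nW <- S - W + 1L
  pass <- logical(nW)
  for (w in seq_len(nW)) {
    win <- w:(w + W - 1L)
    pass[w] <- sum(het[win]) <= params$max_het_per_window &&
      sum(mis[win]) <= params$max_missing_per_window
  }
  hit <- logical(S)
  for (j in seq_len(S)) {
    covering <- intersect(seq_len(nW), (j - W + 1L):j)
    hit[j] <- mean(pass[covering]) >= params$hit_proportion
  }
  segs <- list()
  j <- 1L
  while (j <= S) {
    if (!hit[j]) {
      j <- j + 1L
      next
    }
    k <- j
    while (k < S && hit[k + 1L]) k <- k + 1L
    len <- pos[k] - pos[j] + 1L
    if (len >= params$min_length_bp && (k - j + 1L) >= params$min_snps_in_run)
      segs[[length(segs) + 1L]] <- c(start = pos[j] - 1L, end = pos[k],
                                     n_snps = k - j + 1L)
    j <- k + 1L
  }
  if (!length(segs)) return(NULL)
  as.data.frame(do.call(rbind, segs))
}

# per-basepair ROH sharing count over a population, position by position
oracle_hotspots <- function(seg, n_samples, share_fraction, limit_bp) {
  count <- integer(limit_bp)
  for (i in seq_len(nrow(seg)))
    count[(seg$start[i] + 1L):seg$end[i]] <-
      count[(seg$start[i] + 1L):seg$end[i]] + 1L
  hot <- count > share_fraction * n_samples
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(NULL)
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

# string-based EHH at one offset: group haplotypes by their literal
# sequence over the sites strictly between the focal site and `to`
# (inclusive of `to`); the focal site itself defines the class, not a
# split, so EHH at distance 0 is 1
oracle_ehh_at <- function(hap, rows, focal, to) {
  if (to == focal) return(1)
  span <- if (to > focal) (focal + 1):to else to:(focal - 1)
  key <- apply(hap[rows, span, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(key)
  n <- length(rows)
  sum(choose(cnt, 2)) / choose(n, 2)
}

# independent trapezoid integration of an EHH curve with the gap rules
oracle_ihh_side <- function(ehh_vals, dist_cm, pos_bp, focal_pos,
                            cutoff = 0.05, max_gap = 2e5,
                            gap_scale = 2e4) {
  total <- 0
  prev_e <- 1
  prev_x <- 0
  prev_p <- focal_pos
  for (i in seq_along(ehh_vals)) {
    gap <- abs(pos_bp[i] - prev_p)
    if (gap > max_gap) return(total)
    if (ehh_vals[i] < cutoff) return(total)
    w <- if (gap > gap_scale) gap_scale / gap else 1
    total <- total + w * (prev_e + ehh_vals[i]) / 2 * (dist_cm[i] - prev_x)
    prev_e <- ehh_vals[i]
    prev_x <- dist_cm[i]
    prev_p <- pos_bp[i]
  }
  total
}
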