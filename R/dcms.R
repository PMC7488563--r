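#' Tile chromosomes into non-overlapping windows
#'
#' Windows are 0-based half-open `[start, start + window_bp)`; the last
#' window of a chromosome keeps full width so every position is covered.
#'
#' @param chrom_lengths named chromosome lengths (bp).
#' @param window_bp window width, default 50 kb.
#' @return data.frame `chrom`, `start`, `end` in genomic order.
#' @export
make_windows <- function(chrom_lengths, window_bp = 50000) {
  stopifnot(window_bp > 0)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  out <- lapply(names(chrom_lengths), function(ch) {
    n <- ceiling(chrom_lengths[[ch]] / window_bp)
    data.frame(chrom = ch, start = (seq_len(n) - 1) * window_bp,
               end = seq_len(n) * window_bp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.window_key <- function(chrom, zero_start, window_bp)
  paste(chrom, zero_start %/% window_bp)

#' Average a per-site statistic in windows
#'
#' Sites map to windows by physical position; window values are means
#' over contributing sites, with zero-support windows left `NA`.  For
#' haplotype statistics set `abs_first = TRUE`: absolute values are
#' taken before averaging.
#'
#' @param values data.frame with `chrom`, `pos` (1-based bp) and the
#'   statistic in `col`.
#' @param windows a [make_windows()] table.
#' @param col name of the value column (default the third column).
#' @param abs_first take `abs()` before averaging.
#' @return List with `value` and `support` vectors aligned to
#'   `windows` rows.
#' @export
window_average <- function(values, windows, col = names(values)[3],
                           abs_first = FALSE) {
  wbp <- windows$end[1] - windows$start[1]
  v <- values[[col]]
  if (abs_first) v <- abs(v)
  keep <- !is.na(v)
  key <- .window_key(values$chrom[keep], values$pos[keep] - 1L, wbp)
  wkey <- .window_key(windows$chrom, windows$start, wbp)
  mu <- tapply(v[keep], key, mean)
  cnt <- tapply(v[keep], key, length)
  m <- match(wkey, names(mu))
  list(value = as.numeric(mu[m]),
       support = ifelse(is.na(m), 0L, as.integer(cnt[m])))
}

#' Assemble a window statistic table
#'
#' @param windows a [make_windows()] table.
#' @param stats named list; each element is a list with `values` (a
#'   per-site data.frame for [window_average()]), optional `col`, and
#'   optional `abs` (absolute-value-first flag).
#' @return A `window_stat_table`: the `windows` data.frame with one
#'   numeric column per statistic; attribute `support` holds the
#'   per-window site counts.
#' @export
window_stat_table <- function(windows, stats) {
  out <- windows
  support <- matrix(0L, nrow(windows), length(stats),
                    dimnames = list(NULL, names(stats)))
  for (nm in names(stats)) {
    s <- stats[[nm]]
    wa <- window_average(s$values, windows,
                         col = if (!is.null(s$col)) s$col else
                           names(s$values)[3],
                         abs_first = isTRUE(s$abs))
    out[[nm]] <- wa$value
    support[, nm] <- wa$support
  }
  attr(out, "support") <- support
  class(out) <- c("window_stat_table", "data.frame")
  out
}

#' De-correlated composite of multiple signals (DCMS)
#'
#' Each statistic column is converted to an upper-tail skew-normal
#' empirical p-value, and the composite score for window i is
#' `DCMS_i = sum_s w_s (-log10 p_si)` with weights
#' `w_s = 1 / sum_t |r_st|` (diagonal included), where r is the Pearson
#' correlation matrix of the `-log10 p` columns over all windows
#' (pairwise complete).  Correlated statistics thus share weight while
#' independent ones contribute fully.  Windows missing some columns are
#' scored from the available ones with the weight total renormalized
#' (flagged in `partial`).
#'
#' @param wst a [window_stat_table()], or a plain data.frame of
#'   statistic columns.
#' @param stat_cols columns to composite; default every numeric column
#'   after `chrom`/`start`/`end`.
#' @return A `dcms_result` list: `windows`, `p` (matrix), `fits` (per
#'   column [fit_skew_normal()]), `weights`, `dcms`, `partial`.
#' @export
dcms_score <- function(wst, stat_cols = NULL) {
  if (is.null(stat_cols))
    stat_cols <- setdiff(names(wst)[vapply(wst, is.numeric, TRUE)],
                         c("start", "end"))
  stopifnot(length(stat_cols) >= 1)
  vals <- as.matrix(as.data.frame(wst)[stat_cols])
  fits <- lapply(stat_cols, function(cc) fit_skew_normal(vals[, cc]))
  names(fits) <- stat_cols
  p <- vapply(stat_cols,
              function(cc) empirical_pvalues(fits[[cc]], vals[, cc]),
              numeric(nrow(vals)))
  comp <- dcms_from_pvalues(p)
  structure(
    list(windows = as.data.frame(wst)[c("chrom", "start", "end")],
         p = p[, names(comp$weights), drop = FALSE],
         fits = fits[names(comp$weights)], weights = comp$weights,
         dcms = comp$dcms, partial = comp$partial),
    class = "dcms_result")
}

#' DCMS weights and scores from a p-value matrix
#'
#' The weighting core of [dcms_score()]: weights
#' `w_s = 1 / sum_t |r_st|` from the Pearson correlation of the
#' `-log10 p` columns, scores `sum_s w_s (-log10 p_s)` with weight
#' renormalization for windows missing some columns.
#'
#' @param p matrix of upper-tail p-values, one column per statistic.
#' @return List: `weights` (named), `dcms`, `partial` (logical flag per
#'   row for renormalized rows).
#' @export
dcms_from_pvalues <- function(p) {
  p <- as.matrix(p)
  if (is.null(colnames(p))) colnames(p) <- paste0("S", seq_len(ncol(p)))
  nlp <- -log10(p)
  cols <- colnames(p)
  if (ncol(nlp) > 1) {
    const <- apply(nlp, 2, function(x) {
      s <- stats::sd(x, na.rm = TRUE)
      is.na(s) || s == 0
    })
    if (any(const)) {
      warning("dropping constant/undefined column(s): ",
              paste(cols[const], collapse = ", "))
      nlp <- nlp[, !const, drop = FALSE]
      cols <- cols[!const]
    }
  }
  if (ncol(nlp) > 1) {
    r <- suppressWarnings(stats::cor(nlp, use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    diag(r) <- 1
    w <- 1 / rowSums(abs(r))
  } else {
    w <- 1
  }
  names(w) <- cols
  avail <- !is.na(nlp)
  w_tot <- sum(w)
  contrib <- nlp
  contrib[!avail] <- 0
  raw <- as.numeric(contrib %*% w)
  w_avail <- as.numeric(avail %*% w)
  list(weights = w,
       dcms = ifelse(w_avail > 0, raw * w_tot / w_avail, NA_real_),
       partial = w_avail > 0 & w_avail < w_tot)
}

#' Select the top fraction of windows by DCMS score
#'
#' `k = floor(fraction * n)` of the `n` scored (non-missing) windows are
#' selected; ties at the cut are broken by genomic order (earlier
#' windows kept) with a warning.
#'
#' @param result a [dcms_score()] result.
#' @param fraction top fraction, default 0.01.
#' @return `result` with added `selected` (logical per window) and
#'   `threshold` (lowest selected score).
#' @export
select_top <- function(result, fraction = 0.01) {
  stopifnot(inherits(result, "dcms_result"),
            fraction > 0, fraction < 1)
  d <- result$dcms
  scored <- which(!is.na(d))
  k <- floor(fraction * length(scored))
  sel <- rep(FALSE, length(d))
  if (k >= 1) {
    ord <- scored[order(-d[scored], scored)]
    top <- ord[seq_len(k)]
    if (length(ord) > k && d[ord[k]] == d[ord[k + 1]])
      warning("ties at the selection cutoff broken by genomic order")
    sel[top] <- TRUE
    result$threshold <- min(d[top])
  } else {
    result$threshold <- NA_real_
  }
  result$selected <- sel
  result
}

#' Merge adjacent selected windows into sweep regions
#'
#' Bookended (start == previous end, same chromosome) selected windows
#' merge into one region whose peak is its highest window score.
#' Idempotent.
#'
#' @param result a [select_top()] result (or a data.frame with `chrom`,
#'   `start`, `end`, `dcms`, `selected`).
#' @return A `sweep_regions` data.frame: `chrom`, `start`, `end`,
#'   `peak_dcms`, `n_windows`, sorted and non-overlapping.
#' @export
merge_regions <- function(result) {
  if (inherits(result, "dcms_result")) {
    df <- cbind(result$windows, dcms = result$dcms,
                selected = result$selected)
  } else df <- result
  df <- df[df$selected, , drop = FALSE]
  if (!nrow(df)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_dcms = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE)
    class(out) <- c("sweep_regions", "data.frame")
    return(out)
  }
  df <- df[order(df$chrom, df$start), ]
  new_run <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                 df$start[-1] != df$end[-nrow(df)])
  grp <- cumsum(new_run)
  out <- data.frame(
    chrom = tapply(df$chrom, grp, `[`, 1),
    start = as.numeric(tapply(df$start, grp, min)),
    end = as.numeric(tapply(df$end, grp, max)),
    peak_dcms = as.numeric(tapply(df$dcms, grp, max)),
    n_windows = as.integer(tapply(df$dcms, grp, length)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sweep_regions", "data.frame")
  out
}
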