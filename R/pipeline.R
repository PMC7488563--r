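.chrom_lengths_of <- function(data, window_bp) {
  if (!is.null(data$config$chrom_lengths))
    return(data$config$chrom_lengths)
  sites <- data$panel$sites
  vapply(split(sites$pos, sites$chrom),
         function(p) ceiling(max(p) / window_bp) * window_bp, 0)
}

.manifest <- function(stage, params) {
  params <- params[order(names(params))]
  list(stage = stage, created = format(Sys.time(), tz = "UTC"),
       params = params, config_hash = rlang::hash(params))
}

#' Within-population sweep scan: CLR + |iHS| -> DCMS -> regions
#'
#' For every population, runs the composite likelihood ratio scan and
#' the standardized iHS scan, averages them (|iHS| absolute first) in
#' non-overlapping windows, composites all `{CLR, |iHS|} x population`
#' columns into one DCMS score, and calls the top-fraction windows as
#' sweep regions.
#'
#' @param data a `sweep_sim` (from [simulate_neutral()]) or a list with
#'   `panel` ([haplotype_panel()]), `genotypes` ([genotype_matrix()]),
#'   and optionally `config$chrom_lengths`.
#' @param window_bp window width (default 50 kb).
#' @param top_fraction selected fraction of windows (default 0.01).
#' @return List: `window_table`, `dcms` (a [select_top()] result),
#'   `regions` ([merge_regions()] with `source = "within"`),
#'   `manifest`.
#' @export
run_within <- function(data, window_bp = 50000, top_fraction = 0.01) {
  panel <- data$panel
  if (is.null(panel)) stop("within-population scan needs phased haplotypes")
  lens <- .chrom_lengths_of(data, window_bp)
  windows <- make_windows(lens, window_bp)
  pops <- unique(unname(panel$popmap))
  stats <- list()
  for (pp in pops) {
    sub <- subset_pop(panel, pp)
    clr <- clr_scan(sub, chrom_lengths = lens, window_bp = window_bp)
    ihs <- standardize_ihs(ihs_scan(sub))
    stats[[paste0("CLR_", pp)]] <-
      list(values = clr[, c("chrom", "pos", "clr")], abs = FALSE)
    stats[[paste0("iHS_", pp)]] <-
      list(values = ihs[, c("chrom", "pos", "std")], abs = TRUE)
  }
  wst <- window_stat_table(windows, stats)
  res <- select_top(dcms_score(wst), top_fraction)
  regions <- merge_regions(res)
  if (nrow(regions)) regions$source <- "within"
  list(window_table = wst, dcms = res, regions = regions,
       manifest = .manifest("within",
                            list(window_bp = window_bp,
                                 top_fraction = top_fraction,
                                 populations = pops,
                                 chrom_lengths = as.list(lens))))
}

#' Cross-population sweep scan: F_ST + |XP-EHH| -> DCMS -> regions
#'
#' For every population pair, computes per-site F_ST and standardized
#' XP-EHH, averages them (|XP-EHH| absolute first) in windows,
#' composites all `{F_ST, |XP-EHH|} x pair` columns into one DCMS
#' score, and calls the top-fraction windows.
#'
#' @inheritParams run_within
#' @return As [run_within()], with `source = "cross"`.
#' @export
run_cross <- function(data, window_bp = 50000, top_fraction = 0.01) {
  panel <- data$panel
  gm <- data$genotypes
  if (is.null(panel) || is.null(gm))
    stop("cross-population scan needs haplotypes and genotypes")
  lens <- .chrom_lengths_of(data, window_bp)
  windows <- make_windows(lens, window_bp)
  pops <- unique(unname(panel$popmap))
  if (length(pops) < 2) stop("need at least 2 populations")
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  stats <- list()
  for (pr in pairs) {
    tag <- paste(pr, collapse = "_")
    fst <- fst_pair(gm, pr[1], pr[2])
    xp <- standardize_xpehh(xpehh_scan(panel, pr[1], pr[2]))
    stats[[paste0("FST_", tag)]] <-
      list(values = fst[, c("chrom", "pos", "fst")], abs = FALSE)
    stats[[paste0("XPEHH_", tag)]] <-
      list(values = xp[, c("chrom", "pos", "std")], abs = TRUE)
  }
  wst <- window_stat_table(windows, stats)
  res <- select_top(dcms_score(wst), top_fraction)
  regions <- merge_regions(res)
  if (nrow(regions)) regions$source <- "cross"
  list(window_table = wst, dcms = res, regions = regions,
       manifest = .manifest("cross",
                            list(window_bp = window_bp,
                                 top_fraction = top_fraction,
                                 pairs = vapply(pairs, paste, "",
                                                collapse = "_"),
                                 chrom_lengths = as.list(lens))))
}

#' ROH stage: segments, F_ROH, hotspots, and sweep intersections
#'
#' @param data as in [run_within()] (needs `genotypes`).
#' @param params an [roh_params()].
#' @param l_gen_bp genome length for F_ROH; defaults to the simulated
#'   genome length when available, else the cattle UMD 3.1 value used
#'   by [froh()].
#' @param sweeps optional [merge_regions()] table; when given, the
#'   hotspot x sweep intersection is computed.
#' @return List: `segments`, `froh`, `summary`, `hotspots`,
#'   `intersections` (or `NULL`), `manifest`.
#' @export
run_roh <- function(data, params = roh_params(), l_gen_bp = NULL,
                    sweeps = NULL) {
  gm <- data$genotypes
  if (is.null(gm)) stop("ROH stage needs genotypes")
  if (is.null(l_gen_bp))
    l_gen_bp <- if (!is.null(data$config$chrom_lengths))
      sum(data$config$chrom_lengths) else formals(froh)$l_gen_bp
  segments <- detect_roh(gm, params)
  tab <- froh(segments, rownames(gm$calls), l_gen_bp)
  hotspots <- roh_hotspots(segments, gm$popmap)
  inter <- if (!is.null(sweeps))
    intersect_sweeps_hotspots(sweeps, hotspots) else NULL
  list(segments = segments, froh = tab,
       summary = froh_summary(tab, gm$popmap), hotspots = hotspots,
       intersections = inter,
       manifest = .manifest("roh",
                            list(params = unclass(params),
                                 l_gen_bp = as.numeric(l_gen_bp))))
}
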