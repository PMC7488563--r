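.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Read an interval feature table (BED or 1-based TSV)
#'
#' BED input keeps its 0-based half-open coordinates; TSV input is
#' declared 1-based closed (header `chrom`, `start`, `end`, optional
#' `name`) and is converted.  Records with `end <= start` (after
#' conversion) are rejected with a message; output is sorted, stable on
#' ties.
#'
#' @param path file path.
#' @param format `"bed"` or `"tsv"`.
#' @param source label stored in the `source` column (e.g. "gene",
#'   "qtl").
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `source`.
#' @export
read_features <- function(path, format = c("bed", "tsv"),
                          source = "feature") {
  format <- match.arg(format)
  if (format == "bed") {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    names(tab)[1:3] <- c("chrom", "start", "end")
    tab$name <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
      paste0("feature_", seq_len(nrow(tab)))
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end") %in% names(tab)))
    tab$start <- tab$start - 1L  # 1-based closed -> 0-based half-open
    if (is.null(tab$name)) tab$name <- paste0("feature_", seq_len(nrow(tab)))
  }
  bad <- tab$end <= tab$start
  if (any(bad)) {
    message(sum(bad), " record(s) with end <= start rejected")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab <- tab[order(tab$chrom, tab$start, tab$end), ]
  rownames(tab) <- NULL
  data.frame(chrom = as.character(tab$chrom), start = tab$start,
             end = tab$end, name = tab$name, source = source,
             stringsAsFactors = FALSE)
}

#' Write a feature table as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if (!is.null(df$name)) df$name else "."
  utils::write.table(
    data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE), name),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}

#' All overlapping interval pairs between two tables
#'
#' @param query,subject data.frames with `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `name`.
#' @return data.frame with one row per overlapping pair: query and
#'   subject indices, names and coordinates, and `overlap_bp` (> 0).
#' @export
overlap_features <- function(query, subject) {
  empty <- data.frame(query = integer(), subject = integer(),
                      chrom = character(), q_start = numeric(),
                      q_end = numeric(), s_start = numeric(),
                      s_end = numeric(), q_name = character(),
                      s_name = character(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(query) || !nrow(subject)) return(empty)
  gq <- .as_granges(query)
  gs <- .as_granges(subject)
  # differing chromosome sets between the two tables are expected
  h <- suppressWarnings(GenomicRanges::findOverlaps(gq, gs))
  if (!length(h)) return(empty)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  inter <- GenomicRanges::pintersect(gq[qi], gs[si])
  data.frame(
    query = qi, subject = si, chrom = query$chrom[qi],
    q_start = query$start[qi], q_end = query$end[qi],
    s_start = subject$start[si], s_end = subject$end[si],
    q_name = if (!is.null(query$name)) query$name[qi] else NA_character_,
    s_name = if (!is.null(subject$name)) subject$name[si] else
      NA_character_,
    overlap_bp = GenomicRanges::width(inter), stringsAsFactors = FALSE)
}

#' Nearest subject feature for non-overlapping queries
#'
#' For each query with no overlapping subject, reports the
#' minimum-gap subject on the same chromosome and the gap in bp;
#' queries beyond `max_distance_bp` (or with no same-chromosome
#' subject) get no entry.
#'
#' @param query,subject feature data.frames (0-based half-open).
#' @param max_distance_bp optional cap on the reported gap.
#' @return data.frame `query`, `subject`, `chrom`, `q_name`, `s_name`,
#'   `distance_bp` (0 for the overlapping queries, reported via the
#'   overlap path).
#' @export
nearest_features <- function(query, subject, max_distance_bp = NULL) {
  if (!nrow(query) || !nrow(subject))
    return(data.frame(query = integer(), subject = integer(),
                      chrom = character(), q_name = character(),
                      s_name = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE))
  gq <- .as_granges(query)
  gs <- .as_granges(subject)
  # disjoint chromosome sets are an expected no-hit case, not a problem
  h <- suppressWarnings(GenomicRanges::distanceToNearest(gq, gs))
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  d <- S4Vectors::mcols(h)$distance
  out <- data.frame(
    query = qi, subject = si, chrom = query$chrom[qi],
    q_name = if (!is.null(query$name)) query$name[qi] else NA_character_,
    s_name = if (!is.null(subject$name)) subject$name[si] else
      NA_character_,
    distance_bp = as.numeric(d), stringsAsFactors = FALSE)
  if (!is.null(max_distance_bp))
    out <- out[out$distance_bp <= max_distance_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect sweep regions with ROH hotspots
#'
#' The shared-signal table: every interval where a called sweep region
#' and a population ROH hotspot overlap, annotated with the sweep run
#' and the hotspot's population.
#'
#' @param sweeps a [merge_regions()] table (optionally with a `source`
#'   column naming the run, e.g. "within" or "cross").
#' @param hotspots a [roh_hotspots()] table.
#' @return data.frame `chrom`, `start`, `end` (the shared interval,
#'   0-based half-open), `source`, `population`, `peak_dcms`.
#' @export
intersect_sweeps_hotspots <- function(sweeps, hotspots) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), source = character(),
                      population = character(), peak_dcms = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(sweeps) || !nrow(hotspots)) return(empty)
  ov <- overlap_features(sweeps, hotspots)
  if (!nrow(ov)) return(empty)
  data.frame(
    chrom = ov$chrom,
    start = pmax(ov$q_start, ov$s_start),
    end = pmin(ov$q_end, ov$s_end),
    source = if (!is.null(sweeps$source)) sweeps$source[ov$query] else
      NA_character_,
    population = hotspots$population[ov$subject],
    peak_dcms = if (!is.null(sweeps$peak_dcms))
      sweeps$peak_dcms[ov$query] else NA_real_,
    stringsAsFactors = FALSE)
}
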