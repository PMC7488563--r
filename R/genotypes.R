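#' Genotype matrix container
#'
#' Bundles diploid genotype calls for samples x biallelic SNP sites with
#' per-site metadata and a sample-to-population map.  Calls count copies
#' of the alternate allele (0/1/2); `NA` marks a missing genotype and is
#' excluded from every allele-frequency denominator downstream.
#'
#' @param calls integer matrix, samples in rows, sites in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param sites data.frame with at least `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; optionally `ancestral` and caller-annotation columns
#'   (`FS`, `MQ`, `BaseQRankSum`, `MQRankSum`, `ReadPosRankSum`, `DP`).
#'   Sites must be sorted with strictly increasing `pos` within `chrom`.
#' @param popmap named character vector mapping every sample (rowname of
#'   `calls`) to a population label.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, popmap) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            ncol(calls) == nrow(sites))
  if (is.null(rownames(calls)))
    stop("calls must carry sample IDs as rownames")
  missing_pop <- setdiff(rownames(calls), names(popmap))
  if (length(missing_pop))
    stop("samples missing from the population map: ",
         paste(missing_pop, collapse = ", "))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (!"ancestral" %in% names(sites)) sites$ancestral <- NA_character_
  .check_sorted_sites(sites)
  structure(
    list(calls = calls, sites = sites,
         popmap = popmap[rownames(calls)]),
    class = "genotype_matrix")
}

#' Phased haplotype panel container
#'
#' Phased binary haplotypes (2 per diploid sample) over the sites of a
#' [genotype_matrix()].  Allele 1 is the derived allele where the site is
#' polarized by an ancestral call, otherwise the alternate allele.  The
#' genetic map defaults to the 1 Mb ~ 1 cM convention, `pos / 1e6`.
#'
#' @param hap integer 0/1 matrix, 2n haplotypes in rows (rownames
#'   `<sample>_1`, `<sample>_2`), sites in columns.
#' @param sites per-site data.frame as in [genotype_matrix()].
#' @param popmap named character vector, sample -> population.
#' @param map_cM per-site genetic position in centimorgans; default
#'   `sites$pos / 1e6`.
#' @param phased logical flag, recorded as-is.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(hap, sites, popmap,
                            map_cM = sites$pos / 1e6, phased = TRUE) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  stopifnot(ncol(hap) == nrow(sites), nrow(hap) %% 2L == 0L,
            all(hap %in% c(0L, 1L)), length(map_cM) == nrow(sites))
  if (is.null(rownames(hap)))
    stop("hap must carry haplotype IDs as rownames (<sample>_1, <sample>_2)")
  sample_of <- sub("_[12]$", "", rownames(hap))
  missing_pop <- setdiff(unique(sample_of), names(popmap))
  if (length(missing_pop))
    stop("samples missing from the population map: ",
         paste(missing_pop, collapse = ", "))
  if (!"ancestral" %in% names(sites)) sites$ancestral <- NA_character_
  .check_sorted_sites(sites)
  for (ch in unique(sites$chrom)) {
    m <- map_cM[sites$chrom == ch]
    if (is.unsorted(m)) stop("map_cM must be non-decreasing within chrom")
  }
  structure(
    list(hap = hap, sites = sites, popmap = popmap,
         sample = sample_of, map_cM = map_cM, phased = isTRUE(phased)),
    class = "haplotype_panel")
}

.check_sorted_sites <- function(sites) {
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(p < 1)) stop("positions must be >= 1")
    if (any(diff(p) <= 0))
      stop("sites must be strictly increasing within chromosome ", ch)
  }
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "sites;", length(unique(x$popmap)), "population(s)\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(table(x$popmap)), table(x$popmap)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$hap), "haplotypes x", ncol(x$hap),
      "sites;", if (x$phased) "phased" else "unphased", "\n")
  invisible(x)
}

#' Subset a genotype matrix or haplotype panel to a set of sites
#'
#' @param x a `genotype_matrix` or `haplotype_panel`.
#' @param idx integer or logical site index.
#' @return Object of the same class restricted to the selected sites.
#' @export
subset_sites <- function(x, idx) {
  if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$calls[, idx, drop = FALSE],
                    x$sites[idx, , drop = FALSE], x$popmap)
  } else if (inherits(x, "haplotype_panel")) {
    haplotype_panel(x$hap[, idx, drop = FALSE],
                    x$sites[idx, , drop = FALSE], x$popmap,
                    map_cM = x$map_cM[idx], phased = x$phased)
  } else stop("unsupported class")
}

#' Restrict a haplotype panel to one population
#'
#' @param panel a `haplotype_panel`.
#' @param pop population label present in the panel's popmap.
#' @return A `haplotype_panel` containing only that population's
#'   haplotypes.
#' @export
subset_pop <- function(panel, pop) {
  stopifnot(inherits(panel, "haplotype_panel"))
  keep <- panel$popmap[panel$sample] == pop
  if (!any(keep)) stop("no samples in population ", pop)
  haplotype_panel(panel$hap[keep, , drop = FALSE], panel$sites,
                  panel$popmap[panel$popmap == pop],
                  map_cM = panel$map_cM, phased = panel$phased)
}

#' Collapse a phased haplotype panel into diploid genotype calls
#'
#' @param panel a `haplotype_panel`.
#' @return A [genotype_matrix()] whose calls are the per-sample sums of
#'   the two haplotype alleles.
#' @export
genotypes_from_panel <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  samples <- unique(panel$sample)
  calls <- t(vapply(samples, function(s) {
    rows <- which(panel$sample == s)
    as.integer(panel$hap[rows[1], ] + panel$hap[rows[2], ])
  }, integer(ncol(panel$hap))))
  rownames(calls) <- samples
  genotype_matrix(calls, panel$sites, panel$popmap)
}
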