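#' Read a sample-to-population map
#'
#' Two-column TSV, `sample<TAB>population`, no header.
#'
#' @param path file path.
#' @return Named character vector, sample -> population.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("sample", "population"),
                           colClasses = "character")
  stats::setNames(tab$population, tab$sample)
}

#' Read a VCF into genotype and haplotype containers
#'
#' Keeps biallelic SNPs only; indels and multi-allelic records are
#' dropped and counted in the returned log.  Genotypes are encoded as
#' alternate-allele counts 0/1/2 with `NA` for missing.  When every
#' genotype uses the phased `|` separator a [haplotype_panel()] is built
#' as well (allele 1 = ALT; use [polarize_panel()] to recode to derived).
#' Caller statistics (FS, MQ, BaseQRankSum, MQRankSum, ReadPosRankSum,
#' DP) are pulled from INFO when present.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param popmap_path popmap TSV covering all samples in the VCF.
#' @return List with `genotypes` ([genotype_matrix()]), `haplotypes`
#'   ([haplotype_panel()] or `NULL` when unphased), and `log` (named
#'   removal counts).
#' @export
read_vcf <- function(path, popmap_path) {
  popmap <- read_popmap(popmap_path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT %in% c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  indel <- !multi & !snp
  log <- c(multiallelic_removed = sum(multi), indel_removed = sum(indel))
  if (!any(snp)) stop("no biallelic SNPs in ", path)
  vcf <- vcf[snp, ]
  fix <- fix[snp, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  missing_pop <- setdiff(samples, names(popmap))
  if (length(missing_pop))
    stop("samples missing from the population map: ",
         paste(missing_pop, collapse = ", "))

  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  cal <- matrix(NA_integer_, nrow = nrow(fix), ncol = length(samples))
  cal[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  calls <- t(cal)
  rownames(calls) <- samples

  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  for (field in c("FS", "MQ", "BaseQRankSum", "MQRankSum",
                  "ReadPosRankSum", "DP")) {
    val <- suppressWarnings(
      vcfR::extract.info(vcf, element = field, as.numeric = TRUE))
    if (!is.null(val) && !all(is.na(val))) sites[[field]] <- val
  }
  gm <- genotype_matrix(calls, sites, popmap)

  panel <- NULL
  sep <- substr(gt, 2, 2)
  phased <- all(sep[ok] == "|") && all(ok)
  if (phased) {
    hap <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(fix))
    rownames(hap) <- as.vector(rbind(paste0(samples, "_1"),
                                     paste0(samples, "_2")))
    hap[seq(1, nrow(hap), 2), ] <- t(matrix(as.integer(a1),
                                            nrow = nrow(fix)))
    hap[seq(2, nrow(hap), 2), ] <- t(matrix(as.integer(a2),
                                            nrow = nrow(fix)))
    panel <- haplotype_panel(hap, gm$sites, popmap)
  }
  list(genotypes = gm, haplotypes = panel, log = log)
}

#' Write genotypes or phased haplotypes as a VCF 4.2 text file
#'
#' @param x a [haplotype_panel()] (phased `a|b` genotypes) or a
#'   [genotype_matrix()] (unphased `a/b`; heterozygotes written `0/1`).
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "haplotype_panel")) {
    sites <- x$sites
    samples <- unique(x$sample)
    gt <- vapply(seq_along(samples), function(i) {
      rows <- which(x$sample == samples[i])
      paste0(x$hap[rows[1], ], "|", x$hap[rows[2], ])
    }, character(nrow(sites)))
  } else if (inherits(x, "genotype_matrix")) {
    sites <- x$sites
    samples <- rownames(x$calls)
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- vapply(seq_along(samples), function(i) {
      g <- x$calls[i, ]
      out <- rep("./.", length(g))
      out[!is.na(g)] <- code[as.character(g[!is.na(g)])]
      out
    }, character(nrow(sites)))
  } else stop("unsupported class")
  gt <- matrix(gt, nrow = nrow(sites))

  ann_fields <- intersect(c("FS", "MQ", "BaseQRankSum", "MQRankSum",
                            "ReadPosRankSum", "DP"), names(sites))
  info <- rep(".", nrow(sites))
  if (length(ann_fields)) {
    parts <- lapply(ann_fields, function(f)
      ifelse(is.na(sites[[f]]), NA_character_,
             paste0(f, "=", format(sites[[f]], trim = TRUE, digits = 10))))
    info <- apply(do.call(cbind, parts), 1, function(r)
      if (all(is.na(r))) "." else paste(r[!is.na(r)], collapse = ";"))
  }
  if ("ancestral" %in% names(sites) && any(!is.na(sites$ancestral))) {
    aa <- ifelse(is.na(sites$ancestral), NA_character_,
                 paste0("AA=", sites$ancestral))
    info <- ifelse(is.na(aa), info,
                   ifelse(info == ".", aa, paste(info, aa, sep = ";")))
  }

  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(sites$chrom), ">"),
           "##INFO=<ID=AA,Number=1,Type=Character,Description=\"Ancestral allele\">",
           paste0("##INFO=<ID=", ann_fields,
                  ",Number=1,Type=Float,Description=\"Caller statistic\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ancestral-allele table and attach it to a container
#'
#' @param x a `genotype_matrix` or `haplotype_panel`.
#' @param path TSV with columns `chrom`, `pos`, `ancestral` (1-based
#'   positions, single bases).
#' @return `x` with its `sites$ancestral` filled where the table matches
#'   a site and the base equals REF or ALT; other sites stay unknown.
#' @export
attach_ancestral <- function(x, path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer",
                                          "character"))
  key <- paste(x$sites$chrom, x$sites$pos)
  m <- match(key, paste(tab$chrom, tab$pos))
  anc <- tab$ancestral[m]
  valid <- !is.na(anc) & (anc == x$sites$ref | anc == x$sites$alt)
  x$sites$ancestral[valid] <- anc[valid]
  x
}

#' Recode haplotype alleles so that 1 = derived allele
#'
#' Sites whose ancestral base equals ALT are flipped; sites with no
#' ancestral call fall back to treating REF as ancestral (coding
#' unchanged) and are flagged.
#'
#' @param panel a [haplotype_panel()].
#' @return The panel with a logical `sites$polarized` column; flipped
#'   sites have ref/alt-coded alleles inverted in `hap`.
#' @export
polarize_panel <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  anc <- panel$sites$ancestral
  flip <- !is.na(anc) & anc == panel$sites$alt
  if (any(flip)) panel$hap[, flip] <- 1L - panel$hap[, flip]
  panel$sites$polarized <- !is.na(anc)
  panel
}
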