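#' Configuration for the synthetic multi-population simulator
#'
#' The generator emulates a small re-sequencing study design: a few
#' populations of about a dozen diploids each, allele-frequency
#' divergence following the Balding-Nichols model, phased haplotypes on
#' a 1 Mb ~ 1 cM map, and (optionally) injected hard sweeps and
#' autozygous tracts that supply ground truth.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploids per population (scalar or length-`n_pops`).
#' @param chrom_lengths chromosome lengths in bp.
#' @param snp_density expected SNPs per bp (default 1/1000).
#' @param fst_target Balding-Nichols divergence parameter F (scalar or
#'   per population), in (0, 1).
#' @param sweep_specs data.frame of sweeps to inject, columns `pop`,
#'   `chrom`, `position`, `final_freq`, `core_halflength`; or `NULL`.
#' @param roh_specs data.frame of autozygosity to inject, columns `pop`,
#'   `target_fraction`, `tract_mean_bp`; or `NULL`.
#' @param seed RNG seed (integer) or `NULL` to use the current state.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 4L, n_per_pop = 12L,
                       chrom_lengths = rep(1e7, 5), snp_density = 1 / 1000,
                       fst_target = 0.05, sweep_specs = NULL,
                       roh_specs = NULL, seed = NULL) {
  stopifnot(n_pops >= 1, all(fst_target > 0), all(fst_target < 1),
            all(chrom_lengths > 0), snp_density > 0)
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  fst_target <- rep_len(fst_target, n_pops)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  structure(list(n_pops = as.integer(n_pops), n_per_pop = n_per_pop,
                 chrom_lengths = chrom_lengths, snp_density = snp_density,
                 fst_target = fst_target, sweep_specs = sweep_specs,
                 roh_specs = roh_specs, seed = seed),
            class = "sim_config")
}

#' Simulate neutral multi-population phased genotypes
#'
#' Per-site ancestral derived-allele frequencies are drawn uniformly on
#' (0.05, 0.95); each population's frequency is drawn from the
#' Balding-Nichols distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)`; alleles
#' are then sampled independently per site (linkage-equilibrium
#' baseline).  Haplotypes are coded 1 = derived, the ancestral allele is
#' recorded (REF), and the genetic map is `pos/1e6` cM.
#'
#' @param cfg a [sim_config()]; its `seed` (when non-`NULL`) seeds the
#'   RNG so equal seeds give bit-identical output.
#' @return A `sweep_sim` list: `panel` ([haplotype_panel()]),
#'   `genotypes` ([genotype_matrix()]), `truth` (sweeps, tracts,
#'   per-site ancestral frequency), `config`.
#' @export
simulate_neutral <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sim <- .simulate_neutral_core(cfg)
  if (!is.null(cfg$sweep_specs))
    for (i in seq_len(nrow(cfg$sweep_specs))) {
      s <- cfg$sweep_specs[i, ]
      sim <- inject_sweep(sim, pop = s$pop, chrom = s$chrom,
                          position = s$position,
                          final_freq = s$final_freq,
                          core_halflength = s$core_halflength)
    }
  if (!is.null(cfg$roh_specs))
    for (i in seq_len(nrow(cfg$roh_specs))) {
      r <- cfg$roh_specs[i, ]
      sim <- inject_autozygosity(sim, pop = r$pop,
                                 target_fraction = r$target_fraction,
                                 tract_mean_bp = r$tract_mean_bp)
    }
  sim
}

.simulate_neutral_core <- function(cfg) {
  chroms <- names(cfg$chrom_lengths)
  site_list <- lapply(seq_along(chroms), function(ci) {
    L <- cfg$chrom_lengths[ci]
    n <- max(2L, round(L * cfg$snp_density))
    pos <- sort(sample.int(L, n))
    data.frame(chrom = chroms[ci], pos = pos, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  S <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, S, replace = TRUE)
  sites$alt <- vapply(sites$ref,
                      function(b) sample(setdiff(bases, b), 1L), "")
  sites$ancestral <- sites$ref

  p0 <- stats::runif(S, 0.05, 0.95)
  pops <- paste0("pop", seq_len(cfg$n_pops))
  hap_list <- vector("list", cfg$n_pops)
  popmap <- character(0)
  for (k in seq_len(cfg$n_pops)) {
    F <- cfg$fst_target[k]
    pk <- stats::rbeta(S, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    nh <- 2L * cfg$n_per_pop[k]
    h <- matrix(stats::rbinom(nh * S, 1L, rep(pk, each = nh)),
                nrow = nh, ncol = S)
    samples <- sprintf("%s_s%02d", pops[k], seq_len(cfg$n_per_pop[k]))
    rownames(h) <- as.vector(rbind(paste0(samples, "_1"),
                                   paste0(samples, "_2")))
    popmap <- c(popmap, stats::setNames(rep(pops[k], length(samples)),
                                        samples))
    hap_list[[k]] <- h
  }
  hap <- do.call(rbind, hap_list)
  panel <- haplotype_panel(hap, sites, popmap)
  panel$sites$polarized <- TRUE
  structure(
    list(panel = panel, genotypes = genotypes_from_panel(panel),
         truth = list(
           sweeps = data.frame(pop = character(), chrom = character(),
                               pos = integer(), site = integer(),
                               final_freq = numeric(),
                               core_halflength = numeric(),
                               stringsAsFactors = FALSE),
           tracts = data.frame(sample = character(), chrom = character(),
                               start = integer(), end = integer(),
                               stringsAsFactors = FALSE),
           ancestral_freq = p0),
         config = cfg),
    class = "sweep_sim")
}

#' Inject a hard selective sweep into a simulated panel
#'
#' In the target population, a randomly chosen core haplotype is copied
#' over every haplotype carrying the favored (derived) allele across a
#' geometric-length interval around the sweep site (mean
#' `core_halflength` bp per side, drawn independently per haplotype and
#' side), and the favored-allele frequency is lifted to `final_freq` by
#' converting randomly chosen non-carriers into carriers.  This creates
#' the three signal classes a sweep scan responds to: elevated
#' differentiation, a high-frequency-derived-skewed SFS, and a long
#' shared haplotype.
#'
#' @param sim a `sweep_sim` from [simulate_neutral()].
#' @param pop target population label.
#' @param chrom chromosome of the sweep.
#' @param position target bp position; the sweep lands on the nearest
#'   simulated SNP.
#' @param final_freq derived-allele frequency after the sweep.
#' @param core_halflength mean one-sided extent of the copied core
#'   haplotype, bp.
#' @return The modified `sweep_sim`; `truth$sweeps` gains one row.
#' @export
inject_sweep <- function(sim, pop, chrom, position, final_freq = 0.95,
                         core_halflength = 2e5) {
  stopifnot(inherits(sim, "sweep_sim"), final_freq >= 0, final_freq <= 1)
  panel <- sim$panel
  on_chr <- which(panel$sites$chrom == chrom)
  if (!length(on_chr)) stop("no sites on chromosome ", chrom)
  rows <- which(panel$popmap[panel$sample] == pop)
  if (!length(rows)) stop("no samples in population ", pop)
  # land on the nearest site that segregates in the target population
  pf <- colMeans(panel$hap[rows, on_chr, drop = FALSE])
  poly <- on_chr[pf > 0 & pf < 1]
  if (!length(poly))
    stop("no site polymorphic in population ", pop, " on ", chrom)
  s <- poly[which.min(abs(panel$sites$pos[poly] - position))]
  alleles <- panel$hap[rows, s]

  carriers <- rows[alleles == 1L]
  core <- sample(carriers, 1L)
  n_target <- round(final_freq * length(rows))
  if (n_target > length(carriers)) {
    converts <- sample(rows[alleles == 0L], n_target - length(carriers))
    panel$hap[converts, s] <- 1L
    carriers <- c(carriers, converts)
  }
  pos_s <- panel$sites$pos[s]
  chr_pos <- panel$sites$pos[on_chr]
  core_alleles <- panel$hap[core, ]
  for (h in carriers) {
    ext_l <- if (core_halflength > 0)
      stats::rexp(1, 1 / core_halflength) else 0
    ext_r <- if (core_halflength > 0)
      stats::rexp(1, 1 / core_halflength) else 0
    span <- on_chr[chr_pos >= pos_s - ext_l & chr_pos <= pos_s + ext_r]
    panel$hap[h, span] <- core_alleles[span]
  }
  sim$panel <- panel
  sim$genotypes <- genotypes_from_panel(panel)
  sim$truth$sweeps <- rbind(
    sim$truth$sweeps,
    data.frame(pop = pop, chrom = chrom, pos = pos_s, site = s,
               final_freq = final_freq,
               core_halflength = core_halflength,
               stringsAsFactors = FALSE))
  sim
}

#' Inject autozygous tracts of controlled total length
#'
#' For each selected individual, non-overlapping tracts with
#' exponentially distributed lengths (mean `tract_mean_bp`, the final
#' tract trimmed so the total lands on target) are placed uniformly at
#' random; within a tract the individual's second haplotype is
#' overwritten by the first, making every site homozygous.
#'
#' @param sim a `sweep_sim`.
#' @param pop population whose samples receive tracts (default: all).
#' @param target_fraction target autozygous share of the genome, in
#'   `[0, 1)`.
#' @param tract_mean_bp mean tract length, bp.
#' @param max_tries placement retries per tract before giving up.
#' @return The modified `sweep_sim`; `truth$tracts` gains the placed
#'   intervals (0-based half-open).
#' @export
inject_autozygosity <- function(sim, pop = NULL, target_fraction,
                                tract_mean_bp = 2e6, max_tries = 1000L) {
  stopifnot(inherits(sim, "sweep_sim"),
            target_fraction >= 0, target_fraction < 1)
  if (target_fraction == 0) return(sim)
  panel <- sim$panel
  samples <- unique(panel$sample)
  if (!is.null(pop)) samples <- samples[panel$popmap[samples] == pop]
  lens <- sim$config$chrom_lengths
  l_gen <- sum(lens)
  target_bp <- target_fraction * l_gen

  new_tracts <- list()
  for (smp in samples) {
    placed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
    total <- 0
    tries <- 0L
    while (total < target_bp) {
      L <- min(stats::rexp(1, 1 / tract_mean_bp), target_bp - total)
      L <- max(L, 1)
      ci <- sample.int(length(lens), 1L, prob = lens)
      if (L >= lens[ci]) {
        tries <- tries + 1L
        if (tries > max_tries) stop("could not place tracts for ", smp)
        next
      }
      start <- floor(stats::runif(1, 0, lens[ci] - L))
      end <- start + ceiling(L)
      same <- placed[placed$chrom == names(lens)[ci], ]
      if (nrow(same) && any(start < same$end & end > same$start)) {
        tries <- tries + 1L
        if (tries > max_tries) stop("could not place tracts for ", smp)
        next
      }
      placed <- rbind(placed, data.frame(chrom = names(lens)[ci],
                                         start = start, end = end))
      total <- total + (end - start)
    }
    rows <- which(panel$sample == smp)
    for (i in seq_len(nrow(placed))) {
      idx <- which(panel$sites$chrom == placed$chrom[i] &
                     panel$sites$pos > placed$start[i] &
                     panel$sites$pos <= placed$end[i])
      panel$hap[rows[2], idx] <- panel$hap[rows[1], idx]
    }
    placed$sample <- smp
    new_tracts[[smp]] <- placed
  }
  sim$panel <- panel
  sim$genotypes <- genotypes_from_panel(panel)
  add <- do.call(rbind, new_tracts)
  sim$truth$tracts <- rbind(sim$truth$tracts,
                            add[, c("sample", "chrom", "start", "end")])
  rownames(sim$truth$tracts) <- NULL
  sim
}

#' Simulate a per-site caller-annotation table
#'
#' Emits the six statistics the hard filters act on, with shapes that
#' resemble real caller output: FS heavy-tailed positive (lognormal),
#' rank sums approximately normal, DP overdispersed (gamma with
#' CV ~ 0.45), and MQ a high mode with a low-quality tail.
#'
#' @param n_sites number of rows.
#' @param seed optional RNG seed.
#' @return data.frame with columns FS, BaseQRankSum, MQRankSum,
#'   ReadPosRankSum, DP, MQ.
#' @export
simulate_annotation_table <- function(n_sites, seed = NULL) {
  stopifnot(n_sites > 0)
  if (!is.null(seed)) set.seed(seed)
  low <- stats::runif(n_sites) < 0.03
  data.frame(
    FS = stats::rlnorm(n_sites, log(2), 1),
    BaseQRankSum = stats::rnorm(n_sites, 0, 1.3),
    MQRankSum = stats::rnorm(n_sites, 0, 1),
    ReadPosRankSum = stats::rnorm(n_sites, 0, 1),
    DP = stats::rgamma(n_sites, shape = 5, scale = 100),
    MQ = ifelse(low, stats::runif(n_sites, 5, 40),
                stats::rnorm(n_sites, 60, 1.5)))
}
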