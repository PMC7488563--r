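#' Principal component analysis of genotypes
#'
#' Missing calls are mean-imputed per site, monomorphic sites dropped,
#' sites centered by their mean call and (by default) scaled by
#' `sqrt(p(1-p))` with p the alternate-allele frequency; the principal
#' axes come from the singular value decomposition of the resulting
#' samples x sites matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param sites optional site index to use (e.g. an [ld_prune()]
#'   result).
#' @param scale divide each site by `sqrt(p(1-p))` (default `TRUE`).
#' @return A `pca_result` list: `coordinates` (samples x components,
#'   rownames = samples) and `variance_explained` (fraction per
#'   component, non-increasing).
#' @export
pca_genotypes <- function(gm, sites = NULL, scale = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$calls) >= 2)
  X <- gm$calls
  if (!is.null(sites)) X <- X[, sites, drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  for (jj in which(colSums(is.na(X)) > 0))
    X[is.na(X[, jj]), jj] <- mu[jj]
  v <- apply(X, 2, stats::var)
  keep <- !is.na(v) & v > 0
  X <- X[, keep, drop = FALSE]
  mu <- mu[keep]
  X <- sweep(X, 2, mu)
  if (scale) {
    p <- mu / 2
    X <- sweep(X, 2, sqrt(p * (1 - p)), "/")
  }
  sv <- svd(X)
  d2 <- sv$d^2
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(coords) <- rownames(gm$calls)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 variance_explained = d2 / sum(d2)),
            class = "pca_result")
}

.amova_phi <- function(d2, pop) {
  N <- length(pop)
  groups <- split(seq_len(N), pop)
  k <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- sum(vapply(groups, function(g) {
    if (length(g) < 2) return(0)
    sum(d2[g, g][upper.tri(d2[g, g])]) / length(g)
  }, 0))
  ss_among <- ss_total - ss_within
  df_a <- k - 1
  df_w <- N - k
  ms_a <- ss_among / df_a
  ms_w <- ss_within / df_w
  n0 <- (N - sum(vapply(groups, length, 0L)^2) / N) / df_a
  sigma_w <- ms_w
  sigma_a <- (ms_a - ms_w) / n0
  denom <- sigma_a + sigma_w
  phi <- if (denom > 0) sigma_a / denom else NA_real_
  list(ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
       df_a = df_a, df_w = df_w, sigma_a = sigma_a, sigma_w = sigma_w,
       phi = phi)
}

#' One-level AMOVA with permutation significance
#'
#' Analysis of molecular variance on pairwise squared Euclidean
#' distances between genotype vectors (0/1/2 coding; pairs with missing
#' calls use shared sites only, rescaled by the shared-site count).
#' Sums of squares follow the Excoffier framework
#' (`SS_total = sum_{i<j} d2_ij / N`, within-group analogues per
#' group), variance components come from the expected mean squares, and
#' `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`.
#' Significance is the add-one permutation estimate
#' `p = (1 + #{Phi_perm >= Phi_obs}) / (1 + n_perm)` under random
#' reassignment of samples to populations of fixed sizes.
#'
#' @param gm a [genotype_matrix()] with at least 2 populations of at
#'   least 2 samples.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed for the permutations.
#' @return An `amova_result` list: `sigma_among`, `sigma_within`,
#'   `phi_st`, `p_value`, `n_perm`, `ss` (sums of squares and df).
#' @export
amova <- function(gm, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pop <- factor(unname(gm$popmap[rownames(gm$calls)]))
  if (nlevels(pop) < 2) stop("need at least 2 populations")
  if (any(table(pop) < 2)) stop("every population needs >= 2 samples")
  if (!is.null(seed)) set.seed(seed)

  X <- gm$calls
  S <- ncol(X)
  if (anyNA(X)) {
    obs <- !is.na(X)
    X0 <- X
    X0[!obs] <- 0
    G <- tcrossprod(X0)
    sq <- tcrossprod(X0^2, obs)
    shared <- tcrossprod(obs * 1)
    d2 <- (sq + t(sq) - 2 * G) * S / pmax(shared, 1)
  } else {
    d2 <- as.matrix(stats::dist(X))^2
  }

  obs_fit <- .amova_phi(d2, pop)
  if (is.na(obs_fit$phi))
    return(structure(list(sigma_among = obs_fit$sigma_a,
                          sigma_within = obs_fit$sigma_w,
                          phi_st = NA_real_, p_value = NA_real_,
                          n_perm = n_perm, ss = obs_fit),
                     class = "amova_result"))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    phi_b <- .amova_phi(d2, sample(pop))$phi
    if (!is.na(phi_b) && phi_b >= obs_fit$phi) hits <- hits + 1L
  }
  structure(list(sigma_among = obs_fit$sigma_a,
                 sigma_within = obs_fit$sigma_w, phi_st = obs_fit$phi,
                 p_value = (1 + hits) / (1 + n_perm),
                 n_perm = as.integer(n_perm), ss = obs_fit),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA: Phi_ST =", format(x$phi_st, digits = 4),
      " sigma2 among =", format(x$sigma_among, digits = 4),
      " within =", format(x$sigma_within, digits = 4), "\n")
  cat("permutation p =", format(x$p_value, digits = 4),
      sprintf("(n = %d)\n", x$n_perm))
  invisible(x)
}
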