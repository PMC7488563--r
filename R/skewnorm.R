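#' Owen's T function
#'
#' `T(h, a) = (2*pi)^-1 integral_0^a exp(-h^2 (1+x^2)/2) / (1+x^2) dx`,
#' evaluated by 64-node Gauss-Legendre quadrature, with the standard
#' reduction `T(h, a) = Phi(h)/2 + Phi(ah)/2 - Phi(h) Phi(ah)
#' - T(ah, 1/a)` applied for `|a| > 1` so the quadrature interval stays
#' short.  Vectorized over `h`.
#'
#' @param h numeric vector.
#' @param a scalar slope.
#' @return `T(h, a)` for each `h`.
#' @export
owen_t <- function(h, a) {
  if (length(a) != 1L) stop("a must be scalar")
  if (a == 0) return(rep(0, length(h)))
  if (a < 0) return(-owen_t(h, -a))
  if (a > 1) {
    ah <- a * h
    return(0.5 * stats::pnorm(h) + 0.5 * stats::pnorm(ah) -
             stats::pnorm(h) * stats::pnorm(ah) - owen_t(ah, 1 / a))
  }
  gl <- .gauss_legendre_64
  x <- 0.5 * a * (gl$nodes + 1)
  w <- 0.5 * a * gl$weights
  f <- exp(-0.5 * outer(h^2, 1 + x^2)) /
    rep(1 + x^2, each = length(h))
  as.numeric(f %*% w) / (2 * pi)
}

# 64-point Gauss-Legendre rule on [-1, 1] (Golub-Welsch eigenvalue
# construction, computed once at load)
.gl_rule <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}
.gauss_legendre_64 <- .gl_rule(64L)

#' Skew-normal density, distribution, and random generation
#'
#' Three-parameter skew-normal: location `xi`, scale `omega > 0`, shape
#' `alpha` (`alpha = 0` recovers the normal).  Density
#' `2/omega phi(z) Phi(alpha z)` with `z = (x - xi)/omega`; CDF
#' `Phi(z) - 2 T(z, alpha)` via [owen_t()].
#'
#' @param x,q,n quantiles / sample size.
#' @param xi,omega,alpha parameters.
#' @param log return log-density.
#' @return `dsn`: density; `psn`: lower-tail probability; `rsn`: sample.
#' @export
dsn <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  lg <- base::log(2) - base::log(omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(alpha * z, log.p = TRUE)
  if (log) lg else exp(lg)
}

#' @rdname dsn
#' @export
psn <- function(q, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (q - xi) / omega
  p <- stats::pnorm(z) - 2 * owen_t(z, alpha)
  pmin(pmax(p, 0), 1)
}

#' @rdname dsn
#' @export
rsn <- function(n, xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  xi + omega * z
}

.sn_moment_fit <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  g1 <- mean((x - m)^3) / s^3
  g_max <- 0.5 * (4 - pi) * (2 / (pi - 2))^1.5  # ~0.9953, |alpha| -> Inf
  g1 <- sign(g1) * min(abs(g1), 0.99 * g_max)
  cc <- abs(g1)^(2 / 3)
  delta <- sign(g1) * sqrt(pi / 2 * cc / (cc + ((4 - pi) / 2)^(2 / 3)))
  delta <- max(min(delta, 0.998), -0.998)
  alpha <- delta / sqrt(1 - delta^2)
  omega <- s / sqrt(1 - 2 * delta^2 / pi)
  xi <- m - omega * delta * sqrt(2 / pi)
  c(xi = xi, omega = omega, alpha = alpha)
}

#' Fit a skew-normal by maximum likelihood
#'
#' MLE over (location, log-scale, shape) initialized by the method of
#' moments; falls back to the moment estimates (flagged) when the
#' optimizer fails.
#'
#' @param x numeric data, length at least 50 with positive variance.
#' @return A `skewnormal_fit` list: `xi`, `omega`, `alpha`,
#'   `converged`, `method` ("mle" or "moments").
#' @export
fit_skew_normal <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 50) stop("need at least 50 values to fit")
  if (stats::sd(x) == 0) stop("zero variance: skew-normal fit undefined")
  init <- .sn_moment_fit(x)
  nll <- function(par)
    -sum(dsn(x, par[1], exp(par[2]), par[3], log = TRUE))
  opt <- tryCatch(
    stats::optim(c(init[1], log(init[2]), init[3]), nll,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || !is.finite(opt$value)) {
    return(structure(list(xi = unname(init[1]), omega = unname(init[2]),
                          alpha = unname(init[3]), converged = FALSE,
                          method = "moments"),
                     class = "skewnormal_fit"))
  }
  structure(list(xi = unname(opt$par[1]), omega = unname(exp(opt$par[2])),
                 alpha = unname(opt$par[3]), converged = TRUE,
                 method = "mle"),
            class = "skewnormal_fit")
}

#' Upper-tail empirical p-values from a skew-normal fit
#'
#' `p = 1 - F_sn(value)`: all four statistic families used here (CLR,
#' |iHS|, F_ST, |XP-EHH|) are sweep-like in their upper tail.  Values
#' are floored at the smallest positive double so `-log10(p)` stays
#' finite.
#'
#' @param fit a [fit_skew_normal()] result.
#' @param values numeric vector (may contain `NA`).
#' @return p-values in `(0, 1]`, `NA` where `values` is `NA`.
#' @export
empirical_pvalues <- function(fit, values) {
  stopifnot(inherits(fit, "skewnormal_fit"))
  p <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  p[ok] <- 1 - psn(values[ok], fit$xi, fit$omega, fit$alpha)
  p[ok] <- pmax(p[ok], .Machine$double.xmin)
  p
}
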