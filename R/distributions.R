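#' @name ssd-distributions
#' @title Candidate distributions for the sensitivity analysis
#'
#' @description Density, distribution and quantile functions for the three
#' candidate families not shipped with R, in the parameterizations used
#' throughout this package:
#' Burr III `F(x) = (1 + (x/theta)^(-c))^(-k)`;
#' log-Gumbel `F(x) = exp(-exp(-(ln x - mu)/sigma))` (a Frechet law:
#' `ln x` follows a Gumbel maximum distribution);
#' log-logistic `F(x) = 1 / (1 + (x/alpha)^(-beta))`.
#' All support `x > 0` with strictly positive shape/scale parameters
#' (`mu` may be any real). The gamma, log-normal and Weibull candidates use
#' the corresponding functions from \pkg{stats}.
#'
#' @param x,q Vector of positive quantiles.
#' @param p Vector of probabilities in (0, 1).
#' @param theta,c_,k Burr III scale and the two shape parameters.
#' @param mu,sigma Location and scale of `ln x` (log-Gumbel).
#' @param alpha,beta Log-logistic scale and shape.
#' @param log,lower.tail As in the \pkg{stats} d/p/q functions.
NULL

#' @rdname ssd-distributions
#' @export
dburr3 <- function(x, theta, c_, k, log = FALSE) {
  lx <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  t <- (x[ok] / theta)^(-c_)
  lx[ok] <- log(c_) + log(k) - log(theta) +
    (-c_ - 1) * (log(x[ok]) - log(theta)) + (-k - 1) * log1p(t)
  if (log) lx else exp(lx)
}

#' @rdname ssd-distributions
#' @export
pburr3 <- function(q, theta, c_, k, lower.tail = TRUE) {
  p <- ifelse(q <= 0, 0, (1 + (pmax(q, 0) / theta)^(-c_))^(-k))
  if (lower.tail) p else 1 - p
}

#' @rdname ssd-distributions
#' @export
qburr3 <- function(p, theta, c_, k) {
  stopifnot(all(p > 0 & p < 1))
  theta * (p^(-1 / k) - 1)^(-1 / c_)
}

#' @rdname ssd-distributions
#' @export
dlgumbel <- function(x, mu, sigma, log = FALSE) {
  lx <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  z <- (base::log(x[ok]) - mu) / sigma
  lx[ok] <- -z - exp(-z) - base::log(sigma) - base::log(x[ok])
  if (log) lx else exp(lx)
}

#' @rdname ssd-distributions
#' @export
plgumbel <- function(q, mu, sigma, lower.tail = TRUE) {
  p <- ifelse(q <= 0, 0, exp(-exp(-(log(pmax(q, 1e-300)) - mu) / sigma)))
  if (lower.tail) p else 1 - p
}

#' @rdname ssd-distributions
#' @export
qlgumbel <- function(p, mu, sigma) {
  stopifnot(all(p > 0 & p < 1))
  exp(mu - sigma * log(-log(p)))
}

#' @rdname ssd-distributions
#' @export
dllogis <- function(x, alpha, beta, log = FALSE) {
  lx <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  lr <- beta * (base::log(x[ok]) - base::log(alpha))
  lx[ok] <- base::log(beta) - base::log(x[ok]) + lr - 2 * log1p(exp(lr))
  if (log) lx else exp(lx)
}

#' @rdname ssd-distributions
#' @export
pllogis <- function(q, alpha, beta, lower.tail = TRUE) {
  p <- ifelse(q <= 0, 0, 1 / (1 + (pmax(q, 1e-300) / alpha)^(-beta)))
  if (lower.tail) p else 1 - p
}

#' @rdname ssd-distributions
#' @export
qllogis <- function(p, alpha, beta) {
  stopifnot(all(p > 0 & p < 1))
  alpha * (p / (1 - p))^(1 / beta)
}

#' Names of the candidate sensitivity distributions
#'
#' @return Character vector of the six family names fitted to reciprocal
#'   BCF data: `burr3`, `gamma`, `log_gumbel`, `log_logistic`,
#'   `log_normal`, `weibull`.
#' @export
ssd_dist_names <- function() {
  c("burr3", "gamma", "log_gumbel", "log_logistic", "log_normal", "weibull")
}

# registry: per family, parameter names, log-density, cdf, quantile and a
# moment-based starting value (on the natural scale)
dist_registry <- function(name) {
  switch(
    name,
    burr3 = list(
      par_names = c("theta", "c", "k"),
      logdens = function(x, p) dburr3(x, p[1], p[2], p[3], log = TRUE),
      cdf = function(q, p) pburr3(q, p[1], p[2], p[3]),
      quantile = function(pr, p) qburr3(pr, p[1], p[2], p[3]),
      start = function(y) {
        q <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
        beta <- 2 * log(3) / max(log(q[3] / q[1]), 1e-3)
        c(q[2], beta, 1)
      }
    ),
    gamma = list(
      par_names = c("shape", "scale"),
      logdens = function(x, p) stats::dgamma(x, shape = p[1], scale = p[2],
                                             log = TRUE),
      cdf = function(q, p) stats::pgamma(q, shape = p[1], scale = p[2]),
      quantile = function(pr, p) stats::qgamma(pr, shape = p[1], scale = p[2]),
      start = function(y) {
        m <- mean(y); v <- stats::var(y)
        c(max(m^2 / v, 1e-3), max(v / m, 1e-12))
      }
    ),
    log_gumbel = list(
      par_names = c("mu", "sigma"),
      logdens = function(x, p) dlgumbel(x, p[1], p[2], log = TRUE),
      cdf = function(q, p) plgumbel(q, p[1], p[2]),
      quantile = function(pr, p) qlgumbel(pr, p[1], p[2]),
      start = function(y) {
        ly <- log(y)
        s <- max(stats::sd(ly) * sqrt(6) / pi, 1e-6)
        c(mean(ly) - 0.5772156649 * s, s)
      },
      # mu is a real location: optimized untransformed
      log_scale = c(FALSE, TRUE)
    ),
    log_logistic = list(
      par_names = c("alpha", "beta"),
      logdens = function(x, p) dllogis(x, p[1], p[2], log = TRUE),
      cdf = function(q, p) pllogis(q, p[1], p[2]),
      quantile = function(pr, p) qllogis(pr, p[1], p[2]),
      start = function(y) {
        q <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
        c(q[2], 2 * log(3) / max(log(q[3] / q[1]), 1e-3))
      }
    ),
    log_normal = list(
      par_names = c("mu", "sigma"),
      logdens = function(x, p) stats::dlnorm(x, p[1], p[2], log = TRUE),
      cdf = function(q, p) stats::plnorm(q, p[1], p[2]),
      quantile = function(pr, p) stats::qlnorm(pr, p[1], p[2]),
      start = function(y) {
        ly <- log(y)
        c(mean(ly), max(stats::sd(ly), 1e-6))
      },
      log_scale = c(FALSE, TRUE)
    ),
    weibull = list(
      par_names = c("lambda", "kappa"),
      logdens = function(x, p) stats::dweibull(x, shape = p[2], scale = p[1],
                                               log = TRUE),
      cdf = function(q, p) stats::pweibull(q, shape = p[2], scale = p[1]),
      quantile = function(pr, p) stats::qweibull(pr, shape = p[2],
                                                 scale = p[1]),
      start = function(y) {
        kap <- max(1.2 / stats::sd(log(y)), 0.05)
        c(mean(y) / gamma(1 + 1 / kap), kap)
      }
    ),
    stop("unknown distribution: ", name, call. = FALSE)
  )
}

n_dist_params <- function(name) length(dist_registry(name)$par_names)
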