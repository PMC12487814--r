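#' Zero-inflated negative binomial log-likelihood
#'
#' Log-probability of observed counts under a ZINB distribution with
#' mean `mu`, inverse-dispersion `theta` (variance `mu + mu^2/theta`)
#' and zero-inflation probability `pi`:
#' `P(x) = pi * 1[x = 0] + (1 - pi) * NB(x; mu, theta)`.
#' Inputs may be vectors or matrices (cells x genes); matrices are
#' summed over genes so one value per cell is returned.
#'
#' @param x non-negative counts.
#' @param mu NB mean, `> 0` (typically library size times a per-gene
#'   mean fraction).
#' @param theta inverse dispersion, `> 0`; may be a per-gene vector
#'   recycled across cells.
#' @param pi zero-inflation probability in `[0, 1)` (or 1, giving a
#'   point mass at zero).
#' @return Numeric vector of per-cell log-likelihoods (nats).
#' @examples
#' zinbLogLik(2, mu = 1, theta = 1, pi = 0)  # log(1/8)
#' @export
zinbLogLik <- function(x, mu, theta, pi = 0) {
  if (any(theta <= 0)) stop("theta must be positive")
  if (any(x < 0)) stop("counts must be non-negative")
  xm <- is.matrix(x)
  x <- as.matrix(x)
  n <- nrow(x); g <- ncol(x)
  as_mat <- function(v) {
    if (is.matrix(v)) v
    else if (length(v) == 1) matrix(v, n, g)
    else if (length(v) == g) matrix(v, n, g, byrow = TRUE)
    else matrix(v, n, g)
  }
  mu <- as_mat(mu); theta <- as_mat(theta); pi <- as_mat(pi)
  s <- theta + mu
  log_nb0 <- theta * (log(theta) - log(s))
  ll <- matrix(0, n, g)
  z <- x == 0
  # x = 0: log(pi + (1 - pi) * NB0), computed stably
  if (any(z)) {
    lp <- log(pmax(pi[z], 0))
    l1p <- log1p(-pmin(pi[z], 1 - 1e-300))
    a <- lp; b <- l1p + log_nb0[z]
    m <- pmax(a, b)
    ll[z] <- ifelse(pi[z] == 0, b,
                    ifelse(pi[z] == 1, 0, m + log(exp(a - m) + exp(b - m))))
  }
  if (any(!z)) {
    xi <- x[!z]; mi <- mu[!z]; ti <- theta[!z]; si <- s[!z]; pii <- pi[!z]
    ll[!z] <- log1p(-pii) + lgamma(xi + ti) - lgamma(ti) - lgamma(xi + 1) +
      ti * (log(ti) - log(si)) + xi * (log(mi) - log(si))
  }
  out <- rowSums(ll)
  if (!xm && g == 1 && n == 1) out <- as.numeric(out)
  out
}

#' Bernoulli log-likelihood for binarized accessibility
#'
#' Per-cell sum of `y log p + (1 - y) log(1 - p)` with probabilities
#' clamped to `(1e-6, 1 - 1e-6)` before the log for numerical safety.
#'
#' @param y binary matrix/vector (cells x peaks).
#' @param p probabilities, same shape (or recycled).
#' @return Numeric vector of per-cell log-likelihoods (nats; `<= 0`).
#' @export
bernoulliLogLik <- function(y, p) {
  if (any(y != 0 & y != 1)) stop("accessibility values must be binary (0/1)")
  y <- as.matrix(y)
  p <- if (is.matrix(p)) p else matrix(p, nrow(y), ncol(y), byrow = length(p) == ncol(y))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  rowSums(y * log(p) + (1 - y) * log1p(-p))
}

#' Closed-form KL divergence from a diagonal Gaussian to N(0, I)
#'
#' `KL[N(mu, diag(exp(logVar))) || N(0, I)] =
#'  0.5 * sum(mu^2 + exp(logVar) - logVar - 1)` per row.
#'
#' @param mu,logVar matrices (cells x latent dims) or vectors.
#' @return Numeric vector of per-cell KL divergences (nats).
#' @examples
#' klNormal(0, 0)  # posterior equals prior: 0
#' klNormal(1, 0)  # 0.5
#' @export
klNormal <- function(mu, logVar) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  if (is.null(dim(logVar))) logVar <- matrix(logVar, nrow = 1)
  0.5 * rowSums(mu^2 + exp(logVar) - logVar - 1)
}

# Gradients of the per-entry ZINB log-likelihood with respect to mu,
# log(theta) and the dropout logit g (pi = sigmoid(g)). All inputs are
# cells x genes matrices. Returns d(loglik)/d* with the same shapes.
.zinb_grads <- function(x, mu, theta, g) {
  s <- theta + mu
  pi <- plogis(g)
  q <- exp(theta * (log(theta) - log(s)))   # NB pmf at zero
  z <- x == 0
  A <- pi + (1 - pi) * q
  dmu <- matrix(0, nrow(x), ncol(x))
  dlt <- dmu; dg <- dmu
  # x = 0 branch
  dmu[z] <- (-(1 - pi) * q * theta / (s * A))[z]
  dtheta0 <- ((1 - pi) * q * (log(theta) - log(s) + 1 - theta / s) / A)
  dlt[z] <- (dtheta0 * theta)[z]
  dg[z] <- (pi * (1 - pi) * (1 - q) / A)[z]
  # x > 0 branch
  nz <- !z
  dmu[nz] <- (x / mu - (theta + x) / s)[nz]
  dthetap <- digamma(x + theta) - digamma(theta) +
    log(theta) + 1 - log(s) - (theta + x) / s
  dlt[nz] <- (dthetap * theta)[nz]
  dg[nz] <- (-pi)[nz]
  list(dmu = dmu, dlogtheta = dlt, dlogit = dg)
}
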