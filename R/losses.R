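# Loss functions for representation learning and the multi-task head.
#
# Conventions: the negative binomial is parameterized by mean `mu` and
# inverse dispersion `theta`,
#   NB(x; mu, theta) = G(x+theta)/(G(theta) x!) (theta/(theta+mu))^theta
#                      (mu/(theta+mu))^x,
# and zero-inflated mixtures put probability Pi on an exact zero and
# (1 - Pi) on the base distribution. All mixture logs go through
# log-sum-exp; exported losses return the plain entry sums (task losses are
# batch means, as stated in their docs).

PI_EPS <- 1e-6

check_zi_params <- function(pi, a, b, n) {
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1)) {
    stop_panel("Pi must be finite probabilities in [0, 1]")
  }
  if (any(!is.finite(a)) || any(a <= 0) || any(!is.finite(b)) || any(b <= 0)) {
    stop_panel("distribution parameters must be finite and > 0")
  }
}

# log NB(x; mu, theta), elementwise.
log_nb <- function(x, mu, theta) {
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' Per entry: `-log(Pi + (1 - Pi) NB(0; mu, theta))` when `x = 0`, and
#' `-log((1 - Pi) NB(x; mu, theta))` otherwise; returned summed over all
#' entries. `Pi = 0` degenerates to the plain negative binomial NLL.
#'
#' @param x nonnegative integer counts (vector or matrix).
#' @param pi,mu,theta mixture weight, NB mean and inverse dispersion,
#'   recycled to the shape of `x`.
#' @return Scalar sum of per-entry negative log-likelihoods.
#' @export
nll_zinb <- function(x, pi, mu, theta) {
  if (!is_count_vector(as.numeric(x))) {
    stop_panel("ZINB data must be nonnegative integers")
  }
  check_zi_params(pi, mu, theta)
  sum(nll_zinb_entries(x, pi, mu, theta))
}

nll_zinb_entries <- function(x, pi, mu, theta) {
  # upper clamp only: pi = 0 must degenerate to the plain NB exactly
  pic <- pmin(pi, 1 - PI_EPS)
  lnb <- log_nb(x, mu, theta)
  nll <- -(log1p(-pic) + lnb)
  zero <- x == 0
  if (any(zero)) {
    mix0 <- logaddexp(log(pic), log1p(-pic) + lnb)
    nll[zero] <- -mix0[zero]
  }
  nll
}

# Gradients of sum(nll_zinb_entries) wrt (pi, mu, theta), elementwise.
grad_zinb <- function(x, pi, mu, theta) {
  pic <- clamp(pi, PI_EPS, 1 - PI_EPS)
  lnb0 <- theta * (log(theta) - log(theta + mu))
  dl0_dmu <- -theta / (theta + mu)
  dl0_dth <- log(theta) + 1 - log(theta + mu) - theta / (theta + mu)
  # x > 0 branch
  dpi <- 1 / (1 - pic)
  dmu <- -(x / mu - (x + theta) / (theta + mu))
  dth <- -(digamma(x + theta) - digamma(theta) + log(theta) + 1 -
             log(theta + mu) - theta / (theta + mu) - x / (theta + mu))
  zero <- x == 0
  if (any(zero)) {
    L <- logaddexp(log(pic), log1p(-pic) + lnb0)
    p <- exp(log(pic) - L)            # posterior weight of the point mass
    q <- exp(log1p(-pic) + lnb0 - L)
    dpi[zero] <- (-(p / pic) + q / (1 - pic))[zero]
    dmu[zero] <- (-q * dl0_dmu)[zero]
    dth[zero] <- (-q * dl0_dth)[zero]
  }
  list(dpi = dpi, dmu = dmu, dtheta = dth)
}

#' Zero-inflated normal negative log-likelihood
#'
#' Exact zeros are modeled as a point mass with probability `Pi` mixed with
#' the normal density at zero: per entry, `-log(Pi + (1 - Pi) phi(0; mean,
#' variance))` when `x == 0` and `-log((1 - Pi) phi(x; mean, variance))`
#' otherwise; returned summed over entries. Zeros are detected by exact
#' comparison because the feature builder emits exact zeros.
#'
#' @param x real values (vector or matrix).
#' @param pi,mean,variance mixture weight, normal mean and variance
#'   (variance must be > 0), recycled to the shape of `x`.
#' @return Scalar sum of per-entry negative log-likelihoods.
#' @export
nll_zinormal <- function(x, pi, mean, variance) {
  if (any(!is.finite(x))) stop_panel("ZI-normal data must be finite")
  if (any(!is.finite(variance)) || any(variance <= 0)) {
    stop_panel("variance must be finite and > 0")
  }
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1)) {
    stop_panel("Pi must be finite probabilities in [0, 1]")
  }
  sum(nll_zinormal_entries(x, pi, mean, variance))
}

nll_zinormal_entries <- function(x, pi, mean, variance) {
  pic <- pmin(pi, 1 - PI_EPS)
  lphi <- -0.5 * log(2 * pi_const() * variance) - (x - mean)^2 / (2 * variance)
  nll <- -(log1p(-pic) + lphi)
  zero <- x == 0
  if (any(zero)) {
    mix0 <- logaddexp(log(pic), log1p(-pic) + lphi)
    nll[zero] <- -mix0[zero]
  }
  nll
}

pi_const <- function() 3.141592653589793

# Gradients of sum(nll_zinormal_entries) wrt (pi, mean, variance).
grad_zinormal <- function(x, pi, mean, variance) {
  pic <- clamp(pi, PI_EPS, 1 - PI_EPS)
  v <- variance
  dpi <- 1 / (1 - pic)
  dm <- -(x - mean) / v
  dv <- 0.5 / v - (x - mean)^2 / (2 * v^2)
  zero <- x == 0
  if (any(zero)) {
    lphi0 <- -0.5 * log(2 * pi_const() * v) - mean^2 / (2 * v)
    L <- logaddexp(log(pic), log1p(-pic) + lphi0)
    p <- exp(log(pic) - L)
    q <- exp(log1p(-pic) + lphi0 - L)
    dpi[zero] <- (-(p / pic) + q / (1 - pic))[zero]
    dm[zero] <- (q * mean / v)[zero]
    dv[zero] <- (-q * (mean^2 / (2 * v^2) - 0.5 / v))[zero]
  }
  list(dpi = dpi, dmean = dm, dvar = dv)
}

#' Kullback-Leibler divergence of the variational posterior
#'
#' `-0.5 * sum(1 + log(sigma^2) - mu^2 - sigma^2)`, the closed-form KL
#' divergence between N(mu, sigma^2) and the standard normal prior, summed
#' over all entries. Nonnegative, zero exactly at (mu = 0, sigma = 1).
#'
#' @param mu matrix/vector of posterior means.
#' @param sigma matrix/vector of posterior standard deviations (> 0).
#' @return Scalar KL divergence.
#' @export
kld_loss <- function(mu, sigma) {
  if (any(!is.finite(mu))) stop_panel("mu must be finite")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop_panel("sigma must be finite and > 0")
  }
  -0.5 * sum(1 + log(sigma^2) - mu^2 - sigma^2)
}

batch_covariance <- function(z) {
  zc <- sweep(z, 2, colMeans(z))
  crossprod(zc) / nrow(z)
}

#' Correlation-alignment (CORAL) loss between two representation batches
#'
#' Squared Frobenius norm of the difference between the two batch covariance
#' matrices, each computed with 1/n normalization around the batch mean.
#' Symmetric, nonnegative, and invariant to adding a constant row vector to
#' either batch.
#'
#' @param zC,zP numeric matrices (>= 2 rows each) with the same number of
#'   columns.
#' @return Scalar loss.
#' @export
coral_loss <- function(zC, zP) {
  zC <- as.matrix(zC); zP <- as.matrix(zP)
  if (ncol(zC) != ncol(zP)) {
    stop_panel("CORAL batches must share the latent dimension (%d vs %d)",
               ncol(zC), ncol(zP))
  }
  if (nrow(zC) < 2L || nrow(zP) < 2L) {
    stop_panel("CORAL needs at least 2 rows per batch")
  }
  D <- batch_covariance(zC) - batch_covariance(zP)
  sum(D^2)
}

# Gradient of coral_loss wrt each batch. d/dZ ||C(Z)-C(W)||^2 with
# C(Z) = Z_c' Z_c / n is (4/n) H Z_c D, H the centering projector.
grad_coral <- function(zC, zP) {
  D <- batch_covariance(zC) - batch_covariance(zP)
  gC <- 4 / nrow(zC) * sweep(zC, 2, colMeans(zC)) %*% D
  gP <- -4 / nrow(zP) * sweep(zP, 2, colMeans(zP)) %*% D
  gC <- sweep(gC, 2, colMeans(gC))
  gP <- sweep(gP, 2, colMeans(gP))
  list(dzC = gC, dzP = gP)
}

#' Binary cross-entropy loss on logits
#'
#' Numerically stable `-[y log sigmoid(l) + (1 - y) log(1 - sigmoid(l))]`,
#' averaged over the batch.
#'
#' @param y 0/1 labels.
#' @param logit real-valued predictions before the sigmoid.
#' @return Scalar batch mean.
#' @export
bce_logit_loss <- function(y, logit) {
  if (!all(y %in% c(0, 1))) stop_panel("BCE labels must be 0/1")
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

#' Mean squared error loss
#'
#' @param y,yhat real targets and predictions.
#' @return Scalar batch mean of squared errors.
#' @export
mse_loss <- function(y, yhat) mean((y - yhat)^2)

#' Chebyshev scalarization of the two task losses
#'
#' `max(lambda_P * L_BCE, lambda_C * L_MSE)`. Unlike linear scalarization,
#' minimizing this maximum can reach non-convex parts of the Pareto front;
#' during training the subgradient flows through the active term only.
#'
#' @param l_bce,l_mse scalar task losses.
#' @param lambda_P,lambda_C positive task weights.
#' @return Scalar loss.
#' @export
chebyshev_loss <- function(l_bce, l_mse, lambda_P = 1, lambda_C = 1) {
  if (lambda_P <= 0 || lambda_C <= 0) {
    stop_panel("Chebyshev weights must be > 0")
  }
  max(lambda_P * l_bce, lambda_C * l_mse)
}
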