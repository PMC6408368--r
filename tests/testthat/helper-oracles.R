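# Independent oracles and small fixture builders shared across tests.

# random non-degenerate 2D configuration
rand_config <- function(p, sd = 1) {
  matrix(stats::rnorm(2 * p, sd = sd), p, 2L)
}

# random similarity transform of a configuration
rand_similarity <- function(config) {
  theta <- stats::runif(1, -pi, pi)
  s <- exp(stats::rnorm(1, 0, 0.5))
  shift <- stats::rnorm(2, 0, 5)
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2L, 2L)
  sweep(config %*% R * s, 2L, shift, "+")
}

# Classical GPA, independently coded in complex arithmetic: configurations
# become complex vectors, centring is subtraction of the complex mean,
# scaling divides by the vector norm, and the optimal rotation onto the mean
# is multiplication by the unit phase of the Hermitian inner product.
gpa_complex_oracle <- function(mats, tol = 1e-12, max_iter = 1000L) {
  zs <- lapply(mats, function(m) {
    z <- complex(real = m[, 1], imaginary = m[, 2])
    z <- z - mean(z)
    z / sqrt(sum(Mod(z)^2))
  })
  mu <- zs[[1]]
  for (it in seq_len(max_iter)) {
    zs <- lapply(zs, function(z) {
      w <- sum(Conj(z) * mu)
      z * (w / Mod(w))
    })
    mu_new <- Reduce(`+`, zs) / length(zs)
    mu_new <- mu_new - mean(mu_new)
    mu_new <- mu_new / sqrt(sum(Mod(mu_new)^2))
    # keep the mean's phase anchored to the previous one
    w <- sum(Conj(mu_new) * mu)
    mu_new <- mu_new * (w / Mod(w))
    if (sqrt(sum(Mod(mu_new - mu)^2)) < tol) { mu <- mu_new; break }
    mu <- mu_new
  }
  list(
    aligned = lapply(zs, function(z) cbind(Re(z), Im(z))),
    mean = cbind(Re(mu), Im(mu))
  )
}

# brute-force covariance PCA through a different route: SVD of the centred
# data matrix (eigenvalues = singular values squared / (n - 1))
pca_svd_oracle <- function(x) {
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc)
  list(eigenvalues = sv$d^2 / (nrow(x) - 1), eigenvectors = sv$v,
       scores = xc %*% sv$v)
}

# Bernoulli log-likelihood for a 1-predictor logistic model
loglik_1d <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# 2-D grid search MLE with three refinement rounds
logistic_grid_oracle <- function(x, y, lim = 10) {
  ctr <- c(0, 0); span <- lim
  for (round in 1:4) {
    b0s <- seq(ctr[1] - span, ctr[1] + span, length.out = 41)
    b1s <- seq(ctr[2] - span, ctr[2] + span, length.out = 41)
    ll <- outer(b0s, b1s, Vectorize(function(a, b) loglik_1d(a, b, x, y)))
    best <- arrayInd(which.max(ll), dim(ll))
    ctr <- c(b0s[best[1]], b1s[best[2]])
    span <- span / 10
  }
  ctr
}

# a small well-behaved synthetic landmark world for pipeline-level tests
small_sim <- function(seed = 1L, ...) {
  simulate_outline_dataset(simulation_params(
    n_per_class = 8L, n_fossils = 2L, seed = seed, ...
  ))
}
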