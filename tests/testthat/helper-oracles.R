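# Dense multivariate-normal oracles for the GMRF and small-state helpers for
# the sampler moves. Everything here recomputes quantities by an independent
# route (dense matrices, direct normalization, brute-force grids).

dense_laplacian <- function(n, nb) {
  idx <- seq_len(n)
  A <- outer(idx, idx, function(i, j) as.numeric(abs(i - j) <= nb & i != j))
  diag(rowSums(A)) - A
}

# log N(x; 0, (I + hQ)^{-1}) via dense determinant and quadratic form
dense_gmrf_logdens <- function(x, h, n, nb) {
  P <- diag(n) + h * dense_laplacian(n, nb)
  as.numeric(-0.5 * n * log(2 * pi) +
               0.5 * determinant(P, logarithm = TRUE)$modulus -
               0.5 * t(x) %*% P %*% x)
}

# conditional of x_i | x_{-i} under N(0, (I + hQ)^{-1}) by Schur complement
dense_gmrf_conditional <- function(x, i, h, n, nb) {
  P <- diag(n) + h * dense_laplacian(n, nb)
  list(mean = as.numeric(-P[i, -i] %*% x[-i] / P[i, i]),
       variance = 1 / P[i, i])
}

# brute-force scalar grid for the background calibration
grid_background <- function(cn, obs, step = 1e-4) {
  bs <- seq(step, 10, by = step)
  ss <- vapply(bs, function(b) sum((log2((cn + b) / (2 + b)) - obs)^2), 0)
  bs[which.min(ss)]
}

test_prior <- function(...) prior_config(...)

# context list in the exact shape the compiled sampler expects
make_ctx <- function(y, prior = test_prior(), nb = prior$nb,
                     prior_only = FALSE) {
  graph <- neighbor_graph(length(y), nb)
  cnvmix:::build_ctx(y, prior, graph, prior_only)
}

# a valid random sampler state over a given context
random_state <- function(ctx, k = 3, seed = NULL, x_sd = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  kmax <- ctx$kmax
  act <- sort(sample(kmax, k))
  active <- as.integer(seq_len(kmax) %in% act)
  mu <- (ctx$lower + ctx$upper) / 2
  mu[act] <- runif(k, ctx$lower[act], ctx$upper[act])
  list(active = active,
       mu = mu,
       sigma2 = runif(kmax, 0.02, 0.3),
       x = matrix(rnorm(ctx$n * kmax, sd = x_sd), ctx$n, kmax),
       z = sample(act, ctx$n, replace = TRUE),
       h = runif(1, 0, 20))
}

# mixture log-density at every SNP, computed the plain R way
r_log_mix <- function(ctx, state) {
  act <- which(state$active == 1)
  w <- field_weights(state$x[, act, drop = FALSE], ctx$phi)
  dens <- sapply(seq_along(act), function(l) {
    dnorm(ctx$y, state$mu[act[l]], sqrt(state$sigma2[act[l]]))
  })
  if (ctx$prior_only) dens <- matrix(1, ctx$n, length(act))
  log(rowSums(w * dens))
}

# direct evaluation of the birth acceptance ratio (trans-dimensional move)
r_birth_log_alpha <- function(ctx, state, cnew, mu_s, s2_s, xcol) {
  bprob <- function(k) if (k <= 1) 1 else if (k >= ctx$kmax) 0 else 0.5
  k <- sum(state$active)
  st2 <- state
  st2$active[cnew] <- 1L
  st2$mu[cnew] <- mu_s
  st2$sigma2[cnew] <- s2_s
  st2$x[, cnew] <- xcol
  log(1 - bprob(k + 1)) - log(k + 1) +
    dpois(k + 1, ctx$poisson_mean, log = TRUE) -
    log(bprob(k)) + log(ctx$kmax - k) -
    dpois(k, ctx$poisson_mean, log = TRUE) +
    sum(r_log_mix(ctx, st2) - r_log_mix(ctx, state))
}

r_death_log_alpha <- function(ctx, state, cdel) {
  bprob <- function(k) if (k <= 1) 1 else if (k >= ctx$kmax) 0 else 0.5
  k <- sum(state$active)
  st2 <- state
  st2$active[cdel] <- 0L
  log(bprob(k - 1)) - log(ctx$kmax - (k - 1)) +
    dpois(k - 1, ctx$poisson_mean, log = TRUE) -
    log(1 - bprob(k)) + log(k) -
    dpois(k, ctx$poisson_mean, log = TRUE) +
    sum(r_log_mix(ctx, st2) - r_log_mix(ctx, state))
}

# state invariants that must hold after every sampler iteration
expect_valid_state <- function(state, ctx) {
  act <- which(state$active == 1)
  expect_true(length(act) >= 1 && length(act) <= ctx$kmax)
  expect_true(all(state$z %in% act))
  expect_true(all(state$mu[act] >= ctx$lower[act]))
  expect_true(all(state$mu[act] <= ctx$upper[act]))
  expect_true(all(state$sigma2[act] > 0))
  expect_true(state$h >= 0 && state$h <= ctx$h_max)
  expect_true(all(is.finite(state$x)))
}
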