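test_that("truncated Poisson prior on k normalizes and has the right ratios", {
  pr <- test_prior()
  expect_equal(sum(exp(log_prior_k(1:7, pr))), 1, tolerance = 1e-12)
  # Poisson pmf ratio p(3)/p(2) = lambda/3
  expect_equal(exp(log_prior_k(3, pr) - log_prior_k(2, pr)), 2 / 3,
               tolerance = 1e-12)
  # direct-summation oracle for p(1)
  expect_equal(exp(log_prior_k(1, pr)),
               2 * exp(-2) / sum(2^(1:7) * exp(-2) / factorial(1:7)),
               tolerance = 1e-12)
  expect_error(log_prior_k(0, pr), "1..k_max")
  expect_error(log_prior_k(8, pr), "1..k_max")
})

test_that("birth probabilities follow the b_k schedule", {
  pr <- test_prior()
  expect_equal(birth_probability(1, pr), 1)
  expect_equal(birth_probability(7, pr), 0)
  expect_equal(birth_probability(c(2, 4, 6), pr), c(0.5, 0.5, 0.5))
})

test_that("compiled mixture log-density matches the plain R computation", {
  set.seed(31)
  # moderate temperature keeps the R-side weights away from underflow
  pr <- test_prior(phi = 0.5)
  for (rep in 1:5) {
    y <- runif(8, -1.4, 1.2)
    ctx <- make_ctx(y, pr)
    st <- random_state(ctx, k = sample(2:5, 1))
    expect_equal(cnvmix:::cpp_log_mix(ctx, st), r_log_mix(ctx, st),
                 tolerance = 1e-10)
  }
})

test_that("birth acceptance matches a direct evaluation of the ratio", {
  set.seed(17)
  pr <- test_prior(phi = 0.5)
  for (rep in 1:6) {
    y <- runif(10, -1.4, 1.2)
    ctx <- make_ctx(y, pr)
    st <- random_state(ctx, k = sample(1:5, 1))
    inactive <- which(st$active == 0)
    cnew <- inactive[sample(length(inactive), 1)]
    mu_s <- runif(1, ctx$lower[cnew], ctx$upper[cnew])
    s2_s <- runif(1, 0.02, 0.2)
    xcol <- rnorm(ctx$n, sd = 0.5)
    expect_equal(
      cnvmix:::cpp_birth_log_alpha(ctx, st, cnew, mu_s, s2_s, xcol),
      r_birth_log_alpha(ctx, st, cnew, mu_s, s2_s, xcol),
      tolerance = 1e-8
    )
  }
  # a new component with (numerically) zero weight everywhere leaves the
  # likelihood untouched: only the prior/move factor remains
  y <- runif(6, -1, 1)
  ctx <- make_ctx(y, test_prior(phi = 0.01))
  st <- random_state(ctx, k = 2, seed = 3)
  st$x[] <- 0
  cnew <- which(st$active == 0)[1]
  la <- cnvmix:::cpp_birth_log_alpha(ctx, st, cnew, 0.2, 0.05,
                                     rep(-10, ctx$n))
  k <- 2
  factor_only <- log(1 - 0.5) - log(k + 1) + dpois(k + 1, 2, log = TRUE) -
    log(0.5) + log(ctx$kmax - k) - dpois(k, 2, log = TRUE)
  # weights of the old components change by < 1e-300 at these logits
  expect_equal(la, factor_only, tolerance = 1e-9)
})

test_that("death acceptance matches the direct ratio and reverses birth", {
  set.seed(23)
  pr <- test_prior(phi = 0.5)
  for (rep in 1:6) {
    y <- runif(9, -1.4, 1.2)
    ctx <- make_ctx(y, pr)
    st <- random_state(ctx, k = sample(2:6, 1))
    act <- which(st$active == 1)
    cdel <- act[sample(length(act), 1)]
    expect_equal(cnvmix:::cpp_death_log_alpha(ctx, st, cdel),
                 r_death_log_alpha(ctx, st, cdel), tolerance = 1e-8)
  }
  # detailed-balance identity: the death ratio from the augmented state is the
  # negative of the birth ratio that created it
  y <- runif(7, -1, 1)
  ctx <- make_ctx(y, pr)
  st <- random_state(ctx, k = 3, seed = 9)
  cnew <- which(st$active == 0)[1]
  mu_s <- mean(c(ctx$lower[cnew], ctx$upper[cnew]))
  s2_s <- 0.07
  xcol <- rnorm(ctx$n, sd = 0.3)
  la_birth <- cnvmix:::cpp_birth_log_alpha(ctx, st, cnew, mu_s, s2_s, xcol)
  st2 <- st
  st2$active[cnew] <- 1L
  st2$mu[cnew] <- mu_s
  st2$sigma2[cnew] <- s2_s
  st2$x[, cnew] <- xcol
  expect_equal(cnvmix:::cpp_death_log_alpha(ctx, st2, cnew), -la_birth,
               tolerance = 1e-8)
})

test_that("allocation probabilities are the normalized weighted densities", {
  set.seed(11)
  pr <- test_prior(phi = 0.5)
  y <- runif(12, -1.4, 1.2)
  ctx <- make_ctx(y, pr)
  st <- random_state(ctx, k = 3)
  probs <- cnvmix:::cpp_allocation_probs(ctx, st)
  act <- which(st$active == 1)
  w <- field_weights(st$x[, act, drop = FALSE], ctx$phi)
  dens <- sapply(act, function(j) dnorm(y, st$mu[j], sqrt(st$sigma2[j])))
  direct <- w * dens / rowSums(w * dens)
  expect_equal(probs[, act], direct, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(probs[, -act], matrix(0, 12, 4), ignore_attr = TRUE)
  # degenerate weights force the allocation
  st$x[, act] <- 0
  st$x[1, act[2]] <- 1 # overwhelming logit at phi = 0.5? make it decisive
  st$x[1, act[2]] <- 50
  probs <- cnvmix:::cpp_allocation_probs(ctx, st)
  expect_equal(probs[1, act[2]], 1, tolerance = 1e-10)
  # symmetric two-class case splits 50/50
  ctx2 <- make_ctx(c(0, 0), test_prior(phi = 0.5))
  st2 <- list(active = as.integer(1:7 %in% c(2, 4)),
              mu = c(0, -1, 0, 1, 0, 0, 0), sigma2 = rep(0.04, 7),
              x = matrix(0, 2, 7), z = c(2L, 2L), h = 0)
  probs2 <- cnvmix:::cpp_allocation_probs(ctx2, st2)
  expect_equal(probs2[1, c(2, 4)], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("interval selection uses normal-CDF masses with low-index ties", {
  cls <- cn_classes()
  sel <- cnvmix:::cpp_interval_select(0.3, 0.05, cls$lower, cls$upper)
  expect_equal(sel$index, which(cls$cn == 3))
  expect_equal(sel$masses,
               pnorm(cls$upper, 0.3, 0.05) - pnorm(cls$lower, 0.3, 0.05),
               tolerance = 1e-12)
  # an exact tie (identical masses) resolves to the lower index
  sel <- cnvmix:::cpp_interval_select(0, 1, c(1, 1), c(2, 2))
  expect_equal(sel$index, 1)
  # a mean far outside every interval falls back to the nearest midpoint
  sel <- cnvmix:::cpp_interval_select(50, 1e-4, cls$lower, cls$upper)
  expect_equal(sel$index, 7)
})

test_that("components sampled into one interval merge by allocation weight", {
  pr <- test_prior(phi = 0.5)
  y <- c(rep(0.3, 10), rep(0.4, 30))
  ctx <- make_ctx(y, pr)
  st <- list(active = as.integer(1:7 %in% c(3, 4)),
             mu = c(0, 0, 0, 0.3, 0, 0, 0), sigma2 = rep(0.04, 7),
             x = matrix(rnorm(40 * 7), 40, 7),
             z = c(rep(3L, 10), rep(4L, 30)), h = 1)
  st$sigma2[3] <- 0.01
  st$sigma2[4] <- 0.09
  # both components steered into the CN=3 interval with means 0.3 and 0.4
  merged <- cnvmix:::cpp_resolve_merges(ctx, st, targets = c(4L, 4L),
                                        mut = c(0.3, 0.4))
  expect_equal(which(merged$active == 1), 4)
  expect_equal(merged$mu[4], (10 * 0.3 + 30 * 0.4) / 40) # 0.375
  # sigma is averaged on the SD scale
  expect_equal(merged$sigma2[4], ((10 * 0.1 + 30 * 0.3) / 40)^2)
  # the x column is the same weighted average and allocations are redirected
  expect_equal(merged$x[, 4], (10 * st$x[, 3] + 30 * st$x[, 4]) / 40)
  expect_true(all(merged$z == 4))
  expect_equal(length(merged$z), length(st$z)) # allocation conservation
  # two empty components merge with equal weights
  st0 <- st
  st0$z <- rep(6L, 40)
  st0$active <- as.integer(1:7 %in% c(3, 4, 6))
  merged0 <- cnvmix:::cpp_resolve_merges(ctx, st0, targets = c(4L, 4L, 6L),
                                         mut = c(0.2, 0.4, 0.8))
  expect_equal(merged0$mu[4], 0.3)
  # disjoint targets are a no-op merge (components only migrate)
  moved <- cnvmix:::cpp_resolve_merges(ctx, st, targets = c(3L, 4L),
                                       mut = c(-0.01, 0.3))
  expect_equal(which(moved$active == 1), c(3, 4))
})

test_that("sampler iterations preserve the state invariants", {
  set.seed(101)
  y <- simulate_track("A", sd = 0.15, seed = 5)$log2ratio[1:80]
  ctx <- make_ctx(y, test_prior())
  st <- random_state(ctx, k = 3)
  for (it in 1:150) {
    st <- cnvmix:::cpp_step_iteration(ctx, st, 50)
    if (it %% 30 == 0) expect_valid_state(st, ctx)
  }
  expect_valid_state(st, ctx)
})

test_that("fits are bit-reproducible under a fixed seed", {
  trk <- simulate_track("A", sd = 0.1, seed = 8)
  f1 <- cnv_fit(trk, burnin = 100, samples = 100, seed = 99)
  f2 <- cnv_fit(trk, burnin = 100, samples = 100, seed = 99)
  expect_identical(f1$omega_bar, f2$omega_bar)
  expect_identical(f1$calls, f2$calls)
  expect_identical(f1$h_trace, f2$h_trace)
})

test_that("h proposals keep the 40-70% acceptance window after adaptation", {
  trk <- simulate_track("A", sd = 0.1, seed = 21)
  fit <- cnv_fit(trk, burnin = 1500, samples = 1500, seed = 22)
  acc <- fit$accept$rate[fit$accept$move == "h"]
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.85)
})
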