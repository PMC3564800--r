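test_that("fixed-effects pooling matches hand inverse-variance arithmetic", {
  m <- fixed_effects(data.frame(beta = c(1, 3), se = c(1, 1)))
  expect_equal(m$beta, 2)
  expect_equal(m$se, sqrt(0.5), tolerance = 1e-12)
  # replicating one study k times shrinks the se by 1/sqrt(k)
  one <- data.frame(beta = 1.7, se = 0.4)
  m9 <- fixed_effects(one[rep(1, 9), ])
  expect_equal(m9$beta, 1.7)
  expect_equal(m9$se, 0.4 / 3, tolerance = 1e-12)
  # pooled se never exceeds the smallest study se
  set.seed(5)
  est <- data.frame(beta = rnorm(8), se = runif(8, 0.1, 1))
  expect_lt(fixed_effects(est)$se, min(est$se))
  expect_error(fixed_effects(one), "insufficient")
})

test_that("DerSimonian-Laird reproduces the moment-estimator hand example", {
  est <- data.frame(beta = c(0, 4), se = c(1, 1))
  m <- dersimonian_laird(est)
  expect_equal(m$Q, 8)
  expect_equal(m$tau2, 7)                 # (8 - 1) / (2 - 1)
  expect_equal(m$beta, 2)
  expect_equal(m$se, 2)                   # sqrt((1 + 7) / 2)
  # homogeneous inputs collapse to fixed effects
  hom <- data.frame(beta = c(1.2, 1.2, 1.2), se = c(0.3, 0.5, 0.4))
  expect_equal(dersimonian_laird(hom)$tau2, 0)
  expect_equal(dersimonian_laird(hom)$beta, fixed_effects(hom)$beta)
  expect_equal(dersimonian_laird(hom)$se, fixed_effects(hom)$se)
})

test_that("pooling agrees with metafor on arbitrary inputs", {
  set.seed(11)
  est <- data.frame(beta = rnorm(12, 0.5, 0.6), se = runif(12, 0.1, 0.5))
  fe <- fixed_effects(est)
  dl <- dersimonian_laird(est)
  m_fe <- metafor::rma(yi = est$beta, sei = est$se, method = "FE")
  m_dl <- metafor::rma(yi = est$beta, sei = est$se, method = "DL")
  expect_equal(fe$beta, as.vector(m_fe$beta), tolerance = 1e-10)
  expect_equal(fe$se, m_fe$se, tolerance = 1e-10)
  expect_equal(dl$beta, as.vector(m_dl$beta), tolerance = 1e-10)
  expect_equal(dl$se, m_dl$se, tolerance = 1e-10)
  expect_equal(dl$tau2, m_dl$tau2, tolerance = 1e-10)
  expect_equal(fe$Q, m_fe$QE, tolerance = 1e-10)
})

test_that("DL tau2 is approximately unbiased at true tau2 = 0.5", {
  k <- 50; se_i <- 0.1
  tau2_hat <- vapply(1:1000, function(r) {
    set.seed(5000 + r)
    b <- rnorm(k, 0, sqrt(0.5 + se_i^2))
    dersimonian_laird(data.frame(beta = b, se = se_i))$tau2
  }, 1)
  expect_lt(abs(mean(tau2_hat) - 0.5) / 0.5, 0.1)
})

test_that("heterogeneity statistics follow the Q / I2 definitions", {
  same <- data.frame(beta = c(2, 2, 2), se = c(1, 2, 0.5))
  h <- heterogeneity(same)
  expect_equal(h$Q, 0)
  expect_equal(h$i2, 0)
  h2 <- heterogeneity(data.frame(beta = c(0, 4), se = c(1, 1)))
  expect_equal(h2$Q, 8)
  expect_equal(h2$p_Q, pchisq(8, 1, lower.tail = FALSE))
  # I2 is clamped to [0, 100] and zero whenever Q <= k - 1
  set.seed(3)
  for (r in 1:20) {
    est <- data.frame(beta = rnorm(5), se = runif(5, 0.5, 2))
    h <- heterogeneity(est)
    expect_gte(h$i2, 0); expect_lte(h$i2, 100)
    if (h$Q <= 4) expect_equal(h$i2, 0)
  }
})

test_that("pool selects fixed vs random by the heterogeneity p-value", {
  hom <- data.frame(beta = c(1, 1.05, 0.95), se = c(0.3, 0.3, 0.3))
  expect_equal(pool(hom)$model, "fixed")
  het <- data.frame(beta = c(-3, 0, 3, 6), se = rep(0.2, 4))
  m <- pool(het)
  expect_equal(m$model, "random")
  expect_gt(m$se, fixed_effects(het)$se)
  # strict inequality at the threshold: p_Q == alpha stays fixed
  p_q <- heterogeneity(het)$p_Q
  expect_equal(pool(het, alpha_het = p_q)$model, "fixed")
})

test_that("pooled estimates are order-invariant and within the study range", {
  set.seed(13)
  est <- data.frame(beta = rnorm(9), se = runif(9, 0.2, 1))
  perm <- est[sample(9), ]
  expect_equal(fixed_effects(est)$beta, fixed_effects(perm)$beta)
  expect_equal(dersimonian_laird(est)$beta, dersimonian_laird(perm)$beta)
  for (f in list(fixed_effects, dersimonian_laird)) {
    b <- f(est)$beta
    expect_gte(b, min(est$beta)); expect_lte(b, max(est$beta))
  }
})

test_that("DL approaches fixed effects continuously as dispersion vanishes", {
  base <- c(1, 1.4, 0.6, 1.2)
  prev_gap <- Inf
  for (shrink in c(1, 0.5, 0.1, 0.01)) {
    est <- data.frame(beta = 1 + (base - 1) * shrink, se = 0.5)
    gap <- abs(dersimonian_laird(est)$se - fixed_effects(est)$se)
    expect_lte(gap, prev_gap + 1e-12)
    prev_gap <- gap
  }
  expect_lt(prev_gap, 1e-6)
})

test_that("meta-regression recovers group separation and injected trends", {
  # two groups with effects differing by delta and negligible se
  est <- data.frame(beta = c(rep(0, 5), rep(0.8, 5)), se = 1e-4)
  grp <- rep(c("a", "b"), each = 5)
  mr <- meta_regression(est, grp, reference = "a")
  expect_equal(mr$slope, 0.8, tolerance = 1e-6)
  # numeric covariate: -0.03 per age band injected into simulated estimates
  set.seed(17)
  band <- rep(0:2, length.out = 21)
  est2 <- data.frame(beta = 0.14 - 0.03 * band + rnorm(21, 0, 0.01),
                     se = 0.01)
  mr2 <- meta_regression(est2, band)
  expect_lt(abs(mr2$slope - (-0.03)), 3 * mr2$se)
})

test_that("meta-regression holds its type-I error under the null", {
  k <- 30
  pvals <- vapply(1:1000, function(r) {
    set.seed(20000 + r)
    est <- data.frame(beta = rnorm(k, 0.5, 0.3), se = runif(k, 0.05, 0.3))
    meta_regression(est, rnorm(k))$p
  }, 1)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("meta-regression validates its covariate input", {
  est <- data.frame(beta = rnorm(6), se = rep(0.2, 6))
  expect_error(meta_regression(est, rep(1, 6)), "no contrast")
  expect_error(meta_regression(est, rep("x", 6)), "no contrast")
  expect_error(meta_regression(est, rep(c("a", "b"), 3)), "reference")
  expect_error(meta_regression(est, 1:3), "one value per study")
})

test_that("multivariate pooling decouples under diagonal covariances", {
  set.seed(19)
  biv <- lapply(1:4, function(i) {
    list(beta = c(synthesis = rnorm(1), metabolism = rnorm(1)),
         cov = diag(runif(2, 0.05, 0.3)))
  })
  mv <- multivariate_pool(biv)
  for (j in 1:2) {
    uni <- fixed_effects(data.frame(
      beta = vapply(biv, function(s) s$beta[j], 1),
      se = vapply(biv, function(s) sqrt(s$cov[j, j]), 1)))
    expect_equal(unname(mv$beta[j]), uni$beta, tolerance = 1e-10)
    expect_equal(sqrt(mv$vcov[j, j]), uni$se, tolerance = 1e-10)
  }
})

test_that("multivariate pooling equals a dense stacked GLS solve", {
  set.seed(23)
  biv <- lapply(1:3, function(i) {
    A <- matrix(rnorm(4, sd = 0.3), 2)
    list(beta = c(synthesis = rnorm(1), metabolism = rnorm(1)),
         cov = crossprod(A) + diag(0.05, 2))
  })
  mv <- multivariate_pool(biv)
  # oracle: stack the 6 coefficients, X = stacked identities, block-diag V
  X <- do.call(rbind, replicate(3, diag(2), simplify = FALSE))
  y <- unlist(lapply(biv, `[[`, "beta"))
  V <- matrix(0, 6, 6)
  for (i in 1:3) {
    idx <- c(2 * i - 1, 2 * i)
    V[idx, idx] <- biv[[i]]$cov
  }
  Vi <- solve(V)
  gls_cov <- solve(t(X) %*% Vi %*% X)
  gls_beta <- as.vector(gls_cov %*% t(X) %*% Vi %*% y)
  expect_equal(unname(mv$beta), gls_beta, tolerance = 1e-10)
  expect_equal(unname(mv$vcov), unname(gls_cov), tolerance = 1e-10)
})

test_that("joint Wald p-values are uniform under the bivariate null", {
  pvals <- vapply(1:1000, function(r) {
    set.seed(30000 + r)
    biv <- lapply(1:6, function(i) {
      A <- matrix(rnorm(4, sd = 0.4), 2)
      C <- crossprod(A) + diag(0.1, 2)
      ch <- chol(C)
      list(beta = as.vector(t(ch) %*% rnorm(2)), cov = C)
    })
    multivariate_pool(biv)$joint_p
  }, 1)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("an exploding variance in one component reproduces univariate pooling", {
  set.seed(29)
  biv <- lapply(1:4, function(i) {
    list(beta = c(a = rnorm(1), b = rnorm(1)),
         cov = diag(c(0.04, 1e8)))
  })
  mv <- multivariate_pool(biv)
  uni <- fixed_effects(data.frame(
    beta = vapply(biv, function(s) s$beta["a"], 1), se = 0.2))
  expect_equal(unname(mv$beta["a"]), uni$beta, tolerance = 1e-6)
  expect_equal(sqrt(mv$vcov[1, 1]), uni$se, tolerance = 1e-6)
})

test_that("singular within-study covariances are dropped with a warning", {
  good <- list(beta = c(a = 0.1, b = 0.2), cov = diag(c(0.1, 0.1)))
  bad <- list(beta = c(a = 5, b = 5), cov = matrix(c(0.1, 0.1, 0.1, 0.1), 2))
  expect_warning(mv <- multivariate_pool(list(good, good, bad)), "dropped")
  expect_equal(mv$k, 2)
  expect_error(suppressWarnings(multivariate_pool(list(bad, bad))), "singular")
})
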