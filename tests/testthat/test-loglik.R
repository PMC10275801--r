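# joint log-densities of the model families against closed forms and
# numerical integration on toy family sets

dmvn <- function(x, S) {
  ch <- chol(S)
  z <- backsolve(ch, x, transpose = TRUE)
  exp(-0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2))
}

test_that("homoscedastic sum-score density integrates to the closed-form
          twin likelihood", {
  d <- toy_families()
  d$y <- c(0.4, -0.2, 1.1, 0.3, -0.8)
  va <- 0.5; b0 <- log(0.4)
  pars <- list(beta_sex = 0.2, beta_age = -0.1, var_a = va, beta0 = b0,
               beta1 = 0)
  mu_cov <- 0.2 * d$sex - 0.1 * d$age_std
  r <- d$y - mu_cov
  ve <- exp(b0)

  # closed form: per family multivariate normal with A integrated out
  S_mz <- matrix(c(va + ve, va, va, va + ve), 2)
  S_dz <- matrix(c(va + ve, 0.5 * va, 0.5 * va, va + ve), 2)
  ll_closed <- log(dmvn(r[1:2], S_mz)) + log(dmvn(r[3:4], S_dz)) +
    log(dmvn(r[5], matrix(va + ve)))

  # numerical integration of the joint density over the genetic latents
  grid <- seq(-4.5, 4.5, length.out = 301)
  h <- grid[2] - grid[1]
  # MZ pair: one shared A
  f_mz <- vapply(grid, function(a)
    exp(loglik_unmeasured_sum(c(pars, list(A = c(a, a))), d[1:2, ])),
    numeric(1))
  ll_mz <- log(sum(f_mz) * h)
  # DZ pair: two correlated A values on a 2-d grid (coarser, still well
  # inside the comparison tolerance)
  grid2 <- seq(-4, 4, length.out = 161)
  h2 <- grid2[2] - grid2[1]
  gd <- expand.grid(a1 = grid2, a2 = grid2)
  f_dz <- mapply(function(a1, a2)
    exp(loglik_unmeasured_sum(c(pars, list(A = c(a1, a2))), d[3:4, ])),
    gd$a1, gd$a2)
  ll_dz <- log(sum(f_dz) * h2^2)
  # DZ singleton
  f_s <- vapply(grid, function(a)
    exp(loglik_unmeasured_sum(c(pars, list(A = a)), d[5, , drop = FALSE])),
    numeric(1))
  ll_s <- log(sum(f_s) * h)

  expect_equal(ll_mz + ll_dz + ll_s, ll_closed, tolerance = 1e-4)
})

test_that("sum-score density behaves on empty and duplicated data", {
  d <- toy_families(); d$y <- c(0.4, -0.2, 1.1, 0.3, -0.8)
  pars <- list(beta_sex = 0, beta_age = 0, var_a = 0.5, beta0 = 0,
               beta1 = 0.3, A = c(0.1, 0.1, -0.2, 0.4, 0))
  expect_identical(loglik_unmeasured_sum(c(pars[1:5], list(A = numeric(0))),
                                         d[0, ]), 0)
  ll1 <- loglik_unmeasured_sum(pars, d)
  d2 <- rbind(d, transform(d, family_id = family_id + 10))
  pars2 <- pars; pars2$A <- c(pars$A, pars$A)
  expect_equal(loglik_unmeasured_sum(pars2, d2), 2 * ll1, tolerance = 1e-12)
  expect_error(loglik_unmeasured_sum(c(list(beta_sex = NaN), pars[-1]), d),
               "non-finite")
})

test_that("item-level density is additive and respects identification", {
  d <- toy_families()
  bank <- tiny_bank()
  set.seed(21)
  theta <- rnorm(5)
  Y <- simulate_item_responses(theta, bank)
  colnames(Y) <- paste0("y_", colnames(Y))
  d <- cbind(d, as.data.frame(Y))
  pars <- list(beta_sex = 0.1, beta_age = 0, var_a = 0.4, beta0 = log(0.5),
               beta1 = 0.2, A = c(0.2, 0.2, -0.1, 0.3, 0), theta = theta,
               bank = bank)
  ll <- loglik_unmeasured_item(pars, d)

  # additivity: total = latent-structure part + sum of item terms
  sum_pars <- pars; sum_pars$y <- NULL
  dsum <- d; dsum$y <- theta
  ll_struct <- loglik_unmeasured_sum(pars[c("beta_sex", "beta_age", "var_a",
                                            "beta0", "beta1", "A")],
                                     transform(d, y = theta))
  ll_items <- 0
  for (j in 1:3) {
    p <- grm_category_probs(theta, bank$items[[j]])
    ll_items <- ll_items + sum(log(p[cbind(1:5, Y[, j])]))
  }
  expect_equal(ll, ll_struct + ll_items, tolerance = 1e-10)

  # dropping an already-missing cell changes nothing
  d_miss <- d; d_miss$y_item2[3] <- NA
  ll_m <- loglik_unmeasured_item(pars, d_miss)
  p2 <- unname(grm_category_probs(theta[3], bank$items[[2]])[, Y[3, 2]])
  expect_equal(ll_m, ll - log(p2), tolerance = 1e-10)

  # first discrimination must be fixed at one
  bank_bad <- item_bank(list(grm_item(1.5, c(-1, 0, 1)),
                             bank$items[[2]], bank$items[[3]]))
  pars_bad <- pars; pars_bad$bank <- bank_bad
  expect_error(loglik_unmeasured_item(pars_bad, d), "identification")
})

test_that("rescaling discriminations against the latent scale changes the
          likelihood once alpha1 is fixed", {
  d <- toy_families()
  bank <- tiny_bank()
  set.seed(22)
  theta <- rnorm(5)
  Y <- simulate_item_responses(theta, bank)
  colnames(Y) <- paste0("y_", colnames(Y))
  d <- cbind(d, as.data.frame(Y))
  base <- list(beta_sex = 0, beta_age = 0, var_a = 0.4, beta0 = log(0.5),
               beta1 = 0, A = c(0.2, 0.2, -0.1, 0.3, 0), theta = theta,
               bank = bank)
  ll <- loglik_unmeasured_item(base, d)
  # scaling theta while keeping alpha1 = 1 shifts the first item's terms
  c2 <- 1.3
  scaled <- base
  scaled$theta <- theta * c2
  scaled$A <- base$A * c2
  scaled$var_a <- base$var_a * c2^2
  scaled$beta0 <- base$beta0 + 2 * log(c2)
  scaled$bank <- item_bank(list(
    grm_item(1, bank$items[[1]]$thresholds * c2),
    grm_item(bank$items[[2]]$alpha / c2, bank$items[[2]]$thresholds * c2),
    grm_item(bank$items[[3]]$alpha / c2, bank$items[[3]]$thresholds * c2)))
  ll_scaled <- loglik_unmeasured_item(scaled, d)
  expect_false(isTRUE(all.equal(ll, ll_scaled, tolerance = 1e-6)))
})

test_that("measured model nests the unmeasured one and matches closed forms", {
  d <- toy_families()
  d$y <- c(0.4, -0.2, 1.1, 0.3, -0.8)
  d$m <- c(0.5, -0.5, 0.2, 0.9, -1.2)
  A_std <- c(0.3, 0.3, -0.4, 0.2, 0.6)
  gamma <- 0.35
  pars_m <- list(beta_sex = 0.2, beta_age = -0.1,
                 beta1_mz = gamma, beta2_mz = 0, beta1_dz = gamma,
                 beta2_dz = 0, beta0a = 0, beta1a = 0, beta0e = log(0.4),
                 beta1e = 0, A_std = A_std)
  ll_m <- loglik_measured(pars_m, d, form = "sum")
  # with sd_a = 1 the genetic latents coincide, so regressing the moderator
  # out of y reproduces the unmeasured density
  pars_u <- list(beta_sex = 0.2, beta_age = -0.1, var_a = 1,
                 beta0 = log(0.4), beta1 = 0, A = A_std)
  ll_u <- loglik_unmeasured_sum(pars_u, transform(d, y = y - gamma * m))
  expect_equal(ll_m, ll_u, tolerance = 1e-10)

  # homoscedastic case integrates to the closed-form conditional-on-M
  # bivariate normal per pair
  pars0 <- pars_m; pars0$beta2_mz <- 0.1; pars0$beta2_dz <- 0.05
  va <- exp(pars0$beta0a); ve <- exp(pars0$beta0e)
  b2 <- ifelse(d$zygosity == "MZ", 0.1, 0.05)
  mco <- c(d$m[2], d$m[1], d$m[4], d$m[3], 0)
  mu <- 0.2 * d$sex - 0.1 * d$age_std + gamma * d$m +
    ifelse(seq_len(5) == 5, 0, b2 * mco)
  r <- d$y - mu
  S_mz <- matrix(c(va + ve, va, va, va + ve), 2)
  S_dz <- matrix(c(va + ve, 0.5 * va, 0.5 * va, va + ve), 2)
  ll_closed <- log(dmvn(r[1:2], S_mz)) + log(dmvn(r[3:4], S_dz)) +
    log(dmvn(r[5], matrix(va + ve)))
  grid <- seq(-4.5, 4.5, length.out = 301)
  h <- grid[2] - grid[1]
  int_mz <- sum(vapply(grid, function(a) {
    p <- pars0; p$A_std <- c(a, a)
    exp(loglik_measured(p, d[1:2, ], "sum"))
  }, numeric(1))) * h
  grid2 <- seq(-4, 4, length.out = 161)
  h2 <- grid2[2] - grid2[1]
  gd <- expand.grid(a1 = grid2, a2 = grid2)
  int_dz <- sum(mapply(function(a1, a2) {
    p <- pars0; p$A_std <- c(a1, a2)
    exp(loglik_measured(p, d[3:4, ], "sum"))
  }, gd$a1, gd$a2)) * h2^2
  int_s <- sum(vapply(grid, function(a) {
    p <- pars0; p$A_std <- a
    exp(loglik_measured(p, d[5, , drop = FALSE], "sum"))
  }, numeric(1))) * h
  expect_equal(log(int_mz) + log(int_dz) + log(int_s), ll_closed,
               tolerance = 1e-4)

  # monotonicity: beta1e < 0 means higher moderator, smaller E variance
  p_h2 <- list(beta0a = 0, beta1a = 0, beta0e = 0, beta1e = -0.5)
  expect_gt(derive_h2(p_h2, at = 1), derive_h2(p_h2, at = 0))
})

test_that("bivariate density factorizes, defines rA, and matches the full
          covariance oracle", {
  d <- toy_families()
  d$y1 <- c(0.4, -0.2, 1.1, 0.3, -0.8)
  d$y2 <- c(-0.1, 0.6, 0.2, -0.5, 0.9)
  A <- cbind(c(0.3, 0.3, -0.2, 0.1, 0.4), c(-0.2, -0.2, 0.5, 0, -0.3))
  beta <- matrix(c(0.1, -0.05, 0.2, 0.05), 2)   # rows sex/age, cols traits

  # diagonal matrices: the joint splits into two univariate AE densities
  SA <- diag(c(0.5, 0.4)); SE <- diag(c(0.4, 0.6))
  pars <- list(Sigma_A = SA, Sigma_E = SE, beta = beta, A = A)
  ll_bi <- loglik_bivariate(pars, d, form = "sum")
  ll_u1 <- loglik_unmeasured_sum(
    list(beta_sex = 0.1, beta_age = -0.05, var_a = 0.5, beta0 = log(0.4),
         beta1 = 0, A = A[, 1]), transform(d, y = y1))
  ll_u2 <- loglik_unmeasured_sum(
    list(beta_sex = 0.2, beta_age = 0.05, var_a = 0.4, beta0 = log(0.6),
         beta1 = 0, A = A[, 2]), transform(d, y = y2))
  expect_equal(ll_bi, ll_u1 + ll_u2, tolerance = 1e-10)

  # rA from the genetic covariance matrix
  SA2 <- matrix(c(0.5, 0.3, 0.3, 0.4), 2)
  expect_equal(0.3 / sqrt(0.5 * 0.4), SA2[1, 2] / sqrt(SA2[1, 1] * SA2[2, 2]))
  expect_error(loglik_bivariate(
    list(Sigma_A = matrix(c(1, 2, 2, 1), 2), Sigma_E = SE, beta = beta,
         A = A), d, "sum"), "positive semi-definite")

  # MZ pair: integrate the shared genetic 2-vector numerically and compare
  # with the marginal 4-dimensional normal of the pair
  SA2 <- matrix(c(0.5, 0.25, 0.25, 0.4), 2)
  SE2 <- matrix(c(0.4, 0.1, 0.1, 0.6), 2)
  dmz <- d[1:2, ]
  mu <- cbind(beta[1, 1] * dmz$sex + beta[2, 1] * dmz$age_std,
              beta[1, 2] * dmz$sex + beta[2, 2] * dmz$age_std)
  r4 <- c(dmz$y1[1] - mu[1, 1], dmz$y2[1] - mu[1, 2],
          dmz$y1[2] - mu[2, 1], dmz$y2[2] - mu[2, 2])
  S4 <- rbind(cbind(SA2 + SE2, SA2), cbind(SA2, SA2 + SE2))
  ll_closed <- log(dmvn(r4, S4))
  grid <- seq(-3.5, 3.5, length.out = 101)
  h <- grid[2] - grid[1]
  gd <- expand.grid(a1 = grid, a2 = grid)
  int <- sum(mapply(function(a1, a2) {
    p <- list(Sigma_A = SA2, Sigma_E = SE2, beta = beta,
              A = rbind(c(a1, a2), c(a1, a2)))
    exp(loglik_bivariate(p, dmz, "sum"))
  }, gd$a1, gd$a2)) * h^2
  expect_equal(log(int), ll_closed, tolerance = 1e-4)
})

test_that("log-densities are invariant to swapping twins within families", {
  d <- toy_families()
  d$y <- c(0.4, -0.2, 1.1, 0.3, -0.8)
  pars <- list(beta_sex = 0.1, beta_age = -0.1, var_a = 0.5, beta0 = 0,
               beta1 = 0.4, A = c(0.2, 0.2, -0.3, 0.5, 0.1))
  swap <- c(2, 1, 4, 3, 5)
  d2 <- d[swap, ]; d2$twin_index <- d$twin_index
  pars2 <- pars; pars2$A <- pars$A[swap]
  expect_equal(loglik_unmeasured_sum(pars, d),
               loglik_unmeasured_sum(pars2, d2), tolerance = 1e-12)
})

test_that("heritability derivations match the reported arithmetic", {
  h2 <- derive_h2(list(var_a = 0.34, beta0 = log(0.40), beta1 = 0))
  expect_equal(h2, 0.34 / 0.74, tolerance = 1e-12)
  expect_equal(round(h2, 2), 0.46)
  expect_equal(derive_h2(list(var_a = 1, beta0 = 0, beta1 = 0)), 0.5)
  # equal moderation slopes cancel in the standardized ratio
  p <- list(beta0a = log(0.3), beta1a = 0.4, beta0e = log(0.5), beta1e = 0.4)
  expect_equal(derive_h2(p, at = -1), derive_h2(p, at = 1), tolerance = 1e-12)
  expect_error(derive_h2(list(var_a = 0, beta0 = -Inf, beta1 = 0)), "zero")
})

test_that("moderation curves summarize draws pointwise", {
  one <- data.frame(beta0a = log(0.3), beta1a = -0.2, beta0e = log(0.5),
                    beta1e = 0.1)
  mc <- moderation_curve(one, grid = c(-1, 0, 1))
  expect_equal(mc$median, mc$lower, tolerance = 1e-12)
  expect_equal(mc$median[mc$quantity == "sigma2_a" & mc$grid == 1],
               exp(log(0.3) - 0.2), tolerance = 1e-12)
  set.seed(30)
  many <- data.frame(beta0a = rnorm(500, log(0.3), 0.1),
                     beta1a = rnorm(500, -0.2, 0.1),
                     beta0e = rnorm(500, log(0.5), 0.1),
                     beta1e = rnorm(500, 0.1, 0.1))
  mc2 <- moderation_curve(many, grid = seq(-2, 2, 0.5))
  h2rows <- mc2[mc2$quantity == "h2", ]
  expect_true(all(h2rows$lower >= 0 & h2rows$upper <= 1))
  expect_true(all(mc2$lower <= mc2$median & mc2$median <= mc2$upper))
  expect_error(moderation_curve(many[0, ]), "draws")
})
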