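# inference machinery: HPD, DIC, diagnostics, and sampler validation
# against closed forms, grid posteriors, and the R joint densities

test_that("HPD intervals are the shortest windows", {
  set.seed(101)
  x <- rnorm(100000)
  h <- hpd_interval(x)
  expect_equal(h[1], -1.96, tolerance = 0.03)
  expect_equal(h[2], 1.96, tolerance = 0.03)

  expect_equal(hpd_interval(rep(2.5, 500)), c(2.5, 2.5))

  y <- rexp(50000)
  he <- hpd_interval(y)
  expect_lt(he[1], 0.01)                       # lower end hugs zero
  eq <- quantile(y, c(0.025, 0.975))
  expect_lt(he[2] - he[1], eq[2] - eq[1])      # shorter than equal-tailed

  # brute force over every window of the required size
  set.seed(102)
  z <- sort(rgamma(400, 2))
  k <- ceiling(0.95 * 400)
  widths <- z[(k + 1):400] - z[1:(400 - k)]
  i <- which.min(widths)
  expect_equal(hpd_interval(z), c(z[i], z[i + k]))
  expect_error(hpd_interval(z, mass = 1.2), "mass")
})

test_that("DIC reduces to the plug-in deviance for a point-mass posterior
          and matches the conjugate effective-parameter count", {
  d <- dic(rep(123.4, 1000), 123.4)
  expect_equal(d$pD, 0)
  expect_equal(d$DIC, 123.4)
  expect_error(dic(c(rep(1, 50), rep(NA, 50)), 1), "non-finite")

  # normal mean with known variance: pD equals n * postvar / sigma^2
  set.seed(103)
  n <- 25; sigma <- 2; tau <- 3
  y <- rnorm(n, 1.3, sigma)
  postvar <- 1 / (n / sigma^2 + 1 / tau^2)
  postmean <- postvar * sum(y) / sigma^2
  mu_draws <- rnorm(20000, postmean, sqrt(postvar))
  dev <- vapply(mu_draws, function(m) -2 * sum(dnorm(y, m, sigma, log = TRUE)),
                numeric(1))
  dd <- dic(dev, -2 * sum(dnorm(y, mean(mu_draws), sigma, log = TRUE)))
  expect_equal(dd$pD, n * postvar / sigma^2, tolerance = 0.05)
})

test_that("R-hat and ESS behave on reference chains", {
  set.seed(104)
  chains <- replicate(4, rnorm(5000), simplify = FALSE)
  dg <- rhat_ess(chains)
  expect_equal(dg$rhat, 1, tolerance = 0.01)
  expect_equal(dg$ess, 20000, tolerance = 0.1)
  expect_false(dg$flag)

  apart <- list(rnorm(1000), rnorm(1000) + 10)
  expect_gt(rhat_ess(apart)$rhat, 1.1)

  single <- rhat_ess(list(rnorm(500)))
  expect_true(is.na(single$rhat) || abs(single$rhat - 1) < 0.05)
  expect_gt(single$ess, 0)
})

test_that("seeded fits are exactly reproducible", {
  cfg <- sim_config(n_mz_pairs = 40, n_dz_pairs = 40, seed = 5)
  d <- simulate_twin_data(cfg)
  mc <- mcmc_config(n_chains = 2, n_burnin = 150, n_iter = 150, seed = 11)
  f1 <- fit_twin_model(d, "unmeasured", form = "sum", gxe = TRUE, config = mc)
  f2 <- fit_twin_model(d, "unmeasured", form = "sum", gxe = TRUE, config = mc)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$summary, f2$summary)
})

test_that("posterior matches a 2-d grid oracle for the homoscedastic AE
          model, and zero covariates recover their prior", {
  set.seed(105)
  cfg <- sim_config(n_mz_pairs = 25, n_dz_pairs = 25, var_a = 0.5,
                    beta0_e = log(0.5), beta_sex = 0, beta_age = 0, seed = 9)
  d <- simulate_twin_data(cfg, bank = NULL)
  d2 <- as.data.frame(d)
  # a 7-bin coarsening of the latent acts as the single "item"; its
  # standardized score is the phenotype both the sampler and the grid see
  d2$y <- (d2$theta - mean(d2$theta)) / sd(d2$theta)

  # grid posterior over (log var_a, beta0) with the sampler's priors,
  # integrating the genetic latents analytically per family
  mz1 <- which(d2$zygosity == "MZ" & d2$twin_index == 1)
  mz2 <- which(d2$zygosity == "MZ" & d2$twin_index == 2)
  dz1 <- which(d2$zygosity == "DZ" & d2$twin_index == 1)
  dz2 <- which(d2$zygosity == "DZ" & d2$twin_index == 2)
  pair_ll <- function(va, ve, r) {
    S_mz <- matrix(c(va + ve, va, va, va + ve), 2)
    S_dz <- matrix(c(va + ve, 0.5 * va, 0.5 * va, va + ve), 2)
    ld2 <- function(S, x1, x2) {
      det <- S[1, 1] * S[2, 2] - S[1, 2]^2
      q <- (S[2, 2] * x1^2 - 2 * S[1, 2] * x1 * x2 + S[1, 1] * x2^2) / det
      -log(2 * pi) - 0.5 * log(det) - 0.5 * q
    }
    sum(ld2(S_mz, r[mz1], r[mz2])) + sum(ld2(S_dz, r[dz1], r[dz2]))
  }
  lsa_grid <- seq(log(0.05), log(3), length.out = 120)
  b0_grid <- seq(log(0.05), log(3), length.out = 120)
  prior_lsa <- function(x) -exp(x) / 12.5 + 0.5 * x

  # zero the covariates so their posteriors equal the N(0, 100) prior
  d2$sex <- 0; d2$age_std <- 0
  attr(d2, "banks") <- NULL
  d2$y_item1 <- as.integer(cut(d2$y, breaks = quantile(d2$y, 0:7 / 7),
                               include.lowest = TRUE))
  f <- fit_twin_model(structure(d2, class = c("twin_data", "data.frame")),
                      "unmeasured", form = "sum", gxe = FALSE,
                      config = mcmc_config(n_chains = 2, n_burnin = 2000,
                                           n_iter = 4000, seed = 3))
  s <- posterior_summary(f)
  # the fitted sum is the standardized 7-bin coarsening of y, so compare
  # against a grid posterior computed on that same score
  ys <- sum_scores(d2, "y", bank = NULL, standardize = TRUE)
  lp2 <- outer(lsa_grid, b0_grid, Vectorize(function(lsa, b0)
    pair_ll(exp(lsa), exp(b0), ys) + prior_lsa(lsa) - b0^2 / 200))
  w2 <- exp(lp2 - max(lp2)); w2 <- w2 / sum(w2)
  gm_va <- sum(w2 * outer(exp(lsa_grid), rep(1, 120)))
  gm_b0 <- sum(w2 * outer(rep(1, 120), b0_grid))
  expect_equal(s$mean[s$parameter == "var_a"], gm_va, tolerance = 0.08)
  expect_equal(s$mean[s$parameter == "beta0"], gm_b0, tolerance = 0.08)

  # flat-likelihood coefficients reproduce their N(0, 10^2) prior spread
  expect_gt(s$sd[s$parameter == "beta_sex"], 6)
  expect_lt(abs(s$mean[s$parameter == "beta_sex"]) /
              s$sd[s$parameter == "beta_sex"], 0.5)
})

test_that("compiled plug-in deviances agree with the R joint densities", {
  # univariate item form
  cfg <- sim_config(n_mz_pairs = 40, n_dz_pairs = 40, seed = 7)
  d <- simulate_twin_data(cfg, bank = item_bank_preset("shs"))
  f <- fit_twin_model(d, "unmeasured", form = "item", gxe = TRUE,
                      config = mcmc_config(n_chains = 1, n_burnin = 200,
                                           n_iter = 200, seed = 2))
  pm <- f$post_mean[[1]]
  bank_fit <- item_bank(mapply(function(a, th) grm_item(a, th),
                               as.list(pm$alpha), pm$thresholds,
                               SIMPLIFY = FALSE))
  Y <- as.matrix(d[, grep("^y_item", names(d))])
  for (j in c(3, 4)) Y[, j] <- 8L - Y[, j]    # undo reverse coding
  itll <- 0
  for (j in 1:4) {
    p <- grm_category_probs(pm$theta, bank_fit$items[[j]])
    itll <- itll + sum(log(p[cbind(seq_len(nrow(Y)), Y[, j])]))
  }
  devR <- -2 * itll     # observed-data focus: item responses only
  expect_equal(f$dic$Dbar - f$dic$pD, devR, tolerance = 1e-6)

  # bivariate sum form
  bc <- bivariate_sim_config(sim_config(n_mz_pairs = 30, n_dz_pairs = 30,
                                        seed = 3),
                             sim_config(), r_a = 0.5, r_e = 0.2, seed = 4)
  db <- simulate_bivariate_twin_data(bc)
  fb <- fit_twin_model(db, "bivariate", form = "sum",
                       config = mcmc_config(n_chains = 1, n_burnin = 200,
                                            n_iter = 200, seed = 5))
  s <- posterior_summary(fb)
  getm <- function(p) s$mean[s$parameter == p]
  pmb <- fb$post_mean[[1]]
  y1 <- sum_scores(db, "y", standardize = TRUE)
  y2 <- sum_scores(db, "m", standardize = TRUE)
  # posterior-mean Sigma_E is mean of Cholesky entries, matching the C++
  # accumulation; rebuild it from the returned latent means is not enough,
  # so only check that the reported deviance is finite and pD positive here
  expect_true(is.finite(fb$dic$DIC))
  expect_gt(fb$dic$pD, 0)
})

test_that("fits expose Table-style summaries, curves and draws", {
  cfg <- sim_config(n_mz_pairs = 60, n_dz_pairs = 60, seed = 13)
  d <- simulate_twin_data(cfg)
  f <- fit_twin_model(d, "unmeasured", form = "sum", gxe = TRUE,
                      config = mcmc_config(n_chains = 2, n_burnin = 300,
                                           n_iter = 300, seed = 1))
  s <- posterior_summary(f)
  expect_true(all(c("beta_sex", "beta_age", "var_a", "beta0", "beta1",
                    "h2") %in% s$parameter))
  expect_true(all(s$hpd_lower <= s$hpd_upper))
  expect_true(all(is.finite(s$mean) & is.finite(s$sd)))
  h2row <- s[s$parameter == "h2", ]
  expect_gte(h2row$hpd_lower, 0)
  expect_lte(h2row$hpd_upper, 1)

  mc <- fit_moderation_curve(f, grid = seq(-2, 2, 1))
  expect_s3_class(mc, "moderation_curve")
  expect_true(all(mc$median[mc$quantity == "sigma2_a"] ==
                    mc$median[mc$quantity == "sigma2_a"][1]))

  dd <- as.data.frame(f)
  expect_equal(nrow(dd), 600)
  expect_true(all(c("chain", "iteration", "deviance") %in% names(dd)))
  expect_output(print(f), "unmeasured")
})

test_that("missing covariates and moderators are imputed, not dropped", {
  cfg <- sim_config(n_mz_pairs = 80, n_dz_pairs = 80, seed = 23)
  d <- simulate_twin_data(cfg)
  d <- inject_missingness(d, item_rate = 0.03, covariate_rate = 0.1,
                          seed = 3)
  expect_gt(sum(is.na(d$age_std)), 0)
  f <- fit_twin_model(d, "unmeasured", form = "item", gxe = FALSE,
                      config = mcmc_config(n_chains = 1, n_burnin = 300,
                                           n_iter = 300, seed = 6))
  expect_true(all(is.finite(f$summary$mean)))
  expect_equal(f$n_twins, nrow(d))   # item form keeps everyone
})
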