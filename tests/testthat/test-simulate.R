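# synthetic twin-family generator: genetic structure, latent phenotypes,
# item responses, missingness, sum scores and moment reports

test_that("genetic values honor the twin covariance structure", {
  cfg <- sim_config(n_mz_pairs = 5, n_dz_pairs = 5, var_a = 0, seed = 1)
  expect_true(all(simulate_genetic_values(cfg)$A == 0))

  cfg <- sim_config(n_mz_pairs = 200, n_dz_pairs = 0, var_a = 0.7, seed = 2)
  g <- simulate_genetic_values(cfg)
  a1 <- g$A[g$twin_index == 1]; a2 <- g$A[g$twin_index == 2]
  expect_identical(a1, a2)            # MZ identity by definition

  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 50000, var_a = 1, seed = 3)
  g <- simulate_genetic_values(cfg)
  a1 <- g$A[g$twin_index == 1]; a2 <- g$A[g$twin_index == 2]
  expect_lt(abs(cor(a1, a2) - 0.5), 0.01)
  expect_equal(var(g$A), 1, tolerance = 0.02)
  expect_error(sim_config(var_a = -1), "var_a")
})

test_that("latent phenotype variance follows the log-linear E model", {
  # beta1 = 0: residual variance equals exp(beta0)
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 25000, var_a = 0.5,
                    beta0_e = log(0.7), beta1_e_on_a = 0, seed = 4)
  g <- simulate_genetic_values(cfg)
  set.seed(41)
  ph <- simulate_latent_phenotype(g$A, cfg)
  expect_equal(var(ph$theta - g$A), 0.7, tolerance = 0.02)

  # beta0 = beta1 = 0, A = 0, no covariates: standard normal
  cfg0 <- sim_config(beta0_e = 0, beta1_e_on_a = 0)
  set.seed(42)
  ph0 <- simulate_latent_phenotype(rep(0, 50000), cfg0)
  expect_equal(var(ph0$theta), 1, tolerance = 0.03)
  expect_equal(mean(ph0$theta), 0, tolerance = 0.02)

  # beta1 = 0.5: conditional variance in narrow bins of A tracks exp(b0+0.5a)
  cfg1 <- sim_config(n_mz_pairs = 0, n_dz_pairs = 50000, var_a = 1,
                     beta0_e = log(0.5), beta1_e_on_a = 0.5, seed = 5)
  g1 <- simulate_genetic_values(cfg1)
  set.seed(43)
  ph1 <- simulate_latent_phenotype(g1$A, cfg1)
  E <- ph1$theta - g1$A
  for (a0 in c(-1, 0, 1)) {
    sel <- abs(g1$A - a0) < 0.1
    expect_equal(var(E[sel]), exp(log(0.5) + 0.5 * a0), tolerance = 0.08)
  }
  expect_error(simulate_latent_phenotype(1:3, cfg1, sex = 1:2), "length")
})

test_that("twin covariance algebra and the lognormal variance identity hold", {
  cfg <- sim_config(n_mz_pairs = 30000, n_dz_pairs = 30000, var_a = 0.6,
                    beta0_e = log(0.4), beta1_e_on_a = 0.3,
                    beta_sex = 0, beta_age = 0, seed = 6)
  g <- simulate_genetic_values(cfg)
  set.seed(61)
  ph <- simulate_latent_phenotype(g$A, cfg)
  th <- ph$theta
  mz <- g$zygosity == "MZ"
  c_mz <- cov(th[mz & g$twin_index == 1], th[mz & g$twin_index == 2])
  c_dz <- cov(th[!mz & g$twin_index == 1], th[!mz & g$twin_index == 2])
  expect_equal(c_mz, 0.6, tolerance = 0.03)
  expect_equal(c_dz, 0.3, tolerance = 0.03)
  expect_equal(var(th), 0.6 + exp(log(0.4) + 0.3^2 * 0.6 / 2),
               tolerance = 0.03)
})

test_that("retained latent components reconstruct theta exactly", {
  cfg <- sim_config(n_mz_pairs = 50, n_dz_pairs = 50, seed = 7)
  d <- simulate_twin_data(cfg)
  rebuilt <- cfg$beta_sex * d$sex + cfg$beta_age * d$age_std + d$A + d$E
  expect_equal(d$theta, rebuilt, tolerance = 1e-12)
})

test_that("item responses follow the GRM category law", {
  # single binary item at theta = 0: top-category frequency one half
  b <- item_bank(list(grm_item(1, 0)))
  set.seed(8)
  Y <- simulate_item_responses(rep(0, 20000), b)
  expect_equal(mean(Y[, 1] == 2), 0.5, tolerance = 0.02)
  # saturation far below every threshold
  set.seed(81)
  Yl <- simulate_item_responses(rep(-20, 200), tiny_bank())
  expect_true(all(Yl == 1))
})

test_that("skew presets induce the intended sum-score regimes", {
  cfg <- sim_config(n_mz_pairs = 2500, n_dz_pairs = 2500, seed = 9)
  d <- simulate_twin_data(cfg, bank = item_bank_preset("fssq"))
  mo <- score_moments(sum_scores(d, "y"))
  expect_lt(mo$skewness, -1)

  # monotone: shifting thresholds lower makes the skew more negative
  base <- lapply(item_bank_preset("swls")$items, function(it)
    list(alpha = it$alpha, thr = it$thresholds))
  sk <- vapply(c(0.8, 0, -0.8), function(shift) {
    bank <- item_bank(lapply(base, function(b)
      grm_item(b$alpha, b$thr + shift)))
    d <- simulate_twin_data(sim_config(n_mz_pairs = 2500, n_dz_pairs = 2500,
                                       seed = 10), bank = bank)
    score_moments(sum_scores(d, "y"))$skewness
  }, numeric(1))
  expect_true(all(diff(sk) < 0))
})

test_that("missingness injection is MCAR at the requested rate", {
  cfg <- sim_config(n_mz_pairs = 1250, n_dz_pairs = 1250, seed = 11)
  d <- simulate_twin_data(cfg)   # 5000 twins x 4 items
  d0 <- inject_missingness(d, item_rate = 0, seed = 1)
  expect_identical(as.data.frame(d0)[, grep("item", names(d0))],
                   as.data.frame(d)[, grep("item", names(d))])
  d1 <- inject_missingness(d, item_rate = 1, seed = 1)
  expect_true(all(is.na(d1[, grep("item", names(d1))])))
  d05 <- inject_missingness(d, item_rate = 0.05, seed = 2)
  n_miss <- sum(is.na(d05[, grep("item", names(d05))]))
  ncells <- nrow(d) * 4
  bounds <- qbinom(c(0.005, 0.995), ncells, 0.05)
  expect_gte(n_miss, bounds[1])
  expect_lte(n_miss, bounds[2])
})

test_that("sum scores follow the one-missing-item rule and reverse coding", {
  bank <- item_bank(list(grm_item(1, c(-1, 0, 1, 2, 3, 4)),
                         grm_item(1, c(-1, 0, 1, 2, 3, 4)),
                         grm_item(1, c(-1, 0, 1, 2, 3, 4)),
                         grm_item(1, c(-1, 0, 1, 2, 3, 4)),
                         grm_item(1, c(-1, 0, 1, 2, 3, 4))))
  d <- data.frame(y_item1 = c(7, 7, 1, 7), y_item2 = c(7, NA, 1, NA),
                  y_item3 = c(7, 7, 1, NA), y_item4 = c(6, 6, 1, 7),
                  y_item5 = c(7, 7, 1, 7))
  s <- sum_scores(d, "y", bank = bank)
  expect_equal(s[1], 34)                      # plain arithmetic
  expect_equal(s[2], 6.75 * 4 + 6.75)         # person-mean imputation
  expect_equal(s[3], 5)                       # boundary: all minimum
  expect_true(is.na(s[4]))                    # two missing -> missing
  z <- sum_scores(d[1:3, ], "y", bank = bank, standardize = TRUE)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(var(z) - 1), 1e-10)

  # reverse-coded item contributes K + 1 - y
  bank_r <- item_bank(list(grm_item(1, 0), grm_item(1, 0, reverse = TRUE)))
  dr <- data.frame(y_item1 = 2, y_item2 = 1)   # K = 2, reversed 1 -> 2
  expect_equal(sum_scores(dr, "y", bank = bank_r), 4)
})

test_that("moment report uses the documented conventions", {
  expect_equal(score_moments(rep(c(-1, 1), 50))$skewness, 0)
  set.seed(12)
  x <- rexp(200000)
  expect_equal(score_moments(x)$skewness, 2, tolerance = 0.1)
  z <- rnorm(200000)
  expect_equal(score_moments(z)$kurtosis, 3, tolerance = 0.1)
  expect_equal(score_moments(z, kurtosis = "excess")$kurtosis, 0,
               tolerance = 0.1)
  expect_error(score_moments(c(1, 2)), "at least 3")
})

test_that("bivariate latents honor correlations, moderation and main effects", {
  mkcfg <- function(...) bivariate_sim_config(
    trait = sim_config(n_mz_pairs = 12500, n_dz_pairs = 12500, var_a = 0.5,
                       beta0_e = log(0.5), beta_sex = 0, beta_age = 0),
    moderator = sim_config(var_a = 0.4, beta0_e = log(0.6), beta_sex = 0,
                           beta_age = 0), ...)

  # independence case
  lat0 <- simulate_bivariate_latents(mkcfg(r_a = 0, r_e = 0, seed = 13))
  expect_lt(abs(cor(lat0$theta_mod, lat0$theta_trait)), 0.02)

  # perfect genetic correlation: genetic parts identical up to scale
  lat1 <- simulate_bivariate_latents(mkcfg(r_a = 1, r_e = 0, seed = 14))
  expect_equal(cor(lat1$A_mod, lat1$A_trait), 1, tolerance = 1e-6)

  # cross-twin cross-trait MZ covariance = r_a * sqrt(va_t * va_m)
  cfg7 <- mkcfg(r_a = 0.7, r_e = 0, seed = 15)
  lat <- simulate_bivariate_latents(cfg7)
  mz1 <- lat$zygosity == "MZ" & lat$twin_index == 1
  mz2 <- lat$zygosity == "MZ" & lat$twin_index == 2
  expect_equal(cov(lat$A_trait[mz1], lat$A_mod[mz2]),
               0.7 * sqrt(0.5 * 0.4), tolerance = 0.02)

  # moderation scales the conditional variances of the trait's components
  cfgm <- mkcfg(r_a = 0, r_e = 0, beta1a_mod = -0.4, beta1e_mod = 0.3,
                seed = 16)
  latm <- simulate_bivariate_latents(cfgm)
  E_tr <- latm$theta_trait - latm$A_trait
  for (m0 in c(-1, 1)) {
    sel <- abs(latm$theta_mod - m0) < 0.1
    expect_equal(var(latm$A_trait[sel]), 0.5 * exp(-0.4 * m0),
                 tolerance = 0.12)
    expect_equal(var(E_tr[sel]), 0.5 * exp(0.3 * m0), tolerance = 0.12)
  }
  expect_error(bivariate_sim_config(r_a = 1.2), "r_a")
})

test_that("datasets round-trip through CSV with their truth sidecar", {
  cfg <- sim_config(n_mz_pairs = 10, n_dz_pairs = 10, seed = 17)
  d <- simulate_twin_data(cfg)
  path <- tempfile(fileext = ".csv")
  write_twin_data(d, path)
  d2 <- read_twin_data(path)
  expect_equal(nrow(d2), nrow(d))
  expect_equal(d2$theta, d$theta, tolerance = 1e-12)
  expect_equal(attr(d2, "truth_json")$var_a, cfg$var_a)
  b2 <- attr(d2, "banks")$y
  expect_equal(length(b2), 4L)
  # same seed, same bytes
  path2 <- tempfile(fileext = ".csv")
  write_twin_data(simulate_twin_data(cfg), path2)
  expect_identical(readLines(path), readLines(path2))
})
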