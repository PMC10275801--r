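#' MCMC configuration
#'
#' Desk-scale defaults: 2 chains of 2,000 retained iterations after 2,000
#' burn-in each, no thinning.  Production-scale runs (more chains or the
#' classic tens-of-thousands of iterations) are configured here too.
#' Proposal scales adapt during burn-in only and are frozen afterwards, so
#' retained draws target the exact posterior.
#'
#' @param n_chains Number of chains (>= 1).
#' @param n_burnin Burn-in (adaptation) iterations per chain.
#' @param n_iter Retained iterations per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`, so a full run is
#'   reproducible bit-for-bit from the config.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_burnin = 2000L, n_iter = 2000L,
                        thin = 1L, seed = 1L) {
  stopifnot(n_chains >= 1, n_burnin >= 1, n_iter >= 1, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Highest posterior density interval
#'
#' Shortest interval containing the requested posterior mass, found by the
#' sliding-window search over the sorted draws.
#'
#' @param draws Numeric vector of posterior draws (>= 100 for a stable
#'   interval).
#' @param mass Probability mass in (0, 1).
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n < 2L) return(c(x[1], x[1]))
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean deviance, `pD = Dbar - Dhat` the effective
#' number of parameters with `Dhat` the deviance at the posterior means, and
#' `DIC = Dbar + pD`.
#'
#' @param deviance Numeric vector of per-draw deviances.
#' @param dhat Deviance evaluated at the posterior means of parameters (and,
#'   in hierarchical models, latents -- the focus must be held fixed across
#'   compared models).
#' @return List with `DIC`, `Dbar`, `pD`.
#' @export
dic <- function(deviance, dhat) {
  bad <- !is.finite(deviance)
  if (mean(bad) > 0.01) stop("deviance non-finite for more than 1% of draws")
  dbar <- mean(deviance[!bad])
  pd <- dbar - dhat
  list(DIC = dbar + pd, Dbar = dbar, pD = pd)
}

#' Split R-hat and effective sample size
#'
#' Classic split-chain potential scale reduction factor and an effective
#' sample size from the initial positive sequence of autocorrelations.
#' With a single chain R-hat is `NA` (still split for ESS).
#'
#' @param chains List of numeric vectors (one per chain) or a single vector.
#' @return List with `rhat`, `ess`, and `flag` (TRUE when R-hat > 1.05).
#' @export
rhat_ess <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  single <- length(chains) == 1L
  # split each chain in half
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    list(x[1:h], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  rhat <- if (single && W <= 0) NA_real_ else sqrt((W * (n - 1) / n + B / n) /
                                                     W)
  if (W <= 0 || !is.finite(W)) rhat <- NA_real_
  # ESS via mean autocorrelation over chains, initial positive sequence
  total <- sum(lengths(chains))
  rho_sum <- 0
  max_lag <- min(n - 2L, 200L)
  if (max_lag >= 1L && W > 0) {
    acfs <- lapply(halves, function(x)
      stats::acf(x, lag.max = max_lag, plot = FALSE,
                 demean = TRUE)$acf[-1])
    rho <- Reduce(`+`, acfs) / m
    for (l in seq_along(rho)) {
      if (rho[l] < 0.05 && (l > 1 && rho[l - 1] < 0.05)) break
      if (rho[l] > 0) rho_sum <- rho_sum + rho[l] else break
    }
  }
  ess <- total / (1 + 2 * rho_sum)
  list(rhat = rhat, ess = ess, flag = is.finite(rhat) && rhat > 1.05)
}

# ---------------------------------------------------------------------
# data preparation shared by the model fitters
# ---------------------------------------------------------------------

# 0-based family/cotwin indexing for the compiled samplers
layout_for_cpp <- function(data) {
  fam_ids <- unique(data$family_id)
  fam <- match(data$family_id, fam_ids) - 1L
  co <- cotwin_index(data$family_id, data$twin_index)
  list(fam = fam,
       zyg = ifelse(data$zygosity == "MZ", 0L, 1L),
       cotwin = ifelse(is.na(co), -1L, co - 1L))
}

# recode reverse items, validate codes, NA -> 0 for the sampler
item_matrix_for_cpp <- function(data, scale, bank) {
  cols <- grep(paste0("^", scale, "_item"), names(data), value = TRUE)
  if (length(cols) == 0L) stop(sprintf("no '%s_item*' columns found", scale))
  Y <- as.matrix(data[, cols, drop = FALSE])
  storage.mode(Y) <- "integer"
  if (!is.null(bank)) {
    if (length(bank$items) != ncol(Y))
      stop("bank size does not match the number of item columns")
    K <- bank_ncat(bank)
    rev <- bank_reverse(bank)
    for (j in which(rev)) Y[, j] <- K[j] + 1L - Y[, j]
  } else {
    K <- apply(Y, 2, function(y) max(y, na.rm = TRUE))
  }
  for (j in seq_len(ncol(Y))) {
    bad <- !is.na(Y[, j]) & (Y[, j] < 1L | Y[, j] > K[j])
    if (any(bad)) stop(sprintf("item codes out of range 1..%d in column %s",
                               K[j], cols[j]))
  }
  Y[is.na(Y)] <- 0L
  list(Y = Y, ncat = as.integer(K))
}

# threshold inits from empirical cumulative category proportions
thr_init_from_data <- function(Y, ncat) {
  lapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]; y <- y[y > 0]
    K <- ncat[j]
    tab <- tabulate(y, nbins = K) + 0.5
    cp <- rev(cumsum(rev(tab / sum(tab))))[-1]
    thr <- stats::qlogis(pmin(pmax(1 - cp, 1e-3), 1 - 1e-3))
    sort(thr) + seq(0, 1e-6, length.out = K - 1)
  })
}

theta_init_from_items <- function(Y, ncat) {
  Z <- Y
  Z[Z == 0L] <- NA
  pm <- rowMeans(sweep(Z, 2, ncat / 2, `/`), na.rm = TRUE)
  pm[!is.finite(pm)] <- 1
  as.numeric(scale(pm)) * 1.0
}

# item-layer starting values: a short phenotypic MML fit under a N(0,1)
# latent, rescaled to the alpha1 = 1 identification so the chains start
# near the right latent scale; falls back to cumulative-proportion
# thresholds when the MML fit fails
item_init_values <- function(Y, ncat) {
  fallback <- list(thr = thr_init_from_data(Y, ncat),
                   alpha = rep(1, ncol(Y)),
                   theta = theta_init_from_items(Y, ncat))
  Z <- Y
  Z[Z == 0L] <- NA
  fit <- tryCatch(
    suppressWarnings(fit_irt_mml(Z, "grm", n_categories = ncat,
                                 max_cycles = 15L, tol = 1e-3)),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$dropped) > 0) return(fallback)
  a <- vapply(fit$bank$items, `[[`, numeric(1), "alpha")
  cc <- a[1]
  thr <- lapply(fit$bank$items, function(it) cc * it$thresholds)
  list(thr = thr, alpha = a / cc, theta = fallback$theta * cc)
}

check_twin_layout <- function(data) {
  need <- c("family_id", "twin_index", "zygosity", "sex", "age_std")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tab <- table(data$family_id, data$twin_index)
  if (any(tab > 1L)) stop("at most one twin per twin_index per family")
  invisible(TRUE)
}

run_chains <- function(sampler, dat, opts, config) {
  lapply(seq_len(config$n_chains), function(ch) {
    set.seed(config$seed + ch - 1L)
    sampler(dat, opts)
  })
}

summarize_draws <- function(chain_mats) {
  pars <- colnames(chain_mats[[1]])
  out <- lapply(pars, function(p) {
    per_chain <- lapply(chain_mats, function(m) m[, p])
    x <- unlist(per_chain)
    hpd <- hpd_interval(x)
    dg <- rhat_ess(per_chain)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               hpd_lower = hpd[1], hpd_upper = hpd[2],
               rhat = dg$rhat, ess = dg$ess)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit a twin GxE / AE model by MCMC
#'
#' End-to-end Bayesian estimation of one of the three model families:
#' \describe{
#'   \item{`"unmeasured"`}{AE model with the E variance log-linear in the
#'     genotypic value A (`exp(beta0 + beta1 * A)`); `gxe = FALSE` fixes
#'     `beta1 = 0` (the plain AE model).}
#'   \item{`"measured"`}{moderated AE model: the moderator enters the trait
#'     mean through zygosity-specific own- and co-twin effects and the
#'     residual A and E variances log-linearly (`gxe = FALSE` fixes both
#'     moderation slopes at 0).}
#'   \item{`"bivariate"`}{bivariate AE decomposition with Cholesky-
#'     parametrized genetic and environmental covariance matrices.}
#' }
#' Each family is fitted either on standardized sum scores (`form = "sum"`,
#' computed with the one-missing-item rule and z-standardized) or on the
#' ordinal item responses through a graded response model measurement layer
#' (`form = "item"`), identified by a zero population mean and the first
#' discrimination fixed at 1 so the latent variance components are free.
#' Missing item responses are skipped in the likelihood; missing covariates
#' (standardized age) and, in the measured sum-score model, missing
#' moderator scores are imputed at every iteration under a `N(0, 10)`
#' (variance 10) prior.
#'
#' @param data A `twin_data` data frame (one row per twin) as produced by
#'   [simulate_twin_data()] / [simulate_bivariate_twin_data()] or read with
#'   [read_twin_data()].
#' @param family Model family, see above.
#' @param form `"item"` or `"sum"`.
#' @param gxe Estimate the interaction slope(s)?  Ignored for `"bivariate"`.
#' @param scale,moderator_scale Item-column prefixes of the trait and (for
#'   measured/bivariate fits) the moderator/second scale.
#' @param banks Optional named list of [item_bank()]s giving category counts
#'   and reverse flags per scale; defaults to the banks attached to `data`.
#'   Only the category structure and reverse flags are used -- item
#'   parameters are estimated.
#' @param score_col For `form = "sum"` only: name of a column holding a
#'   precomputed continuous phenotype score to use (standardized
#'   internally) instead of summing item columns -- for datasets that carry
#'   only total scores, or for fitting directly on a continuous measure.
#' @param config An [mcmc_config()].
#' @return An object of class `twinirt_fit`: posterior summary table
#'   (`$summary`: mean, SD, 95% HPD, split R-hat, ESS per parameter
#'   including derived heritability and, for bivariate fits, genetic and
#'   environmental correlations and bivariate heritability), `$dic`,
#'   `$draws` (per chain, including derived columns), `$post_mean` latents,
#'   and the fitting metadata.
#' @export
fit_twin_model <- function(data, family = c("unmeasured", "measured",
                                            "bivariate"),
                           form = c("item", "sum"), gxe = TRUE,
                           scale = "y", moderator_scale = "m", banks = NULL,
                           score_col = NULL, config = mcmc_config()) {
  family <- match.arg(family)
  form <- match.arg(form)
  check_twin_layout(data)
  if (is.null(banks)) banks <- attr(data, "banks")
  data <- as.data.frame(data)

  sexv <- as.numeric(data$sex)
  agev <- as.numeric(data$age_std)
  age_miss <- is.na(agev)
  agev[age_miss] <- 0

  trait_bank <- banks[[scale]]
  mod_bank <- banks[[moderator_scale]]

  prep_sum <- function(sc, bk) {
    s <- sum_scores(data, scale = sc, bank = bk, standardize = TRUE)
    s
  }

  if (form == "sum") {
    ysum <- if (!is.null(score_col)) {
      s <- as.numeric(data[[score_col]])
      (s - mean(s, na.rm = TRUE)) / stats::sd(s, na.rm = TRUE)
    } else prep_sum(scale, trait_bank)
    keep <- !is.na(ysum)
    if (family %in% c("measured", "bivariate")) {
      msum <- prep_sum(moderator_scale, mod_bank)
      if (family == "bivariate") keep <- keep & !is.na(msum)
    }
    data2 <- data[keep, , drop = FALSE]
    sexv <- sexv[keep]; agev <- agev[keep]; age_miss <- age_miss[keep]
    ysum <- ysum[keep]
    if (family %in% c("measured", "bivariate")) msum <- msum[keep]
  } else {
    data2 <- data
  }

  lay <- layout_for_cpp(data2)
  dat <- list(fam = lay$fam, zyg = lay$zyg, cotwin = lay$cotwin,
              sex = sexv, age = agev, age_miss = age_miss,
              item_level = (form == "item"))

  opts <- list(gxe = isTRUE(gxe), n_burn = config$n_burnin,
               n_iter = config$n_iter, thin = config$thin)

  if (form == "item") {
    im <- item_matrix_for_cpp(data2, scale, trait_bank)
    dat$Y <- im$Y; dat$ncat <- im$ncat
    ii <- item_init_values(im$Y, im$ncat)
    opts$thr_init <- ii$thr
    opts$alpha_init <- ii$alpha
    theta0 <- ii$theta
    if (family %in% c("measured", "bivariate")) {
      imm <- item_matrix_for_cpp(data2, moderator_scale, mod_bank)
      dat$Ym <- imm$Y; dat$ncat_m <- imm$ncat
      iim <- item_init_values(imm$Y, imm$ncat)
      opts$thr_init_m <- iim$thr
      opts$alpha_init_m <- iim$alpha
      M0 <- iim$theta
    }
  } else {
    dat$ysum <- ysum
    if (family == "measured") {
      dat$msum <- ifelse(is.na(msum), 0, msum)
      dat$m_miss <- is.na(msum)
    }
    if (family == "bivariate") dat$msum <- msum
  }

  # starting total variances follow the (scaled) latent inits
  v0 <- if (form == "item") max(stats::var(theta0), 0.1) else 1
  vm0 <- if (form == "item" && family %in% c("measured", "bivariate"))
    max(stats::var(M0), 0.1) else 1
  if (family == "unmeasured") {
    opts$init <- list(beta_sex = 0, beta_age = 0,
                      log_var_a = log(0.4 * v0), beta0 = log(0.5 * v0),
                      beta1 = 0,
                      theta = if (form == "item") theta0 else numeric(0))
    res <- run_chains(mcmc_univariate_cpp, dat, opts, config)
  } else if (family == "measured") {
    opts$init <- list(beta_sex = 0, beta_age = 0, beta1_mz = 0, beta2_mz = 0,
                      beta1_dz = 0, beta2_dz = 0,
                      beta0a = log(0.4 * v0), beta1a = 0,
                      beta0e = log(0.5 * v0), beta1e = 0,
                      log_var_a_mod = log(0.4 * vm0),
                      log_var_e_mod = log(0.5 * vm0),
                      theta = if (form == "item") theta0 else numeric(0),
                      M = if (form == "item") M0 else numeric(0))
    res <- run_chains(mcmc_measured_cpp, dat, opts, config)
  } else {
    opts$init <- list(beta_sex1 = 0, beta_age1 = 0, beta_sex2 = 0,
                      beta_age2 = 0,
                      la11 = sqrt(0.4 * v0), la21 = 0.1,
                      la22 = sqrt(0.35 * vm0),
                      le11 = sqrt(0.5 * v0), le21 = 0.1,
                      le22 = sqrt(0.45 * vm0),
                      theta1 = if (form == "item") theta0 else numeric(0),
                      theta2 = if (form == "item") M0 else numeric(0))
    res <- run_chains(mcmc_bivariate_cpp, dat, opts, config)
  }

  chain_mats <- lapply(res, function(r) add_derived(r$draws, family))
  summary <- summarize_draws(chain_mats)
  devs <- unlist(lapply(chain_mats, function(m) m[, "deviance"]))
  dhat <- mean(vapply(res, function(r) r$dhat, numeric(1)))
  dic_out <- dic(devs, dhat)

  fit <- structure(list(
    family = family, form = form, gxe = isTRUE(gxe),
    summary = summary, dic = dic_out, draws = chain_mats,
    post_mean = lapply(res, `[[`, "post_mean"),
    config = config,
    n_twins = nrow(data2),
    n_families = length(unique(data2$family_id))),
    class = "twinirt_fit")
  fit
}

# derived per-draw quantities appended as extra columns
add_derived <- function(draws, family) {
  if (family == "unmeasured") {
    h2 <- draws[, "var_a"] / (draws[, "var_a"] + exp(draws[, "beta0"]))
    cbind(draws, h2 = h2)
  } else if (family == "measured") {
    va <- exp(draws[, "beta0a"]); ve <- exp(draws[, "beta0e"])
    cbind(draws, exp_beta0a = va, exp_beta0e = ve, h2 = va / (va + ve))
  } else {
    a11 <- draws[, "a11"]; a21 <- draws[, "a21"]; a22 <- draws[, "a22"]
    e11 <- draws[, "e11"]; e21 <- draws[, "e21"]; e22 <- draws[, "e22"]
    cbind(draws,
          r_a = a21 / sqrt(a11 * a22), r_e = e21 / sqrt(e11 * e22),
          h2_trait1 = a11 / (a11 + e11), h2_trait2 = a22 / (a22 + e22),
          bivariate_h2 = a21 / (a21 + e21),
          r_p = (a21 + e21) / sqrt((a11 + e11) * (a22 + e22)))
  }
}

#' @export
print.twinirt_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Twin %s model (%s form%s): %d twins in %d families\n",
              x$family, x$form,
              if (x$family != "bivariate")
                paste0(", GxE ", if (x$gxe) "estimated" else "fixed at 0")
              else "",
              x$n_twins, x$n_families))
  cat(sprintf("%d chain(s) x %d retained iterations\n",
              x$config$n_chains, x$config$n_iter))
  s <- x$summary
  main <- s[!grepl("^(thr|y_thr|m_thr|alpha|y_alpha|m_alpha)", s$parameter), ]
  main[-1] <- lapply(main[-1], round, digits = digits)
  print(main, row.names = FALSE)
  cat(sprintf("DIC %.2f (Dbar %.2f, pD %.2f)\n",
              x$dic$DIC, x$dic$Dbar, x$dic$pD))
  invisible(x)
}

#' Posterior summary table of a fit
#'
#' @param fit A `twinirt_fit`.
#' @param params Optional character vector restricting to some parameters.
#' @return Data frame with mean, SD, 95% HPD bounds, R-hat and ESS.
#' @export
posterior_summary <- function(fit, params = NULL) {
  s <- fit$summary
  if (!is.null(params)) s <- s[s$parameter %in% params, ]
  s
}

#' Posterior draws of a fit as one data frame
#'
#' @param x A `twinirt_fit`.
#' @param ... Unused.
#' @return Data frame of stacked chains with `chain` and `iteration`
#'   columns.
#' @export
as.data.frame.twinirt_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(seq_along(x$draws), function(ch) {
    d <- as.data.frame(x$draws[[ch]])
    d$chain <- ch
    d$iteration <- seq_len(nrow(d))
    d
  }))
  out
}

#' Moderation curve from a fitted model
#'
#' @param fit A `twinirt_fit` of family `"unmeasured"` or `"measured"`.
#' @param grid Grid of genotypic values (unmeasured) or moderator levels
#'   (measured).
#' @return A [moderation_curve()] data frame.
#' @export
fit_moderation_curve <- function(fit, grid = seq(-2, 2, by = 0.25)) {
  if (fit$family == "bivariate")
    stop("moderation curves apply to unmeasured/measured fits")
  d <- as.data.frame.twinirt_fit(fit)
  if (fit$family == "measured") {
    moderation_curve(d[, c("beta0a", "beta1a", "beta0e", "beta1e")], grid)
  } else {
    moderation_curve(d[, c("var_a", "beta0", "beta1")], grid)
  }
}
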