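# Joint log-densities of the twin GxE model families, written directly from
# the model definitions.  Latent values enter as part of the parameter list,
# so each function returns the joint density of (data, latents) given the
# structural parameters -- the target the MCMC sampler explores.  These pure
# R versions are the reference the compiled sampler is tested against.

ld_norm <- function(x, mean, sd) stats::dnorm(x, mean, sd, log = TRUE)

# log density of a zero-mean multivariate normal (small dimension)
ld_mvnorm <- function(x, Sigma) {
  p <- length(x)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("covariance matrix not positive definite")
  z <- backsolve(ch, x, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# log structure density of per-twin genetic values with variance var_a:
# MZ co-twins share one N(0, var_a) value, DZ co-twins are jointly normal
# with correlation 0.5.  `A` is per-twin; MZ pairs must carry equal values.
ld_genetic_structure <- function(A, zygosity, family_id, var_a) {
  if (length(A) == 0L) return(0)
  if (var_a <= 0) stop("var_a must be > 0 for a proper structure density")
  ll <- 0
  for (f in unique(family_id)) {
    idx <- which(family_id == f)
    a <- A[idx]
    if (zygosity[idx[1]] == "MZ") {
      if (length(idx) == 2L && abs(a[1] - a[2]) > 1e-9)
        stop("MZ co-twins must share identical A values")
      ll <- ll + ld_norm(a[1], 0, sqrt(var_a))
    } else if (length(idx) == 2L) {
      ll <- ll + ld_mvnorm(a, var_a * matrix(c(1, 0.5, 0.5, 1), 2))
    } else {
      ll <- ll + ld_norm(a, 0, sqrt(var_a))
    }
  }
  ll
}

# GRM log-likelihood of a response matrix given per-twin theta; NA skipped
ld_items <- function(Y, theta, bank) {
  ll <- 0
  for (j in seq_along(bank$items)) {
    it <- bank$items[[j]]
    y <- Y[, j]
    if (isTRUE(it$reverse)) y <- n_categories(it) + 1L - y
    obs <- which(!is.na(y))
    if (!length(obs)) next
    p <- grm_category_probs(theta[obs], it)
    ll <- ll + sum(log(pmax(p[cbind(seq_along(obs), y[obs])], 1e-300)))
  }
  ll
}

check_finite <- function(params) {
  bad <- vapply(params, function(p) any(!is.finite(unlist(p))), logical(1))
  if (any(bad)) stop("non-finite parameter(s): ",
                     paste(names(params)[bad], collapse = ", "))
}

#' Joint log-density, unmeasured GxE, sum-score form
#'
#' Each twin's standardized sum is normal with mean
#' `beta_sex * sex + beta_age * age_std + A` and variance
#' `exp(beta0 + beta1 * A)`; the genetic values follow the AE twin structure
#' (MZ shared, DZ correlation 0.5).
#'
#' @param params List with `beta_sex`, `beta_age`, `var_a`, `beta0`, `beta1`
#'   and the per-twin genetic values `A`.
#' @param data Data frame with columns `y` (standardized sum), `sex`,
#'   `age_std`, `zygosity`, `family_id`.
#' @return Scalar joint log density of the sums and the genetic values.
#' @export
loglik_unmeasured_sum <- function(params, data) {
  check_finite(params[c("beta_sex", "beta_age", "var_a", "beta0", "beta1")])
  if (nrow(data) == 0L) return(0)
  A <- params$A
  mu <- params$beta_sex * data$sex + params$beta_age * data$age_std + A
  sd_e <- sqrt(exp(params$beta0 + params$beta1 * A))
  sum(ld_norm(data$y, mu, sd_e)) +
    ld_genetic_structure(A, data$zygosity, data$family_id, params$var_a)
}

#' Joint log-density, unmeasured GxE, item-level form
#'
#' As [loglik_unmeasured_sum()] but the latent phenotype `theta` replaces
#' the observed sum and each twin contributes the GRM log-probability of its
#' item responses given `theta`.  Identification requires the population
#' mean fixed at 0 (no intercept) and the first item discrimination fixed at
#' 1; a bank violating the latter is rejected.
#'
#' @param params As in [loglik_unmeasured_sum()] plus per-twin `theta` and
#'   the GRM `bank`.
#' @param data Data frame with item columns `y_item*` plus `sex`, `age_std`,
#'   `zygosity`, `family_id`.
#' @return Scalar joint log density of (responses, theta, A).
#' @export
loglik_unmeasured_item <- function(params, data) {
  check_finite(params[c("beta_sex", "beta_age", "var_a", "beta0", "beta1")])
  if (nrow(data) == 0L) return(0)
  bank <- params$bank
  if (abs(bank$items[[1]]$alpha - 1) > 1e-12)
    stop("identification: the first item discrimination must be fixed at 1")
  A <- params$A; theta <- params$theta
  Y <- as.matrix(data[, grep("^y_item", names(data)), drop = FALSE])
  mu <- params$beta_sex * data$sex + params$beta_age * data$age_std + A
  sd_e <- sqrt(exp(params$beta0 + params$beta1 * A))
  ld_items(Y, theta, bank) +
    sum(ld_norm(theta, mu, sd_e)) +
    ld_genetic_structure(A, data$zygosity, data$family_id, params$var_a)
}

cotwin_index <- function(family_id, twin_index) {
  n <- length(family_id)
  co <- rep(NA_integer_, n)
  for (f in unique(family_id)) {
    idx <- which(family_id == f)
    if (length(idx) == 2L) co[idx] <- rev(idx)
  }
  co
}

#' Joint log-density, measured-moderator GxE
#'
#' Trait mean: covariates plus zygosity-specific own- and co-twin moderator
#' main effects (`beta1_mz`, `beta2_mz`, `beta1_dz`, `beta2_dz`; singletons
#' use the own effect only).  Trait variances: `sigma2_A =
#' exp(beta0a + beta1a * M)` and `sigma2_E = exp(beta0e + beta1e * M)` at
#' the twin's own moderator level, with the genetic part built as
#' `sqrt(sigma2_A) * A_std` from standard-normal AE-structured latents.  In
#' the item form the moderator is itself a latent with its own AE
#' decomposition and GRM layer; in the sum form it is the observed
#' standardized sum.
#'
#' @param params List with `beta_sex`, `beta_age`, `beta1_mz`, `beta2_mz`,
#'   `beta1_dz`, `beta2_dz`, `beta0a`, `beta1a`, `beta0e`, `beta1e`, per-twin
#'   `A_std`; item form adds `theta` (trait latent), `M` (moderator latent),
#'   `var_a_mod`, `var_e_mod`, per-twin `A_mod`, and banks `trait_bank`,
#'   `mod_bank`.
#' @param data Data frame with `sex`, `age_std`, `zygosity`, `family_id`,
#'   `twin_index`, plus `y`/`m` (sum form) or `y_item*`/`m_item*` columns.
#' @param form `"sum"` or `"item"`.
#' @return Scalar joint log density.
#' @export
loglik_measured <- function(params, data, form = c("sum", "item")) {
  form <- match.arg(form)
  check_finite(params[c("beta_sex", "beta_age", "beta1_mz", "beta2_mz",
                        "beta1_dz", "beta2_dz", "beta0a", "beta1a",
                        "beta0e", "beta1e")])
  if (nrow(data) == 0L) return(0)
  n <- nrow(data)
  co <- cotwin_index(data$family_id, data$twin_index)
  M <- if (form == "item") params$M else data$m
  if (form == "sum" && anyNA(M))
    stop("missing moderator values in sum form must be imputed (latent) values")
  M_co <- ifelse(is.na(co), NA_real_, M[co])
  b1 <- ifelse(data$zygosity == "MZ", params$beta1_mz, params$beta1_dz)
  b2 <- ifelse(data$zygosity == "MZ", params$beta2_mz, params$beta2_dz)
  mu <- params$beta_sex * data$sex + params$beta_age * data$age_std +
    b1 * M + ifelse(is.na(co), 0, b2 * ifelse(is.na(M_co), 0, M_co))
  sd_a <- sqrt(exp(params$beta0a + params$beta1a * M))
  sd_e <- sqrt(exp(params$beta0e + params$beta1e * M))
  phen <- if (form == "item") params$theta else data$y
  ll <- sum(ld_norm(phen, mu + sd_a * params$A_std, sd_e)) +
    ld_genetic_structure(params$A_std, data$zygosity, data$family_id, 1)
  if (form == "item") {
    Yt <- as.matrix(data[, grep("^y_item", names(data)), drop = FALSE])
    Ym <- as.matrix(data[, grep("^m_item", names(data)), drop = FALSE])
    if (abs(params$trait_bank$items[[1]]$alpha - 1) > 1e-12 ||
        abs(params$mod_bank$items[[1]]$alpha - 1) > 1e-12)
      stop("identification: first discriminations must be fixed at 1")
    ll <- ll + ld_items(Yt, params$theta, params$trait_bank) +
      ld_items(Ym, M, params$mod_bank) +
      sum(ld_norm(M, params$A_mod, sqrt(params$var_e_mod))) +
      ld_genetic_structure(params$A_mod, data$zygosity, data$family_id,
                           params$var_a_mod)
  }
  ll
}

#' Joint log-density, bivariate AE model
#'
#' Standard bivariate AE twin likelihood: per twin, the 2-vector phenotype
#' is `covariates + A + E` with `A ~ N2(0, Sigma_A)` following the twin
#' structure (cross-twin genetic covariance `Sigma_A` for MZ, `0.5 Sigma_A`
#' for DZ) and `E ~ N2(0, Sigma_E)` independent across twins.  The item form
#' replaces the observed score 2-vector with IRT-linked latents.
#'
#' @param params List with `Sigma_A`, `Sigma_E` (2x2 PSD), `beta` (2x2
#'   matrix: rows sex/age, columns trait 1/2), `A` (n x 2 matrix of genetic
#'   latents); item form adds `theta` (n x 2) and `banks` (list of two GRM
#'   banks).
#' @param data Data frame with `sex`, `age_std`, `zygosity`, `family_id`,
#'   plus `y1`/`y2` (sum form) or `y_item*`/`m_item*` (item form).
#' @param form `"sum"` or `"item"`.
#' @return Scalar joint log density.
#' @export
loglik_bivariate <- function(params, data, form = c("sum", "item")) {
  form <- match.arg(form)
  SA <- params$Sigma_A; SE <- params$Sigma_E
  if (any(eigen(SA, symmetric = TRUE, only.values = TRUE)$values < -1e-10) ||
      any(eigen(SE, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("covariance matrices must be positive semi-definite")
  if (nrow(data) == 0L) return(0)
  n <- nrow(data)
  A <- params$A
  phen <- if (form == "item") params$theta else
    cbind(data$y1, data$y2)
  mu <- cbind(params$beta[1, 1] * data$sex + params$beta[2, 1] * data$age_std,
              params$beta[1, 2] * data$sex + params$beta[2, 2] * data$age_std)
  ll <- 0
  for (i in seq_len(n))
    ll <- ll + ld_mvnorm(phen[i, ] - mu[i, ] - A[i, ], SE)
  # genetic structure per family
  for (f in unique(data$family_id)) {
    idx <- which(data$family_id == f)
    if (data$zygosity[idx[1]] == "MZ") {
      if (length(idx) == 2L && max(abs(A[idx[1], ] - A[idx[2], ])) > 1e-9)
        stop("MZ co-twins must share identical A vectors")
      ll <- ll + ld_mvnorm(A[idx[1], ], SA)
    } else if (length(idx) == 2L) {
      big <- rbind(cbind(SA, 0.5 * SA), cbind(0.5 * SA, SA))
      ll <- ll + ld_mvnorm(c(A[idx[1], ], A[idx[2], ]), big)
    } else {
      ll <- ll + ld_mvnorm(A[idx, ], SA)
    }
  }
  if (form == "item") {
    Y1 <- as.matrix(data[, grep("^y_item", names(data)), drop = FALSE])
    Y2 <- as.matrix(data[, grep("^m_item", names(data)), drop = FALSE])
    ll <- ll + ld_items(Y1, params$theta[, 1], params$banks[[1]]) +
      ld_items(Y2, params$theta[, 2], params$banks[[2]])
  }
  ll
}

#' Heritability at a reference level
#'
#' `h2 = sigma2_A(ref) / (sigma2_A(ref) + sigma2_E(ref))`.  For the
#' unmeasured model the reference is a genotypic value (default `A = 0`, so
#' `sigma2_E = exp(beta0)`); for the measured model it is a moderator level
#' (default `M = 0`, the standardized moderator mean).
#'
#' @param params List with `var_a`, `beta0`, `beta1` (unmeasured) or
#'   `beta0a`, `beta1a`, `beta0e`, `beta1e` (measured).
#' @param at Reference level of A or M.
#' @return Scalar heritability in `[0, 1]`.
#' @export
derive_h2 <- function(params, at = 0) {
  if (!is.null(params$beta0a)) {
    va <- exp(params$beta0a + params$beta1a * at)
    ve <- exp(params$beta0e + params$beta1e * at)
  } else {
    va <- params$var_a
    ve <- exp(params$beta0 + params$beta1 * at)
  }
  if (va + ve == 0) stop("both variance components are zero")
  va / (va + ve)
}

#' Variance and heritability moderation curves from posterior draws
#'
#' Evaluates `sigma2_A(m)`, `sigma2_E(m)` and `h2(m)` on a grid for every
#' posterior draw and summarizes each pointwise with the posterior median
#' and a central 95% band.  For the unmeasured model the grid runs over
#' genotypic values and only `sigma2_E(a)` varies.
#'
#' @param draws Data frame or matrix of posterior draws containing columns
#'   `beta0a`, `beta1a`, `beta0e`, `beta1e` (measured) or `var_a`, `beta0`,
#'   `beta1` (unmeasured).
#' @param grid Numeric grid of moderator (or genotypic) values.
#' @return A data frame of class `moderation_curve` with columns `grid`,
#'   `quantity` (`sigma2_a`, `sigma2_e`, `h2`), `median`, `lower`, `upper`.
#' @export
moderation_curve <- function(draws, grid = seq(-2, 2, by = 0.25)) {
  draws <- as.data.frame(draws)
  if (nrow(draws) == 0L) stop("no posterior draws supplied")
  measured <- "beta0a" %in% names(draws)
  out <- lapply(grid, function(g) {
    if (measured) {
      va <- exp(draws$beta0a + draws$beta1a * g)
      ve <- exp(draws$beta0e + draws$beta1e * g)
    } else {
      va <- draws$var_a
      ve <- exp(draws$beta0 + draws$beta1 * g)
    }
    h2 <- va / (va + ve)
    qs <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(grid = g,
               quantity = c("sigma2_a", "sigma2_e", "h2"),
               rbind(qs(va), qs(ve), qs(h2)))
  })
  out <- do.call(rbind, out)
  names(out)[3:5] <- c("median", "lower", "upper")
  rownames(out) <- NULL
  class(out) <- c("moderation_curve", "data.frame")
  out
}
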