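#' Generator configuration (univariate)
#'
#' Settings for simulating additive-genetic (A) and latent phenotype values
#' for MZ/DZ twin families under the AE model with optional unmeasured AxE
#' interaction: the non-shared environmental variance of each twin is
#' `exp(beta0_e + beta1_e_on_a * A)`, so `beta1_e_on_a = 0` gives the
#' homoscedastic AE model.
#'
#' Defaults emulate a well-being-like trait on the latent scale: heritability
#' 0.45 with unit total variance (`var_a = 0.45`, `exp(beta0_e) = 0.55`),
#' small negative sex and age effects on the latent mean, and no true
#' interaction.
#'
#' @param n_mz_pairs,n_dz_pairs Numbers of complete MZ and DZ pairs.
#' @param var_a Additive genetic variance (>= 0).
#' @param beta0_e Log baseline E variance.
#' @param beta1_e_on_a Unmeasured AxE slope on the log E variance.
#' @param beta_sex,beta_age Covariate effects on the latent mean (sex coded
#'   -0.5/+0.5, age standardized).
#' @param seed Master RNG seed; all sub-streams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 500L, n_dz_pairs = 500L, var_a = 0.45,
                       beta0_e = log(0.55), beta1_e_on_a = 0,
                       beta_sex = -0.1, beta_age = -0.1, seed = 1L) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0)
  if (var_a < 0) stop("var_a must be >= 0")
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 var_a = var_a, beta0_e = beta0_e,
                 beta1_e_on_a = beta1_e_on_a,
                 beta_sex = beta_sex, beta_age = beta_age,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generator configuration (bivariate / measured moderator)
#'
#' Joint settings for a trait and a moderator, each with its own AE
#' decomposition, genetic and environmental correlations between them, and
#' optional measured-moderator GxE: the trait's residual A and E variances
#' scale as `exp(beta1a_mod * M)` and `exp(beta1e_mod * M)` with the
#' moderator's latent level `M`, after the moderator's main effect (own- and
#' co-twin, zygosity-specific) has entered the trait mean.
#'
#' @param trait,moderator [sim_config()] objects for the two phenotypes
#'   (their count and seed fields are taken from `trait`).
#' @param r_a,r_e Genetic and environmental correlations in `[-1, 1]`.
#' @param beta1a_mod,beta1e_mod Moderation slopes of the trait's log A and
#'   log E variance on the moderator level.
#' @param beta1_mz,beta2_mz,beta1_dz,beta2_dz Own- and co-twin moderator
#'   main effects on the trait mean by zygosity.
#' @param seed Master RNG seed.
#' @return A list of class `bivariate_sim_config`.
#' @export
bivariate_sim_config <- function(trait = sim_config(), moderator = sim_config(),
                                 r_a = 0.6, r_e = 0.25,
                                 beta1a_mod = 0, beta1e_mod = 0,
                                 beta1_mz = 0, beta2_mz = 0,
                                 beta1_dz = 0, beta2_dz = 0, seed = 1L) {
  if (abs(r_a) > 1 || abs(r_e) > 1) stop("|r_a| and |r_e| must be <= 1")
  structure(list(trait = trait, moderator = moderator, r_a = r_a, r_e = r_e,
                 beta1a_mod = beta1a_mod, beta1e_mod = beta1e_mod,
                 beta1_mz = beta1_mz, beta2_mz = beta2_mz,
                 beta1_dz = beta1_dz, beta2_dz = beta2_dz,
                 seed = as.integer(seed)),
            class = "bivariate_sim_config")
}

# family frame shared by the simulators: one row per twin
family_frame <- function(n_mz, n_dz) {
  n_fam <- n_mz + n_dz
  if (n_fam == 0L) {
    return(data.frame(family_id = integer(0), twin_index = integer(0),
                      zygosity = character(0)))
  }
  data.frame(
    family_id = rep(seq_len(n_fam), each = 2L),
    twin_index = rep(1:2, n_fam),
    zygosity = rep(c("MZ", "DZ")[rep(1:2, c(n_mz, n_dz))], each = 2L),
    stringsAsFactors = FALSE)
}

#' Simulate additive genetic values
#'
#' MZ co-twins receive identical A values; DZ co-twins receive
#' `A = sqrt(0.5) * A_common + sqrt(0.5) * A_specific` with both parts
#' `N(0, var_a)`, giving marginal variance `var_a` and co-twin covariance
#' `0.5 * var_a`.
#'
#' @param config A [sim_config()].
#' @return A data frame (one row per twin) with `family_id`, `twin_index`,
#'   `zygosity`, and the genetic value `A`.
#' @export
simulate_genetic_values <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fam <- family_frame(config$n_mz_pairs, config$n_dz_pairs)
  fam$A <- draw_genetic(fam$zygosity, fam$family_id, config$var_a)
  fam
}

# A values for an arbitrary zygosity/family layout; uses the current RNG
# stream.  Correlated-with supplies standard-normal common/specific parts to
# reuse (for cross-trait genetic correlation); when NULL fresh ones are drawn.
draw_genetic <- function(zygosity, family_id, var_a, parts = NULL) {
  n <- length(zygosity)
  fams <- unique(family_id)
  if (is.null(parts)) {
    zc <- stats::rnorm(length(fams))            # family-common standard part
    zs <- stats::rnorm(n)                       # twin-specific standard part
    parts <- list(common = zc[match(family_id, fams)], specific = zs)
  }
  sdA <- sqrt(var_a)
  ifelse(zygosity == "MZ",
         sdA * parts$common,
         sdA * (sqrt(0.5) * parts$common + sqrt(0.5) * parts$specific))
}

# standard-normal genetic parts for one layout (for building correlated traits)
draw_genetic_parts <- function(zygosity, family_id) {
  fams <- unique(family_id)
  zc <- stats::rnorm(length(fams))
  list(common = zc[match(family_id, fams)],
       specific = stats::rnorm(length(zygosity)))
}

genetic_from_parts <- function(zygosity, var_a, parts) {
  sdA <- sqrt(var_a)
  ifelse(zygosity == "MZ",
         sdA * parts$common,
         sdA * (sqrt(0.5) * parts$common + sqrt(0.5) * parts$specific))
}

#' Simulate latent phenotype values
#'
#' `theta = beta_sex * sex + beta_age * age_std + A + E` with
#' `E ~ N(0, exp(beta0_e + beta1_e_on_a * A))`, independent across twins
#' given A.
#'
#' @param A Per-twin genetic values.
#' @param config A [sim_config()].
#' @param sex Numeric sex code per twin (-0.5/+0.5 in generated data).
#' @param age Standardized age per twin.
#' @return A data frame with columns `theta` and `E`.
#' @export
simulate_latent_phenotype <- function(A, config, sex = NULL, age = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(A)
  if (is.null(sex)) sex <- numeric(n)
  if (is.null(age)) age <- numeric(n)
  if (length(sex) != n || length(age) != n)
    stop("length mismatch between A and covariates")
  E <- stats::rnorm(n, 0, sqrt(exp(config$beta0_e + config$beta1_e_on_a * A)))
  data.frame(theta = config$beta_sex * sex + config$beta_age * age + A + E,
             E = E)
}

#' Simulate GRM item responses
#'
#' Each response is drawn from the graded-response category distribution at
#' the twin's latent value; responses are conditionally independent given
#' theta.  For items flagged reverse-coded the bank parameters describe the
#' recoded (indicative-direction) item; the emitted raw code is flipped to
#' `K + 1 - y`, mirroring how non-indicative questionnaire items arrive
#' before recoding.
#'
#' @param theta Per-twin latent values.
#' @param bank A GRM [item_bank()].
#' @return Integer matrix `length(theta) x J` of codes 1..K.
#' @export
simulate_item_responses <- function(theta, bank) {
  stopifnot(inherits(bank, "item_bank"))
  if (bank$family != "grm") stop("response simulation implemented for GRM banks")
  n <- length(theta)
  Y <- matrix(NA_integer_, n, length(bank$items))
  for (j in seq_along(bank$items)) {
    p <- grm_category_probs(theta, bank$items[[j]])
    cum <- t(apply(p, 1, cumsum))
    cum[, ncol(cum)] <- 1
    u <- stats::runif(n)
    y <- max.col(u <= cum, ties.method = "first")
    if (isTRUE(bank$items[[j]]$reverse))
      y <- n_categories(bank$items[[j]]) + 1L - y
    Y[, j] <- y
  }
  colnames(Y) <- paste0("item", seq_len(ncol(Y)))
  Y
}

#' Simulate a complete univariate twin dataset
#'
#' Draws genetic values, covariates (sex -0.5/+0.5 shared within a pair at
#' random; age standardized within the sample, shared within a pair), the
#' latent phenotype, and GRM item responses.  True latent values are
#' retained for recovery audits.
#'
#' @param config A [sim_config()].
#' @param bank A GRM [item_bank()]; `NULL` skips the item layer.
#' @param scale_name Column prefix for the item responses.
#' @return A data frame of class `twin_data`, one row per twin, with the
#'   bank(s) attached as attribute `banks` and the generating config as
#'   attribute `truth`.
#' @export
simulate_twin_data <- function(config, bank = item_bank_preset("shs"),
                               scale_name = "y") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fam <- family_frame(config$n_mz_pairs, config$n_dz_pairs)
  n <- nrow(fam)
  n_fam <- config$n_mz_pairs + config$n_dz_pairs
  fam$A <- draw_genetic(fam$zygosity, fam$family_id, config$var_a)
  sex_f <- sample(c(-0.5, 0.5), n_fam, replace = TRUE)
  age_f <- stats::rnorm(n_fam, 35, 13)
  fam$sex <- sex_f[fam$family_id]
  fam$age <- age_f[fam$family_id]
  fam$age_std <- if (n > 0) as.numeric(scale(fam$age)) else numeric(0)
  ph <- simulate_latent_phenotype(fam$A, config, fam$sex, fam$age_std)
  fam$theta <- ph$theta
  fam$E <- ph$E
  if (!is.null(bank)) {
    Y <- simulate_item_responses(fam$theta, bank)
    colnames(Y) <- paste0(scale_name, "_", colnames(Y))
    fam <- cbind(fam, as.data.frame(Y))
  }
  structure(fam, class = c("twin_data", "data.frame"),
            banks = stats::setNames(list(bank), scale_name),
            truth = config)
}

#' Simulate correlated trait and moderator latents
#'
#' The moderator latent is built from its own AE decomposition.  The trait's
#' genetic and environmental standard parts correlate with the moderator's
#' via `r_a` and `r_e`; the trait mean includes the zygosity-specific own-
#' and co-twin moderator main effects; and when moderation is on the trait's
#' A and E variances scale as `exp(beta1a_mod * M)` and `exp(beta1e_mod * M)`
#' at the twin's own moderator level.
#'
#' @param config A [bivariate_sim_config()].
#' @param sex,age Optional per-twin covariates entering both latent means
#'   via each phenotype's own `beta_sex`/`beta_age`.
#' @param fam Optional family frame (from [family_frame()] layout); when
#'   `NULL` one is built from `config$trait`.
#' @return A data frame with per-twin `theta_mod`, `theta_trait`, true
#'   components `A_mod`, `A_trait`, and the family layout columns.
#' @export
simulate_bivariate_latents <- function(config, sex = NULL, age = NULL,
                                       fam = NULL) {
  stopifnot(inherits(config, "bivariate_sim_config"))
  tr <- config$trait; mo <- config$moderator
  if (is.null(fam)) {
    set.seed(config$seed)
    fam <- family_frame(tr$n_mz_pairs, tr$n_dz_pairs)
  }
  n <- nrow(fam)
  if (is.null(sex)) sex <- numeric(n)
  if (is.null(age)) age <- numeric(n)

  # moderator: AE with its own variances
  pm <- draw_genetic_parts(fam$zygosity, fam$family_id)
  A_mod <- genetic_from_parts(fam$zygosity, mo$var_a, pm)
  E_mod_z <- stats::rnorm(n)
  E_mod <- sqrt(exp(mo$beta0_e)) * E_mod_z
  theta_mod <- mo$beta_sex * sex + mo$beta_age * age + A_mod + E_mod
  M <- theta_mod

  # trait standard genetic parts correlated r_a with the moderator's
  pt <- draw_genetic_parts(fam$zygosity, fam$family_id)
  mix <- function(zm, zt, r) r * zm + sqrt(1 - r^2) * zt
  parts_tr <- list(common = mix(pm$common, pt$common, config$r_a),
                   specific = mix(pm$specific, pt$specific, config$r_a))
  A_std <- genetic_from_parts(fam$zygosity, 1, parts_tr)  # unit-variance part
  sd_a <- sqrt(tr$var_a * exp(config$beta1a_mod * M))
  A_trait <- sd_a * A_std

  E_tr_z <- mix(E_mod_z, stats::rnorm(n), config$r_e)
  sd_e <- sqrt(exp(tr$beta0_e + config$beta1e_mod * M))
  E_trait <- sd_e * E_tr_z

  co <- ifelse(fam$twin_index == 1, 1L, -1L)
  idx_cotwin <- seq_len(n) + co
  M_cotwin <- M[idx_cotwin]
  b1 <- ifelse(fam$zygosity == "MZ", config$beta1_mz, config$beta1_dz)
  b2 <- ifelse(fam$zygosity == "MZ", config$beta2_mz, config$beta2_dz)
  theta_trait <- tr$beta_sex * sex + tr$beta_age * age +
    b1 * M + b2 * M_cotwin + A_trait + E_trait

  cbind(fam, data.frame(theta_mod = theta_mod, theta_trait = theta_trait,
                        A_mod = A_mod, A_trait = A_trait, A_std = A_std))
}

#' Simulate a bivariate (trait + moderator) twin dataset with item responses
#'
#' @param config A [bivariate_sim_config()].
#' @param trait_bank,moderator_bank GRM item banks for the two scales.
#' @return A `twin_data` data frame with item columns `y_item*` (trait) and
#'   `m_item*` (moderator), true latents retained.
#' @export
simulate_bivariate_twin_data <- function(config,
                                         trait_bank = item_bank_preset("shs"),
                                         moderator_bank = item_bank_preset("fssq")) {
  tr <- config$trait
  set.seed(config$seed)
  fam <- family_frame(tr$n_mz_pairs, tr$n_dz_pairs)
  n_fam <- tr$n_mz_pairs + tr$n_dz_pairs
  sex_f <- sample(c(-0.5, 0.5), n_fam, replace = TRUE)
  age_f <- stats::rnorm(n_fam, 35, 13)
  fam$sex <- sex_f[fam$family_id]
  fam$age <- age_f[fam$family_id]
  fam$age_std <- if (nrow(fam) > 0) as.numeric(scale(fam$age)) else numeric(0)
  lat <- simulate_bivariate_latents(config, fam$sex, fam$age_std, fam = fam)
  Yt <- simulate_item_responses(lat$theta_trait, trait_bank)
  Ym <- simulate_item_responses(lat$theta_mod, moderator_bank)
  colnames(Yt) <- paste0("y_", colnames(Yt))
  colnames(Ym) <- paste0("m_", colnames(Ym))
  out <- cbind(lat, as.data.frame(Yt), as.data.frame(Ym))
  structure(out, class = c("twin_data", "data.frame"),
            banks = list(y = trait_bank, m = moderator_bank),
            truth = config)
}

#' Mask item responses and covariates completely at random
#'
#' True values are retained in attribute `masked_truth` so imputation audits
#' can compare against them.
#'
#' @param data A `twin_data` data frame.
#' @param item_rate,covariate_rate Missingness probabilities in `[0, 1]`.
#' @param seed RNG seed.
#' @return The dataset with NA injected.
#' @export
inject_missingness <- function(data, item_rate = 0, covariate_rate = 0,
                               seed = 1L) {
  stopifnot(item_rate >= 0, item_rate <= 1,
            covariate_rate >= 0, covariate_rate <= 1)
  set.seed(seed)
  item_cols <- grep("item", names(data), value = TRUE)
  masked <- list()
  for (cl in item_cols) {
    hit <- stats::runif(nrow(data)) < item_rate
    masked[[cl]] <- data.frame(row = which(hit), value = data[[cl]][hit])
    data[[cl]][hit] <- NA
  }
  if ("age_std" %in% names(data) && covariate_rate > 0) {
    hit <- stats::runif(nrow(data)) < covariate_rate
    masked[["age_std"]] <- data.frame(row = which(hit),
                                      value = data$age_std[hit])
    data$age_std[hit] <- NA
  }
  attr(data, "masked_truth") <- masked
  data
}

#' Sum scores from item responses
#'
#' Reverse-coded items are recoded `K + 1 - y` before summing.  A twin's
#' score is computed when at most one item on the scale is missing: the
#' single missing item is filled with the twin's mean over the observed
#' items (person-mean imputation); with more than one missing item the score
#' is NA.
#'
#' @param data A `twin_data` data frame (or any data frame with the item
#'   columns).
#' @param scale Column prefix of the scale (`"y"` selects `y_item*`).
#' @param bank The scale's [item_bank()]; defaults to the bank attached to
#'   `data`.
#' @param standardize When `TRUE` the scores are z-standardized over the
#'   non-missing values.
#' @return Numeric per-twin score vector.
#' @export
sum_scores <- function(data, scale = "y", bank = NULL, standardize = FALSE) {
  if (is.null(bank)) bank <- attr(data, "banks")[[scale]]
  cols <- grep(paste0("^", scale, "_item"), names(data), value = TRUE)
  if (length(cols) == 0L) stop(sprintf("no item columns for scale '%s'", scale))
  Y <- as.matrix(data[, cols, drop = FALSE])
  if (!is.null(bank)) {
    K <- bank_ncat(bank); rev <- bank_reverse(bank)
    for (j in which(rev)) Y[, j] <- K[j] + 1L - Y[, j]
  }
  n_miss <- rowSums(is.na(Y))
  s <- rowSums(Y, na.rm = TRUE) +
    ifelse(n_miss == 1, rowMeans(Y, na.rm = TRUE), 0)
  s[n_miss > 1] <- NA
  s[rowSums(!is.na(Y)) == 0] <- NA
  if (standardize) s <- (s - mean(s, na.rm = TRUE)) / stats::sd(s, na.rm = TRUE)
  s
}

#' Sample skewness and kurtosis
#'
#' Adjusted Fisher-Pearson skewness; kurtosis reported raw (normal = 3) by
#' default, or as excess kurtosis.
#'
#' @param scores Numeric vector (NA dropped); at least 3 values required.
#' @param kurtosis One of `"raw"` or `"excess"`.
#' @return A list with `skewness`, `kurtosis`, `n`.
#' @export
score_moments <- function(scores, kurtosis = c("raw", "excess")) {
  kurtosis <- match.arg(kurtosis)
  x <- scores[!is.na(scores)]
  n <- length(x)
  if (n < 3L) stop("at least 3 non-missing scores required")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  kraw <- m4 / m2^2
  list(skewness = skew,
       kurtosis = if (kurtosis == "raw") kraw else kraw - 3,
       n = n)
}

#' Write a twin dataset as CSV with a JSON truth sidecar
#'
#' @param data A `twin_data` data frame.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path` invisibly.
#' @export
write_twin_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  truth <- attr(data, "truth")
  banks <- attr(data, "banks")
  side <- list(
    truth = if (!is.null(truth)) unclass_deep(truth) else NULL,
    banks = if (!is.null(banks))
      lapply(banks, function(b) if (is.null(b)) NULL else
        jsonlite::fromJSON(write_item_bank(b), simplifyVector = FALSE))
    else NULL)
  writeLines(as.character(jsonlite::toJSON(side, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             paste0(path, ".json"))
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Read a twin dataset written by [write_twin_data()]
#'
#' @param path CSV path.
#' @return A `twin_data` data frame; the truth sidecar, when present, is
#'   attached as attribute `truth_json`.
#' @export
read_twin_data <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  side_path <- paste0(path, ".json")
  banks <- NULL; side <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::fromJSON(side_path, simplifyVector = FALSE)
    if (!is.null(side$banks)) {
      banks <- lapply(side$banks, function(b)
        read_item_bank(as.character(jsonlite::toJSON(b, auto_unbox = TRUE,
                                                     digits = NA))))
    }
  }
  structure(d, class = c("twin_data", "data.frame"),
            banks = banks, truth_json = side$truth)
}
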