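#' GRM category probabilities
#'
#' Cumulative-logit graded response model: `P*(k) = plogis(alpha * (theta -
#' beta_k))` is the probability of responding in category `k` or above, and
#' category probabilities are differences of adjacent cumulative curves.
#' The logistic link is used without the 1.7 scaling constant.
#'
#' @param theta Numeric vector of latent trait values.
#' @param item A [grm_item()].
#' @return A matrix `length(theta) x K` of category probabilities (rows sum
#'   to one).
#' @export
grm_category_probs <- function(theta, item) {
  stopifnot(inherits(item, "grm_item"))
  K <- n_categories(item)
  if (length(theta) == 0L)
    return(matrix(numeric(0), 0, K, dimnames = list(NULL, seq_len(K))))
  cum <- cbind(1, stats::plogis(outer(theta, item$thresholds,
                                      function(t, b) item$alpha * (t - b))),
               0)
  p <- cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE]
  dimnames(p) <- list(NULL, seq_len(K))
  p
}

#' GPCM category probabilities
#'
#' Adjacent-category (softmax) model: the log score of category `k` is the
#' cumulative sum `alpha * sum_{v<=k} (theta - delta_v)`, with an empty sum
#' for the first category.
#'
#' @param theta Numeric vector of latent trait values.
#' @param item A [gpcm_item()].
#' @return A matrix `length(theta) x K` of category probabilities.
#' @export
gpcm_category_probs <- function(theta, item) {
  stopifnot(inherits(item, "gpcm_item"))
  K <- n_categories(item)
  # scores: n x K, column k = alpha * ((k-1) theta - sum steps[1:(k-1)])
  csteps <- c(0, cumsum(item$steps))
  s <- item$alpha * (outer(theta, 0:(K - 1)) -
                       matrix(csteps, length(theta), K, byrow = TRUE))
  s <- s - apply(s, 1, max)
  e <- exp(s)
  p <- e / rowSums(e)
  dimnames(p) <- list(NULL, seq_len(K))
  p
}

category_probs <- function(theta, item) {
  if (inherits(item, "grm_item")) grm_category_probs(theta, item)
  else gpcm_category_probs(theta, item)
}

#' Item information function
#'
#' Fisher information of a single item at latent value `theta`: the expected
#' negative second derivative of the log category probability,
#' `sum_k P_k'(theta)^2 / P_k(theta)`.
#'
#' @param theta Numeric vector.
#' @param item A [grm_item()] or [gpcm_item()].
#' @return Numeric vector of the same length as `theta`.
#' @export
item_information <- function(theta, item) {
  if (inherits(item, "grm_item")) {
    K <- n_categories(item)
    cum <- cbind(1, stats::plogis(outer(theta, item$thresholds,
                                        function(t, b) item$alpha * (t - b))),
                 0)
    dcum <- item$alpha * cum * (1 - cum)     # derivative of each P*
    dcum[, 1] <- 0; dcum[, K + 1] <- 0
    p <- cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE]
    dp <- dcum[, 1:K, drop = FALSE] - dcum[, 2:(K + 1), drop = FALSE]
    rowSums(dp^2 / pmax(p, 1e-300))
  } else {
    p <- gpcm_category_probs(theta, item)
    K <- ncol(p)
    scores <- matrix(0:(K - 1), nrow(p), K, byrow = TRUE)
    m1 <- rowSums(p * scores)
    m2 <- rowSums(p * scores^2)
    item$alpha^2 * (m2 - m1^2)
  }
}

#' Test information function
#'
#' Information is additive over the items of a bank.
#'
#' @param theta Numeric vector of latent values.
#' @param bank An [item_bank()].
#' @return Numeric vector of total information at each `theta`.
#' @export
test_information <- function(theta, bank) {
  stopifnot(inherits(bank, "item_bank"))
  Reduce(`+`, lapply(bank$items, function(it) item_information(theta, it)))
}

#' Information curve table
#'
#' Evaluates per-item and total test information on a latent grid; the tidy
#' long-format analogue of a test information plot.
#'
#' @param bank An [item_bank()].
#' @param grid Numeric grid of latent values.
#' @return A data frame with columns `theta`, `item` (item index or
#'   `"total"`), `information`.
#' @export
information_table <- function(bank, grid = seq(-4, 4, by = 0.1)) {
  per <- lapply(seq_along(bank$items), function(j)
    data.frame(theta = grid, item = as.character(j),
               information = item_information(grid, bank$items[[j]])))
  tot <- data.frame(theta = grid, item = "total",
                    information = test_information(grid, bank))
  rbind(do.call(rbind, per), tot)
}

# fixed quadrature grid used for EAP scoring and MML fitting
quad_grid <- function(n = 61L, lim = 6) {
  x <- seq(-lim, lim, length.out = n)
  list(nodes = x, step = x[2] - x[1])
}

#' EAP latent trait score
#'
#' Posterior mean and standard deviation of the latent trait given a
#' response pattern, under a normal prior, computed on a fixed quadrature
#' grid.  Missing responses (NA) are skipped.
#'
#' @param responses Integer vector of category codes (1..K per item), length
#'   equal to the bank; NA allowed.
#' @param bank An [item_bank()].
#' @param prior_mean,prior_var Normal prior on the latent trait.
#' @param n_quad Number of quadrature nodes.
#' @return A list with elements `theta` (posterior mean) and `se` (posterior
#'   SD).
#' @export
eap_score <- function(responses, bank, prior_mean = 0, prior_var = 1,
                      n_quad = 61L) {
  stopifnot(inherits(bank, "item_bank"),
            length(responses) == length(bank$items))
  if (all(is.na(responses))) {
    return(list(theta = prior_mean, se = sqrt(prior_var)))
  }
  q <- quad_grid(n_quad)
  lw <- stats::dnorm(q$nodes, prior_mean, sqrt(prior_var), log = TRUE)
  for (j in seq_along(bank$items)) {
    y <- responses[j]
    if (is.na(y)) next
    K <- n_categories(bank$items[[j]])
    if (y < 1 || y > K) stop(sprintf("response %d out of range for item %d", y, j))
    p <- category_probs(q$nodes, bank$items[[j]])[, y]
    lw <- lw + log(pmax(p, 1e-300))
  }
  w <- exp(lw - max(lw)); w <- w / sum(w)
  m <- sum(w * q$nodes)
  v <- sum(w * (q$nodes - m)^2)
  list(theta = m, se = sqrt(v))
}

#' Empirical reliability
#'
#' Single-number reliability of a set of latent trait estimates:
#' `Var(theta_hat) / (Var(theta_hat) + mean(SE^2))`.
#'
#' @param theta_estimates Numeric vector of trait estimates.
#' @param theta_ses Matching vector of their standard errors.
#' @return Scalar in `[0, 1]`.
#' @export
empirical_reliability <- function(theta_estimates, theta_ses) {
  if (length(theta_estimates) == 0L) stop("empty input")
  stopifnot(length(theta_estimates) == length(theta_ses))
  v <- stats::var(theta_estimates)
  if (!is.finite(v)) stop("variance of estimates not finite")
  if (v == 0) return(0)
  v / (v + mean(theta_ses^2))
}

# expected log-lik tables and M-step helpers for Bock-Aitkin MML-EM -------

# r: K x Q expected counts for one item; returns function of packed params
grm_pack <- function(alpha, thresholds)
  c(log(alpha), thresholds[1], log(diff(c(thresholds[1], thresholds))[-1]))

grm_unpack <- function(par, K) {
  alpha <- exp(par[1])
  # floor on the spacings keeps optim trajectories strictly ordered
  thr <- if (K == 2L) par[2] else
    cumsum(c(par[2], pmax(exp(par[3:K]), 1e-6)))
  list(alpha = alpha, thresholds = thr)
}

#' Fit an IRT model by marginal maximum likelihood
#'
#' Bock-Aitkin EM with a fixed `N(0,1)` latent distribution on a 61-point
#' quadrature grid; the standard identification for phenotypic (single
#' phenotype, unrelated individuals) IRT analyses.  Items observed in fewer
#' than two categories are excluded with a warning.  Missing responses are
#' skipped in the likelihood (missing at random).
#'
#' @param data Integer matrix or data frame, rows = persons, columns =
#'   items, codes 1..K, NA allowed.
#' @param family `"grm"` or `"gpcm"`.
#' @param n_categories Optional vector giving K per item; defaults to the
#'   maximum observed code per item.
#' @param max_cycles,tol EM control: maximum cycles and log-likelihood
#'   convergence tolerance.
#' @return A list with the fitted `bank`, `loglik`, `AIC`, `BIC`, `n_params`,
#'   number of EM `cycles`, and the indices of any `dropped` items.
#' @export
fit_irt_mml <- function(data, family = c("grm", "gpcm"), n_categories = NULL,
                        max_cycles = 200L, tol = 1e-5) {
  family <- match.arg(family)
  Y <- as.matrix(data)
  if (nrow(Y) == 0L) stop("no response rows")
  storage.mode(Y) <- "integer"
  J <- ncol(Y)
  if (is.null(n_categories)) {
    n_categories <- apply(Y, 2, function(y) max(y, na.rm = TRUE))
  }
  keep <- vapply(seq_len(J), function(j)
    length(unique(stats::na.omit(Y[, j]))) >= 2L, logical(1))
  dropped <- which(!keep)
  if (length(dropped)) {
    warning(sprintf("item(s) %s observed in a single category; excluded",
                    paste(dropped, collapse = ", ")))
    Y <- Y[, keep, drop = FALSE]
    n_categories <- n_categories[keep]
    J <- ncol(Y)
    if (J == 0L) stop("no usable items")
  }

  q <- quad_grid()
  Q <- length(q$nodes)
  Aw <- stats::dnorm(q$nodes); Aw <- Aw / sum(Aw)

  # initial items from empirical cumulative proportions
  items <- lapply(seq_len(J), function(j) {
    K <- n_categories[j]
    tab <- tabulate(Y[, j], nbins = K)
    cp <- rev(cumsum(rev(tab / sum(tab))))[-1]        # P(Y >= k), k = 2..K
    thr <- stats::qlogis(pmin(pmax(1 - cp, 1e-3), 1 - 1e-3))
    thr <- sort(thr) + seq(0, 1e-6, length.out = K - 1)   # enforce strict order
    if (family == "grm") grm_item(1, thr) else gpcm_item(1, thr)
  })

  prob_arr <- function(items) {
    lapply(items, function(it) category_probs(q$nodes, it))  # each Q x K
  }

  loglik_of <- function(P) {
    lp <- matrix(0, nrow(Y), Q)
    for (j in seq_len(J)) {
      obs <- !is.na(Y[, j])
      lp[obs, ] <- lp[obs, ] + log(pmax(t(P[[j]])[Y[obs, j], , drop = FALSE],
                                        1e-300))
    }
    # t(P[[j]]) is K x Q; indexing rows by observed codes gives n_obs x Q
    m <- apply(lp, 1, max)
    sum(m + log(as.vector(exp(lp - m) %*% Aw)))
  }

  ll_old <- -Inf; cycles <- 0L
  for (cyc in seq_len(max_cycles)) {
    cycles <- cyc
    P <- prob_arr(items)
    lp <- matrix(0, nrow(Y), Q)
    for (j in seq_len(J)) {
      obs <- !is.na(Y[, j])
      lp[obs, ] <- lp[obs, ] + log(pmax(t(P[[j]])[Y[obs, j], , drop = FALSE],
                                        1e-300))
    }
    m <- apply(lp, 1, max)
    w <- exp(lp - m) * matrix(Aw, nrow(Y), Q, byrow = TRUE)
    w <- w / rowSums(w)                               # posterior weights n x Q
    # expected counts and per-item M-step
    for (j in seq_len(J)) {
      K <- n_categories[j]
      obs <- which(!is.na(Y[, j]))
      r <- matrix(0, K, Q)
      for (k in seq_len(K)) {
        idx <- obs[Y[obs, j] == k]
        if (length(idx)) r[k, ] <- colSums(w[idx, , drop = FALSE])
      }
      it <- items[[j]]
      if (family == "grm") {
        par0 <- grm_pack(it$alpha, it$thresholds)
        nll <- function(par) {
          if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
          up <- grm_unpack(par, K)
          if (any(!is.finite(up$thresholds)) || !is.finite(up$alpha))
            return(1e10)
          p <- grm_category_probs(q$nodes, grm_item(up$alpha, up$thresholds))
          -sum(r * t(log(pmax(p, 1e-300))))
        }
        opt <- stats::optim(par0, nll, method = "BFGS",
                            control = list(maxit = 50))
        up <- grm_unpack(opt$par, K)
        items[[j]] <- grm_item(up$alpha, up$thresholds, reverse = it$reverse)
      } else {
        par0 <- c(log(it$alpha), it$steps)
        nll <- function(par) {
          if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
          p <- gpcm_category_probs(q$nodes, gpcm_item(exp(par[1]), par[-1]))
          -sum(r * t(log(pmax(p, 1e-300))))
        }
        opt <- stats::optim(par0, nll, method = "BFGS",
                            control = list(maxit = 50))
        items[[j]] <- gpcm_item(exp(opt$par[1]), opt$par[-1],
                                reverse = it$reverse)
      }
    }
    ll <- loglik_of(prob_arr(items))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { ll_old <- ll; break }
    ll_old <- ll
  }

  n_par <- sum(n_categories)  # alpha + (K-1) params per item
  bank <- item_bank(items)
  list(bank = bank, loglik = ll_old, AIC = -2 * ll_old + 2 * n_par,
       BIC = -2 * ll_old + log(nrow(Y)) * n_par, n_params = n_par,
       cycles = cycles, dropped = dropped)
}
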