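# File-based pipeline front end: simulate / fit / compare / irt-info.
# Each run writes machine-readable outputs plus a JSON provenance record
# (config, seed, package version) sufficient to reproduce them exactly.

provenance <- function(config_list, path) {
  rec <- list(config = config_list,
              package = "twinirt",
              version = as.character(utils::packageVersion("twinirt")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              timestamp_utc = format(Sys.time(), tz = "UTC",
                                     "%Y-%m-%dT%H:%M:%SZ"))
  writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             path)
  invisible(path)
}

#' Simulate a dataset from a JSON-style run configuration
#'
#' Configuration fields: `kind` (`"univariate"` or `"bivariate"`), `preset`
#' (trait bank preset) and `moderator_preset`, `seed`, plus any
#' [sim_config()] / [bivariate_sim_config()] fields under `sim`.  Writes the
#' dataset CSV, its truth sidecar, a provenance record, and logs a sample
#' summary (pair counts by zygosity, sum-score skewness per scale).
#'
#' @param config List (or path to a JSON file) with the fields above.
#' @param out Output CSV path.
#' @param quiet Suppress the console summary.
#' @return The dataset, invisibly.
#' @export
run_simulate <- function(config, out, quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  kind <- if (is.null(config$kind)) "univariate" else config$kind
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  simargs <- if (is.null(config$sim)) list() else config$sim

  if (kind == "univariate") {
    sc <- do.call(sim_config, c(simargs, list(seed = seed)))
    preset <- if (is.null(config$preset)) "shs" else config$preset
    d <- simulate_twin_data(sc, bank = item_bank_preset(preset))
    scales <- "y"
  } else if (kind == "bivariate") {
    tr <- do.call(sim_config, c(simargs$trait %||% list(), list(seed = seed)))
    mo <- do.call(sim_config, simargs$moderator %||% list())
    extra <- simargs[setdiff(names(simargs), c("trait", "moderator"))]
    bc <- do.call(bivariate_sim_config,
                  c(list(trait = tr, moderator = mo, seed = seed), extra))
    preset <- if (is.null(config$preset)) "shs" else config$preset
    mpreset <- if (is.null(config$moderator_preset)) "fssq"
               else config$moderator_preset
    d <- simulate_bivariate_twin_data(bc,
                                      trait_bank = item_bank_preset(preset),
                                      moderator_bank = item_bank_preset(mpreset))
    scales <- c("y", "m")
  } else stop("unknown simulation kind: ", kind)

  if (!is.null(config$missing)) {
    d <- inject_missingness(d,
                            item_rate = config$missing$item_rate %||% 0,
                            covariate_rate = config$missing$covariate_rate %||% 0,
                            seed = seed + 1000L)
  }

  write_twin_data(d, out)
  provenance(config, paste0(out, ".provenance.json"))

  if (!quiet && nrow(d) > 0) {
    tab <- table(d$zygosity) / 2
    cat(sprintf("simulated %d twins (%d MZ pairs, %d DZ pairs)\n",
                nrow(d), tab[["MZ"]], tab[["DZ"]]))
    for (sc in scales) {
      s <- sum_scores(d, sc)
      mo <- score_moments(s)
      cat(sprintf("  scale %s: sum skewness %.2f, kurtosis %.2f\n",
                  sc, mo$skewness, mo$kurtosis))
    }
  }
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a model from a run configuration and write report files
#'
#' Writes `<out>_summary.csv` (posterior point estimates, SDs, 95% HPD
#' bounds, R-hat, ESS), `<out>_dic.json`, `<out>_curve.csv` (moderation
#' curve, when applicable) and a provenance record.  With
#' `compare_null = TRUE` the matching no-GxE model is fitted too and both
#' DICs reported.
#'
#' @param data_path CSV written by [run_simulate()] / [write_twin_data()].
#' @param config List (or JSON path) with `family`, `form`, `gxe`,
#'   `compare_null`, `seed` and optional `mcmc` fields
#'   (`n_chains`, `n_burnin`, `n_iter`, `thin`).
#' @param out Output path stem.
#' @return The fit (with `$null_fit` attached when `compare_null`),
#'   invisibly.
#' @export
run_fit <- function(data_path, config, out) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  d <- read_twin_data(data_path)
  mc <- config$mcmc %||% list()
  cfg <- mcmc_config(n_chains = mc$n_chains %||% 2L,
                     n_burnin = mc$n_burnin %||% 2000L,
                     n_iter = mc$n_iter %||% 2000L,
                     thin = mc$thin %||% 1L,
                     seed = config$seed %||% 1L)
  fit <- fit_twin_model(d, family = config$family %||% "unmeasured",
                        form = config$form %||% "item",
                        gxe = config$gxe %||% TRUE,
                        config = cfg)
  utils::write.csv(fit$summary, paste0(out, "_summary.csv"),
                   row.names = FALSE)
  dics <- list(model = fit$dic)
  if (isTRUE(config$compare_null) && fit$family != "bivariate") {
    null_fit <- fit_twin_model(d, family = fit$family, form = fit$form,
                               gxe = FALSE, config = cfg)
    dics$null <- null_fit$dic
    fit$null_fit <- null_fit
  }
  writeLines(as.character(jsonlite::toJSON(dics, auto_unbox = TRUE,
                                           digits = NA)),
             paste0(out, "_dic.json"))
  if (fit$family != "bivariate") {
    utils::write.csv(fit_moderation_curve(fit), paste0(out, "_curve.csv"),
                     row.names = FALSE)
  }
  provenance(config, paste0(out, "_provenance.json"))
  invisible(fit)
}

#' Compare posterior summary files side by side
#'
#' Joins two summary CSVs on parameter name and flags sign flips of the
#' point estimates and changes of HPD-based significance (interval excludes
#' zero) -- the headline contrast between sum-score and item-level fits.
#'
#' @param paths Character vector of at least two `_summary.csv` files (or a
#'   list of summary data frames).
#' @param labels Column labels, defaulting to file basenames.
#' @return Data frame with per-parameter estimates under each fit and
#'   `sign_flip` / `significance_change` flags for the first pair.
#' @export
run_compare <- function(paths, labels = NULL) {
  sums <- lapply(paths, function(p) {
    s <- if (is.character(p)) utils::read.csv(p, stringsAsFactors = FALSE)
         else as.data.frame(p)
    need <- c("parameter", "mean", "hpd_lower", "hpd_upper")
    miss <- setdiff(need, names(s))
    if (length(miss)) stop("summary schema mismatch: missing column(s) ",
                           paste(miss, collapse = ", "))
    s
  })
  if (length(sums) < 2L) stop("at least two summaries required")
  if (is.null(labels)) {
    labels <- if (is.character(paths)) basename(unlist(paths))
              else paste0("fit", seq_along(sums))
  }
  common <- Reduce(intersect, lapply(sums, `[[`, "parameter"))
  out <- data.frame(parameter = common, stringsAsFactors = FALSE)
  for (i in seq_along(sums)) {
    s <- sums[[i]][match(common, sums[[i]]$parameter), ]
    out[[paste0("mean_", labels[i])]] <- s$mean
    out[[paste0("sig_", labels[i])]] <- s$hpd_lower > 0 | s$hpd_upper < 0
  }
  m1 <- sums[[1]][match(common, sums[[1]]$parameter), ]
  m2 <- sums[[2]][match(common, sums[[2]]$parameter), ]
  out$sign_flip <- sign(m1$mean) != sign(m2$mean) &
    abs(m1$mean) > 1e-12 & abs(m2$mean) > 1e-12
  out$significance_change <-
    (m1$hpd_lower > 0 | m1$hpd_upper < 0) !=
    (m2$hpd_lower > 0 | m2$hpd_upper < 0)
  out
}

#' Export test information curves for a bank preset or bank file
#'
#' @param bank An [item_bank()], a preset name, or a path to a bank JSON.
#' @param out Output CSV path.
#' @param grid Latent grid.
#' @return The information table, invisibly.
#' @export
run_irt_info <- function(bank, out, grid = seq(-4, 4, by = 0.1)) {
  if (is.character(bank)) {
    bank <- if (file.exists(bank)) read_item_bank(bank)
            else item_bank_preset(bank)
  }
  tab <- information_table(bank, grid)
  utils::write.csv(tab, out, row.names = FALSE)
  invisible(tab)
}
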