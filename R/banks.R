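#' Graded response model item
#'
#' Constructs a single GRM item with discrimination `alpha` and strictly
#' increasing thresholds on the latent scale.  An item with `K` ordered
#' response categories has `K - 1` thresholds.
#'
#' @param alpha Positive discrimination (slope) parameter.
#' @param thresholds Numeric vector of strictly increasing category
#'   thresholds.
#' @param reverse Logical; `TRUE` marks a non-indicative item whose observed
#'   codes are reverse-coded before sum-scoring.
#' @return An object of class `grm_item`.
#' @examples
#' it <- grm_item(1.5, c(-2, -1, 0, 1))
#' grm_category_probs(0, it)
#' @export
grm_item <- function(alpha, thresholds, reverse = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0) stop("discrimination 'alpha' must be > 0")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L) stop("at least one threshold required (K >= 2)")
  if (any(!is.finite(thresholds))) stop("thresholds must be finite")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("GRM thresholds must be strictly increasing")
  structure(list(alpha = alpha, thresholds = thresholds,
                 reverse = isTRUE(reverse)),
            class = c("grm_item", "irt_item"))
}

#' Generalized partial credit model item
#'
#' Step difficulties are unconstrained (no ordering requirement), one fewer
#' than the number of categories.
#'
#' @param alpha Positive discrimination parameter.
#' @param steps Numeric vector of step difficulty parameters.
#' @param reverse Logical reverse-coding flag.
#' @return An object of class `gpcm_item`.
#' @export
gpcm_item <- function(alpha, steps, reverse = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0) stop("discrimination 'alpha' must be > 0")
  steps <- as.numeric(steps)
  if (length(steps) < 1L) stop("at least one step required (K >= 2)")
  if (any(!is.finite(steps))) stop("steps must be finite")
  structure(list(alpha = alpha, steps = steps, reverse = isTRUE(reverse)),
            class = c("gpcm_item", "irt_item"))
}

n_categories <- function(item) {
  length(if (inherits(item, "grm_item")) item$thresholds else item$steps) + 1L
}

#' Item bank
#'
#' An ordered collection of items of one model family (all GRM or all GPCM)
#' forming a scale.
#'
#' @param items List of [grm_item()] or [gpcm_item()] objects.
#' @param name Optional scale name.
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(items, name = NULL) {
  if (length(items) == 0L) stop("item bank must contain at least one item")
  grm <- vapply(items, inherits, logical(1), what = "grm_item")
  gpcm <- vapply(items, inherits, logical(1), what = "gpcm_item")
  if (!(all(grm) || all(gpcm)))
    stop("all items must belong to the same model family (GRM or GPCM)")
  structure(list(items = items,
                 family = if (all(grm)) "grm" else "gpcm",
                 name = name),
            class = "item_bank")
}

#' @export
length.item_bank <- function(x) length(x$items)

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %s: %d %s item(s), %s categories\n",
              if (is.null(x$name)) "(unnamed)" else x$name,
              length(x$items), toupper(x$family),
              paste(unique(vapply(x$items, n_categories, integer(1))),
                    collapse = "/")))
  invisible(x)
}

bank_alphas <- function(bank) vapply(bank$items, `[[`, numeric(1), "alpha")
bank_ncat <- function(bank) vapply(bank$items, n_categories, integer(1))
bank_reverse <- function(bank) vapply(bank$items, `[[`, logical(1), "reverse")

#' Bundled skew-calibrated item banks
#'
#' Three GRM presets emulating short well-being / social-support Likert
#' scales whose sum scores show ceiling effects: `"swls"` (5 items, 7-point,
#' sum skewness near -1.1), `"shs"` (4 items, 7-point, two reverse-coded
#' items, skewness near -1.2) and `"fssq"` (8 items, 5-point, extreme
#' ceiling, skewness near -2.2).  The first discrimination in each preset is
#' fixed at 1 so that latent-scale parameters of models fitted under the
#' alpha1 = 1 identification are directly comparable with the generating
#' values.
#'
#' @param preset One of `"swls"`, `"shs"`, `"fssq"`.
#' @return An [item_bank()].
#' @export
item_bank_preset <- function(preset = c("swls", "shs", "fssq")) {
  preset <- match.arg(preset)
  sh <- function(base, shift) base + shift
  switch(preset,
    # threshold shifts calibrated once against the target sum skewness of
    # each scale (about -1.1, -1.2 and -2.2) at theta ~ N(0, 1)
    swls = item_bank(list(
      grm_item(1.0, sh(c(-3.4, -2.7, -2.0, -1.3, -0.5, 0.6), -0.7)),
      grm_item(1.6, sh(c(-3.3, -2.6, -1.9, -1.2, -0.4, 0.7), -0.7)),
      grm_item(1.8, sh(c(-3.5, -2.8, -2.1, -1.3, -0.5, 0.6), -0.7)),
      grm_item(1.4, sh(c(-3.2, -2.5, -1.8, -1.1, -0.3, 0.8), -0.7)),
      grm_item(1.2, sh(c(-3.0, -2.3, -1.6, -0.9, -0.1, 1.0), -0.7))),
      name = "swls"),
    shs = item_bank(list(
      grm_item(1.0, sh(c(-3.6, -2.9, -2.2, -1.5, -0.7, 0.5), -0.65)),
      grm_item(1.7, sh(c(-3.5, -2.8, -2.1, -1.4, -0.6, 0.6), -0.65)),
      grm_item(1.5, sh(c(-3.4, -2.7, -2.0, -1.3, -0.5, 0.7), -0.65),
               reverse = TRUE),
      grm_item(1.3, sh(c(-3.3, -2.6, -1.9, -1.2, -0.4, 0.8), -0.65),
               reverse = TRUE)),
      name = "shs"),
    fssq = item_bank(list(
      grm_item(1.0, c(-3.9, -3.1, -2.3, -1.4)),
      grm_item(1.8, c(-3.8, -3.0, -2.2, -1.3)),
      grm_item(2.0, c(-4.0, -3.2, -2.4, -1.5)),
      grm_item(1.6, c(-3.7, -2.9, -2.1, -1.2)),
      grm_item(1.9, c(-3.9, -3.1, -2.3, -1.4)),
      grm_item(1.5, c(-3.6, -2.8, -2.0, -1.1)),
      grm_item(1.7, c(-3.8, -3.0, -2.2, -1.3)),
      grm_item(1.4, c(-3.5, -2.7, -1.9, -1.0))),
      name = "fssq"))
}

#' Serialize an item bank to JSON
#'
#' @param bank An [item_bank()].
#' @param path File path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
write_item_bank <- function(bank, path = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  obj <- list(
    family = bank$family,
    name = bank$name,
    items = lapply(bank$items, function(it) {
      list(alpha = it$alpha,
           params = if (bank$family == "grm") it$thresholds else it$steps,
           n_categories = n_categories(it),
           reverse = it$reverse)
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read an item bank from JSON
#'
#' @param path File path or JSON string produced by [write_item_bank()].
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ctor <- if (identical(obj$family, "grm")) grm_item else gpcm_item
  items <- lapply(obj$items, function(it)
    ctor(it$alpha, unlist(it$params), reverse = isTRUE(it$reverse)))
  item_bank(items, name = obj$name)
}
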