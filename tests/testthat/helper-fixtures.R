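# small fixture builders shared across test files

tiny_bank <- function() {
  item_bank(list(
    grm_item(1.0, c(-1, 0, 1)),
    grm_item(1.5, c(-0.5, 0.5)),
    grm_item(0.8, c(-2, -1, 0, 1))))
}

# three-family toy layout: one MZ pair, one DZ pair, one DZ singleton
toy_families <- function() {
  data.frame(
    family_id = c(1, 1, 2, 2, 3),
    twin_index = c(1, 2, 1, 2, 1),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "DZ"),
    sex = c(0.5, 0.5, -0.5, -0.5, 0.5),
    age_std = c(0.2, 0.2, -1.0, -1.0, 0.6),
    stringsAsFactors = FALSE)
}

# numerically integrate f over a grid (trapezoid-free simple Riemann sum)
grid_integrate <- function(f, lower, upper, n = 2001L) {
  x <- seq(lower, upper, length.out = n)
  h <- x[2] - x[1]
  sum(f(x)) * h
}

expect_simplex <- function(p, tol = 1e-12) {
  expect_true(all(p >= -tol))
  expect_true(all(abs(rowSums(p) - 1) < tol))
}
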