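# brute-force oracle: enumerate all 2^n carbon labeling states
enumerate_carbon_mid <- function(n, p, max_shift = n) {
  out <- numeric(max_shift + 1)
  for (state in 0:(2^n - 1)) {
    k <- sum(bitwAnd(state, 2^(0:(n - 1))) > 0)
    if (k <= max_shift) out[k + 1] <- out[k + 1] + p^k * (1 - p)^(n - k)
  }
  out / sum(out)
}

test_that("natural MID of carbon-only formulas matches the binomial law and state enumeration", {
  p <- 0.0107
  got <- natural_mid(c(C = 6), max_shift = 6)
  expect_equal(got, dbinom(0:6, 6, p), tolerance = 1e-12)
  expect_equal(got[1], 0.93748, tolerance = 1e-4)
  expect_equal(got[2], 0.06084, tolerance = 1e-4)
  # exhaustive enumeration oracle, several sizes
  for (n in c(1, 3, 7, 10)) {
    expect_equal(natural_mid(c(C = n), max_shift = n),
                 enumerate_carbon_mid(n, p), tolerance = 1e-10)
  }
  # single atom at p = 0.5
  ab <- natural_abundances(list(C = c(0.5, 0.5)))
  expect_equal(natural_mid(c(C = 1), ab, max_shift = 1), c(0.5, 0.5))
  # all-monoisotopic abundances give a delta at M0
  mono <- natural_abundances(list(C = c(1, 0), H = c(1, 0), N = c(1, 0),
                                  O = c(1, 0, 0)))
  expect_equal(natural_mid("C5H9NO4", mono, max_shift = 6),
               c(1, rep(0, 6)))
})

test_that("natural MID handles multi-element formulas including +2 oxygen shifts", {
  ab <- natural_abundances()
  # two-element oracle by direct double convolution of binomials
  pC <- 0.0107; pN <- 0.00364
  direct <- outer(dbinom(0:5, 5, pC), dbinom(0:1, 1, pN))
  byshift <- sapply(0:6, function(s) sum(direct[row(direct) + col(direct) - 2 == s]))
  got <- natural_mid(c(C = 5, N = 1),
                     natural_abundances(list(H = c(1, 0), O = c(1, 0, 0))),
                     max_shift = 6)
  expect_equal(got, byshift / sum(byshift), tolerance = 1e-12)
  # 18O contributes at +2: M2 of a pure-O species exceeds the 17O-squared term
  o2 <- natural_mid(c(O = 2), ab, max_shift = 4)
  expect_gt(o2[3], ab$O[2]^2)
  expect_error(natural_mid(c(Xx = 1)), "abundances")
})

test_that("correction matrix columns are the expected measured envelopes", {
  p <- 0.0107
  cm <- build_correction_matrix(c(C = 2), c(C = 2))
  expect_equal(cm$M[, 1], c((1 - p)^2, 2 * p * (1 - p), p^2), tolerance = 1e-12)
  # purity 1 and p = 0 -> identity
  mono <- natural_abundances(list(C = c(1, 0)))
  cmI <- build_correction_matrix(c(C = 3), c(C = 3), abundances = mono)
  expect_equal(cmI$M, diag(4))
  # column sums <= 1, strictly lower-triangular zero block above diagonal
  cm6 <- build_correction_matrix("C6H12O6", c(C = 6))
  expect_true(all(colSums(cm6$M) <= 1 + 1e-12))
  expect_true(all(cm6$M[upper.tri(cm6$M)] == 0))
  expect_true(all(diag(cm6$M) > 0))
  # impurity puts mass below the diagonal
  cmp <- build_correction_matrix(c(C = 2), c(C = 2), purity = 0.99)
  expect_gt(cmp$M[1, 3], 0)
  expect_error(build_correction_matrix(c(C = 2), c(C = 3)), "exceed")
})

test_that("correct_mid inverts the measurement operator on the simplex", {
  cm <- build_correction_matrix("C5H9NO4", c(C = 5, N = 1))
  # unlabeled measured species corrects to a delta at M0
  raw <- natural_mid("C5H9NO4", max_shift = 6)
  expect_equal(correct_mid(raw, cm), c(1, rep(0, 6)), tolerance = 1e-9)
  # round-trip on random simplex vectors
  set.seed(11)
  for (i in 1:25) {
    x <- rexp(7); x <- x / sum(x)
    raw <- normalize_mid(as.numeric(cm$M %*% x))
    expect_equal(correct_mid(raw, cm), x, tolerance = 1e-8)
  }
  # identity matrix passes input through
  mono <- natural_abundances(list(C = c(1, 0), H = c(1, 0), N = c(1, 0),
                                  O = c(1, 0, 0)))
  cmI <- build_correction_matrix("C5H9NO4", c(C = 5, N = 1), abundances = mono)
  x <- c(0.2, 0.1, 0, 0.3, 0, 0.15, 0.25)
  expect_equal(correct_mid(x, cmI), x, tolerance = 1e-12)
  expect_error(correct_mid(c(1, 0), cm), "match")
  expect_error(correct_mid(rep(0, 7), cm), "all-zero")
})

test_that("correction is monotone in natural abundance for an unlabeled species", {
  ps <- c(0.005, 0.0107, 0.02, 0.05)
  meas <- natural_mid(c(C = 5), natural_abundances(list(C = c(1 - 0.0107, 0.0107))),
                      max_shift = 5)
  resid <- sapply(ps, function(p) {
    ab <- natural_abundances(list(C = c(1 - p, p)))
    cm <- build_correction_matrix(c(C = 5), c(C = 5), abundances = ab)
    sum(correct_mid(natural_mid(c(C = 5), ab, max_shift = 5), cm)[-1])
  })
  expect_true(all(resid < 1e-9))
})

test_that("convolution behaves as a distribution product", {
  a <- c(0.2, 0.5, 0.3)
  expect_equal(convolve_mids(a, 1), a, tolerance = 1e-12)
  expect_equal(convolve_mids(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25),
               tolerance = 1e-12)
  # n-fold self-convolution of (1-D, D) is Binomial(n, D)
  D <- 0.37
  acc <- c(1 - D, D)
  for (i in 2:7) acc <- convolve_mids(acc, c(1 - D, D))
  expect_equal(acc, dbinom(0:7, 7, D), tolerance = 1e-10)
})

test_that("internal-standard normalization is a guarded area ratio", {
  expect_equal(is_normalize(1000, 500, 1), 2)
  expect_equal(is_normalize(0, 500, 1), 0)
  expect_equal(is_normalize(1000, 500, 0.5), 1)
  expect_error(is_normalize(10, 0, 1, sample = "s7"), "s7")
})

test_that("tidy MID tables are corrected cell-wise", {
  cm <- build_correction_matrix(c(C = 3), c(C = 3))
  x <- c(0.6, 0.1, 0.05, 0.25)
  raw <- normalize_mid(as.numeric(cm$M %*% x))
  tbl <- tibble::tibble(
    sample = rep(c("a", "b"), each = 4), group = "g1",
    metabolite = "lactate", tracer = "glc_u13c",
    shift = rep(0:3, 2), abundance = rep(raw, 2), corrected = FALSE)
  out <- correct_mid_table(tbl, formulas = list(lactate = "C3H6O3"),
                           tracer_atoms = list(lactate = c(C = 3)))
  expect_true(all(out$corrected))
  expect_equal(out$abundance[out$sample == "a"][order(out$shift[out$sample == "a"])],
               correct_mid(raw, build_correction_matrix("C3H6O3", c(C = 3))),
               tolerance = 1e-10)
  expect_error(
    correct_mid_table(dplyr::filter(tbl, shift < 3),
                      formulas = list(lactate = "C3H6O3"),
                      tracer_atoms = list(lactate = c(C = 3))),
    "shifts 0..3")
})
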