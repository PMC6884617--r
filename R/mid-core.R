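#' Natural isotope abundances
#'
#' Default terrestrial isotope abundances used for theoretical mass-isotopomer
#' distributions (MIDs) and natural-abundance correction. Each element maps to
#' a vector of isotope fractions indexed by mass shift (position 1 = +0,
#' position 2 = +1, ...). The carbon +1 fraction is the natural 13C fraction
#' (0.0107); oxygen carries a +2 channel (18O), sulfur +2 and +4.
#'
#' @param overrides Named list of replacement abundance vectors, e.g.
#'   `list(C = c(0.989201, 0.010799))` to use a locally measured 13C baseline.
#' @return Named list of per-element mass-shift fraction vectors, each summing
#'   to 1.
#' @examples
#' natural_abundances()$C
#' natural_abundances(list(C = c(0.99, 0.01)))$C
#' @export
natural_abundances <- function(overrides = NULL) {
  ab <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
  if (!is.null(overrides)) {
    for (el in names(overrides)) ab[[el]] <- overrides[[el]]
  }
  validate_abundances(ab)
  ab
}

validate_abundances <- function(ab) {
  for (el in names(ab)) {
    v <- ab[[el]]
    if (any(v < 0) || any(v > 1)) {
      stop("isotope fractions for ", el, " must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(v) - 1) > 1e-12) {
      stop("isotope fractions for ", el, " must sum to 1 (got ",
           format(sum(v), digits = 15), ")", call. = FALSE)
    }
  }
  invisible(ab)
}

#' Parse an elemental formula
#'
#' @param formula Either a named integer vector (`c(C = 6, H = 12, O = 6)`) or
#'   a formula string (`"C6H12O6"`). Element symbols are one capital letter
#'   optionally followed by one lowercase letter.
#' @return Named integer vector of atom counts.
#' @examples
#' parse_formula("C5H9NO4") # glutamate
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula)))) {
      stop("numeric formula must be a named vector of atom counts", call. = FALSE)
    }
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (sum(nchar(toks)) != nchar(formula)) {
      stop("cannot parse formula '", formula, "'", call. = FALSE)
    }
    els <- sub("[0-9]*$", "", toks)
    ns <- as.integer(ifelse(grepl("[0-9]+$", toks),
                            sub("^[A-Za-z]+", "", toks), "1"))
    counts <- tapply(ns, els, sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  if (any(counts < 0)) stop("atom counts must be >= 0", call. = FALSE)
  counts[counts > 0]
}

#' Renormalize a MID to unit sum
#'
#' @param x Non-negative numeric vector of isotopologue abundances.
#' @return `x / sum(x)`.
#' @export
normalize_mid <- function(x) {
  if (any(x < 0)) stop("MID abundances must be non-negative", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("cannot normalize an all-zero MID", call. = FALSE)
  x / s
}

assert_normalized_mid <- function(x, tol = 1e-9, what = "MID") {
  if (any(x < -tol)) stop(what, " has negative abundances", call. = FALSE)
  if (abs(sum(x) - 1) > tol) {
    stop(what, " is not normalized (sum = ", format(sum(x), digits = 12), ")",
         call. = FALSE)
  }
  invisible(x)
}

#' Convolve two mass-isotopomer distributions
#'
#' The MID of two independent moieties combined in one molecule is the
#' discrete convolution of their shift distributions.
#'
#' @param a,b Normalized numeric MID vectors (index 1 = mass shift 0).
#' @return Normalized MID of length `length(a) + length(b) - 1`.
#' @examples
#' convolve_mids(c(0.5, 0.5), c(0.5, 0.5))
#' @export
convolve_mids <- function(a, b) {
  assert_normalized_mid(a, what = "first MID")
  assert_normalized_mid(b, what = "second MID")
  normalize_mid(conv_raw(a, b))
}

# single-atom shift distributions convolved over every atom in the formula
full_natural_mid <- function(counts, abundances) {
  out <- 1
  for (el in names(counts)) {
    v <- abundances[[el]]
    if (is.null(v)) {
      stop("no isotope abundances configured for element '", el, "'",
           call. = FALSE)
    }
    n <- counts[[el]]
    if (n == 0) next
    # repeated squaring over atom count
    base <- v
    acc <- NULL
    k <- n
    while (k > 0) {
      if (k %% 2 == 1) acc <- if (is.null(acc)) base else conv_raw(acc, base)
      k <- k %/% 2
      if (k > 0) base <- conv_raw(base, base)
    }
    out <- conv_raw(out, acc)
  }
  out
}

# exact direct convolution; MID vectors are short, so O(nm) is fine and
# avoids FFT round-off contaminating structurally-zero entries
conv_raw <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Theoretical natural-abundance MID of an unlabeled species
#'
#' Convolves the single-atom isotope-shift distributions of every atom in the
#' formula, truncates at `max_shift` and renormalizes. For a carbon-only
#' formula this reduces to the binomial `choose(n, k) p^k (1-p)^(n-k)` with
#' p the natural 13C fraction.
#'
#' @param formula Elemental formula (string or named counts); see
#'   [parse_formula()].
#' @param abundances Isotope abundances, see [natural_abundances()].
#' @param max_shift Largest mass shift retained (>= 0).
#' @return Normalized numeric MID of length `max_shift + 1`.
#' @examples
#' natural_mid(c(C = 6), max_shift = 6)[1:2]
#' @export
natural_mid <- function(formula, abundances = natural_abundances(),
                        max_shift = NULL) {
  counts <- parse_formula(formula)
  validate_abundances(abundances)
  full <- full_natural_mid(counts, abundances)
  if (is.null(max_shift)) max_shift <- length(full) - 1L
  if (max_shift < 0) stop("max_shift must be >= 0", call. = FALSE)
  out <- full[seq_len(max_shift + 1L)]
  out[is.na(out)] <- 0
  normalize_mid(out)
}

#' Build a natural-abundance correction matrix
#'
#' Column `j` (0-based) is the expected measured MID of a species carrying
#' exactly `j` tracer-derived heavy atoms: the tracer positions contribute a
#' `Binomial(j, purity)` shift (impure positions revert to the light isotope)
#' and every remaining atom contributes its natural isotope envelope. The
#' matrix maps a true (tracer-only) MID to the expected measured MID; its
#' non-negative least-squares inverse is applied by [correct_mid()].
#'
#' For dual-isotope tracers the tracer atoms span two elements (e.g. glutamate
#' under U-13C,15N2-glutamine: `tracer_atoms = c(C = 5, N = 1)`); heavy atoms
#' in column `j` are assigned to elements in the order given, first element
#' filled first, when computing the residual natural envelope.
#'
#' @param formula Elemental formula of the measured species.
#' @param tracer_atoms Named count vector of tracer-accessible positions per
#'   element, e.g. `c(C = 5)`; `sum(tracer_atoms)` sets the matrix size.
#' @param abundances Isotope abundances ([natural_abundances()]).
#' @param purity Tracer isotopic purity in (0, 1]; default 1.
#' @return Object of class `correction_matrix`: list with the
#'   `(n+1) x (n+1)` matrix `M`, plus `formula`, `tracer_atoms`, `purity`.
#' @examples
#' cm <- build_correction_matrix(c(C = 2), c(C = 2))
#' cm$M[, 1] # ((1-p)^2, 2p(1-p), p^2), p = 0.0107
#' @export
build_correction_matrix <- function(formula, tracer_atoms,
                                    abundances = natural_abundances(),
                                    purity = 1) {
  counts <- parse_formula(formula)
  stopifnot(is.numeric(tracer_atoms), !is.null(names(tracer_atoms)))
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]", call. = FALSE)
  for (el in names(tracer_atoms)) {
    have <- if (el %in% names(counts)) counts[[el]] else 0L
    if (tracer_atoms[[el]] > have) {
      stop("tracer positions for ", el, " (", tracer_atoms[[el]],
           ") exceed formula count (", have, ")", call. = FALSE)
    }
  }
  n <- sum(tracer_atoms)
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    # assign j heavy atoms across tracer elements, first element first
    assigned <- integer(length(tracer_atoms))
    names(assigned) <- names(tracer_atoms)
    left <- j
    for (el in names(tracer_atoms)) {
      take <- min(left, tracer_atoms[[el]])
      assigned[[el]] <- take
      left <- left - take
    }
    residual <- counts
    for (el in names(assigned)) residual[[el]] <- residual[[el]] - assigned[[el]]
    nat <- full_natural_mid(residual[residual > 0], abundances)
    pur <- stats::dbinom(0:j, j, purity)
    col <- conv_raw(pur, nat)
    col <- col[seq_len(n + 1L)]
    col[is.na(col)] <- 0
    M[, j + 1L] <- col
  }
  structure(list(M = M, formula = counts, tracer_atoms = tracer_atoms,
                 purity = purity, abundances = abundances),
            class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat("Natural-abundance correction matrix (", nrow(x$M), "x", ncol(x$M),
      "), tracer atoms:", paste0(names(x$tracer_atoms), x$tracer_atoms,
                                 collapse = " "),
      ", purity ", x$purity, "\n", sep = "")
  invisible(x)
}

#' Correct a measured MID for naturally occurring isotopes
#'
#' Solves `M x ~ raw` by non-negative least squares and renormalizes, so that
#' nonzero corrected abundances reflect tracer-derived label only. NNLS rather
#' than matrix inversion keeps noisy high-shift tails from going negative.
#'
#' @param raw Normalized measured MID (numeric vector, length `n + 1`).
#' @param cm A [build_correction_matrix()] object.
#' @return Normalized corrected MID of the same length.
#' @examples
#' cm <- build_correction_matrix(c(C = 3), c(C = 3))
#' correct_mid(natural_mid(c(C = 3), max_shift = 3), cm)
#' @export
correct_mid <- function(raw, cm) {
  stopifnot(inherits(cm, "correction_matrix"))
  if (length(raw) != nrow(cm$M)) {
    stop("MID length ", length(raw), " does not match correction matrix size ",
         nrow(cm$M), call. = FALSE)
  }
  if (all(raw == 0)) stop("cannot correct an all-zero MID", call. = FALSE)
  assert_normalized_mid(raw, tol = 1e-6, what = "measured MID")
  fit <- pracma::lsqnonneg(cm$M, as.numeric(raw))
  normalize_mid(fit$x)
}

#' Internal-standard normalization of a peak area
#'
#' Relative quantification through the integrated peak-area ratio of an
#' analyte and its internal standard, scaled by a response factor.
#'
#' @param analyte_area,internal_standard_area Integrated ion counts.
#' @param response_factor Relative response factor (default 1).
#' @param sample Optional sample label used in error messages.
#' @return `analyte_area / internal_standard_area * response_factor`
#'   (vectorized).
#' @examples
#' is_normalize(1000, 500, 0.5)
#' @export
is_normalize <- function(analyte_area, internal_standard_area,
                         response_factor = 1, sample = NULL) {
  bad <- internal_standard_area <= 0
  if (any(bad)) {
    lab <- if (!is.null(sample)) paste(sample[bad], collapse = ", ") else
      paste("index", paste(which(bad), collapse = ", "))
    stop("zero/negative internal-standard area in sample(s): ", lab,
         call. = FALSE)
  }
  analyte_area / internal_standard_area * response_factor
}

#' Correct a tidy MID table for natural abundance
#'
#' Applies [correct_mid()] group-wise to a long MID table with columns
#' `sample, metabolite, tracer, shift, abundance` (extra columns such as
#' `group` are carried through). Each (sample, metabolite, tracer) cell must
#' hold a complete shift ladder 0..n matching the metabolite's tracer-atom
#' specification.
#'
#' @param tbl Long MID tibble (see [read_mid_table()] for the dialect).
#' @param formulas Named list/vector: metabolite -> elemental formula.
#' @param tracer_atoms Named list: metabolite -> named tracer-atom count
#'   vector (e.g. `list(glutamate = c(C = 5, N = 1))`).
#' @param abundances,purity Passed to [build_correction_matrix()].
#' @return Tibble of the same shape with corrected abundances and
#'   `corrected = TRUE`.
#' @export
correct_mid_table <- function(tbl, formulas, tracer_atoms,
                              abundances = natural_abundances(), purity = 1) {
  need <- c("sample", "metabolite", "tracer", "shift", "abundance")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("MID table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cms <- lapply(stats::setNames(nm = names(formulas)), function(met) {
    build_correction_matrix(formulas[[met]], tracer_atoms[[met]],
                            abundances = abundances, purity = purity)
  })
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("sample", "group", "metabolite", "tracer")))) |>
    dplyr::group_modify(function(d, key) {
      met <- key$metabolite
      if (!met %in% names(cms)) {
        stop("no formula/tracer-atom spec for metabolite '", met, "'",
             call. = FALSE)
      }
      d <- dplyr::arrange(d, .data$shift)
      n <- nrow(cms[[met]]$M) - 1L
      if (!identical(as.integer(d$shift), 0:n)) {
        stop("metabolite '", met, "' needs shifts 0..", n, call. = FALSE)
      }
      d$abundance <- correct_mid(normalize_mid(d$abundance), cms[[met]])
      d$corrected <- TRUE
      d
    }) |>
    dplyr::ungroup()
}
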