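#' Specify an isotope tracer
#'
#' @param substrate External metabolite carrying the label (e.g.
#'   `"gln_media"`).
#' @param carbon_positions Integer vector of 13C-labeled carbon positions
#'   (1-based, standard biochemical numbering).
#' @param nitrogen_positions Integer vector of 15N-labeled nitrogen positions.
#' @param enrichment Isotopic enrichment per labeled position, in (0, 1].
#' @return A `tracer_spec` list.
#' @seealso [tracer_gln_u13c15n2()], [tracer_glc_u13c()], [tracer_gln_5c13()],
#'   [tracer_gln_1c13()] for the packaged designs.
#' @export
tracer_spec <- function(substrate, carbon_positions = integer(),
                        nitrogen_positions = integer(), enrichment = 1) {
  if (enrichment <= 0 || enrichment > 1) {
    stop("enrichment must be in (0, 1]", call. = FALSE)
  }
  structure(list(substrate = substrate,
                 carbon_positions = as.integer(carbon_positions),
                 nitrogen_positions = as.integer(nitrogen_positions),
                 enrichment = enrichment),
            class = "tracer_spec")
}

#' Packaged tracer designs
#'
#' The four labeling designs used by the study conditions: uniformly labeled
#' 13C5,15N2-glutamine (2 mM), uniformly labeled 13C6-glucose (3.15 g/L),
#' 5-13C-glutamine, and 1-13C-glutamine.
#'
#' @param enrichment Tracer enrichment per position (default 1).
#' @return A [tracer_spec()].
#' @export
tracer_gln_u13c15n2 <- function(enrichment = 1)
  tracer_spec("gln_media", 1:5, 1:2, enrichment)

#' @rdname tracer_gln_u13c15n2
#' @export
tracer_glc_u13c <- function(enrichment = 1)
  tracer_spec("glc_media", 1:6, integer(), enrichment)

#' @rdname tracer_gln_u13c15n2
#' @export
tracer_gln_5c13 <- function(enrichment = 1)
  tracer_spec("gln_media", 5L, integer(), enrichment)

#' @rdname tracer_gln_u13c15n2
#' @export
tracer_gln_1c13 <- function(enrichment = 1)
  tracer_spec("gln_media", 1L, integer(), enrichment)

#' @rdname tracer_gln_u13c15n2
#' @export
tracer_none <- function() tracer_spec("gln_media", integer(), integer())

# positional labeling distribution of an external substrate under a tracer:
# independent Bernoulli(enrichment) per labeled position
tracer_distribution <- function(met, tracer) {
  dist <- numeric(2^met$bits)
  dist[1] <- 1
  if (!identical(met$name, tracer$substrate)) return(dist)
  bits <- integer(0)
  if (length(tracer$carbon_positions)) {
    if (any(tracer$carbon_positions > met$carbons)) {
      stop("tracer carbon positions outside the skeleton of ", met$name,
           call. = FALSE)
    }
    bits <- c(bits, tracer$carbon_positions - 1L)
  }
  if (length(tracer$nitrogen_positions)) {
    if (any(tracer$nitrogen_positions > met$nitrogens)) {
      stop("tracer nitrogen positions outside the skeleton of ", met$name,
           call. = FALSE)
    }
    bits <- c(bits, met$carbons + tracer$nitrogen_positions - 1L)
  }
  e <- tracer$enrichment
  for (b in bits) {
    new <- numeric(length(dist))
    idx <- bitwAnd(seq_along(dist) - 1L, bitwShiftL(1L, b)) > 0
    on <- which(idx); off <- which(!idx)
    new[on] <- dist[off] * e # flip bit on
    new[off] <- dist[off] * (1 - e)
    new[on] <- new[on] + dist[on] # states already containing the bit: keep
    dist <- new
  }
  dist
}

popcount <- function(x) {
  n <- 0L
  while (any(x > 0)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

# carbon-reversal permutation (1-based state indices) for symmetric skeletons
reversal_index <- function(carbons) {
  states <- 0:(2^carbons - 1)
  rev_state <- integer(length(states))
  for (b in 0:(carbons - 1)) {
    has <- bitwAnd(states, bitwShiftL(1L, b)) > 0
    rev_state[has] <- bitwOr(rev_state[has], bitwShiftL(1L, carbons - 1L - b))
  }
  rev_state + 1L
}

# per (reaction, product): map joint substrate state -> product state (1-based)
product_targets <- function(r, p, mets) {
  sizes <- vapply(r$substrates, function(s) 2^mets[[s]]$bits, 0)
  njoint <- prod(sizes)
  joint <- 0:(njoint - 1)
  # decode substrate states (substrate 1 varies fastest)
  sub_states <- matrix(0L, nrow = njoint, ncol = length(sizes))
  rest <- joint
  for (k in seq_along(sizes)) {
    sub_states[, k] <- rest %% sizes[k]
    rest <- rest %/% sizes[k]
  }
  target <- integer(njoint)
  for (a in seq_len(ncol(p$pmap))) {
    si <- p$pmap[1, a]
    if (si == 0) next # unlabeled source contributes bit 0
    atom <- p$pmap[2, a]
    has <- bitwAnd(sub_states[, si], bitwShiftL(1L, atom - 1L)) > 0
    target[has] <- bitwOr(target[has], bitwShiftL(1L, a - 1L))
  }
  target + 1L
}

#' Steady-state label propagation
#'
#' Solves the isotopomer balance fixed point: each internal metabolite's
#' positional-labeling distribution equals the flux-weighted mixture of its
#' producing reactions' mapped outputs (joint substrate distributions under
#' independence, pushed through the atom map). Symmetric metabolites are
#' scrambled by averaging with their carbon-reversed image after every
#' update. Iteration (Gauss-Seidel sweeps) stops when the largest L1 change
#' falls below `tol`.
#'
#' @param net A [network()] object.
#' @param tracer A [tracer_spec()] fixing the labeling of one external
#'   substrate; all other externals are unlabeled.
#' @param tol Convergence tolerance on the per-sweep max L1 change.
#' @param max_iter Sweep limit; non-convergence raises an error reporting the
#'   residual.
#' @return An `isotopomer_state` list: `distributions` (named list of
#'   positional probability vectors, including the fixed externals),
#'   `iterations`, `residual`, `net`, `tracer`.
#' @export
steady_state_labeling <- function(net, tracer, tol = 1e-10, max_iter = 2000) {
  stopifnot(inherits(net, "tracenet"), inherits(tracer, "tracer_spec"))
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  mets <- net$metabolites
  dists <- lapply(mets, function(m) {
    if (m$external) tracer_distribution(m, tracer) else
      c(1, numeric(2^m$bits - 1))
  })
  internal <- names(mets)[!vapply(mets, `[[`, TRUE, "external")]
  # producer bookkeeping: for each internal metabolite, the list of
  # (reaction, product) terms with positive flux, plus precomputed targets
  producers <- stats::setNames(vector("list", length(internal)), internal)
  for (r in net$reactions) {
    if (r$flux <= 0) next
    for (p in r$products) {
      if (!p$met %in% internal) next
      producers[[p$met]] <- c(producers[[p$met]], list(list(
        flux = r$flux, substrates = r$substrates,
        targets = product_targets(r, p, mets),
        size = 2^mets[[p$met]]$bits)))
    }
  }
  revidx <- lapply(mets, function(m) {
    if (m$symmetric) reversal_index(m$carbons) else NULL
  })
  # update order: roughly follow the flow from the tracer inward
  order_hint <- c("gln", "glu", "akg", "suc", "fum", "mal", "oaa", "cit",
                  "accoa", "pyr", "lac", "p5c", "pro", "orn", "aminoN")
  ord <- c(intersect(order_hint, internal), setdiff(internal, order_hint))
  residual <- Inf
  for (it in seq_len(max_iter)) {
    residual <- 0
    for (m in ord) {
      terms <- producers[[m]]
      if (is.null(terms)) next # no active producers: stays unlabeled
      total <- sum(vapply(terms, `[[`, 0, "flux"))
      new <- numeric(2^mets[[m]]$bits)
      for (tm in terms) {
        joint <- dists[[tm$substrates[1]]]
        if (length(tm$substrates) > 1) {
          for (k in 2:length(tm$substrates)) {
            joint <- as.vector(outer(joint, dists[[tm$substrates[k]]]))
          }
        }
        agg <- rowsum(joint, tm$targets)
        contrib <- numeric(tm$size)
        contrib[as.integer(rownames(agg))] <- agg[, 1]
        new <- new + tm$flux * contrib
      }
      new <- new / total
      # keep the update on the probability simplex: round-off in the joint
      # outer products otherwise compounds multiplicatively across sweeps
      new <- new / sum(new)
      if (!is.null(revidx[[m]])) new <- (new + new[revidx[[m]]]) / 2
      residual <- max(residual, sum(abs(new - dists[[m]])))
      dists[[m]] <- new
    }
    if (residual < tol) {
      return(structure(list(distributions = dists, iterations = it,
                            residual = residual, net = net, tracer = tracer),
                       class = "isotopomer_state"))
    }
  }
  stop("label propagation did not converge in ", max_iter,
       " sweeps (residual ", signif(residual, 4), ")", call. = FALSE)
}

#' @export
print.isotopomer_state <- function(x, ...) {
  cat("Steady-state labeling (", x$iterations, " sweeps, residual ",
      signif(x$residual, 3), ") for tracer on ", x$tracer$substrate, "\n",
      sep = "")
  invisible(x)
}

#' Marginalize a positional distribution to a MID
#'
#' @param state An `isotopomer_state` from [steady_state_labeling()].
#' @param met Metabolite name.
#' @param channel `"total"` counts all heavy atoms (the mass shift an
#'   isotopologue LC-MS assay indexes), `"carbon"`/`"nitrogen"` count one
#'   element only.
#' @return Normalized numeric MID (index 1 = shift 0).
#' @export
state_mid <- function(state, met, channel = c("total", "carbon", "nitrogen")) {
  channel <- match.arg(channel)
  m <- state$net$metabolites[[met]]
  if (is.null(m)) stop("unknown metabolite '", met, "'", call. = FALSE)
  dist <- state$distributions[[met]]
  states <- 0:(2^m$bits - 1)
  cmask <- if (m$carbons > 0) sum(bitwShiftL(1L, 0:(m$carbons - 1))) else 0L
  counts <- switch(channel,
    total = popcount(states),
    carbon = popcount(bitwAnd(states, cmask)),
    nitrogen = popcount(bitwAnd(states, bitwNot(cmask) |> bitwAnd(2^m$bits - 1L))))
  n <- switch(channel, total = m$bits, carbon = m$carbons,
              nitrogen = m$nitrogens)
  mid <- vapply(0:n, function(k) sum(dist[counts == k]), 0)
  normalize_mid(mid)
}

#' Mean labeled atoms of a metabolite at steady state
#'
#' @inheritParams state_mid
#' @return Expected number of heavy atoms per molecule (carbon channel).
#' @export
mean_labeled_carbons <- function(state, met) {
  mid <- state_mid(state, met, "carbon")
  sum((seq_along(mid) - 1) * mid)
}

#' Fraction of molecules carrying any label
#'
#' @inheritParams state_mid
#' @return `1 - M0` of the chosen channel.
#' @export
labeled_fraction <- function(state, met, channel = "total") {
  1 - state_mid(state, met, channel)[1]
}
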