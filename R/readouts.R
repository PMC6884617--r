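# push a labeling distribution along a named reaction chain. Each step
# applies one reaction's atom map; the carried metabolite uses the incoming
# distribution, co-substrates are unlabeled (or taken from `co_dists` by
# metabolite name). Returns the distribution of the step's named product.
trace_route <- function(net, tracer, steps, co_dists = list()) {
  mets <- net$metabolites
  rx <- stats::setNames(net$reactions,
                        vapply(net$reactions, `[[`, "", "name"))
  carried_met <- NULL
  carried <- NULL
  for (stp in steps) {
    r <- rx[[stp[1]]]
    if (is.null(r)) stop("unknown reaction '", stp[1], "'", call. = FALSE)
    p <- NULL
    for (pp in r$products) if (pp$met == stp[2]) p <- pp
    if (is.null(p)) stop("reaction '", stp[1], "' has no product '", stp[2],
                         "'", call. = FALSE)
    sub_dists <- lapply(r$substrates, function(s) {
      if (!is.null(carried_met) && s == carried_met) return(carried)
      if (s %in% names(co_dists)) return(co_dists[[s]])
      if (mets[[s]]$external) return(tracer_distribution(mets[[s]], tracer))
      c(1, numeric(2^mets[[s]]$bits - 1))
    })
    joint <- sub_dists[[1]]
    if (length(sub_dists) > 1) {
      for (k in 2:length(sub_dists)) joint <- as.vector(outer(joint,
                                                              sub_dists[[k]]))
    }
    targets <- product_targets(r, p, mets)
    agg <- rowsum(joint, targets)
    out <- numeric(2^mets[[p$met]]$bits)
    out[as.integer(rownames(agg))] <- agg[, 1]
    if (mets[[p$met]]$symmetric) {
      ridx <- reversal_index(mets[[p$met]]$carbons)
      out <- (out + out[ridx]) / 2
    }
    carried_met <- p$met
    carried <- out
  }
  list(met = carried_met, dist = carried)
}

# mass shifts carrying label after a route (beyond the unlabeled state)
route_shifts <- function(net, tracer, steps, co_dists = list(), tol = 1e-9) {
  res <- trace_route(net, tracer, steps, co_dists)
  m <- net$metabolites[[res$met]]
  states <- 0:(2^m$bits - 1)
  counts <- popcount(states)
  shifts <- sort(unique(counts[res$dist > tol & counts > 0]))
  list(met = res$met, shifts = shifts)
}

stp <- function(reaction, product) c(reaction, product)

# pathway routes through the packaged network, per tracer design
packaged_routes <- function() {
  up <- list(stp("gln_uptake", "gln"), stp("gls", "glu"))
  ox <- c(up, list(stp("ta_fwd", "akg"), stp("ogdh", "suc")))
  list(
    gln_u13c15n2 = list(
      list(pathway = "deamidation", routes = list(up)),
      list(pathway = "transamination cycle (carbon retained)",
           routes = list(c(up, list(stp("ta_fwd", "akg"),
                              stp("ta_rev", "glu"))))),
      list(pathway = "15N transamination",
           routes = list(c(up, list(stp("ta_fwd", "aminoN"),
                              stp("ta_rev", "glu"))))),
      list(pathway = "reductive carboxylation",
           routes = list(
             c(up, list(stp("ta_fwd", "akg"), stp("idh_rev", "cit"))),
             c(up, list(stp("ta_fwd", "akg"), stp("idh_rev", "cit"),
                        stp("acl", "oaa"), stp("mdh_rev", "mal"))))),
      list(pathway = "oxidative TCA",
           routes = list(ox,
                         c(ox, list(stp("sdh", "fum"))),
                         c(ox, list(stp("sdh", "fum"), stp("fh", "mal"))))),
      list(pathway = "malic enzyme route (glutaminolysis)",
           routes = list(c(ox, list(stp("sdh", "fum"), stp("fh", "mal"),
                                    stp("me", "pyr"), stp("ldh", "lac"))))),
      list(pathway = "oxidative TCA + labeled acetyl condensation",
           routes = "cit_m6")
    ),
    glc_u13c = list(
      list(pathway = "PDH route",
           routes = list(list(stp("glycolysis", "pyr"), stp("pdh", "accoa"),
                              stp("cs", "cit"), stp("idh_fwd", "akg"),
                              stp("ta_rev", "glu")))),
      list(pathway = "pyruvate carboxylase route",
           routes = list(list(stp("glycolysis", "pyr"), stp("pc", "oaa"),
                              stp("cs", "cit"), stp("idh_fwd", "akg"),
                              stp("ta_rev", "glu"))))
    ),
    gln_1c13 = list(
      list(pathway = "reductive carboxylation (C1 retained)",
           routes = list(
             c(up, list(stp("ta_fwd", "akg"), stp("idh_rev", "cit"))),
             c(up, list(stp("ta_fwd", "akg"), stp("idh_rev", "cit"),
                        stp("acl", "oaa"), stp("mdh_rev", "mal")))))
    ),
    gln_5c13 = list(
      list(pathway = "reductive carboxylation to lipogenic acetyl-CoA",
           routes = list(
             c(up, list(stp("ta_fwd", "akg"), stp("idh_rev", "cit"),
                        stp("acl", "accoa")))))
    )
  )
}

#' Classify tracer-derived isotopologues by pathway origin
#'
#' Derives, from the network's atom maps, which mass shifts of which
#' metabolites a tracer design can label through each canonical pathway —
#' e.g. under U-13C,15N2-glutamine, glutamate M6 arises from deamidation
#' only, M5 from the carbon-retaining transamination cycle, and M1 from 15N
#' transamination onto an unlabeled skeleton; citrate M5 and malate M3 flag
#' reductive carboxylation while M4 species flag oxidative cycling. The
#' assignments are computed by pushing the tracer's positional distribution
#' through each route's atom maps, so they stay consistent if the network is
#' edited.
#'
#' @param tracer One of the four packaged designs ([tracer_gln_u13c15n2()],
#'   [tracer_glc_u13c()], [tracer_gln_5c13()], [tracer_gln_1c13()]), at
#'   enrichment 1.
#' @param net A network built by [build_default_network()].
#' @return Tibble: `tracer`, `metabolite` (reported name), `shift`,
#'   `pathway`.
#' @export
classify_isotopologues <- function(tracer, net = NULL) {
  stopifnot(inherits(tracer, "tracer_spec"))
  if (is.null(net)) net <- build_default_network(hepl_fluxes())
  key <- tracer_key(tracer)
  routes <- packaged_routes()[[key]]
  if (is.null(routes)) {
    if (length(tracer$carbon_positions) + length(tracer$nitrogen_positions)
        == 0) {
      return(tibble::tibble(tracer = character(), metabolite = character(),
                            shift = integer(), pathway = character()))
    }
    stop("no packaged fate assignments for this tracer design", call. = FALSE)
  }
  node_names <- stats::setNames(names(sim_metabolites), sim_metabolites)
  out <- purrr::map_dfr(routes, function(entry) {
    if (identical(entry$routes, "cit_m6")) {
      # two labeled moieties condense: oxidative OAA + malic-enzyme acetyl
      pre <- list(stp("gln_uptake", "gln"), stp("gls", "glu"),
                  stp("ta_fwd", "akg"), stp("ogdh", "suc"),
                  stp("sdh", "fum"), stp("fh", "mal"))
      oaa <- trace_route(net, tracer, c(pre, list(stp("mdh", "oaa"))))
      ac <- trace_route(net, tracer,
                        c(pre, list(stp("me", "pyr"), stp("pdh", "accoa"))))
      res <- route_shifts(net, tracer, list(stp("cs", "cit")),
                          co_dists = list(oaa = oaa$dist, accoa = ac$dist))
      hits <- list(res)
    } else {
      hits <- lapply(entry$routes, function(r) route_shifts(net, tracer, r))
    }
    purrr::map_dfr(hits, function(h) {
      if (!length(h$shifts)) return(NULL)
      tibble::tibble(metabolite = node_names[[h$met]], shift = h$shifts,
                     pathway = entry$pathway)
    })
  })
  dplyr::distinct(dplyr::mutate(out, tracer = key, .before = 1))
}

tracer_key <- function(tracer) {
  cp <- tracer$carbon_positions
  np <- tracer$nitrogen_positions
  if (tracer$substrate == "gln_media") {
    if (setequal(cp, 1:5) && setequal(np, 1:2)) return("gln_u13c15n2")
    if (identical(sort(cp), 5L) && !length(np)) return("gln_5c13")
    if (identical(sort(cp), 1L) && !length(np)) return("gln_1c13")
  }
  if (tracer$substrate == "glc_media" && setequal(cp, 1:6) && !length(np)) {
    return("glc_u13c")
  }
  "custom"
}

#' Alpha-ketoglutarate to citrate concentration ratio
#'
#' A readout of reductive glutamine metabolism: a higher aKG/citrate pool
#' ratio favors the reverse (reductive) IDH direction. Inputs are
#' intracellular concentrations normalized by cell volume (see
#' [intracellular_concentration()]), not raw ion currents.
#'
#' @param akg_conc,citrate_conc Intracellular concentrations (same units).
#' @return The ratio (vectorized).
#' @export
reductive_index <- function(akg_conc, citrate_conc) {
  if (any(citrate_conc <= 0)) stop("citrate concentration must be > 0",
                                   call. = FALSE)
  akg_conc / citrate_conc
}

#' Sum of MID abundances at selected mass shifts
#'
#' @param mid Corrected, normalized MID (numeric vector or tidy slice with
#'   `shift`/`abundance`/`corrected`).
#' @param shifts Integer mass shifts to sum (0-based).
#' @return Fraction in `[0, 1]`.
#' @examples
#' isotopologue_fraction(c(0.7, 0.1, 0.2), shifts = c(1, 2))
#' @export
isotopologue_fraction <- function(mid, shifts) {
  mid <- as_corrected_mid(mid)
  if (!length(shifts)) return(0)
  shifts <- as.integer(shifts)
  if (any(shifts < 0 | shifts > length(mid) - 1)) {
    stop("shift outside the MID range 0-", length(mid) - 1, call. = FALSE)
  }
  sum(mid[shifts + 1])
}

#' Fold change of labeled-pool measurements with a Welch test
#'
#' Compares labeled-isotopologue pools (EIC per mg protein) between two
#' conditions: ratio of means and a two-sided Welch t-test.
#'
#' @param a,b Numeric vectors of per-replicate labeled-pool values (>= 2
#'   each), or tibbles with an `eic_per_mg` column.
#' @return One-row tibble: `fold_change` (mean(a)/mean(b)), `p_value`,
#'   `n_a`, `n_b`.
#' @export
labeled_pool_fold_change <- function(a, b) {
  if (is.data.frame(a)) a <- a$eic_per_mg
  if (is.data.frame(b)) b <- b$eic_per_mg
  if (length(a) < 2 || length(b) < 2) {
    stop("need >= 2 replicates per condition", call. = FALSE)
  }
  if (mean(b) == 0) stop("reference mean is zero", call. = FALSE)
  p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) 1 else 0
  } else {
    stats::t.test(a, b)$p.value
  }
  tibble::tibble(fold_change = mean(a) / mean(b), p_value = p,
                 n_a = length(a), n_b = length(b))
}
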