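#' Define a network metabolite
#'
#' Atoms are tracked positionally: carbon positions first (standard
#' biochemical numbering, C1 = carboxyl for the glutamate family), then any
#' tracked nitrogen positions. Symmetric intermediates (succinate, fumarate)
#' are scrambled by carbon-order reversal at every steady-state update.
#'
#' @param name Metabolite name.
#' @param carbons,nitrogens Tracked atom counts (nitrogens only where 15N
#'   routing matters: glutamine, glutamate, the amino-nitrogen pool).
#' @param symmetric Is the carbon skeleton rotationally symmetric?
#' @param external Externals have a fixed labeling state (media pools, CO2,
#'   sinks) and are excluded from the mass-balance check.
#' @return A `net_metabolite` list.
#' @export
metabolite <- function(name, carbons, nitrogens = 0L, symmetric = FALSE,
                       external = FALSE) {
  stopifnot(carbons >= 0, nitrogens >= 0, carbons + nitrogens >= 1)
  structure(list(name = name, carbons = as.integer(carbons),
                 nitrogens = as.integer(nitrogens), symmetric = symmetric,
                 external = external,
                 bits = as.integer(carbons + nitrogens)),
            class = "net_metabolite")
}

# parse "glu.C3" / "aminoN.N1" / "*" map tokens against the substrate list
parse_map <- function(map, substrates, mets) {
  out <- matrix(0L, nrow = 2, ncol = length(map))
  for (i in seq_along(map)) {
    tok <- map[[i]]
    if (identical(tok, "*")) next # unlabeled source (CO2 fixation, fresh N)
    parts <- strsplit(tok, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("bad atom map token '", tok, "'", call. = FALSE)
    si <- match(parts[1], substrates)
    if (is.na(si)) stop("map token '", tok, "' references a non-substrate",
                        call. = FALSE)
    m <- mets[[parts[1]]]
    kind <- substr(parts[2], 1, 1)
    idx <- as.integer(substr(parts[2], 2, nchar(parts[2])))
    atom <- if (kind == "C") idx else if (kind == "N") m$carbons + idx else
      stop("atom must be C<k> or N<k> in '", tok, "'", call. = FALSE)
    if (atom < 1 || atom > m$bits) {
      stop("atom '", tok, "' outside the skeleton of ", parts[1], call. = FALSE)
    }
    out[, i] <- c(si, atom)
  }
  out
}

#' Define an atom-mapped reaction
#'
#' @param name Reaction name.
#' @param flux Non-negative flux value (µmol per mg protein per day).
#' @param substrates Character vector of substrate metabolite names
#'   (stoichiometry 1 each).
#' @param products List of product specifications; each is
#'   `list(met = "name", map = c("sub.C1", ...))` with one map token per
#'   product atom: `"substrate.C<k>"`, `"substrate.N<k>"`, or `"*"` for an
#'   unlabeled source. Every substrate atom should appear in some product so
#'   that label is conserved reaction-by-reaction.
#' @return A `net_reaction` list (maps are parsed lazily by [network()]).
#' @export
reaction <- function(name, flux, substrates, products) {
  if (flux < 0) stop("flux of '", name, "' is negative (", flux, ")",
                     call. = FALSE)
  structure(list(name = name, flux = flux, substrates = substrates,
                 products = products),
            class = "net_reaction")
}

#' Assemble and validate a labeled-atom network
#'
#' Checks that atom maps are complete and within skeletons and that flux into
#' each internal metabolite equals flux out (steady-state mass balance) to
#' within `1e-6` of the total network flux.
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @return A `tracenet` object used by [steady_state_labeling()].
#' @export
network <- function(metabolites, reactions) {
  mets <- stats::setNames(metabolites, vapply(metabolites, `[[`, "", "name"))
  if (anyDuplicated(names(mets))) stop("duplicate metabolite names",
                                       call. = FALSE)
  for (r in reactions) {
    miss <- setdiff(c(r$substrates, vapply(r$products, `[[`, "", "met")),
                    names(mets))
    if (length(miss)) stop("reaction '", r$name, "' references unknown ",
                           "metabolite(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    for (p in r$products) {
      if (length(p$map) != mets[[p$met]]$bits) {
        stop("reaction '", r$name, "': product ", p$met, " needs ",
             mets[[p$met]]$bits, " map entries, got ", length(p$map),
             call. = FALSE)
      }
    }
  }
  # parse maps once
  reactions <- lapply(reactions, function(r) {
    r$products <- lapply(r$products, function(p) {
      p$pmap <- parse_map(p$map, r$substrates, mets)
      p
    })
    r
  })
  net <- structure(list(metabolites = mets, reactions = reactions),
                   class = "tracenet")
  bal <- flux_balance(net)
  tot <- sum(vapply(reactions, `[[`, 0, "flux"))
  bad <- bal[abs(bal$production - bal$consumption) > 1e-6 * max(tot, 1), ]
  if (nrow(bad)) {
    stop("steady-state mass imbalance for: ",
         paste0(bad$metabolite, " (in ", signif(bad$production, 6), ", out ",
                signif(bad$consumption, 6), ")", collapse = "; "),
         call. = FALSE)
  }
  net
}

#' Production/consumption flux per internal metabolite
#'
#' @param net A [network()] object.
#' @return Tibble with `metabolite`, `production`, `consumption`.
#' @export
flux_balance <- function(net) {
  internal <- names(net$metabolites)[!vapply(net$metabolites, `[[`, TRUE,
                                             "external")]
  prod <- cons <- stats::setNames(numeric(length(internal)), internal)
  for (r in net$reactions) {
    for (s in r$substrates) if (s %in% internal) cons[s] <- cons[s] + r$flux
    for (p in r$products) if (p$met %in% internal)
      prod[p$met] <- prod[p$met] + r$flux
  }
  tibble::tibble(metabolite = internal, production = unname(prod),
                 consumption = unname(cons))
}

#' @export
print.tracenet <- function(x, ...) {
  cat("Atom-mapped tracer network: ", length(x$metabolites),
      " metabolites, ", length(x$reactions), " reactions (total flux ",
      signif(sum(vapply(x$reactions, `[[`, 0, "flux")), 4), ")\n", sep = "")
  invisible(x)
}

id5 <- function(met) paste0(met, ".C", 1:5)

#' Default glutamine/glutamate/TCA/proline/fatty-acid network
#'
#' Packages the cultured-cell network used throughout: glutamine uptake and
#' deamidation (glutaminase, amide nitrogen released), glutamine synthetase,
#' transamination exchanging glutamate with alpha-ketoglutarate against a
#' well-mixed amino-nitrogen pool, oxidative TCA flux (aKG C1 lost as CO2;
#' succinate/fumarate symmetric), reductive IDH (aKG + CO2 -> citrate), ATP-
#' citrate lyase feeding the lipogenic acetyl-CoA pool (aKG C4/C5 lineage),
#' malic enzyme, PDH, pyruvate carboxylase, glycolysis, lactate release,
#' proline/ornithine synthesis and catabolism, media exchange, and
#' biomass/protein sinks.
#'
#' Closure fluxes (lactate release, ATP-citrate lyase, fatty-acid synthesis,
#' malate dehydrogenase, and the sink fluxes) are derived from the named free
#' fluxes so that every internal metabolite balances exactly; a derived flux
#' that would be negative raises an error naming it.
#'
#' @param fluxes Named list of free fluxes (µmol/mg/day); see
#'   [hepl_fluxes()] / [hdf_fluxes()] for the packaged condition presets.
#' @return A `tracenet` object.
#' @export
build_default_network <- function(fluxes) {
  f <- fluxes
  need <- c("gln_uptake", "gls", "gs", "glu_secretion", "glu_media_uptake",
            "ta_fwd", "ta_rev", "ogdh", "idh_fwd", "idh_rev", "cs", "me",
            "pdh", "pc", "glycolysis", "pyr_influx", "accoa_influx",
            "oaa_influx", "mdh_rev",
            "pycr", "oat", "prodh", "orn_degr",
            "pro_uptake", "orn_uptake", "n_influx")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("missing fluxes: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(unlist(f[need]) < 0)) stop("free fluxes must be >= 0", call. = FALSE)
  d <- list( # derived closure fluxes
    p5cs = f$pycr + f$oat,
    ldh = 2 * f$glycolysis + f$me + f$pyr_influx - f$pdh - f$pc,
    acl = f$cs + f$idh_rev - f$idh_fwd,
    mdh = f$ogdh + f$mdh_rev - f$me,
    akg_sink = f$ta_fwd + f$idh_fwd - f$ta_rev - f$ogdh - f$idh_rev,
    gln_sink = f$gln_uptake + f$gs - f$gls,
    pro_sink = f$pycr + f$pro_uptake - f$prodh,
    orn_sink = f$oat + f$orn_uptake - f$orn_degr,
    n_sink = f$ta_fwd + f$n_influx - f$ta_rev
  )
  d$fas <- f$pdh + d$acl + f$accoa_influx - f$cs
  d$oaa_sink <- d$mdh + f$pc + d$acl + f$oaa_influx - f$cs - f$mdh_rev
  d$glu_sink <- f$gls + f$ta_rev + f$prodh + f$orn_degr + f$glu_media_uptake -
    (f$gs + f$ta_fwd + d$p5cs + f$glu_secretion)
  neg <- names(d)[unlist(d) < -1e-9]
  if (length(neg)) {
    stop("flux set is infeasible: derived flux(es) ",
         paste0(neg, " = ", signif(unlist(d[neg]), 4), collapse = ", "),
         " would be negative", call. = FALSE)
  }
  d <- lapply(d, function(x) max(x, 0))

  mets <- list(
    # internal
    metabolite("gln", 5, 2), metabolite("glu", 5, 1), metabolite("akg", 5),
    metabolite("suc", 4, symmetric = TRUE),
    metabolite("fum", 4, symmetric = TRUE),
    metabolite("mal", 4), metabolite("oaa", 4), metabolite("cit", 6),
    metabolite("accoa", 2), metabolite("pyr", 3), metabolite("lac", 3),
    metabolite("p5c", 5), metabolite("pro", 5), metabolite("orn", 5),
    metabolite("aminoN", 0, 1),
    # external supplies
    metabolite("gln_media", 5, 2, external = TRUE),
    metabolite("glc_media", 6, external = TRUE),
    metabolite("glu_media", 5, 1, external = TRUE),
    metabolite("pro_media", 5, external = TRUE),
    metabolite("orn_media", 5, external = TRUE),
    metabolite("pyr_ext", 3, external = TRUE),
    metabolite("oaa_ext", 4, external = TRUE),
    metabolite("accoa_ext", 2, external = TRUE),
    metabolite("co2", 1, external = TRUE),
    metabolite("nh3", 0, 1, external = TRUE),
    metabolite("n_ext", 0, 1, external = TRUE),
    # external outlets (atom-complete bookkeeping of every exit)
    metabolite("co2_out", 1, external = TRUE),
    metabolite("nh3_out", 0, 1, external = TRUE),
    metabolite("n_out", 0, 1, external = TRUE),
    metabolite("glu_out", 5, 1, external = TRUE),
    metabolite("lac_out", 3, external = TRUE),
    metabolite("fa_out", 2, external = TRUE),
    metabolite("gln_prot", 5, 2, external = TRUE),
    metabolite("glu_prot", 5, 1, external = TRUE),
    metabolite("pro_prot", 5, external = TRUE),
    metabolite("akg_out", 5, external = TRUE),
    metabolite("oaa_out", 4, external = TRUE),
    metabolite("orn_out", 5, external = TRUE)
  )

  pr <- function(met, map) list(met = met, map = map)
  rx <- list(
    reaction("gln_uptake", f$gln_uptake, "gln_media",
             list(pr("gln", c(id5("gln_media"), "gln_media.N1", "gln_media.N2")))),
    reaction("gls", f$gls, "gln",
             list(pr("glu", c(id5("gln"), "gln.N1")),
                  pr("nh3_out", "gln.N2"))),
    reaction("gs", f$gs, c("glu", "nh3"),
             list(pr("gln", c(id5("glu"), "glu.N1", "nh3.N1")))),
    reaction("glu_secretion", f$glu_secretion, "glu",
             list(pr("glu_out", c(id5("glu"), "glu.N1")))),
    reaction("glu_media_uptake", f$glu_media_uptake, "glu_media",
             list(pr("glu", c(id5("glu_media"), "glu_media.N1")))),
    reaction("ta_fwd", f$ta_fwd, "glu",
             list(pr("akg", id5("glu")), pr("aminoN", "glu.N1"))),
    reaction("ta_rev", f$ta_rev, c("akg", "aminoN"),
             list(pr("glu", c(id5("akg"), "aminoN.N1")))),
    reaction("ogdh", f$ogdh, "akg",
             list(pr("suc", paste0("akg.C", 2:5)), pr("co2_out", "akg.C1"))),
    reaction("sdh", f$ogdh, "suc", list(pr("fum", paste0("suc.C", 1:4)))),
    reaction("fh", f$ogdh, "fum", list(pr("mal", paste0("fum.C", 1:4)))),
    reaction("mdh", d$mdh, "mal", list(pr("oaa", paste0("mal.C", 1:4)))),
    reaction("mdh_rev", f$mdh_rev, "oaa",
             list(pr("mal", paste0("oaa.C", 1:4)))),
    reaction("cs", f$cs, c("oaa", "accoa"),
             list(pr("cit", c("accoa.C1", "accoa.C2", paste0("oaa.C", 1:4))))),
    reaction("idh_fwd", f$idh_fwd, "cit",
             list(pr("akg", paste0("cit.C", 5:1)), pr("co2_out", "cit.C6"))),
    reaction("idh_rev", f$idh_rev, c("akg", "co2"),
             list(pr("cit", c(paste0("akg.C", 5:1), "co2.C1")))),
    reaction("acl", d$acl, "cit",
             list(pr("accoa", c("cit.C1", "cit.C2")),
                  pr("oaa", paste0("cit.C", 3:6)))),
    reaction("me", f$me, "mal",
             list(pr("pyr", paste0("mal.C", 1:3)), pr("co2_out", "mal.C4"))),
    reaction("pdh", f$pdh, "pyr",
             list(pr("accoa", c("pyr.C2", "pyr.C3")), pr("co2_out", "pyr.C1"))),
    reaction("pc", f$pc, c("pyr", "co2"),
             list(pr("oaa", c(paste0("pyr.C", 1:3), "co2.C1")))),
    reaction("glycolysis", f$glycolysis, "glc_media",
             list(pr("pyr", c("glc_media.C3", "glc_media.C2", "glc_media.C1")),
                  pr("pyr", c("glc_media.C4", "glc_media.C5", "glc_media.C6")))),
    reaction("pyr_influx", f$pyr_influx, "pyr_ext",
             list(pr("pyr", paste0("pyr_ext.C", 1:3)))),
    reaction("oaa_influx", f$oaa_influx, "oaa_ext",
             list(pr("oaa", paste0("oaa_ext.C", 1:4)))),
    reaction("accoa_influx", f$accoa_influx, "accoa_ext",
             list(pr("accoa", c("accoa_ext.C1", "accoa_ext.C2")))),
    reaction("ldh", d$ldh, "pyr", list(pr("lac", paste0("pyr.C", 1:3)))),
    reaction("lac_secretion", d$ldh, "lac",
             list(pr("lac_out", paste0("lac.C", 1:3)))),
    reaction("p5cs", d$p5cs, "glu",
             list(pr("p5c", id5("glu")), pr("n_out", "glu.N1"))),
    reaction("pycr", f$pycr, "p5c", list(pr("pro", id5("p5c")))),
    reaction("oat", f$oat, "p5c", list(pr("orn", id5("p5c")))),
    reaction("prodh", f$prodh, "pro",
             list(pr("glu", c(id5("pro"), "*")))),
    reaction("orn_degr", f$orn_degr, "orn",
             list(pr("glu", c(id5("orn"), "*")))),
    reaction("pro_uptake", f$pro_uptake, "pro_media",
             list(pr("pro", id5("pro_media")))),
    reaction("orn_uptake", f$orn_uptake, "orn_media",
             list(pr("orn", id5("orn_media")))),
    reaction("fas", d$fas, "accoa",
             list(pr("fa_out", c("accoa.C1", "accoa.C2")))),
    reaction("n_influx", f$n_influx, "n_ext", list(pr("aminoN", "n_ext.N1"))),
    reaction("n_sink", d$n_sink, "aminoN", list(pr("n_out", "aminoN.N1"))),
    reaction("gln_sink", d$gln_sink, "gln",
             list(pr("gln_prot", c(id5("gln"), "gln.N1", "gln.N2")))),
    reaction("glu_sink", d$glu_sink, "glu",
             list(pr("glu_prot", c(id5("glu"), "glu.N1")))),
    reaction("pro_sink", d$pro_sink, "pro", list(pr("pro_prot", id5("pro")))),
    reaction("akg_sink", d$akg_sink, "akg", list(pr("akg_out", id5("akg")))),
    reaction("oaa_sink", d$oaa_sink, "oaa",
             list(pr("oaa_out", paste0("oaa.C", 1:4)))),
    reaction("orn_sink", d$orn_sink, "orn", list(pr("orn_out", id5("orn"))))
  )
  net <- network(mets, rx)
  net$free_fluxes <- f
  net$derived_fluxes <- d
  net
}
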