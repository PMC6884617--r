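#' Condition flux presets
#'
#' Free-flux sets (µmol per mg protein per day) for the three study-like
#' conditions, usable with [build_default_network()]. The presets are
#' calibration products: magnitudes were fixed once so that the steady-state
#' labeling and media balances of the packaged network reproduce the headline
#' fractional readouts of the study conditions (secreted-glutamate source
#' shares, glutamine re-secretion split, proline-labeling and biomass-
#' enrichment contrasts, lipogenic acetyl-CoA enrichment contrast) — see the
#' methods vignette for the calibration procedure.
#'
#' Key contrasts encoded: the hepatocyte-like (HEP-L) condition deamidates
#' most glutamine and secretes glutamate (uptake 3.26, of which 58% returns
#' to the media as glutamate), with active reductive IDH flux; the dermal-
#' fibroblast (HDF) condition takes up half as much glutamine, consumes
#' media glutamate, channels glutamate into proline synthesis and protein,
#' and has weak reductive carboxylation; the primary-hepatocyte-like (PHH)
#' condition mirrors HEP-L with stronger reductive IDH flux.
#'
#' @return Named list of free fluxes.
#' @export
hepl_fluxes <- function() {
  list(gln_uptake = 3.2619, gls = 2.9808, gs = 0.05, glu_secretion = 2.6646,
       glu_media_uptake = 0, ta_fwd = 2.9937, ta_rev = 2.7937, ogdh = 0.3,
       idh_fwd = 2.7812, idh_rev = 1.2771, cs = 3.364, me = 0.1,
       pdh = 1.9428, pc = 1.9197, glycolysis = 5, pyr_influx = 1.6832,
       accoa_influx = 0, oaa_influx = 1.9242, mdh_rev = 0.3, pycr = 0.016,
       oat = 0.05, prodh = 0.05, orn_degr = 0.05, pro_uptake = 0.3,
       orn_uptake = 0.2, n_influx = 1.0)
}

#' @rdname hepl_fluxes
#' @export
hdf_fluxes <- function() {
  list(gln_uptake = 1.63095, gls = 1.689, gs = 0.3, glu_secretion = 0.02,
       glu_media_uptake = 0.08, ta_fwd = 2.0193, ta_rev = 1.2, ogdh = 0.4,
       idh_fwd = 0.5, idh_rev = 0.3012, cs = 0.6, me = 0.1, pdh = 1.2,
       pc = 0.3, glycolysis = 4, pyr_influx = 1, accoa_influx = 0.2,
       oaa_influx = 0.2, mdh_rev = 0.2, pycr = 0.1485, oat = 0.1, prodh = 0,
       orn_degr = 0, pro_uptake = 0.1, orn_uptake = 0.05, n_influx = 1.0)
}

#' @rdname hepl_fluxes
#' @export
phh_fluxes <- function() {
  f <- hepl_fluxes()
  f$idh_rev <- 1.6  # strongest reductive carboxylation of the three
  f$gs <- 0.03
  f
}

#' Study-condition preset
#'
#' Bundles a condition's flux set with the culture parameters the simulated
#' measurements need: media composition (HMM-like: 2 mM glutamine, 3.15 g/L
#' glucose = 17.49 mM, 54 µM glutamate, 0.03 g/L proline, 0.1 g/L ornithine),
#' well geometry, the fraction of newly synthesized lipid g accrued over the
#' 2-day fatty-acid labeling, and the scales converting simulator fluxes to
#' measurement units (biomass atom-percent, EIC per mg).
#'
#' @param condition `"HEP-L"`, `"HDF"`, or `"PHH"`.
#' @return A `condition_preset` list with elements `condition`, `fluxes`,
#'   `media_mM` (glutamine/glucose/glutamate), `volume_l`, `protein_mg`,
#'   `hours`, `g_newlipid`, `bio_scale` (atom-percent points per unit
#'   labeled-carbon sink flux), `eic_scale`, `baseline_atom_pct`.
#' @export
condition_preset <- function(condition = c("HEP-L", "HDF", "PHH")) {
  condition <- match.arg(condition)
  fluxes <- switch(condition, "HEP-L" = hepl_fluxes(), "HDF" = hdf_fluxes(),
                   "PHH" = phh_fluxes())
  structure(list(
    condition = condition,
    fluxes = fluxes,
    media_mM = c(glutamine = 2, glucose = 17.49, glutamate = 0.054),
    volume_l = 0.001,
    protein_mg = switch(condition, "HDF" = 0.6, 0.4),
    hours = 24,
    g_newlipid = 0.5,
    bio_scale = 0.05,
    eic_scale = 1e6,
    baseline_atom_pct = 1.0799
  ), class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat("Condition preset '", x$condition, "': ", x$protein_mg,
      " mg protein/well, ", x$volume_l * 1000, " mL media, ", x$hours,
      " h incubation\n", sep = "")
  invisible(x)
}
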