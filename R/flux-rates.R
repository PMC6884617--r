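#' Media-based exchange rate
#'
#' Rate of net uptake (positive) or net secretion (negative) from blank vs
#' harvest media concentrations, normalized per mg protein and per 24-h day:
#' `(blank - harvest) [mM] * volume [L] * 1000 / protein [mg] / (hours/24)`.
#'
#' @param blank_mM Concentration in control (no-cell) media, mM.
#' @param harvest_mM Concentration after incubation, mM.
#' @param volume_l Media volume, litres.
#' @param protein_mg Protein mass per well, mg.
#' @param hours Incubation time, hours.
#' @return Signed rate in µmol per mg protein per day; positive = uptake,
#'   negative = secretion. Vectorized.
#' @examples
#' exchange_rate(2.0, 1.5, 0.002, 0.25, 24) # +4 umol/mg/day uptake
#' @export
exchange_rate <- function(blank_mM, harvest_mM, volume_l, protein_mg, hours) {
  if (any(protein_mg <= 0)) stop("protein mass must be > 0", call. = FALSE)
  if (any(hours <= 0)) stop("incubation time must be > 0", call. = FALSE)
  if (any(volume_l <= 0)) stop("media volume must be > 0", call. = FALSE)
  if (any(blank_mM < 0) || any(harvest_mM < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  (blank_mM - harvest_mM) * volume_l * 1000 / protein_mg / (hours / 24)
}

#' Exchange rates from a tidy media table
#'
#' Applies [exchange_rate()] row-wise to a media-measurement tibble (the
#' `media` element of a [simulate_experiment()] bundle, or the same columns
#' read from file).
#'
#' @param media Tibble with `blank_mM`, `harvest_mM`, `volume_l`,
#'   `protein_mg`, `hours` (other columns carried through).
#' @return Input with `rate_umol_per_mg_day` and `direction`
#'   (`"uptake"`/`"secretion"`/`"balanced"`) appended.
#' @export
exchange_rates <- function(media) {
  need <- c("blank_mM", "harvest_mM", "volume_l", "protein_mg", "hours")
  miss <- setdiff(need, names(media))
  if (length(miss)) stop("media table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  media |>
    dplyr::mutate(
      rate_umol_per_mg_day = exchange_rate(
        .data$blank_mM, .data$harvest_mM, .data$volume_l, .data$protein_mg,
        .data$hours),
      direction = dplyr::case_when(
        .data$rate_umol_per_mg_day > 0 ~ "uptake",
        .data$rate_umol_per_mg_day < 0 ~ "secretion",
        TRUE ~ "balanced"))
}

# accept a corrected MID as a bare numeric vector or as a tidy table slice
as_corrected_mid <- function(x, what = "MID") {
  if (is.data.frame(x)) {
    if ("corrected" %in% names(x) && !all(x$corrected)) {
      stop(what, " must be natural-abundance corrected before use",
           call. = FALSE)
    }
    x <- x$abundance[order(x$shift)]
  }
  assert_normalized_mid(x, tol = 1e-6, what = what)
  x
}

#' MID of de novo secreted material
#'
#' Removes the pre-existing unlabeled media pool from a harvest-media MID by
#' concentration-weighted subtraction: the secreted component is
#' `(harvest_conc * harvest_mid - blank_conc * delta_M0) / (harvest - blank)`.
#' Valid for net producers (harvest > blank) under the linear-accumulation
#' media model.
#'
#' @param blank_mM,harvest_mM Media concentrations (blank assumed entirely
#'   unlabeled, M0).
#' @param harvest_mid Corrected, normalized MID of the metabolite in harvest
#'   media.
#' @return Normalized MID of the secreted component.
#' @export
denovo_secreted_mid <- function(blank_mM, harvest_mM, harvest_mid) {
  if (harvest_mM <= blank_mM) {
    stop("harvest concentration must exceed blank for a net producer",
         call. = FALSE)
  }
  mid <- as_corrected_mid(harvest_mid, "harvest MID")
  out <- harvest_mM * mid
  out[1] <- out[1] - blank_mM
  out[out < 0] <- 0
  normalize_mid(out)
}

#' Dual-tracer source apportionment of secreted glutamate
#'
#' Combines the uniformly labeled glutamine experiment and the uniformly
#' labeled glucose experiment into carbon-source fractions of de novo
#' secreted glutamate. The glutamine-derived fraction is the M5 + M6 share of
#' the secreted-glutamate MID in the glutamine-tracer experiment (M6 =
#' deamidation product, M5 = carbon-retaining transamination cycle); the
#' glucose-derived fraction is the M2 + M3 share in the glucose-tracer
#' experiment (PDH and pyruvate-carboxylase routes); the remainder is
#' attributed to other sources. Glutamate M1 in the glutamine experiment is
#' 15N-only — nitrogen exchanged onto an unlabeled carbon skeleton — and
#' therefore counts toward NON-glutamine carbon; summing it into the
#' glutamine share is the easiest mistake to make with this assay.
#'
#' Each labeled share is computed within its own experiment; combining them
#' assumes the two experiments' net secretion rates agree, so a difference
#' beyond 20% triggers a consistency warning.
#'
#' @param net_secretion Net glutamate secretion rate (µmol/mg/day, positive).
#' @param gln_tracer_glu_mid Corrected MID of de novo secreted glutamate in
#'   the glutamine-tracer experiment (length 7, shifts 0-6).
#' @param glc_tracer_glu_mid Corrected MID in the glucose-tracer experiment
#'   (carbon shifts, length >= 4).
#' @param gln_tracer_secretion,glc_tracer_secretion Net secretion rates
#'   measured in each experiment (> 0).
#' @return One-row tibble: `fraction_glutamine`, `fraction_glucose`,
#'   `fraction_other`, `net_secretion_umol_per_mg_day`.
#' @export
source_apportionment <- function(net_secretion, gln_tracer_glu_mid,
                                 glc_tracer_glu_mid, gln_tracer_secretion,
                                 glc_tracer_secretion) {
  if (gln_tracer_secretion <= 0 || glc_tracer_secretion <= 0) {
    stop("secretion rates must be > 0 in both tracer experiments",
         call. = FALSE)
  }
  gmid <- as_corrected_mid(gln_tracer_glu_mid, "glutamine-tracer MID")
  cmid <- as_corrected_mid(glc_tracer_glu_mid, "glucose-tracer MID")
  if (length(gmid) < 7) {
    stop("glutamine-tracer glutamate MID must cover shifts 0-6", call. = FALSE)
  }
  if (length(cmid) < 4) {
    stop("glucose-tracer glutamate MID must cover shifts 0-3", call. = FALSE)
  }
  rel <- abs(gln_tracer_secretion - glc_tracer_secretion) /
    mean(c(gln_tracer_secretion, glc_tracer_secretion))
  if (rel > 0.2) {
    warning("net secretion differs by ", round(100 * rel), "% between the ",
            "tracer experiments; the combined apportionment assumes they ",
            "measure the same flux", call. = FALSE)
  }
  f_gln <- sum(gmid[c(6, 7)])  # M5 + M6
  f_glc <- sum(cmid[c(3, 4)])  # M2 + M3
  if (f_gln + f_glc > 1 + 0.05) {
    stop("labeled shares sum to ", signif(f_gln + f_glc, 3),
         " > 1: the two experiments are inconsistent", call. = FALSE)
  }
  f_other <- 1 - f_gln - f_glc
  if (f_other < 0) {
    warning("other-source fraction floored at 0", call. = FALSE)
    f_other <- 0
  }
  tibble::tibble(fraction_glutamine = f_gln, fraction_glucose = f_glc,
                 fraction_other = f_other,
                 net_secretion_umol_per_mg_day = net_secretion)
}

#' Glutamine utilization split
#'
#' Separates glutamine uptake into the part re-secreted as glutamate and the
#' part actually utilized by intracellular metabolism.
#'
#' @param uptake Glutamine uptake rate (> 0), µmol/mg/day.
#' @param gln_derived_glu_secretion Glutamine-derived glutamate secretion
#'   rate, in `[0, uptake]`.
#' @return One-row tibble: `uptake`, `secreted_as_glutamate`, `utilized`,
#'   `utilized_fraction`.
#' @examples
#' utilization_split(3.26, 1.89)
#' @export
utilization_split <- function(uptake, gln_derived_glu_secretion) {
  if (uptake <= 0) stop("uptake must be > 0", call. = FALSE)
  if (gln_derived_glu_secretion < 0) {
    stop("secretion must be >= 0", call. = FALSE)
  }
  if (gln_derived_glu_secretion > uptake) {
    stop("glutamine-derived glutamate secretion (",
         signif(gln_derived_glu_secretion, 4), ") exceeds uptake (",
         signif(uptake, 4), "): mass-balance violation", call. = FALSE)
  }
  utilized <- uptake - gln_derived_glu_secretion
  tibble::tibble(uptake = uptake,
                 secreted_as_glutamate = gln_derived_glu_secretion,
                 utilized = utilized, utilized_fraction = utilized / uptake)
}

#' Biomass 13C enrichment over the unlabeled baseline
#'
#' C/IRMS enrichment: the difference between the sample's 13C atom percent
#' and the natural-abundance baseline measured in cells incubated without
#' tracer (default 1.0799 atom percent).
#'
#' @param sample_atom_pct Measured 13C atom percent, in `[0, 100]`.
#' @param baseline_atom_pct Baseline atom percent (default 1.0799).
#' @return Enrichment in atom-percent points (vectorized); negative values
#'   are reported with a warning.
#' @examples
#' cirms_enrichment(1.25)
#' @export
cirms_enrichment <- function(sample_atom_pct, baseline_atom_pct = 1.0799) {
  if (any(sample_atom_pct < 0 | sample_atom_pct > 100) ||
      any(baseline_atom_pct < 0 | baseline_atom_pct > 100)) {
    stop("atom percentages must lie in [0, 100]", call. = FALSE)
  }
  out <- sample_atom_pct - baseline_atom_pct
  if (any(out < 0)) {
    warning("negative enrichment (sample below baseline) reported as-is",
            call. = FALSE)
  }
  out
}

#' Intracellular concentration from extract amount and cell volume
#'
#' @param amount_mol Metabolite amount in the extract, mol.
#' @param cell_count Cells per plate.
#' @param mean_cell_volume_l Average single-cell volume, litres.
#' @return Molar concentration (mol/L).
#' @examples
#' intracellular_concentration(1e-9, 1e6, 1e-12) # 1 mM
#' @export
intracellular_concentration <- function(amount_mol, cell_count,
                                        mean_cell_volume_l) {
  if (any(cell_count <= 0) || any(mean_cell_volume_l <= 0)) {
    stop("cell count and cell volume must be > 0", call. = FALSE)
  }
  amount_mol / (cell_count * mean_cell_volume_l)
}
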