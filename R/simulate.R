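# run code with a private RNG stream derived from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# chemical formulas of the measured species (free-acid forms)
metabolite_formulas <- function() {
  list(glutamine = "C5H10N2O3", glutamate = "C5H9NO4", citrate = "C6H8O7",
       malate = "C4H6O5", succinate = "C4H6O4", fumarate = "C4H4O4",
       lactate = "C3H6O3", akg = "C5H6O5", proline = "C5H9NO2",
       ornithine = "C5H12N2O2", myristate = "C14H28O2")
}

# network node behind each reported metabolite
sim_metabolites <- c(glutamine = "gln", glutamate = "glu", citrate = "cit",
                     malate = "mal", succinate = "suc", fumarate = "fum",
                     lactate = "lac", akg = "akg", proline = "pro",
                     ornithine = "orn")

#' Tracer-accessible atoms of a measured metabolite
#'
#' The shift range an isotopologue assay needs to cover: the metabolite's
#' carbons, plus its tracked nitrogens when the tracer carries 15N. This also
#' sizes the correction matrix for [correct_mid()].
#'
#' @param metabolite Reported metabolite name (e.g. `"glutamate"`).
#' @param tracer A [tracer_spec()].
#' @param net Network supplying atom counts (default packaged HEP-L network
#'   topology; counts are condition-independent).
#' @return Named count vector, e.g. `c(C = 5, N = 1)`.
#' @export
tracer_atoms_for <- function(metabolite, tracer,
                             net = build_default_network(hepl_fluxes())) {
  node <- sim_metabolites[[metabolite]]
  if (is.null(node)) stop("unknown metabolite '", metabolite, "'",
                          call. = FALSE)
  m <- net$metabolites[[node]]
  out <- c(C = m$carbons)
  if (length(tracer$nitrogen_positions) && m$nitrogens > 0) {
    out <- c(out, N = m$nitrogens)
  }
  out
}

#' Design a simulated tracer experiment
#'
#' @param condition `"HEP-L"`, `"HDF"`, or `"PHH"` (picks the flux preset and
#'   culture parameters via [condition_preset()]).
#' @param tracer A [tracer_spec()]; default the U-13C,15N2-glutamine design.
#' @param n_replicates Biological replicates (wells).
#' @param mid_cv Multiplicative noise CV on measured MID channels.
#' @param conc_cv Multiplicative noise CV on media concentrations.
#' @param bio_cv Multiplicative noise CV on the biomass-enrichment increment.
#' @param seed Integer seed; every random draw of the bundle flows from it.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(condition = "HEP-L",
                              tracer = tracer_gln_u13c15n2(),
                              n_replicates = 7, mid_cv = 0.05,
                              conc_cv = 0.05, bio_cv = 0.02, seed = 1) {
  stopifnot(n_replicates >= 1, mid_cv >= 0, conc_cv >= 0, bio_cv >= 0)
  preset <- condition_preset(condition)
  structure(list(condition = preset$condition, preset = preset,
                 tracer = tracer, n_replicates = as.integer(n_replicates),
                 mid_cv = mid_cv, conc_cv = conc_cv, bio_cv = bio_cv,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  pmax(x * (1 + stats::rnorm(length(x), 0, cv)), 0)
}

# measured (uncorrected, noisy) MID rows for one true MID
measure_mid <- function(true_mid, metabolite, tracer, mid_cv, purity = 1) {
  ta <- tracer_atoms_for(metabolite, tracer)
  cm <- build_correction_matrix(metabolite_formulas()[[metabolite]], ta,
                                purity = purity)
  n <- sum(ta)
  stopifnot(length(true_mid) == n + 1)
  meas <- as.numeric(cm$M %*% true_mid)
  normalize_mid(mult_noise(meas, mid_cv))
}

#' Simulate a full tracer experiment
#'
#' Produces the measurement bundle one 24-h labeling experiment yields, per
#' replicate: (i) media concentrations at 0 h (blank) and harvest for
#' glutamine, glutamate and glucose — linear accumulation/depletion from the
#' net fluxes times protein mass and time over volume; (ii) measured
#' (uncorrected) MIDs for intracellular metabolites and media glutamate —
#' steady-state MIDs pushed through the natural-abundance measurement
#' operator, then multiplicative noise and renormalization; (iii) labeled
#' proline/ornithine pools as EIC per mg protein; (iv) biomass 13C atom
#' percent (baseline plus incorporation-flux-proportional enrichment from the
#' protein sinks); (v) myristate MIDs from the ISA forward model with D set
#' by the simulated lipogenic acetyl-CoA enrichment and the preset g.
#'
#' @param design An [experiment_design()].
#' @param net Optional pre-built network (defaults to the design's preset).
#' @return A `sirm_sim` list of tibbles: `media`, `mids`, `pools`, `biomass`,
#'   `fatty_acid`, plus `state` (the noiseless steady state) and `design`.
#' @export
simulate_experiment <- function(design, net = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  preset <- design$preset
  if (is.null(net)) net <- build_default_network(preset$fluxes)
  tracer <- design$tracer
  state <- steady_state_labeling(net, tracer)
  f <- net$free_fluxes
  k <- preset$protein_mg * preset$hours / 24 / (1000 * preset$volume_l)

  net_rate <- c(glutamine = -f$gln_uptake, glucose = -f$glycolysis,
                glutamate = f$glu_secretion - f$glu_media_uptake)
  blank0 <- preset$media_mM[c("glutamine", "glucose", "glutamate")]
  harvest0 <- blank0 + net_rate[names(blank0)] * k
  if (any(harvest0 < 0)) {
    stop("harvest concentration of ",
         paste(names(harvest0)[harvest0 < 0], collapse = ", "),
         " driven negative; reduce fluxes or shorten the incubation",
         call. = FALSE)
  }

  # media glutamate labeling: pre-existing unlabeled pool minus uptake, plus
  # secretion carrying the intracellular distribution
  n_glu <- sum(tracer_atoms_for("glutamate", tracer))
  glu_true <- sim_true_mid(state, "glutamate", tracer)
  blank_amt <- preset$media_mM[["glutamate"]]
  removed <- f$glu_media_uptake * k
  added <- f$glu_secretion * k
  if (blank_amt - removed < 0) {
    stop("media glutamate exhausted by uptake; reduce fluxes or shorten the ",
         "incubation", call. = FALSE)
  }
  media_glu_mid <- (blank_amt - removed) * c(1, numeric(n_glu)) +
    added * glu_true
  media_glu_mid <- normalize_mid(media_glu_mid)

  mets <- names(sim_metabolites)
  true_mids <- lapply(stats::setNames(nm = mets), sim_true_mid,
                      state = state, tracer = tracer)

  bio_sinks <- net$derived_fluxes[c("gln_sink", "glu_sink", "pro_sink")]
  bio_sub <- c("gln", "glu", "pro")
  incorporation <- sum(vapply(seq_along(bio_sub), function(i) {
    bio_sinks[[i]] * mean_labeled_carbons(state, bio_sub[i])
  }, 0))
  enrich0 <- preset$bio_scale * incorporation

  D <- lipogenic_D(state, tracer)
  fa_spec <- isa_model(n_units = 7, unit_shift = D$shift)
  fa_true <- isa_forward(fa_spec, D$D, preset$g_newlipid)

  with_seed(design$seed, {
    reps <- seq_len(design$n_replicates)
    samples <- sprintf("%s_r%02d", design$condition, reps)

    media <- purrr::map_dfr(reps, function(i) {
      tibble::tibble(
        sample = samples[i], condition = design$condition,
        metabolite = names(blank0),
        blank_mM = mult_noise(unname(blank0), design$conc_cv),
        harvest_mM = mult_noise(unname(harvest0), design$conc_cv),
        volume_l = preset$volume_l, protein_mg = preset$protein_mg,
        hours = preset$hours)
    })

    mids <- purrr::map_dfr(reps, function(i) {
      intra <- purrr::imap_dfr(true_mids, function(tm, met) {
        meas <- measure_mid(tm, met, tracer, design$mid_cv)
        tibble::tibble(compartment = "cell", metabolite = met,
                       shift = seq_along(meas) - 1L, abundance = meas)
      })
      mglu <- measure_mid(media_glu_mid, "glutamate", tracer, design$mid_cv)
      dplyr::bind_rows(intra, tibble::tibble(
        compartment = "media", metabolite = "glutamate",
        shift = seq_along(mglu) - 1L, abundance = mglu)) |>
        dplyr::mutate(sample = samples[i], group = design$condition,
                      tracer = tracer_label(tracer), corrected = FALSE,
                      .before = 1)
    })

    pools <- purrr::map_dfr(reps, function(i) {
      tibble::tibble(
        sample = samples[i], condition = design$condition,
        metabolite = c("proline", "ornithine"),
        eic_per_mg = mult_noise(preset$eic_scale * c(
          1 - true_mids$proline[1], 1 - true_mids$ornithine[1]),
          design$mid_cv))
    })

    biomass <- tibble::tibble(
      sample = samples, condition = design$condition,
      atom_pct = preset$baseline_atom_pct +
        mult_noise(rep(enrich0, design$n_replicates), design$bio_cv))

    fatty_acid <- purrr::map_dfr(reps, function(i) {
      meas <- normalize_mid(mult_noise(fa_true, design$mid_cv))
      tibble::tibble(sample = samples[i], group = design$condition,
                     tracer = tracer_label(tracer), metabolite = "myristate",
                     shift = seq_along(meas) - 1L, abundance = meas,
                     corrected = FALSE)
    })

    structure(list(media = media, mids = mids, pools = pools,
                   biomass = biomass, fatty_acid = fatty_acid,
                   state = state, design = design,
                   truth = list(mids = true_mids,
                                media_glutamate = media_glu_mid,
                                D = D$D, g = preset$g_newlipid,
                                biomass_enrichment = enrich0)),
              class = "sirm_sim")
  })
}

#' @export
print.sirm_sim <- function(x, ...) {
  cat("Simulated tracer experiment: ", x$design$condition, ", ",
      x$design$n_replicates, " replicates, tracer ",
      tracer_label(x$design$tracer), "\n", sep = "")
  invisible(x)
}

# true MID of a reported metabolite on its tracer-accessible shift range
sim_true_mid <- function(state, metabolite, tracer) {
  node <- sim_metabolites[[metabolite]]
  m <- state$net$metabolites[[node]]
  use_n <- length(tracer$nitrogen_positions) > 0 && m$nitrogens > 0
  if (use_n) state_mid(state, node, "total") else
    state_mid(state, node, "carbon")
}

tracer_label <- function(tracer) {
  lab <- tracer$substrate
  if (length(tracer$carbon_positions)) {
    lab <- paste0(lab, "_13C", paste(tracer$carbon_positions, collapse = ""))
  }
  if (length(tracer$nitrogen_positions)) {
    lab <- paste0(lab, "_15N", paste(tracer$nitrogen_positions, collapse = ""))
  }
  lab
}

# lipogenic acetyl-CoA tracer enrichment implied by the steady state:
# per-unit shift 2 under a uniform carbon tracer, 1 under 5-13C-glutamine
lipogenic_D <- function(state, tracer) {
  mid <- state_mid(state, "accoa", "carbon")
  if (length(tracer$carbon_positions) > 1) {
    list(D = mid[3], shift = 2L)
  } else {
    list(D = mid[2], shift = 1L)
  }
}

#' Simulate biomass 13C enrichment measurements
#'
#' Convenience wrapper producing only the C/IRMS-style biomass atom-percent
#' values for one condition under the U-13C,15N2-glutamine tracer.
#'
#' @inheritParams experiment_design
#' @return Tibble with `sample`, `condition`, `atom_pct`.
#' @export
simulate_biomass_enrichment <- function(condition = "HEP-L", n_replicates = 8,
                                        bio_cv = 0.02, seed = 1) {
  d <- experiment_design(condition, tracer_gln_u13c15n2(),
                         n_replicates = n_replicates, mid_cv = 0,
                         conc_cv = 0, bio_cv = bio_cv, seed = seed)
  simulate_experiment(d)$biomass
}

#' Simulate an untargeted feature table
#'
#' Log-normal feature intensities for a two-group design; `n_changed`
#' features receive a group-mean shift of `log2_effect` (group B over group
#' A), the rest are null. Intensity noise is log-normal with the requested
#' coefficient of variation.
#'
#' @param n_features Number of features (the study screen had 858).
#' @param n_per_group Samples per group.
#' @param n_changed Number of truly changed features.
#' @param log2_effect Log2 fold change planted in the changed features.
#' @param cv Within-group coefficient of variation of intensities.
#' @param seed Integer seed.
#' @param groups Two group labels.
#' @param missing_rate Probability any single intensity is missing (default
#'   0; the presence filter is exercised through this).
#' @return Long tibble: `feature_id`, `sample`, `group`, `intensity`,
#'   plus a `changed` flag carried in the attribute `"truth"`.
#' @export
simulate_feature_table <- function(n_features = 858, n_per_group = 7,
                                   n_changed = 101, log2_effect = 3,
                                   cv = 0.3, seed = 1,
                                   groups = c("HDF", "HEP-L"),
                                   missing_rate = 0) {
  stopifnot(n_changed <= n_features, n_per_group >= 2, length(groups) == 2)
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    base <- stats::rlnorm(n_features, meanlog = log(1e5), sdlog = 1)
    changed <- seq_len(n_features) <= n_changed
    # planted effects split between directions
    dir <- rep(c(1, -1), length.out = n_changed)
    fc <- rep(1, n_features)
    fc[changed] <- 2^(log2_effect * dir)
    mass <- round(stats::runif(n_features, 80, 600), 4)
    rt <- round(stats::runif(n_features, 0.5, 11.5), 2)
    feature_id <- sprintf("%.4f@%.2f", mass, rt)
    feature_id <- make.unique(feature_id, sep = "_")
    grid <- tidyr::expand_grid(
      idx = seq_len(n_features),
      tibble::tibble(group = rep(groups, each = n_per_group),
                     rep = rep(seq_len(n_per_group), 2)))
    out <- grid |>
      dplyr::mutate(
        feature_id = feature_id[.data$idx],
        sample = sprintf("%s_s%02d", .data$group, .data$rep),
        mu = base[.data$idx] * ifelse(.data$group == groups[2],
                                      fc[.data$idx], 1),
        intensity = stats::rlnorm(dplyr::n(), log(.data$mu), sdlog)) |>
      dplyr::select("feature_id", "sample", "group", "intensity")
    if (missing_rate > 0) {
      out$intensity[stats::runif(nrow(out)) < missing_rate] <- NA_real_
    }
    attr(out, "truth") <- tibble::tibble(feature_id = feature_id,
                                         changed = changed)
    out
  })
}
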