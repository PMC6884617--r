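#' Correct the measured MIDs of a simulated experiment
#'
#' Natural-abundance-corrects every measured MID in a
#' [simulate_experiment()] bundle (intracellular and media) with the matching
#' formula and tracer-atom specification.
#'
#' @param sim A `sirm_sim` bundle.
#' @param purity Tracer purity passed to [build_correction_matrix()].
#' @return The bundle's `mids` tibble with corrected abundances.
#' @export
correct_sim_mids <- function(sim, purity = 1) {
  stopifnot(inherits(sim, "sirm_sim"))
  tracer <- sim$design$tracer
  forms <- metabolite_formulas()
  mets <- unique(sim$mids$metabolite)
  cms <- lapply(stats::setNames(nm = mets), function(met) {
    build_correction_matrix(forms[[met]], tracer_atoms_for(met, tracer),
                            purity = purity)
  })
  sim$mids |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("sample", "group", "tracer", "compartment", "metabolite")))) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$shift)
      d$abundance <- correct_mid(normalize_mid(d$abundance),
                                 cms[[key$metabolite]])
      d$corrected <- TRUE
      d
    }) |>
    dplyr::ungroup()
}

# mean corrected MID of one metabolite/compartment across replicates
mean_corrected_mid <- function(corrected_mids, metabolite,
                               compartment = "cell") {
  corrected_mids |>
    dplyr::filter(.data$metabolite == !!metabolite,
                  .data$compartment == !!compartment) |>
    dplyr::summarise(abundance = mean(.data$abundance),
                     .by = "shift") |>
    dplyr::arrange(.data$shift) |>
    dplyr::pull("abundance") |>
    normalize_mid()
}

#' Glutamate source apportionment from a dual-tracer pair of simulations
#'
#' Runs the full analysis path on two simulated experiments (same condition,
#' U-13C,15N2-glutamine and U-13C-glucose tracers): media exchange rates,
#' natural-abundance correction of the harvest-media glutamate MIDs,
#' removal of the pre-existing unlabeled media pool, and
#' [source_apportionment()].
#'
#' @param sim_gln,sim_glc `sirm_sim` bundles for the two tracer designs.
#' @return The [source_apportionment()] tibble.
#' @export
apportionment_from_sims <- function(sim_gln, sim_glc) {
  part <- function(sim) {
    rates <- exchange_rates(sim$media)
    glu <- dplyr::filter(rates, .data$metabolite == "glutamate")
    secretion <- -mean(glu$rate_umol_per_mg_day)
    corr <- correct_sim_mids(sim)
    mid <- mean_corrected_mid(corr, "glutamate", "media")
    list(secretion = secretion,
         secreted_mid = denovo_secreted_mid(mean(glu$blank_mM),
                                            mean(glu$harvest_mM), mid))
  }
  a <- part(sim_gln)
  b <- part(sim_glc)
  source_apportionment(
    net_secretion = mean(c(a$secretion, b$secretion)),
    gln_tracer_glu_mid = a$secreted_mid,
    glc_tracer_glu_mid = b$secreted_mid,
    gln_tracer_secretion = a$secretion,
    glc_tracer_secretion = b$secretion)
}

#' Glutamine utilization split from a simulated experiment
#'
#' Computes mean glutamine uptake and glutamine-derived glutamate secretion
#' (net glutamate secretion times the M5+M6 share of the de novo secreted
#' glutamate) from a U-13C,15N2-glutamine simulation, then applies
#' [utilization_split()].
#'
#' @param sim_gln A `sirm_sim` bundle under the glutamine tracer.
#' @return The [utilization_split()] tibble.
#' @export
utilization_from_sim <- function(sim_gln) {
  rates <- exchange_rates(sim_gln$media)
  uptake <- rates |>
    dplyr::filter(.data$metabolite == "glutamine") |>
    dplyr::pull("rate_umol_per_mg_day") |>
    mean()
  glu <- dplyr::filter(rates, .data$metabolite == "glutamate")
  secretion <- -mean(glu$rate_umol_per_mg_day)
  corr <- correct_sim_mids(sim_gln)
  mid <- mean_corrected_mid(corr, "glutamate", "media")
  secreted <- denovo_secreted_mid(mean(glu$blank_mM), mean(glu$harvest_mM),
                                  mid)
  gln_derived <- secretion * isotopologue_fraction(secreted, c(5, 6))
  utilization_split(uptake, gln_derived)
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates (or ingests) the study's measurement bundle, corrects MIDs, and
#' runs every analysis stage: media exchange rates, dual-tracer glutamate
#' source apportionment, glutamine utilization split, biomass enrichment,
#' labeled proline/ornithine pool comparison, ISA fits of myristate labeling
#' with the between-condition comparison, tracer-fate classification, and
#' the untargeted volcano screen. Per-stage CSVs, a JSON summary and a run
#' log are written to `output_dir`; all randomness flows from `seed`, so a
#' fixed config reproduces identical outputs.
#'
#' @param config Named list (or path to a YAML file) with any of:
#'   `conditions` (default `c("HDF", "HEP-L")`), `n_replicates` (7),
#'   `mid_cv` (0.05), `conc_cv` (0.05), `seed` (1), `fc_threshold` (2),
#'   `fdr_threshold` (0.005), `n_features` (858), `n_changed` (101),
#'   `log2_effect` (3), `feature_cv` (0.3), `output_dir` (required).
#' @return Invisibly, a named list of the stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(conditions = c("HDF", "HEP-L"), n_replicates = 7L,
                   mid_cv = 0.05, conc_cv = 0.05, seed = 1L,
                   fc_threshold = 2, fdr_threshold = 0.005,
                   n_features = 858L, n_changed = 101L, log2_effect = 3,
                   feature_cv = 0.3, output_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$output_dir)) stop("config needs an output_dir",
                                    call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tracers <- list(gln = tracer_gln_u13c15n2(), glc = tracer_glc_u13c(),
                  c5 = tracer_gln_5c13())
  sims <- stage("simulate", {
    purrr::imap(stats::setNames(nm = cfg$conditions), function(cond, i) {
      purrr::imap(tracers, function(tr, key) {
        simulate_experiment(experiment_design(
          cond, tr, n_replicates = cfg$n_replicates, mid_cv = cfg$mid_cv,
          conc_cv = cfg$conc_cv,
          seed = cfg$seed + 97L * match(cond, cfg$conditions) +
            13L * match(key, names(tracers))))
      })
    })
  })

  corrected <- stage("correct", {
    purrr::map_dfr(sims, function(bytracer) {
      purrr::map_dfr(bytracer, correct_sim_mids)
    })
  })
  write_mid_table(
    dplyr::select(dplyr::filter(corrected, .data$compartment == "cell"),
                  dplyr::all_of(mid_table_cols)),
    out("corrected_mids.csv"))

  rates <- stage("rates", {
    purrr::map_dfr(sims, function(bytracer) {
      exchange_rates(bytracer$gln$media)
    }) |>
      dplyr::summarise(rate_umol_per_mg_day = mean(.data$rate_umol_per_mg_day),
                       .by = c("condition", "metabolite")) |>
      dplyr::mutate(direction = ifelse(.data$rate_umol_per_mg_day >= 0,
                                       "uptake", "secretion"))
  })
  readr::write_csv(rates, out("exchange_rates.csv"), progress = FALSE)

  producer <- cfg$conditions[length(cfg$conditions)]
  apportionment <- stage("apportion", {
    apportionment_from_sims(sims[[producer]]$gln, sims[[producer]]$glc)
  })
  readr::write_csv(apportionment, out("apportionment.csv"), progress = FALSE)

  utilization <- stage("utilization", utilization_from_sim(sims[[producer]]$gln))
  readr::write_csv(utilization, out("utilization.csv"), progress = FALSE)

  biomass <- stage("biomass", {
    purrr::map_dfr(sims, function(bytracer) bytracer$gln$biomass) |>
      dplyr::mutate(enrichment_pp = cirms_enrichment(.data$atom_pct))
  })
  readr::write_csv(biomass, out("biomass_enrichment.csv"), progress = FALSE)

  pools <- stage("pools", {
    purrr::map_dfr(sims, function(bytracer) bytracer$gln$pools)
  })
  pool_fold <- if (length(cfg$conditions) == 2) {
    pro <- split(dplyr::filter(pools, .data$metabolite == "proline"),
                 dplyr::filter(pools, .data$metabolite == "proline")$condition)
    labeled_pool_fold_change(pro[[cfg$conditions[1]]],
                             pro[[cfg$conditions[2]]])
  } else NULL
  readr::write_csv(pools, out("labeled_pools.csv"), progress = FALSE)

  isa <- stage("isa", {
    fits <- purrr::map(sims, function(bytracer) {
      fa <- bytracer$c5$fatty_acid
      mids <- fa |>
        tidyr::pivot_wider(id_cols = "shift", names_from = "sample",
                           values_from = "abundance") |>
        dplyr::arrange(.data$shift) |>
        dplyr::select(-"shift") |>
        as.matrix()
      fit_isa(mids, isa_model(n_units = 7, unit_shift = 1))
    })
    res <- purrr::imap_dfr(fits, function(f, cond) {
      dplyr::mutate(tidy(f), condition = cond, .before = 1)
    })
    if (length(fits) == 2) {
      attr(res, "pct_difference") <- compare_conditions(fits[[2]], fits[[1]])
    }
    res
  })
  readr::write_csv(isa, out("isa_fits.csv"), progress = FALSE)

  fates <- stage("fates", classify_isotopologues(tracer_gln_u13c15n2()))
  readr::write_csv(fates, out("fate_assignments.csv"), progress = FALSE)

  screen <- stage("screen", {
    tbl <- simulate_feature_table(
      n_features = cfg$n_features, n_per_group = cfg$n_replicates,
      n_changed = cfg$n_changed, log2_effect = cfg$log2_effect,
      cv = cfg$feature_cv, seed = cfg$seed + 1000L)
    volcano_screen(presence_filter(tbl),
                   screen_config(cfg$fc_threshold, cfg$fdr_threshold))
  })
  readr::write_csv(tibble::as_tibble(screen), out("screen_result.csv"),
                   progress = FALSE)

  summary <- list(
    apportionment = as.list(apportionment),
    utilization = as.list(utilization),
    proline_fold_change = if (!is.null(pool_fold)) pool_fold$fold_change,
    isa_pct_difference = attr(isa, "pct_difference"),
    n_significant_features = attr(screen, "n_significant"))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(
    paste0("glntrace ", as.character(utils::packageVersion("glntrace"))),
    paste0("R ", R.version.string),
    paste0("run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed ", cfg$seed),
    paste0("conditions ", paste(cfg$conditions, collapse = ", ")),
    paste0("replicates ", cfg$n_replicates),
    paste0("mid_cv ", cfg$mid_cv, "; conc_cv ", cfg$conc_cv),
    paste0("screen FC>", cfg$fc_threshold, ", FDR<", cfg$fdr_threshold)),
    out("run_log.txt"))

  invisible(list(sims = sims, rates = rates, apportionment = apportionment,
                 utilization = utilization, biomass = biomass,
                 pools = pools, pool_fold = pool_fold, isa = isa,
                 fates = fates, screen = screen, config = cfg))
}
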