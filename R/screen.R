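#' Presence filter for untargeted feature tables
#'
#' Keeps features observed in every sample of at least one complete group —
#' the only missing-value handling the screen applies (no imputation).
#'
#' @param table Long feature tibble: `feature_id`, `sample`, `group`,
#'   `intensity` (NA = missing).
#' @return Filtered tibble; an empty result triggers a warning, not an error.
#' @export
presence_filter <- function(table) {
  need <- c("feature_id", "sample", "group", "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  keep <- table |>
    dplyr::summarise(complete = !any(is.na(.data$intensity)),
                     .by = c("feature_id", "group")) |>
    dplyr::summarise(keep = any(.data$complete), .by = "feature_id") |>
    dplyr::filter(.data$keep)
  out <- dplyr::semi_join(table, keep, by = "feature_id")
  if (nrow(out) == 0) warning("presence filter removed every feature",
                              call. = FALSE)
  out
}

#' Screen configuration
#'
#' @param fc_threshold Fold-change cutoff (two-sided: FC > t or < 1/t);
#'   default 2.
#' @param fdr_threshold Adjusted-p cutoff; default 0.005.
#' @param log_transform Test log2 intensities (default TRUE).
#' @param p_adjust_method Multiple-testing method for [stats::p.adjust()]
#'   (default Benjamini-Hochberg).
#' @return A `screen_config` list.
#' @export
screen_config <- function(fc_threshold = 2, fdr_threshold = 0.005,
                          log_transform = TRUE, p_adjust_method = "BH") {
  stopifnot(fc_threshold > 0, fdr_threshold > 0)
  structure(list(fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 log_transform = log_transform,
                 p_adjust_method = p_adjust_method),
            class = "screen_config")
}

#' Volcano screen of an untargeted feature table
#'
#' Per feature: Welch's two-sided t-test (on log2 intensities by default),
#' Benjamini-Hochberg adjustment across features, and a joint significance
#' flag: |log2 FC| above the threshold AND adjusted p below the FDR cutoff.
#' Fold change is the ratio of raw group means (second group level over
#' first is the reference; reported as group2/group1... the first group
#' level, sorted, is the denominator).
#'
#' @param table Long feature tibble (`feature_id`, `sample`, `group`,
#'   `intensity`) with exactly two groups, >= 2 samples each; apply
#'   [presence_filter()] first if the table has missing values.
#' @param config A [screen_config()].
#' @return A `screen_result`: tibble with per-feature `mean_<group>`,
#'   `log2_fc`, `statistic`, `p_value`, `adj_p`, `significant`; the
#'   significant count and config ride along as attributes (see
#'   [glance.screen_result()]).
#' @export
volcano_screen <- function(table, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  groups <- sort(unique(table$group))
  if (length(groups) != 2) stop("volcano screen needs exactly 2 groups, got ",
                                length(groups), call. = FALSE)
  counts <- table |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::count(.data$feature_id, .data$group)
  if (any(counts$n < 2)) {
    stop("every feature needs >= 2 non-missing samples per group ",
         "(apply presence_filter() and drop incomplete features first)",
         call. = FALSE)
  }
  res <- table |>
    dplyr::filter(!is.na(.data$intensity)) |>
    tidyr::nest(data = -"feature_id") |>
    dplyr::mutate(stats = purrr::map(.data$data, function(d) {
      x <- d$intensity[d$group == groups[2]]
      y <- d$intensity[d$group == groups[1]]
      tx <- if (config$log_transform) log2(x) else x
      ty <- if (config$log_transform) log2(y) else y
      tt <- tryCatch(stats::t.test(tx, ty),
                     error = function(e) list(statistic = NA_real_,
                                              p.value = 1))
      tibble::tibble(mean_a = mean(y), mean_b = mean(x),
                     log2_fc = log2(mean(x) / mean(y)),
                     statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest("stats")
  names(res)[names(res) == "mean_a"] <- paste0("mean_", groups[1])
  names(res)[names(res) == "mean_b"] <- paste0("mean_", groups[2])
  res$adj_p <- stats::p.adjust(res$p_value, method = config$p_adjust_method)
  res$significant <- abs(res$log2_fc) > log2(config$fc_threshold) &
    res$adj_p < config$fdr_threshold
  attr(res, "config") <- config
  attr(res, "groups") <- groups
  attr(res, "n_significant") <- sum(res$significant)
  class(res) <- c("screen_result", class(res))
  res
}

#' Summary of a volcano screen
#'
#' @param x A `screen_result` from [volcano_screen()].
#' @param ... Unused.
#' @return One-row tibble: feature counts, thresholds, significant count.
#' @export
glance.screen_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(n_features = nrow(x),
                 n_significant = attr(x, "n_significant"),
                 fc_threshold = cfg$fc_threshold,
                 fdr_threshold = cfg$fdr_threshold,
                 method = cfg$p_adjust_method)
}

#' Volcano plot of a screen result
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 adjusted p, significant
#'   features highlighted, thresholds drawn.
#' @export
autoplot.screen_result <- function(object, ...) {
  cfg <- attr(object, "config")
  groups <- attr(object, "groups")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$log2_fc, y = -log10(.data$adj_p), colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(cfg$fc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(cfg$fdr_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = paste0("log2 fold change (", groups[2], " / ",
                             groups[1], ")"),
                  y = "-log10 adjusted p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Monte-Carlo sample-size estimation for a Welch test
#'
#' For each candidate group size n, simulates `reps` two-group normal
#' datasets at the given means and SDs, estimates the power of the two-sided
#' Welch test at level `alpha`, and returns the smallest n reaching the
#' target power.
#'
#' @param group_means Length-2 vector of group means.
#' @param group_sds Length-2 vector of group SDs (> 0).
#' @param alpha Significance level (default 0.05).
#' @param target_power Required power (default 0.8).
#' @param reps Simulated datasets per candidate n (default 2000).
#' @param seed Integer seed.
#' @param n_max Largest group size tried before declaring the power
#'   unreachable (default 100).
#' @return One-row tibble: `n_per_group`, `power`, `alpha`, `target_power`.
#' @export
power_sample_size <- function(group_means, group_sds, alpha = 0.05,
                              target_power = 0.8, reps = 2000, seed = 1,
                              n_max = 100) {
  stopifnot(length(group_means) == 2, length(group_sds) == 2,
            all(group_sds > 0), alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  with_seed(seed, {
    for (n in 2:n_max) {
      x <- matrix(stats::rnorm(n * reps, group_means[1], group_sds[1]), n)
      y <- matrix(stats::rnorm(n * reps, group_means[2], group_sds[2]), n)
      mx <- colMeans(x); my <- colMeans(y)
      vx <- apply(x, 2, stats::var); vy <- apply(y, 2, stats::var)
      se2 <- vx / n + vy / n
      tstat <- (mx - my) / sqrt(se2)
      df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / n)^2 / (n - 1))
      pow <- mean(2 * stats::pt(-abs(tstat), df) < alpha)
      if (pow >= target_power) {
        return(tibble::tibble(n_per_group = n, power = pow, alpha = alpha,
                              target_power = target_power))
      }
    }
    stop("target power not reached by n = ", n_max,
         " per group (effect too small?)", call. = FALSE)
  })
}
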