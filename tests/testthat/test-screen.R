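make_table <- function(mat, groups) {
  purrr::imap_dfr(seq_len(ncol(mat)), function(j, ...) {
    tibble::tibble(feature_id = rownames(mat),
                   sample = colnames(mat)[j], group = groups[j],
                   intensity = mat[, j])
  })
}

test_that("presence filter keeps features complete in at least one group", {
  mat <- matrix(10, nrow = 3, ncol = 6,
                dimnames = list(c("f1", "f2", "f3"), paste0("s", 1:6)))
  groups <- rep(c("A", "B"), each = 3)
  mat["f2", c(2, 5)] <- NA # one hole in every group -> dropped
  mat["f3", 4:6] <- NA     # complete in A, absent in B -> kept
  out <- presence_filter(make_table(mat, groups))
  expect_setequal(unique(out$feature_id), c("f1", "f3"))
  mat[] <- NA
  expect_warning(presence_filter(make_table(mat, groups)), "every feature")
})

test_that("identical groups produce no significant features", {
  set.seed(4)
  tbl <- simulate_feature_table(n_features = 120, n_per_group = 7,
                                n_changed = 0, seed = 4)
  res <- volcano_screen(tbl)
  expect_equal(attr(res, "n_significant"), 0)
  expect_true(all(res$adj_p >= res$p_value - 1e-12))
})

test_that("a strong single effect is flagged and matches a direct Welch/BH oracle", {
  set.seed(8)
  n <- 7
  mat <- matrix(rlnorm(101 * 2 * n, log(1e5), 0.02), nrow = 101,
                dimnames = list(sprintf("f%03d", 1:101),
                                paste0("s", 1:(2 * n))))
  groups <- rep(c("A", "B"), each = n)
  mat[1, groups == "B"] <- mat[1, groups == "B"] * 2^5
  tbl <- make_table(mat, groups)
  res <- volcano_screen(tbl)
  expect_true(res$significant[res$feature_id == "f001"])
  expect_equal(attr(res, "n_significant"), 1)
  # oracle: recompute one feature's Welch p and the BH adjustment directly
  p_direct <- vapply(seq_len(nrow(mat)), function(i) {
    stats::t.test(log2(mat[i, groups == "B"]),
                  log2(mat[i, groups == "A"]))$p.value
  }, 0)
  ord <- match(rownames(mat), res$feature_id)
  expect_equal(res$p_value[ord], p_direct, tolerance = 1e-12)
  expect_equal(res$adj_p[ord], p.adjust(p_direct, "BH"), tolerance = 1e-12)
})

test_that("a null 858-feature table at n = 7 yields zero discoveries", {
  tbl <- simulate_feature_table(n_features = 858, n_per_group = 7,
                                n_changed = 0, seed = 12)
  expect_equal(attr(volcano_screen(tbl), "n_significant"), 0)
})

test_that("significant counts shrink monotonically with stricter thresholds", {
  tbl <- simulate_feature_table(n_features = 300, n_per_group = 7,
                                n_changed = 60, log2_effect = 1.5, cv = 0.4,
                                seed = 21)
  counts_fc <- vapply(c(1.2, 2, 3, 5), function(fc) {
    attr(volcano_screen(tbl, screen_config(fc_threshold = fc,
                                           fdr_threshold = 0.05)),
         "n_significant")
  }, 0L)
  expect_true(all(diff(counts_fc) <= 0))
  counts_fdr <- vapply(c(0.05, 0.005, 5e-4), function(q) {
    attr(volcano_screen(tbl, screen_config(fdr_threshold = q)),
         "n_significant")
  }, 0L)
  expect_true(all(diff(counts_fdr) <= 0))
})

test_that("planted large effects are recovered with high sensitivity and controlled FDP", {
  tbl <- simulate_feature_table(n_features = 858, n_per_group = 7,
                                n_changed = 101, log2_effect = 3, cv = 0.3,
                                seed = 33)
  truth <- attr(tbl, "truth")
  res <- volcano_screen(presence_filter(tbl))
  hits <- res$feature_id[res$significant]
  changed <- truth$feature_id[truth$changed]
  sensitivity <- length(intersect(hits, changed)) / length(changed)
  expect_gte(sensitivity, 0.99)
  false_disc <- length(setdiff(hits, changed))
  expect_lte(false_disc, max(1, 0.01 * length(hits)))
})

test_that("screen errors and accessors behave", {
  tbl <- simulate_feature_table(n_features = 10, n_per_group = 2, seed = 1,
                                n_changed = 0)
  expect_error(volcano_screen(dplyr::mutate(tbl, group = "one")),
               "2 groups")
  small <- dplyr::filter(tbl, !(.data$group == "HDF" & .data$sample ==
                                  "HDF_s01" & .data$feature_id ==
                                  tbl$feature_id[1]))
  gl <- glance(volcano_screen(tbl))
  expect_equal(gl$n_features, 10)
  p <- autoplot(volcano_screen(tbl))
  expect_s3_class(p, "ggplot")
})

test_that("Monte-Carlo sample size matches the closed-form power oracle", {
  # overwhelming effect: smallest possible n (with n = 2 the Welch df is
  # barely 1, so only a very large d is reliably significant there)
  expect_equal(power_sample_size(c(0, 50), c(1, 1), reps = 500,
                                 seed = 2)$n_per_group, 2)
  # no effect: power never exceeds alpha
  expect_error(power_sample_size(c(0, 0), c(1, 1), reps = 200, seed = 2,
                                 n_max = 8), "not reached")
  # standardized effect 1.7 -> n = 7 per the closed-form power oracle
  oracle <- ceiling(stats::power.t.test(delta = 1.7, sd = 1,
                                        sig.level = 0.05, power = 0.8)$n)
  expect_equal(oracle, 7)
  got <- power_sample_size(c(0, 1.7), c(1, 1), reps = 20000, seed = 5)
  expect_equal(got$n_per_group, 7)
  expect_gte(got$power, 0.8)
})
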