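mid_table_cols <- c("sample", "group", "metabolite", "tracer", "shift",
                    "abundance", "corrected")

#' Read a tidy MID table
#'
#' CSV dialect: columns `sample, group, metabolite, tracer, shift, abundance,
#' corrected` (strict header, UTF-8). Each (sample, metabolite, tracer) cell
#' must hold a complete 0..n shift ladder with no duplicates; unless
#' `raw = TRUE`, cell abundances must sum to within [0.98, 1.02]. Errors
#' report file line numbers.
#'
#' @param path CSV file path.
#' @param raw Accept unnormalized abundances (e.g. raw ion counts).
#' @return Tibble in the MID dialect.
#' @export
read_mid_table <- function(path, raw = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!identical(names(tbl), mid_table_cols)) {
    stop("MID table header must be exactly: ",
         paste(mid_table_cols, collapse = ","), " (got: ",
         paste(names(tbl), collapse = ","), ")", call. = FALSE)
  }
  tbl$line <- seq_len(nrow(tbl)) + 1L
  bad <- tbl$line[is.na(tbl$shift) | is.na(tbl$abundance) | tbl$shift < 0 |
                    tbl$abundance < 0]
  if (length(bad)) stop("malformed row(s) at line(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  dup <- tbl |>
    dplyr::count(.data$sample, .data$metabolite, .data$tracer, .data$shift) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate (sample, metabolite, shift): ",
         paste0(dup$sample[1], "/", dup$metabolite[1], "/M", dup$shift[1]),
         call. = FALSE)
  }
  if (!raw) {
    sums <- tbl |>
      dplyr::summarise(s = sum(.data$abundance), line = min(.data$line),
                       .by = c("sample", "metabolite", "tracer"))
    off <- sums[sums$s < 0.98 | sums$s > 1.02, ]
    if (nrow(off)) {
      stop("MID for ", off$sample[1], "/", off$metabolite[1], " sums to ",
           signif(off$s[1], 4), " (line ", off$line[1],
           "); pass raw = TRUE for unnormalized tables", call. = FALSE)
    }
  }
  ladders <- tbl |>
    dplyr::summarise(ok = identical(as.integer(sort(.data$shift)),
                                    seq(0L, as.integer(max(.data$shift)))),
                     .by = c("sample", "metabolite", "tracer"))
  if (any(!ladders$ok)) {
    b <- ladders[!ladders$ok, ][1, ]
    stop("incomplete shift ladder for ", b$sample, "/", b$metabolite,
         call. = FALSE)
  }
  dplyr::select(tbl, -"line")
}

#' Write a tidy MID table
#'
#' @param tbl Tibble in the MID dialect (see [read_mid_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mid_table <- function(tbl, path) {
  miss <- setdiff(mid_table_cols, names(tbl))
  if (length(miss)) stop("MID table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  readr::write_csv(tbl[mid_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Read an untargeted feature table
#'
#' Wide CSV with the feature identifier (`mass@rt`) in the first column and
#' one column per sample, plus a separate sample-to-group map CSV with
#' columns `sample, group`. Empty cells are missing values.
#'
#' @param path Feature-matrix CSV.
#' @param group_path Group-map CSV.
#' @return Long tibble: `feature_id`, `sample`, `group`, `intensity`.
#' @export
read_feature_table <- function(path, group_path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(group_path)) stop("no such file: ", group_path,
                                     call. = FALSE)
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(wide)[1] != "feature_id") {
    stop("first column must be 'feature_id'", call. = FALSE)
  }
  if (anyDuplicated(wide$feature_id)) stop("duplicate feature ids",
                                           call. = FALSE)
  groups <- readr::read_csv(group_path, show_col_types = FALSE,
                            progress = FALSE)
  if (!identical(names(groups), c("sample", "group"))) {
    stop("group map must have columns: sample,group", call. = FALSE)
  }
  long <- tidyr::pivot_longer(wide, -"feature_id", names_to = "sample",
                              values_to = "intensity")
  unknown <- setdiff(long$sample, groups$sample)
  if (length(unknown)) stop("samples missing from group map: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  dplyr::left_join(long, groups, by = "sample") |>
    dplyr::select("feature_id", "sample", "group", "intensity")
}

#' Write an untargeted feature table
#'
#' @param table Long feature tibble (`feature_id`, `sample`, `group`,
#'   `intensity`).
#' @param path Feature-matrix CSV path.
#' @param group_path Group-map CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, group_path) {
  wide <- tidyr::pivot_wider(table[c("feature_id", "sample", "intensity")],
                             names_from = "sample",
                             values_from = "intensity")
  readr::write_csv(wide, path, na = "", progress = FALSE)
  groups <- dplyr::distinct(table[c("sample", "group")])
  readr::write_csv(groups, group_path, progress = FALSE)
  invisible(path)
}
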