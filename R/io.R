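#' Read / write spot-centre measurement tables
#'
#' The interchange format is CSV with columns `measurement_id`,
#' `subset_id`, `fluorophore` (integer 1..J), `x_nm`, `y_nm`, `z_nm`
#' (z along the optical axis). `write_spot_data()` optionally writes the
#' simulation ground truth (state affiliations and noise-free positions)
#' to a separate sidecar file so it can never leak into inference input.
#'
#' @param file path to a CSV file.
#' @param data a `polygon_data` data frame.
#' @param truth_file optional sidecar path for the ground-truth table.
#' @return `read_spot_data()` returns a `polygon_data` data frame.
#' @export
read_spot_data <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("measurement_id", "fluorophore", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(d)))
    stop("spot table must have columns ", paste(need, collapse = ", "))
  if (!"subset_id" %in% names(d)) d$subset_id <- "all"
  class(d) <- c("polygon_data", "data.frame")
  d
}

#' @rdname read_spot_data
#' @export
write_spot_data <- function(data, file, truth_file = NULL) {
  utils::write.csv(as.data.frame(data)[, c("measurement_id", "subset_id",
                                           "fluorophore", "x_nm", "y_nm", "z_nm")],
                   file, row.names = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth_file)) {
    if (is.null(truth)) stop("data carries no ground truth to write")
    utils::write.csv(truth, truth_file, row.names = FALSE)
  }
  invisible(file)
}

#' Write / read a posterior trace directory
#'
#' Lossless round trip of a fit's posterior samples plus run metadata:
#' `samples.csv` holds the draw table, `meta.json` the configuration,
#' seed, package version, acceptance rates and the number of sample rows
#' (used to detect truncated files on read).
#'
#' @param fit a `polygon_fit`, `polygon_mixfit` or `pairwise_fit`.
#' @param dir directory to create/write.
#' @return `read_trace()` returns a list with `draws` and `meta`.
#' @export
write_trace <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$draws, file.path(dir, "samples.csv"), row.names = FALSE)
  meta <- list(format_version = 1L,
               package_version = as.character(utils::packageVersion("polycorr")),
               class = class(fit)[1],
               config = fit$config,
               acceptance = fit$acceptance,
               n_rows = nrow(fit$draws),
               columns = colnames(fit$draws))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trace
#' @export
read_trace <- function(dir) {
  mf <- file.path(dir, "meta.json")
  sf <- file.path(dir, "samples.csv")
  if (!file.exists(mf) || !file.exists(sf)) stop("not a trace directory: ", dir)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != 1L)
    stop("unsupported trace format version")
  draws <- utils::read.csv(sf)
  if (nrow(draws) != meta$n_rows)
    stop("trace is truncated: expected ", meta$n_rows, " rows, found ", nrow(draws))
  if (!identical(colnames(draws), meta$columns))
    stop("trace column schema mismatch")
  list(draws = draws, meta = meta)
}
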