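#' Per-mille normalization of lipid signal intensities
#'
#' Expresses each signal relative to the total lipid signal of its sample
#' and channel, per mille: `1000 * intensity / total`. Channels are
#' normalized independently (positive-, negative- and CID-channel signals
#' are never mixed in one total). Missing cells stay missing; zero cells
#' stay zero. Each sample row then sums to 1000 over its non-missing
#' cells.
#'
#' @param data Long intensity table: `sample_id`, `channel`, `variable`,
#'   `intensity`.
#' @return The same table with `intensity` replaced by `per_mille`.
#' @export
#' @examples
#' normalize_per_mille(tibble::tibble(
#'   sample_id = "s1", channel = "positive",
#'   variable = c("a", "b", "c"), intensity = c(2, 3, 5)
#' ))
normalize_per_mille <- function(data) {
  stopifnot(all(c("sample_id", "channel", "variable", "intensity") %in%
                  names(data)))
  out <- data |>
    dplyr::group_by(.data$sample_id, .data$channel) |>
    dplyr::mutate(.total = sum(.data$intensity, na.rm = TRUE)) |>
    dplyr::ungroup()
  bad <- unique(out$sample_id[out$.total <= 0])
  if (length(bad) > 0) {
    abort(paste0("zero total signal for sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  out |>
    dplyr::mutate(per_mille = 1000 * .data$intensity / .data$.total) |>
    dplyr::select("sample_id", "channel", "variable", "per_mille")
}

#' PCA screen for analytical outlier samples
#'
#' Autoscales variables (zero mean, unit variance; zero-variance variables
#' are dropped, missing cells are treated as zero signal for the screen
#' only), computes the first two principal components per channel, and
#' flags samples whose score on PC1 or PC2 lies more than `sd_limit`
#' standard deviations from that component's centre. Flagged samples are
#' meant to be excluded before any differential testing.
#'
#' @param normalized Long per-mille table from [normalize_per_mille()]
#'   (study samples only).
#' @param sd_limit Score threshold in standard deviations (default 3).
#' @return A tibble with one row per sample and channel: `sample_id`,
#'   `channel`, `pc1`, `pc2`, `outlier`. A degenerate channel (fewer than
#'   two variables with variance, or fewer than three samples) yields no
#'   outliers, with a warning.
#' @seealso [pca_outliers()] for just the flagged sample ids.
#' @export
pca_outlier_screen <- function(normalized, sd_limit = 3) {
  purrr::map(split(normalized, normalized$channel), function(d) {
    ch <- d$channel[1]
    wide <- tidyr::pivot_wider(d, id_cols = "sample_id",
                               names_from = "variable",
                               values_from = "per_mille")
    x <- as.matrix(wide[, -1, drop = FALSE])
    x[is.na(x)] <- 0
    keep <- apply(x, 2, sd) > 0
    if (nrow(x) < 3 || sum(keep) < 2) {
      warn(paste0("channel ", ch,
                  ": degenerate matrix, PCA outlier screen skipped"))
      return(tibble::tibble(sample_id = wide$sample_id, channel = ch,
                            pc1 = 0, pc2 = 0, outlier = FALSE))
    }
    sc <- prcomp(scale(x[, keep, drop = FALSE]), center = FALSE,
                 scale. = FALSE)$x
    pc1 <- sc[, 1]
    pc2 <- if (ncol(sc) >= 2) sc[, 2] else rep(0, nrow(sc))
    out <- (abs(pc1 - mean(pc1)) > sd_limit * sd(pc1)) |
      (sd(pc2) > 0 & abs(pc2 - mean(pc2)) > sd_limit * sd(pc2))
    tibble::tibble(sample_id = wide$sample_id, channel = ch,
                   pc1 = pc1, pc2 = pc2, outlier = out)
  }) |>
    dplyr::bind_rows()
}

#' @rdname pca_outlier_screen
#' @return `pca_outliers()` returns the unique ids of samples flagged in
#'   any channel (possibly empty).
#' @export
pca_outliers <- function(normalized, sd_limit = 3) {
  scores <- pca_outlier_screen(normalized, sd_limit = sd_limit)
  unique(scores$sample_id[scores$outlier])
}
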