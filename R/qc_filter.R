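#' Signal-to-noise ratio against blank wells
#'
#' Ratio of the mean non-missing study-sample intensity to the mean blank
#' intensity. Missing blank values count as zero signal (an empty blank
#' well contributes no noise). A blank mean of zero, or no blanks at all,
#' yields `+Inf` so the variable passes the S/N rule.
#'
#' @param study Numeric vector of the variable's intensities in study
#'   samples (may contain `NA`).
#' @param blank Numeric vector of its intensities in blank wells (may be
#'   empty or contain `NA`).
#' @return A single non-negative ratio, possibly `Inf`; `NA` if no study
#'   value is available (the variable is then handled by the presence
#'   rule).
#' @export
#' @examples
#' snr(c(25, 30, 35), c(10, 10))   # 3: retained (only "< 3" is excluded)
snr <- function(study, blank) {
  if (all(is.na(study))) return(NA_real_)
  blank[is.na(blank)] <- 0
  bm <- if (length(blank) == 0) 0 else mean(blank)
  if (bm == 0) return(Inf)
  mean(study, na.rm = TRUE) / bm
}

#' Fraction of study samples in which a variable is present
#'
#' A variable counts as present in a sample when its value is non-missing
#' and non-zero.
#'
#' @param study Numeric vector over all study samples (missing = `NA`).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' presence_fraction(c(0, 5, 7, 0))  # 0.5: retained at the boundary
presence_fraction <- function(study) {
  stopifnot(length(study) >= 1)
  mean(!is.na(study) & study != 0)
}

#' QC dilution-series linearity
#'
#' Pearson correlation of a variable's intensity in the QC dilution
#' series against the dilution factor, used to verify that signal is
#' proportional to analyte amount. Missing QC values count as zero
#' intensity (absence in a diluted QC is informative). Zero variance in
#' the intensities leaves r undefined (`NA`), which fails the filter.
#'
#' @param qc_intensity Numeric vector of QC intensities.
#' @param dilution Matching numeric vector of dilution factors (e.g.
#'   0.25, 0.5, 1.0).
#' @return Pearson r in `[-1, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' qc_linearity_r(c(10, 20, 40), c(0.25, 0.5, 1))  # 1
qc_linearity_r <- function(qc_intensity, dilution) {
  stopifnot(length(qc_intensity) == length(dilution))
  if (length(dilution) < 3 || length(unique(dilution)) < 2) {
    abort("QC design insufficient: need >= 3 QC measurements spanning >= 2 dilution factors")
  }
  qc_intensity[is.na(qc_intensity)] <- 0
  if (sd(qc_intensity) == 0) return(NA_real_)
  cor(qc_intensity, dilution)
}

#' Apply the four signal-quality filters to an intensity table
#'
#' Applies, in fixed order, the per-cell zero rule (zero intensities are
#' treated as missing), the signal-to-noise rule (removed if S/N < `snr_min`),
#' the presence rule (removed if present in fewer than `presence_min` of
#' study samples) and the QC dilution-series linearity rule (removed
#' unless Pearson r > `r_min`). Boundary semantics are strict: S/N exactly
#' 3, presence exactly 0.5 are retained; r exactly 0.75 is removed.
#' The ppm match tolerance is enforced upstream by [annotate()].
#'
#' Variables are filtered per channel; presence is computed over all study
#' samples listed in `metadata` (QCs and blanks excluded from the
#' denominator). Retained cell values are passed through unaltered (zeros
#' included); only column membership changes, so filtering is idempotent.
#'
#' @param data Long intensity table: `sample_id`, `channel`, `variable`,
#'   `intensity`. Absent rows are missing values.
#' @param metadata Sample metadata with columns `sample_id`, `role`
#'   (`"study"`, `"qc"`, `"blank"`) and `dilution` (QC rows only).
#' @param snr_min,presence_min,r_min Filter thresholds (defaults 3, 0.5,
#'   0.75).
#' @param linearity Apply the QC linearity rule? Requires QC rows when
#'   `TRUE` (default).
#' @return An object of class `filter_result`: a list with `data` (the
#'   filtered long table, kept variables only) and `report` (one row per
#'   variable: `variable`, `channel`, `kept`, `first_failing_rule`, `snr`,
#'   `presence_fraction`, `qc_r`). Use [generics::tidy()] for the report
#'   and [generics::glance()] for a one-row summary.
#' @export
apply_filters <- function(data, metadata, snr_min = 3, presence_min = 0.5,
                          r_min = 0.75, linearity = TRUE) {
  stopifnot(all(c("sample_id", "channel", "variable", "intensity") %in%
                  names(data)),
            all(c("sample_id", "role") %in% names(metadata)))
  study_ids <- metadata$sample_id[metadata$role == "study"]
  blank_ids <- metadata$sample_id[metadata$role == "blank"]
  qc_ids <- metadata$sample_id[metadata$role == "qc"]
  if (length(study_ids) == 0) abort("no study samples in metadata")
  if (linearity) {
    qc_meta <- metadata[metadata$role == "qc", , drop = FALSE]
    if (nrow(qc_meta) < 3 || length(unique(qc_meta$dilution)) < 2) {
      abort("QC design insufficient: need >= 3 QC samples spanning >= 2 dilution factors")
    }
    dil <- setNames(qc_meta$dilution, qc_meta$sample_id)
  }

  report <- data |>
    dplyr::distinct(.data$channel, .data$variable) |>
    dplyr::arrange(.data$channel, .data$variable)
  cell_groups <- split(data[, c("sample_id", "intensity")],
                       paste(data$channel, data$variable))
  stats_per_var <- purrr::pmap(report, function(channel, variable) {
    cells <- cell_groups[[paste(channel, variable)]]
    v <- setNames(cells$intensity, cells$sample_id)
    v[!is.na(v) & v == 0] <- NA  # zero rule: zeros become missing
    study <- unname(v[match(study_ids, names(v))])
    blank <- unname(v[match(blank_ids, names(v))])
    blank[is.na(blank)] <- 0
    s <- snr(study, blank)
    p <- presence_fraction(study)
    r <- if (linearity) {
      qc <- unname(v[match(qc_ids, names(v))])
      qc[is.na(qc)] <- 0
      qc_linearity_r(qc, unname(dil[qc_ids]))
    } else NA_real_
    rule <- if (!is.na(s) && s < snr_min) "snr"
      else if (p < presence_min) "presence"
      else if (linearity && (is.na(r) || r <= r_min)) "linearity"
      else NA_character_
    list(snr = s, presence_fraction = p, qc_r = r, first_failing_rule = rule)
  })
  report$snr <- purrr::map_dbl(stats_per_var, "snr")
  report$presence_fraction <- purrr::map_dbl(stats_per_var, "presence_fraction")
  report$qc_r <- purrr::map_dbl(stats_per_var, "qc_r")
  report$first_failing_rule <- purrr::map_chr(stats_per_var,
                                              "first_failing_rule")
  report$kept <- is.na(report$first_failing_rule)
  report <- dplyr::select(report, "variable", "channel", "kept",
                          "first_failing_rule", "snr", "presence_fraction",
                          "qc_r")

  kept_keys <- paste(report$channel[report$kept], report$variable[report$kept])
  filtered <- data[paste(data$channel, data$variable) %in% kept_keys, ,
                   drop = FALSE]
  structure(list(data = tibble::as_tibble(filtered), report = report),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> ", sum(x$report$kept), "of", nrow(x$report),
      "variables kept\n")
  removed <- x$report$first_failing_rule
  if (any(!x$report$kept)) {
    cat("removed by rule:\n")
    print(table(removed[!x$report$kept]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname apply_filters
#' @param x A `filter_result`.
#' @param ... Unused.
#' @export
tidy.filter_result <- function(x, ...) x$report

#' @rdname apply_filters
#' @export
glance.filter_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_variables = nrow(r),
    n_kept = sum(r$kept),
    n_removed_snr = sum(r$first_failing_rule == "snr", na.rm = TRUE),
    n_removed_presence = sum(r$first_failing_rule == "presence", na.rm = TRUE),
    n_removed_linearity = sum(r$first_failing_rule == "linearity", na.rm = TRUE)
  )
}
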