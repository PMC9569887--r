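#' Split participants into motility groups at the cohort median
#'
#' Adds a `motility_group` column: `"low"` for participants strictly below
#' the cohort median progressive motility, `"high"` at or above it. The
#' median is computed over the distinct participants present in `design`,
#' so it should be called (or re-called) after PCA exclusions.
#'
#' @param design Cohort design table with columns `participant_id` and
#'   `motility_pct` (one motility value per participant; the table may
#'   have one row per sample).
#' @return `design` with `motility_group` added.
#' @export
#' @examples
#' split_by_median_motility(tibble::tibble(
#'   participant_id = paste0("P", 1:5),
#'   motility_pct = c(24, 40, 50, 58, 68)
#' ))
split_by_median_motility <- function(design) {
  stopifnot(all(c("participant_id", "motility_pct") %in% names(design)))
  per_part <- dplyr::distinct(design, .data$participant_id,
                              .data$motility_pct)
  if (anyNA(per_part$motility_pct)) {
    abort("motility must be known for every participant")
  }
  if (anyDuplicated(per_part$participant_id)) {
    abort("conflicting motility values within a participant")
  }
  med <- median(per_part$motility_pct)
  dplyr::mutate(
    tibble::as_tibble(design),
    motility_group = ifelse(.data$motility_pct < med, "low", "high")
  )
}

# t statistic and p value with explicit handling of constant data,
# which stats::t.test() refuses ("data are essentially constant")
.safe_paired_t <- function(a, b) {
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) return(c(t = 0, p = 1))
    return(c(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- t.test(a, b, paired = TRUE)
  c(t = unname(tt$statistic), p = tt$p.value)
}

.safe_unpaired_t <- function(a, b, var_equal = FALSE) {
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  c(t = unname(tt$statistic), p = tt$p.value)
}

# align per-mille values of two sample sets into participant-matched
# matrices (participants x variables) for one channel
.compartment_matrix <- function(d, design, compartment) {
  ids <- design[design$compartment == compartment, , drop = FALSE]
  wide <- tidyr::pivot_wider(d, id_cols = "sample_id",
                             names_from = "variable",
                             values_from = "per_mille")
  wide <- wide[match(ids$sample_id, wide$sample_id), , drop = FALSE]
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- ids$participant_id
  m
}

#' Paired differential tests between two compartments
#'
#' For every variable, runs a two-sided paired t-test of per-mille
#' abundance between two compartments across participants measured in
#' both. Pairs with a missing value are dropped variable-wise. The log2
#' fold change is the ratio of arithmetic means over complete pairs,
#' `log2(mean(A) / mean(B))` with `A = compartments[1]`. Variables with
#' fewer than two complete pairs are recorded as untestable (`NA`
#' statistics, `untestable_reason` set).
#'
#' @param normalized Long per-mille table (study samples only).
#' @param design Design table with columns `sample_id`, `participant_id`,
#'   `compartment`.
#' @param compartments Length-2 character vector; the first is the
#'   numerator of the fold change.
#' @param alpha Significance limit; a result is significant iff
#'   `p < alpha`, strictly (default 0.001).
#' @return A tibble with one row per variable and channel: `variable`,
#'   `channel`, `comparison`, `n`, `log2fc`, `t`, `p`, `significant`,
#'   `untestable_reason`.
#' @export
test_compartments <- function(normalized, design,
                              compartments = c("sperm", "serum"),
                              alpha = 0.001) {
  stopifnot(length(compartments) == 2,
            all(compartments %in% design$compartment))
  comparison <- paste0(compartments[1], " vs ", compartments[2], " (paired)")
  res <- purrr::map(split(normalized, normalized$channel), function(d) {
    ch <- d$channel[1]
    a_m <- .compartment_matrix(d, design, compartments[1])
    b_m <- .compartment_matrix(d, design, compartments[2])
    common <- intersect(rownames(a_m), rownames(b_m))
    vars <- union(colnames(a_m), colnames(b_m))
    rows <- purrr::map(vars, function(v) {
      a <- if (v %in% colnames(a_m)) a_m[common, v] else rep(NA_real_, length(common))
      b <- if (v %in% colnames(b_m)) b_m[common, v] else rep(NA_real_, length(common))
      ok <- !is.na(a) & !is.na(b)
      n <- sum(ok)
      if (n < 2) {
        return(list(n = n, log2fc = NA_real_, t = NA_real_, p = NA_real_,
                    reason = "fewer than 2 complete pairs"))
      }
      tp <- .safe_paired_t(a[ok], b[ok])
      list(n = n, log2fc = log2(mean(a[ok]) / mean(b[ok])),
           t = tp[["t"]], p = tp[["p"]], reason = NA_character_)
    })
    tibble::tibble(
      variable = vars, channel = ch, comparison = comparison,
      n = purrr::map_int(rows, ~ as.integer(.x$n)),
      log2fc = purrr::map_dbl(rows, "log2fc"),
      t = purrr::map_dbl(rows, "t"),
      p = purrr::map_dbl(rows, "p"),
      untestable_reason = purrr::map_chr(rows, "reason")
    )
  }) |>
    dplyr::bind_rows()
  significance_mask(res, alpha = alpha)
}

#' Unpaired differential tests between motility groups
#'
#' For every variable, runs a two-sided unpaired t-test of per-mille
#' abundance between the high- and low-motility groups within one
#' compartment. Welch's correction for unequal variances is the default
#' (`var_equal = FALSE`). The log2 fold change is
#' `log2(mean(high) / mean(low))`. A group with fewer than two non-missing
#' values makes the variable untestable.
#'
#' @inheritParams test_compartments
#' @param compartment The compartment to test within.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A tibble shaped as in [test_compartments()].
#' @export
test_motility_groups <- function(normalized, design, compartment,
                                 alpha = 0.001, var_equal = FALSE) {
  if (!"motility_group" %in% names(design)) {
    abort("design lacks motility_group; call split_by_median_motility() first")
  }
  stopifnot(compartment %in% design$compartment)
  comparison <- paste0("high vs low motility in ", compartment,
                       " (unpaired)")
  cohort <- design[design$compartment == compartment, , drop = FALSE]
  res <- purrr::map(split(normalized, normalized$channel), function(d) {
    ch <- d$channel[1]
    wide <- tidyr::pivot_wider(d, id_cols = "sample_id",
                               names_from = "variable",
                               values_from = "per_mille")
    wide <- wide[wide$sample_id %in% cohort$sample_id, , drop = FALSE]
    grp <- cohort$motility_group[match(wide$sample_id, cohort$sample_id)]
    m <- as.matrix(wide[, -1, drop = FALSE])
    rows <- purrr::map(colnames(m), function(v) {
      hi <- m[grp == "high", v]
      lo <- m[grp == "low", v]
      hi <- hi[!is.na(hi)]
      lo <- lo[!is.na(lo)]
      n <- length(hi) + length(lo)
      if (length(hi) < 2 || length(lo) < 2) {
        return(list(n = n, log2fc = NA_real_, t = NA_real_, p = NA_real_,
                    reason = "a group has fewer than 2 values"))
      }
      tp <- .safe_unpaired_t(hi, lo, var_equal = var_equal)
      list(n = n, log2fc = log2(mean(hi) / mean(lo)),
           t = tp[["t"]], p = tp[["p"]], reason = NA_character_)
    })
    tibble::tibble(
      variable = colnames(m), channel = ch, comparison = comparison,
      n = purrr::map_int(rows, ~ as.integer(.x$n)),
      log2fc = purrr::map_dbl(rows, "log2fc"),
      t = purrr::map_dbl(rows, "t"),
      p = purrr::map_dbl(rows, "p"),
      untestable_reason = purrr::map_chr(rows, "reason")
    )
  }) |>
    dplyr::bind_rows()
  significance_mask(res, alpha = alpha)
}

#' Flag significant results at a strict alpha
#'
#' Sets `significant = TRUE` iff `p < alpha`, strictly: a p value exactly
#' equal to the limit is not significant. Untestable results (`NA` p) are
#' never significant.
#'
#' @param results A differential-results tibble with a `p` column.
#' @param alpha Significance limit (default 0.001).
#' @return `results` with the `significant` column set.
#' @export
significance_mask <- function(results, alpha = 0.001) {
  dplyr::mutate(tibble::as_tibble(results),
                significant = !is.na(.data$p) & .data$p < alpha)
}

#' Volcano table of differential results
#'
#' One row per testable variable with finite fold change, carrying
#' `log2fc`, `neg_log10_p` and the significance flag. Untestable
#' variables and those with infinite fold change (a zero denominator
#' mean) are listed separately with a reason, retrievable with
#' [volcano_excluded()].
#'
#' @param results Output of [test_compartments()] or
#'   [test_motility_groups()].
#' @return A tibble of plottable points with attribute `"excluded"`.
#' @export
volcano_table <- function(results) {
  testable <- is.na(results$untestable_reason) & is.finite(results$log2fc)
  points <- results[testable, , drop = FALSE] |>
    dplyr::mutate(neg_log10_p = -log10(.data$p)) |>
    dplyr::select("variable", "channel", "comparison", "log2fc",
                  "neg_log10_p", "significant")
  excluded <- results[!testable, , drop = FALSE] |>
    dplyr::mutate(reason = dplyr::coalesce(.data$untestable_reason,
                                           "infinite fold change")) |>
    dplyr::select("variable", "channel", "comparison", "reason")
  attr(points, "excluded") <- excluded
  points
}

#' @rdname volcano_table
#' @param x A table produced by [volcano_table()].
#' @export
volcano_excluded <- function(x) {
  attr(x, "excluded") %||% tibble::tibble(
    variable = character(), channel = character(),
    comparison = character(), reason = character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
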