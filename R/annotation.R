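#' Adduct m/z from a neutral monoisotopic mass
#'
#' Computes the singly charged adduct m/z for the three adducts formed in
#' direct-infusion ESI lipidomics: protonated (`"M+H"`), ammoniated
#' (`"M+NH4"`, positive mode) and deprotonated (`"M-H"`, negative mode).
#' Electron mass is accounted for, so `(M+H)` and `(M-H)` are exactly two
#' proton masses apart.
#'
#' @param neutral_mass Numeric vector of neutral monoisotopic masses (Da).
#' @param adduct Character vector (recycled) among `"M+H"`, `"M+NH4"`,
#'   `"M-H"`.
#' @return Numeric vector of adduct m/z (Th).
#' @export
#' @examples
#' adduct_mz(760.5851, c("M+H", "M+NH4", "M-H"))
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(all(neutral_mass > 0))
  shift <- .adduct_shift[adduct]
  if (anyNA(shift)) {
    abort(paste0("unknown adduct: ",
                 paste(setdiff(unique(adduct), names(.adduct_shift)),
                       collapse = ", ")))
  }
  unname(neutral_mass + shift)
}

.proton <- unname(.element_mass["H"] - .element_mass["e"])
.adduct_shift <- c(
  "M+H" = .proton,
  "M+NH4" = unname(.element_mass["N"] + 4 * .element_mass["H"] -
                     .element_mass["e"]),
  "M-H" = -.proton
)

# which adducts can occur in which ionisation channel
.adduct_channels <- list(
  "M+H" = "positive",
  "M+NH4" = "positive",
  "M-H" = c("negative", "negative_cid")
)

#' Signed mass deviation in parts per million
#'
#' @param observed,reference Numeric vectors of m/z values; `reference`
#'   must be positive.
#' @return `1e6 * (observed - reference) / reference`.
#' @export
#' @examples
#' ppm_deviation(100.0001, 100)
ppm_deviation <- function(observed, reference) {
  stopifnot(all(reference > 0))
  1e6 * (observed - reference) / reference
}

#' Per-channel isobar priority lists
#'
#' When several library species match one peak within tolerance (isobars),
#' assignment follows a per-channel class-priority list. The defaults
#' encode the two mode-specific rules used for DIMS lipid assignment:
#' in positive mode the balance of probability falls on PC rather than
#' the isobaric PE, and in negative mode on PC rather than PS. Classes
#' not named in a list rank equally after the named ones; remaining ties
#' are broken by minimal absolute ppm error, then canonical name order.
#'
#' @param positive,negative,negative_cid Character vectors of class codes
#'   in decreasing priority.
#' @return A named list of priority vectors, one per channel.
#' @export
isobar_priorities <- function(positive = c("PC", "PE"),
                              negative = c("PC", "PS"),
                              negative_cid = character()) {
  list(positive = positive, negative = negative,
       negative_cid = negative_cid)
}

# rank of a class within a channel's priority list (unlisted -> last)
.isobar_rank <- function(class_code, channel, priorities) {
  pr <- priorities[[channel]]
  r <- match(class_code, pr)
  r[is.na(r)] <- length(pr) + 1L
  r
}

#' Resolve an isobaric candidate set to a single assignment
#'
#' Orders candidates by (1) the channel's class-priority list, (2) minimal
#' absolute ppm error, (3) canonical name then adduct, and returns the
#' first. The result carries `ambiguous = TRUE` when more than one
#' candidate was offered.
#'
#' @param candidates A data frame with columns `name`, `adduct`,
#'   `ppm_error` (one row per candidate assignment).
#' @param channel One of `"positive"`, `"negative"`, `"negative_cid"`.
#' @param priorities Priority lists as from [isobar_priorities()].
#' @return A one-row tibble: the chosen candidate plus `ambiguous`.
#' @export
#' @examples
#' resolve_isobar(
#'   tibble::tibble(name = c("PC(34:1)", "PE(37:1)"), adduct = "M+H",
#'                  ppm_error = c(1.2, 1.2)),
#'   channel = "positive"
#' )
resolve_isobar <- function(candidates, channel,
                           priorities = isobar_priorities()) {
  stopifnot(nrow(candidates) >= 1)
  cls <- sub("\\(.*$", "", candidates$name)
  ord <- order(.isobar_rank(cls, channel, priorities),
               abs(candidates$ppm_error), candidates$name, candidates$adduct)
  chosen <- tibble::as_tibble(candidates)[ord[1], , drop = FALSE]
  chosen$ambiguous <- nrow(candidates) > 1
  chosen
}

# expand a library tibble into one row per (name, channel, adduct, target m/z)
.library_targets <- function(library) {
  stopifnot(all(c("name", "neutral_mass_da", "channels", "adducts") %in%
                  names(library)))
  tgt <- library |>
    dplyr::mutate(.channels = strsplit(.data$channels, ";", fixed = TRUE),
                  .adducts = strsplit(.data$adducts, ";", fixed = TRUE)) |>
    tidyr::unnest(".channels") |>
    tidyr::unnest(".adducts") |>
    dplyr::rename(channel = ".channels", adduct = ".adducts") |>
    dplyr::filter(purrr::map2_lgl(.data$adduct, .data$channel,
                                  ~ .y %in% .adduct_channels[[.x]])) |>
    dplyr::mutate(target_mz = adduct_mz(.data$neutral_mass_da, .data$adduct),
                  class_code = sub("\\(.*$", "", .data$name)) |>
    dplyr::select("name", "class_code", "channel", "adduct", "target_mz")
  tgt
}

#' Annotate centroided peaks against a lipid library
#'
#' Matches each peak to the library entries whose adduct m/z lies within
#' `tolerance_ppm` (inclusive: a deviation of exactly the tolerance is
#' retained; only larger deviations are excluded). Peaks with several
#' candidates are resolved by [resolve_isobar()]; peaks with none are left
#' unannotated (omitted from the result). Each peak receives at most one
#' assignment; a library entry may annotate peaks in many samples.
#' Annotation is fully deterministic.
#'
#' @param peaks A data frame of centroided peaks with columns `sample_id`,
#'   `channel`, `mz`, `intensity`.
#' @param library A lipid library as from [read_lipid_library()] or
#'   [simulate_library()]: columns `name`, `neutral_mass_da`, `channels`,
#'   `adducts` (semicolon-separated).
#' @param tolerance_ppm Match tolerance in ppm (default 9).
#' @param priorities Isobar priority lists, see [isobar_priorities()].
#' @return A tibble with one row per annotated peak: `sample_id`,
#'   `channel`, `mz`, `intensity`, `name`, `adduct`, `variable`
#'   (`"name[adduct]"`), `ppm_error`, `ambiguous`.
#' @export
annotate <- function(peaks, library, tolerance_ppm = 9,
                     priorities = isobar_priorities()) {
  stopifnot(tolerance_ppm > 0)
  if (nrow(library) == 0) abort("empty lipid library")
  empty <- tibble::tibble(
    sample_id = character(), channel = character(), mz = numeric(),
    intensity = numeric(), name = character(), adduct = character(),
    variable = character(), ppm_error = numeric(), ambiguous = logical()
  )
  if (nrow(peaks) == 0) return(empty)
  stopifnot(all(peaks$mz > 0), all(peaks$intensity >= 0))

  targets <- .library_targets(library)
  out <- purrr::map(split(peaks, peaks$channel), function(pk) {
    ch <- pk$channel[1]
    tg <- targets[targets$channel == ch, , drop = FALSE]
    if (nrow(tg) == 0) return(NULL)
    tg <- tg[order(tg$target_mz), , drop = FALSE]
    # window of library targets whose ppm deviation can be within tolerance
    lo <- pk$mz / (1 + tolerance_ppm * 1e-6)
    hi <- pk$mz / (1 - tolerance_ppm * 1e-6)
    i0 <- findInterval(lo, tg$target_mz, left.open = TRUE)
    i1 <- findInterval(hi, tg$target_mz)
    n_cand <- pmax(i1 - i0, 0L)
    keep <- n_cand > 0L
    if (!any(keep)) return(NULL)
    peak_row <- rep(which(keep), n_cand[keep])
    tgt_row <- sequence(n_cand[keep], from = i0[keep] + 1L)
    cand <- tibble::tibble(
      peak_row = peak_row,
      name = tg$name[tgt_row],
      class_code = tg$class_code[tgt_row],
      adduct = tg$adduct[tgt_row],
      ppm_error = ppm_deviation(pk$mz[peak_row], tg$target_mz[tgt_row])
    )
    cand <- cand[abs(cand$ppm_error) <= tolerance_ppm, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand$rank <- .isobar_rank(cand$class_code, ch, priorities)
    cand <- cand[order(cand$peak_row, cand$rank, abs(cand$ppm_error),
                       cand$name, cand$adduct), , drop = FALSE]
    n_per_peak <- table(cand$peak_row)
    first <- !duplicated(cand$peak_row)
    chosen <- cand[first, , drop = FALSE]
    chosen$ambiguous <- as.vector(n_per_peak[as.character(chosen$peak_row)]) > 1
    tibble::tibble(
      sample_id = pk$sample_id[chosen$peak_row],
      channel = ch,
      mz = pk$mz[chosen$peak_row],
      intensity = pk$intensity[chosen$peak_row],
      name = chosen$name,
      adduct = chosen$adduct,
      variable = paste0(chosen$name, "[", chosen$adduct, "]"),
      ppm_error = chosen$ppm_error,
      ambiguous = chosen$ambiguous
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else dplyr::arrange(res, .data$sample_id,
                                                .data$channel, .data$mz)
}

#' Collapse annotations into a long intensity table
#'
#' Sums the intensities of peaks assigned to the same variable within a
#' sample and channel (rare; occurs only when two raw peaks fall inside
#' the same tolerance window), yielding the long-format intensity table
#' consumed by [apply_filters()] and [normalize_per_mille()].
#'
#' @param annotations Output of [annotate()].
#' @return A tibble with columns `sample_id`, `channel`, `variable`,
#'   `intensity`.
#' @export
annotation_intensities <- function(annotations) {
  annotations |>
    dplyr::group_by(.data$sample_id, .data$channel, .data$variable) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
}
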