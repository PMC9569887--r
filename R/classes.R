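#' Aggregate per-mille abundances by lipid class
#'
#' Sums per-mille abundances of member variables per sample and channel,
#' by lipid class. Fatty-acid variables are reported under saturation
#' categories rather than a single FA class: EFA for species in the
#' configured essential set, otherwise SFA (no double bonds), MUFA (one)
#' or PUFA (two or more). Each variable therefore maps to exactly one
#' class, so per-sample class sums never exceed 1000 per mille and equal
#' it exactly when every variable is annotated.
#'
#' Variable names must carry a parseable shorthand species (optionally
#' suffixed with `"[adduct]"`); an unparseable name is an error, never a
#' silent drop.
#'
#' @param normalized Long per-mille table from [normalize_per_mille()].
#' @param essential Essential fatty-acid set, as canonical names
#'   (default `c("FA(18:2)", "FA(18:3)")`).
#' @return A tibble with columns `sample_id`, `channel`, `class`,
#'   `per_mille`.
#' @export
#' @examples
#' aggregate_by_class(tibble::tibble(
#'   sample_id = "s1", channel = "positive",
#'   variable = c("SM(34:1)[M+H]", "SM(42:2)[M+H]", "PC(34:1)[M+H]"),
#'   per_mille = c(10, 5, 20)
#' ))
aggregate_by_class <- function(normalized,
                               essential = c("FA(18:2)", "FA(18:3)")) {
  vars <- unique(normalized$variable)
  species_name <- sub("\\[[^]]*\\]$", "", vars)
  sp <- parse_lipid_name(species_name)
  cls <- sp$class_code
  is_fa <- cls == "FA"
  if (any(is_fa)) {
    fac <- fatty_acid_category(sp[is_fa, , drop = FALSE],
                               essential = essential)
    cls[is_fa] <- ifelse(fac$essential, "EFA", fac$saturation)
  }
  lookup <- setNames(cls, vars)
  normalized |>
    dplyr::mutate(class = unname(lookup[.data$variable])) |>
    dplyr::group_by(.data$sample_id, .data$channel, .data$class) |>
    dplyr::summarise(per_mille = sum(.data$per_mille, na.rm = TRUE),
                     .groups = "drop")
}
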