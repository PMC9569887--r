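#' Lipid class taxonomy
#'
#' Returns the packaged lipid-class taxonomy: one row per class with its
#' shorthand code, long name, headgroup, elemental base composition (the
#' formula of the class scaffold before acyl/alkyl CH2 units and double
#' bonds are added), the ionisation channels it is observed in, and the
#' adducts it forms. The taxonomy covers the sum-composition classes used
#' throughout the package: CER, SM, PC, PC-O, PE, PE-O, PE-P, LPC, LPE,
#' PG, PI, PS, TG, DG, CE, CHOL and FA.
#'
#' @return A tibble with columns `class_code`, `long_name`, `headgroup`,
#'   `base_c`, `base_h`, `base_n`, `base_o`, `base_p`, `channels`
#'   (semicolon-separated) and `adducts` (semicolon-separated).
#' @export
#' @examples
#' lipid_classes()
lipid_classes <- function() {
  path <- system.file("extdata", "lipid_classes.csv", package = "lipidims")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

lipid_class_codes <- function() lipid_classes()$class_code

#' Parse lipid shorthand names
#'
#' Parses sum-composition shorthand of the form `CLASS(C:D)` (e.g.
#' `"TG(46:1)"`, `"PE-P(38:4)"`) or the bare token `"CHOL"` into its
#' components. Only sum compositions are supported: total acyl/alkyl
#' carbons and total double bonds. sn-resolved notation with slashes
#' (e.g. `"SM(d18:1/16:0)"`) is rejected; resolving individual chains is
#' out of scope for shotgun sum-composition data.
#'
#' @param name Character vector of shorthand names.
#' @return A tibble with one row per input name and columns `name`
#'   (canonical form), `class_code`, `carbons`, `double_bonds` and
#'   `ether` (`"none"`, `"O"` or `"P"`, mirroring the class suffix).
#' @seealso [format_lipid_name()] for the inverse operation.
#' @export
#' @examples
#' parse_lipid_name(c("TG(46:1)", "FA(22:6)", "PE-P(38:4)", "CHOL"))
parse_lipid_name <- function(name) {
  stopifnot(is.character(name))
  codes <- lipid_class_codes()
  # longest codes first so PC-O wins over PC, PE-P over PE
  alt <- paste(gsub("-", "\\\\-", codes[order(-nchar(codes))]), collapse = "|")
  rx <- paste0("^(", alt, ")\\((\\d+):(\\d+)\\)$")

  out <- purrr::map(name, function(s) {
    if (grepl("/", s, fixed = TRUE)) {
      abort(paste0("'", s, "': sn-resolved names (with '/') are not supported; ",
                   "use sum composition such as 'SM(34:1)'"))
    }
    if (s == "CHOL") {
      return(list(class_code = "CHOL", carbons = 0L, double_bonds = 0L))
    }
    m <- regmatches(s, regexec(rx, s))[[1]]
    if (length(m) == 0) {
      bad <- sub("[^A-Za-z-].*$", "", s)
      if (!bad %in% codes) {
        abort(paste0("'", s, "': unknown lipid class '", bad, "'"))
      }
      abort(paste0("'", s, "': malformed shorthand; expected '", bad, "(C:D)'"))
    }
    carbons <- as.integer(m[3])
    db <- as.integer(m[4])
    if (carbons > 0 && db > carbons) {
      abort(paste0("'", s, "': double bonds (", db,
                   ") exceed carbons (", carbons, ")"))
    }
    if (carbons == 0 && db > 0) {
      abort(paste0("'", s, "': double bonds without carbons"))
    }
    list(class_code = m[2], carbons = carbons, double_bonds = db)
  })

  res <- tibble::tibble(
    class_code = purrr::map_chr(out, "class_code"),
    carbons = purrr::map_int(out, "carbons"),
    double_bonds = purrr::map_int(out, "double_bonds")
  )
  res$ether <- dplyr::case_when(
    endsWith(res$class_code, "-O") ~ "O",
    endsWith(res$class_code, "-P") ~ "P",
    TRUE ~ "none"
  )
  res <- tibble::add_column(res, name = format_lipid_name(res), .before = 1)
  res
}

#' Format lipid species as shorthand names
#'
#' Inverse of [parse_lipid_name()]: renders the canonical shorthand
#' `CLASS(C:D)`, or `"CHOL"` for cholesterol.
#'
#' @param species A data frame with columns `class_code`, `carbons` and
#'   `double_bonds` (as produced by [parse_lipid_name()]).
#' @return Character vector of canonical names.
#' @export
#' @examples
#' format_lipid_name(parse_lipid_name("SM(34:1)"))
format_lipid_name <- function(species) {
  stopifnot(all(c("class_code", "carbons", "double_bonds") %in% names(species)))
  ifelse(species$class_code == "CHOL", "CHOL",
         paste0(species$class_code, "(", species$carbons, ":",
                species$double_bonds, ")"))
}

#' Categorise fatty acids by saturation, essentiality and chain length
#'
#' Assigns each FA species its saturation category (SFA: no double bonds,
#' MUFA: exactly one, PUFA: two or more), whether it belongs to the
#' configured essential set, and whether it is a long-chain fatty acid
#' with 20-22 carbons (the LCFA window highlighted as sperm-enriched).
#'
#' @param species A data frame of FA species as from [parse_lipid_name()];
#'   all rows must have `class_code == "FA"`.
#' @param essential Character vector of canonical names forming the
#'   essential set. Defaults to linoleic and alpha-linolenic acid,
#'   `c("FA(18:2)", "FA(18:3)")`.
#' @return The input tibble with columns `saturation` (`"SFA"`, `"MUFA"`,
#'   `"PUFA"`), `essential` (logical) and `lcfa_20_22` (logical) appended.
#' @export
#' @examples
#' fatty_acid_category(parse_lipid_name(c("FA(16:0)", "FA(18:2)", "FA(22:6)")))
fatty_acid_category <- function(species,
                                essential = c("FA(18:2)", "FA(18:3)")) {
  if (!all(species$class_code == "FA")) {
    abort("fatty_acid_category() expects FA species only")
  }
  dplyr::mutate(
    tibble::as_tibble(species),
    saturation = dplyr::case_when(
      .data$double_bonds == 0 ~ "SFA",
      .data$double_bonds == 1 ~ "MUFA",
      TRUE ~ "PUFA"
    ),
    essential = format_lipid_name(species) %in% .env$essential,
    lcfa_20_22 = .data$carbons >= 20 & .data$carbons <= 22
  )
}

#' Monoisotopic neutral mass of a lipid species
#'
#' Computes the monoisotopic mass from the class's elemental base
#' composition plus `carbons` CH2 units minus `double_bonds` H2, using
#' monoisotopic element masses. Base compositions are chosen so that,
#' e.g., `PC(c:d)` and `PE(c+3:d)` are exact isobars, as in nature.
#'
#' @param species A data frame with columns `class_code`, `carbons`,
#'   `double_bonds`.
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @export
#' @examples
#' species_mass(parse_lipid_name(c("PC(34:1)", "FA(16:0)")))
species_mass <- function(species) {
  tax <- lipid_classes()
  i <- match(species$class_code, tax$class_code)
  if (anyNA(i)) {
    abort(paste0("unknown lipid class: ",
                 paste(unique(species$class_code[is.na(i)]), collapse = ", ")))
  }
  base <- tax$base_c[i] * .element_mass["C"] +
    tax$base_h[i] * .element_mass["H"] +
    tax$base_n[i] * .element_mass["N"] +
    tax$base_o[i] * .element_mass["O"] +
    tax$base_p[i] * .element_mass["P"]
  unname(base +
    species$carbons * (.element_mass["C"] + 2 * .element_mass["H"]) -
    species$double_bonds * 2 * .element_mass["H"])
}
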