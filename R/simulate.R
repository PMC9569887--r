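#' Specification of a synthetic DIMS cohort
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the study design the package targets: 26 participants sampled in three
#' compartments (blood serum, seminal fluid, spermatozoa), three
#' ionisation channels, log-normal intensity noise, a shared
#' per-participant random effect inducing inter-compartment correlation,
#' uniform progressive motility on 24-68%, blank wells and a pooled-plasma
#' QC dilution series at 0.25/0.5/1.0x. All randomness in the generator
#' flows from `seed` (library: `seed`; cohort: `seed + 1`; peak lists:
#' `seed + 2`); no global RNG state is consumed or left behind.
#'
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_participants Cohort size (default 26).
#' @param compartments Compartments sampled per participant.
#' @param channels Ionisation channels acquired.
#' @param species_per_class Species drawn per lipid class (capped at the
#'   class's composition grid; cholesterol admits a single species).
#' @param sigma Log-normal intensity noise (log-scale SD, default 0.3).
#' @param compartment_cor Inter-compartment correlation of a variable's
#'   log abundance within a participant, implemented as a shared
#'   per-participant log-scale random effect (default 0.5).
#' @param intensity_scale Instrument counts corresponding to a whole
#'   sample's signal (default 1e5).
#' @param measurement_sigma Extra multiplicative log-normal measurement
#'   noise applied when rendering peak lists (default 0.1).
#' @param ppm_jitter Peak m/z jitter, uniform in `[-ppm_jitter, +ppm_jitter]`
#'   ppm (default 3).
#' @param missing_rate Probability that a study peak is dropped (default
#'   0.02). Blanks and QCs are rendered complete.
#' @param missing_overrides Optional named numeric vector of per-variable
#'   missingness rates (names are variables such as `"PC(34:1)[M+H]"`)
#'   overriding `missing_rate`, e.g. to construct presence-filter test
#'   cases.
#' @param n_blanks Number of blank wells (default 4).
#' @param blank_level Blank signal as a fraction of a variable's mean
#'   study intensity (default 0.002).
#' @param qc_dilutions QC dilution factors (default 0.25, 0.5, 1.0).
#' @param qc_replicates QC wells per dilution factor (default 2).
#' @param qc_sigma Log-normal noise on QC intensities (default 0.05).
#' @param motility_range Range of the uniform progressive-motility draw.
#' @param fa_saturation_tilt Emulate the compartment contrast within the
#'   fatty-acid panel (serum tilted towards polyunsaturated species,
#'   sperm/seminal fluid towards C20-22 long-chain species). Disable for
#'   strictly null cohorts with no compartment differences at all.
#' @param spikes Optional tibble of planted effects with columns
#'   `variable`, `fold_change` and optionally `compartment` and `group`
#'   (NA or absent = applies to all); effects multiply abundance before
#'   renormalization.
#' @param plant_isobars Add the planted isobar test pairs to the library
#'   (PC(34:1)/PE(37:1) in positive mode, PC(34:2)/PS(31:2) in negative
#'   mode; the PS mass is synthetic, offset by 2 ppm).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(seed,
                        n_participants = 26,
                        compartments = c("serum", "seminal_fluid", "sperm"),
                        channels = c("positive", "negative", "negative_cid"),
                        species_per_class = 6,
                        sigma = 0.3,
                        compartment_cor = 0.5,
                        intensity_scale = 1e5,
                        measurement_sigma = 0.1,
                        ppm_jitter = 3,
                        missing_rate = 0.02,
                        missing_overrides = NULL,
                        n_blanks = 4,
                        blank_level = 0.002,
                        qc_dilutions = c(0.25, 0.5, 1.0),
                        qc_replicates = 2,
                        qc_sigma = 0.05,
                        motility_range = c(24, 68),
                        fa_saturation_tilt = TRUE,
                        spikes = NULL,
                        plant_isobars = FALSE) {
  if (missing(seed)) abort("cohort_spec() requires an explicit seed")
  stopifnot(n_participants >= 2, sigma >= 0, measurement_sigma >= 0,
            compartment_cor >= 0, compartment_cor <= 1,
            missing_rate >= 0, missing_rate <= 1,
            ppm_jitter >= 0, qc_sigma >= 0, blank_level >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# per-class sum-composition grids for library generation: even carbon
# counts only (as in most natural lipids), ranges chosen so that no two
# default species fall within the annotation tolerance of each other at
# any shared-channel adduct (carbon parity separates the PC/PE, PE-O/PE-P,
# LPC/PC-O and LPE/PE-O exact-isobar families)
.class_grids <- function() {
  g <- list(
    CER = list(c = seq(28, 58, 2), d = 0:4),
    SM = list(c = seq(28, 58, 2), d = 1:4),
    PC = list(c = seq(28, 58, 2), d = 0:12),
    `PC-O` = list(c = seq(28, 58, 2), d = 0:12),
    PE = list(c = seq(28, 58, 2), d = 0:5),
    `PE-O` = list(c = seq(28, 58, 2), d = seq(0, 8, 2)),
    `PE-P` = list(c = seq(28, 58, 2), d = seq(2, 8, 2)),
    LPC = list(c = seq(14, 26, 2), d = 0:4),
    LPE = list(c = seq(14, 26, 2), d = 0:4),
    PG = list(c = seq(28, 58, 2), d = 0:8),
    PI = list(c = seq(28, 58, 2), d = 0:8),
    PS = list(c = seq(28, 58, 2), d = 0:8),
    TG = list(c = seq(40, 68, 2), d = 0:12),
    DG = list(c = seq(28, 42, 2), d = c(0L, 2L, 4L)),
    CE = list(c = seq(12, 26, 2), d = c(1L, 3L, 5L)),
    CHOL = list(c = 0, d = 0),
    FA = list(c = seq(12, 30, 2), d = 0:6)
  )
  purrr::imap(g, function(gr, cls) {
    grid <- expand.grid(carbons = gr$c, double_bonds = gr$d)
    grid <- grid[grid$double_bonds <= pmax(grid$carbons, 1), , drop = FALSE]
    tibble::tibble(class_code = cls, carbons = as.integer(grid$carbons),
                   double_bonds = as.integer(grid$double_bonds))
  }) |>
    dplyr::bind_rows()
}

#' Simulate a lipid library
#'
#' Draws `species_per_class` sum compositions per class from the class's
#' composition grid (deterministically given the spec seed), computes
#' neutral monoisotopic masses from elemental compositions, and attaches
#' each class's channels and adducts from the packaged taxonomy. The
#' default library is guaranteed collision-free: no two entries lie
#' within 30 ppm of each other at any shared-channel adduct, so the only
#' ambiguous assignments are the deliberately planted isobar pairs
#' (enabled with `plant_isobars`).
#'
#' @param spec A [cohort_spec()].
#' @return A library tibble: `name`, `neutral_mass_da`, `channels`,
#'   `adducts`.
#' @export
simulate_library <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tax <- lipid_classes()
  grids <- .class_grids()
  planted <- c("PC(34:1)", "PE(37:1)", "PC(34:2)", "PS(31:2)")

  species <- withr::with_seed(spec$seed, {
    purrr::map(split(grids, grids$class_code), function(g) {
      n <- min(spec$species_per_class, nrow(g))
      g[sort(sample.int(nrow(g), n)), , drop = FALSE]
    }) |>
      dplyr::bind_rows()
  })
  species$name <- format_lipid_name(species)
  if (spec$plant_isobars) {
    species <- species[!species$name %in% planted, , drop = FALSE]
    extra <- parse_lipid_name(planted)[, c("class_code", "carbons",
                                           "double_bonds", "name")]
    species <- dplyr::bind_rows(species, extra)
  }
  lib <- tibble::tibble(
    name = species$name,
    neutral_mass_da = species_mass(species),
    channels = tax$channels[match(species$class_code, tax$class_code)],
    adducts = tax$adducts[match(species$class_code, tax$class_code)]
  )
  if (spec$plant_isobars) {
    # keep each planted pair channel-specific: the PC/PE pair probes the
    # positive-mode rule only
    pe <- lib$name == "PE(37:1)"
    lib$channels[pe] <- "positive"
    lib$adducts[pe] <- "M+H"
    # PE(37:1) is an exact isobar of PC(34:1) by construction; give the
    # planted PS a synthetic mass 2 ppm above PC(34:2) so the negative-mode
    # pair also collides inside the tolerance window
    ps <- lib$name == "PS(31:2)"
    lib$neutral_mass_da[ps] <-
      lib$neutral_mass_da[lib$name == "PC(34:2)"] * (1 + 2e-6)
  }
  lib <- dplyr::arrange(lib, .data$name)
  .check_library_separation(lib, min_ppm = 30,
                            exempt = if (spec$plant_isobars) planted
                                     else character())
  lib
}

# guard: the generated library must keep distinct species far enough
# apart that the ppm tolerance window is unambiguous
.check_library_separation <- function(library, min_ppm = 30,
                                      exempt = character()) {
  tgt <- .library_targets(library)
  tgt <- tgt[!tgt$name %in% exempt, , drop = FALSE]
  for (ch in unique(tgt$channel)) {
    mz <- sort(tgt$target_mz[tgt$channel == ch])
    if (length(mz) < 2) next
    gap_ppm <- 1e6 * diff(mz) / mz[-length(mz)]
    if (any(gap_ppm < min_ppm)) {
      abort(paste0("library species closer than ", min_ppm,
                   " ppm in channel ", ch))
    }
  }
  invisible(library)
}

#' Default compartment lipid-class profiles
#'
#' Mean class-abundance profiles for the three compartments, as relative
#' weights that are normalized to 1000 per mille within each channel.
#' The ordering is faithful to the qualitative pattern reported for
#' serum versus seminal fluid and sperm (serum richer in TG, PC, PC-O,
#' CHOL and CE; sperm and seminal fluid richer in SM, CER, PE-O, PE-P,
#' LPE and PG; similar LPC, PE, PI, PS); the numbers themselves are
#' illustrative, not quantitative measurements.
#'
#' @param sigma Per-class log-normal dispersion (default 0.3).
#' @return A tibble: `compartment`, `class_code`, `weight`, `sigma`.
#' @export
compartment_profiles <- function(sigma = 0.3) {
  w <- tibble::tribble(
    ~class_code, ~serum, ~seminal_fluid, ~sperm,
    "CER",   20,  90, 100,
    "SM",    60, 160, 170,
    "PC",   220, 120, 110,
    "PC-O",  60,  25,  25,
    "PE",    60,  80,  90,
    "PE-O",  25,  90, 100,
    "PE-P",  15,  50,  60,
    "LPC",   40,  45,  40,
    "LPE",   40, 110, 120,
    "PG",    30,  90, 100,
    "PI",    80,  85,  90,
    "PS",    70,  75,  80,
    "TG",   250,  60,  50,
    "DG",    30,  20,  20,
    "CE",   100,  40,  35,
    "CHOL", 120,  60,  55,
    "FA",  1000, 1000, 1000
  )
  tidyr::pivot_longer(w, -"class_code", names_to = "compartment",
                      values_to = "weight") |>
    dplyr::mutate(sigma = sigma) |>
    dplyr::select("compartment", "class_code", "weight", "sigma")
}

#' Simulate a cohort's ground-truth per-mille matrix and design
#'
#' Draws, per participant and compartment, class abundances log-normally
#' around the compartment profile means, allocates them to library
#' species, applies any spiked effects, and renormalizes each sample and
#' channel to 1000 per mille. Inter-compartment correlation is induced by
#' a shared per-participant, per-variable log-scale random effect with
#' weight `sqrt(compartment_cor)`. Within the fatty-acid panel, serum
#' tilts towards polyunsaturated species and sperm/seminal fluid towards
#' the C20-22 long-chain species, mirroring the compartment contrasts the
#' generator emulates. Motility is drawn uniformly on `motility_range`
#' and the median split applied.
#'
#' @param spec A [cohort_spec()].
#' @param library A library tibble; defaults to [simulate_library()] on
#'   the same spec.
#' @param profiles Compartment profiles; defaults to
#'   [compartment_profiles()] with the spec's `sigma`.
#' @return A list of class `sim_cohort` with elements `truth` (long
#'   tibble: `sample_id`, `participant_id`, `compartment`, `channel`,
#'   `variable`, `per_mille`), `design` (`sample_id`, `participant_id`,
#'   `compartment`, `motility_pct`, `motility_group`), `library` and
#'   `spikes`.
#' @export
simulate_cohort <- function(spec, library = simulate_library(spec),
                            profiles = compartment_profiles(spec$sigma)) {
  stopifnot(inherits(spec, "cohort_spec"))
  targets <- .library_targets(library)
  targets <- targets[targets$channel %in% spec$channels, , drop = FALSE]
  targets$variable <- paste0(targets$name, "[", targets$adduct, "]")
  if (!is.null(spec$spikes) &&
      !all(spec$spikes$variable %in% targets$variable)) {
    abort("spiked variable(s) not present in the library")
  }
  sp <- parse_lipid_name(targets$name)
  nv <- nrow(targets)
  np <- spec$n_participants
  participants <- sprintf("P%02d", seq_len(np))

  withr::with_seed(spec$seed + 1L, {
    # within-class species weights, shared across compartments
    base_w <- exp(stats::rnorm(nv, 0, 0.5))

    # compartment-specific mean per-mille per variable
    mean_pm <- purrr::map(spec$compartments, function(cp) {
      pr <- profiles[profiles$compartment == cp, , drop = FALSE]
      class_w <- pr$weight[match(sp$class_code, pr$class_code)]
      if (anyNA(class_w)) abort(paste0("profile missing classes for ", cp))
      w <- base_w
      if (spec$fa_saturation_tilt) {
        fa <- sp$class_code == "FA"
        w[fa & sp$double_bonds >= 2] <- w[fa & sp$double_bonds >= 2] *
          (if (cp == "serum") 2 else 1)
        w[fa & sp$carbons >= 20 & sp$carbons <= 22] <-
          w[fa & sp$carbons >= 20 & sp$carbons <= 22] *
          (if (cp == "serum") 1 else 2)
      }
      # class share x species share within class, normalized per channel
      m <- numeric(nv)
      for (ch in unique(targets$channel)) {
        i <- which(targets$channel == ch)
        cls_i <- sp$class_code[i]
        class_w_one <- tapply(class_w[i], cls_i, function(x) x[1])
        class_share <- class_w_one / sum(class_w_one)
        species_share <- w[i] / stats::ave(w[i], cls_i, FUN = sum)
        m[i] <- 1000 * unname(class_share[cls_i]) * species_share
      }
      m
    })
    names(mean_pm) <- spec$compartments

    motility <- round(stats::runif(np, spec$motility_range[1],
                                   spec$motility_range[2]))
    z_shared <- matrix(stats::rnorm(np * nv), np, nv)
    sigma_v <- profiles$sigma[match(paste(spec$compartments[1],
                                          sp$class_code),
                                    paste(profiles$compartment,
                                          profiles$class_code))]

    rho <- spec$compartment_cor
    blocks <- purrr::map(spec$compartments, function(cp) {
      z_cp <- matrix(stats::rnorm(np * nv), np, nv)
      noise <- sqrt(rho) * z_shared + sqrt(1 - rho) * z_cp
      x <- matrix(rep(mean_pm[[cp]], each = np), np, nv) *
        exp(sweep(noise, 2, sigma_v, `*`))
      dimnames(x) <- list(participants, targets$variable)
      x
    })
    names(blocks) <- spec$compartments
  })

  design <- tidyr::expand_grid(participant_id = participants,
                               compartment = spec$compartments) |>
    dplyr::mutate(sample_id = paste(.data$participant_id,
                                    .data$compartment, sep = "_"),
                  motility_pct = motility[match(.data$participant_id,
                                                participants)]) |>
    dplyr::select("sample_id", "participant_id", "compartment",
                  "motility_pct")
  design <- split_by_median_motility(design)

  # planted effects multiply abundance before renormalization
  if (!is.null(spec$spikes)) {
    sk <- tibble::as_tibble(spec$spikes)
    if (!"compartment" %in% names(sk)) sk$compartment <- NA_character_
    if (!"group" %in% names(sk)) sk$group <- NA_character_
    for (j in seq_len(nrow(sk))) {
      cps <- if (is.na(sk$compartment[j])) spec$compartments
             else sk$compartment[j]
      for (cp in cps) {
        rows <- if (is.na(sk$group[j])) participants else {
          d_cp <- design[design$compartment == cp, , drop = FALSE]
          d_cp$participant_id[d_cp$motility_group == sk$group[j]]
        }
        blocks[[cp]][rows, sk$variable[j]] <-
          blocks[[cp]][rows, sk$variable[j]] * sk$fold_change[j]
      }
    }
  }

  truth <- purrr::imap(blocks, function(x, cp) {
    # renormalize each sample row to 1000 per mille within each channel
    for (ch in unique(targets$channel)) {
      i <- targets$channel == ch
      x[, i] <- 1000 * x[, i, drop = FALSE] /
        rowSums(x[, i, drop = FALSE])
    }
    tibble::as_tibble(x) |>
      dplyr::mutate(participant_id = rownames(x), .before = 1) |>
      tidyr::pivot_longer(-"participant_id", names_to = "variable",
                          values_to = "per_mille") |>
      dplyr::mutate(compartment = cp)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      sample_id = paste(.data$participant_id, .data$compartment, sep = "_"),
      channel = targets$channel[match(.data$variable, targets$variable)]
    ) |>
    dplyr::select("sample_id", "participant_id", "compartment", "channel",
                  "variable", "per_mille")

  structure(list(truth = truth, design = design, library = library,
                 spikes = spec$spikes, spec = spec),
            class = "sim_cohort")
}

#' Render a cohort's peak lists, blanks and QC dilution series
#'
#' Converts ground-truth per-mille abundances into centroided peak lists:
#' peaks are placed at the variable's adduct m/z jittered uniformly
#' within `ppm_jitter`, with intensities scaled by `intensity_scale` and
#' multiplied by log-normal measurement noise. Study peaks are dropped at
#' the configured missingness rate. Blank wells carry `blank_level` of
#' each variable's mean study intensity; QC wells carry a pooled
#' reference profile (the mean serum profile, mimicking pooled plasma)
#' scaled by the dilution factor, with their own noise term. Peak lists
#' are sorted ascending by m/z within each sample and channel.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()], or its `truth`
#'   tibble together with `library`.
#' @param library Library tibble (defaulted from the cohort object).
#' @param spec The [cohort_spec()] (defaulted from the cohort object).
#' @return A list with `peaks` (`sample_id`, `channel`, `mz`,
#'   `intensity`) and `metadata` (`sample_id`, `participant_id`,
#'   `compartment`, `role`, `dilution`, `motility_pct`).
#' @export
simulate_peaklists <- function(cohort, library = cohort$library,
                               spec = cohort$spec) {
  truth <- if (inherits(cohort, "sim_cohort")) cohort$truth else cohort
  design <- if (inherits(cohort, "sim_cohort")) cohort$design else NULL
  targets <- .library_targets(library)
  targets$variable <- paste0(targets$name, "[", targets$adduct, "]")
  tmz <- setNames(targets$target_mz, paste(targets$channel,
                                           targets$variable))
  scale_per_mille <- spec$intensity_scale / 1000

  withr::with_seed(spec$seed + 2L, {
    study <- truth |>
      dplyr::mutate(
        target_mz = unname(tmz[paste(.data$channel, .data$variable)]),
        intensity = .data$per_mille * scale_per_mille *
          exp(stats::rnorm(dplyr::n(), 0, spec$measurement_sigma))
      )
    rate <- rep(spec$missing_rate, nrow(study))
    if (!is.null(spec$missing_overrides)) {
      ov <- spec$missing_overrides[study$variable]
      rate[!is.na(ov)] <- ov[!is.na(ov)]
    }
    keep <- stats::runif(nrow(study)) >= rate
    study <- study[keep, , drop = FALSE]

    mean_int <- study |>
      dplyr::group_by(.data$channel, .data$variable, .data$target_mz) |>
      dplyr::summarise(mean_intensity = mean(.data$intensity),
                       .groups = "drop")

    blanks <- tidyr::expand_grid(
      sample_id = sprintf("BLANK%02d", seq_len(spec$n_blanks)),
      mean_int
    ) |>
      dplyr::mutate(intensity = spec$blank_level * .data$mean_intensity *
                      exp(stats::rnorm(dplyr::n(), 0, 0.3)))

    # pooled-plasma reference: the mean serum profile per variable
    ref <- truth[truth$compartment == "serum", , drop = FALSE] |>
      dplyr::group_by(.data$channel, .data$variable) |>
      dplyr::summarise(ref_pm = mean(.data$per_mille), .groups = "drop") |>
      dplyr::mutate(target_mz = unname(tmz[paste(.data$channel,
                                                 .data$variable)]))
    qc_design <- tidyr::expand_grid(dilution = spec$qc_dilutions,
                                    replicate = seq_len(spec$qc_replicates))
    qc_design$sample_id <- sprintf("QC_%g_r%d", qc_design$dilution,
                                   qc_design$replicate)
    qcs <- tidyr::expand_grid(qc_design, ref) |>
      dplyr::mutate(intensity = .data$ref_pm * scale_per_mille *
                      .data$dilution *
                      exp(stats::rnorm(dplyr::n(), 0, spec$qc_sigma)))

    all_peaks <- dplyr::bind_rows(
      dplyr::select(study, "sample_id", "channel", "target_mz",
                    "intensity"),
      dplyr::select(blanks, "sample_id", "channel", "target_mz",
                    "intensity"),
      dplyr::select(qcs, "sample_id", "channel", "target_mz", "intensity")
    )
    all_peaks$mz <- all_peaks$target_mz *
      (1 + stats::runif(nrow(all_peaks), -spec$ppm_jitter,
                        spec$ppm_jitter) * 1e-6)
  })

  peaks <- all_peaks |>
    dplyr::select("sample_id", "channel", "mz", "intensity") |>
    dplyr::arrange(.data$sample_id, .data$channel, .data$mz)

  meta_study <- if (!is.null(design)) {
    dplyr::mutate(design[, c("sample_id", "participant_id", "compartment",
                             "motility_pct")],
                  role = "study", dilution = NA_real_)
  } else {
    tibble::tibble(sample_id = unique(truth$sample_id),
                   participant_id = NA_character_,
                   compartment = NA_character_,
                   motility_pct = NA_real_, role = "study",
                   dilution = NA_real_)
  }
  metadata <- dplyr::bind_rows(
    meta_study,
    tibble::tibble(sample_id = sprintf("BLANK%02d", seq_len(spec$n_blanks)),
                   participant_id = NA_character_,
                   compartment = NA_character_, motility_pct = NA_real_,
                   role = "blank", dilution = NA_real_),
    tibble::tibble(sample_id = qc_design$sample_id,
                   participant_id = NA_character_,
                   compartment = NA_character_, motility_pct = NA_real_,
                   role = "qc", dilution = qc_design$dilution)
  ) |>
    dplyr::select("sample_id", "participant_id", "compartment", "role",
                  "dilution", "motility_pct")

  list(peaks = peaks, metadata = metadata)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", x$spec$n_participants, "participants x",
      length(x$spec$compartments), "compartments,",
      length(unique(x$truth$variable)), "variables\n")
  invisible(x)
}
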