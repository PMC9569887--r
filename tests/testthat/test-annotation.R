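# frozen oracle constants: CODATA proton and ammonium-cation masses,
# independent of the package's element table
PROTON <- 1.007276466621
NH4 <- 18.033825553

test_that("adduct m/z matches independent mass constants", {
  expect_equal(adduct_mz(760.5851, "M+H"), 760.5851 + PROTON,
               tolerance = 1e-7)
  expect_lt(abs(adduct_mz(760.5851, "M+H") - 761.5924), 1e-4)
  expect_lt(abs(adduct_mz(760.5851, "M+NH4") - 778.6190), 1e-4)
  expect_equal(adduct_mz(760.5851, "M+NH4"), 760.5851 + NH4,
               tolerance = 1e-7)
  # protonated and deprotonated forms are exactly two protons apart
  m <- c(256.24, 759.5778, 1200.9)
  expect_equal(adduct_mz(m, "M+H") - adduct_mz(m, "M-H"),
               rep(2 * PROTON, 3), tolerance = 1e-7)
  expect_error(adduct_mz(700, "M+Na"), "unknown adduct")
})

test_that("ppm deviation is signed and exact at the boundary", {
  expect_equal(ppm_deviation(100.0001, 100), 1, tolerance = 1e-9)
  expect_equal(ppm_deviation(c(55, 700.123, 1e4), c(55, 700.123, 1e4)),
               rep(0, 3))
  expect_equal(ppm_deviation(700.0063, 700), 9, tolerance = 1e-9)
  expect_equal(ppm_deviation(99.9999, 100), -1, tolerance = 1e-9)
})

make_library <- function(names, masses = NULL, channels = "positive",
                         adducts = "M+H") {
  sp <- parse_lipid_name(names)
  tibble::tibble(
    name = names,
    neutral_mass_da = if (is.null(masses)) species_mass(sp) else masses,
    channels = channels, adducts = adducts
  )
}

test_that("peaks within tolerance are annotated, beyond it are not", {
  lib <- make_library(c("PC(34:1)", "SM(34:1)"))
  base <- adduct_mz(lib$neutral_mass_da[1], "M+H")
  in_tol <- tibble::tibble(sample_id = "s", channel = "positive",
                           mz = base * (1 + 5e-6), intensity = 10)
  out_tol <- tibble::tibble(sample_id = "s", channel = "positive",
                            mz = base * (1 + 12e-6), intensity = 10)
  got <- annotate(in_tol, lib)
  expect_equal(nrow(got), 1)
  expect_equal(got$name, "PC(34:1)")
  expect_equal(got$ppm_error, 5, tolerance = 1e-6)
  expect_false(got$ambiguous)
  expect_equal(nrow(annotate(out_tol, lib)), 0)
  # exactly 9 ppm is retained: only deviations beyond 9 ppm are excluded
  at_nine <- tibble::tibble(sample_id = "s", channel = "positive",
                            mz = base * (1 + 9e-6), intensity = 1)
  expect_equal(nrow(annotate(at_nine, lib)), 1)
})

test_that("empty inputs follow the interface contract", {
  lib <- make_library("PC(34:1)")
  expect_error(annotate(tibble::tibble(sample_id = "s",
                                       channel = "positive", mz = 1,
                                       intensity = 1), lib[0, ]),
               "empty lipid library")
  empty_peaks <- tibble::tibble(sample_id = character(),
                                channel = character(), mz = numeric(),
                                intensity = numeric())
  expect_equal(nrow(annotate(empty_peaks, lib)), 0)
})

test_that("peaks generated at exact adduct m/z are fully recovered", {
  spec <- cohort_spec(seed = 11, species_per_class = 12)
  lib <- simulate_library(spec)
  tgt <- lipidims:::.library_targets(lib)
  expect_gte(nrow(tgt), 200)
  peaks <- tibble::tibble(sample_id = "s", channel = tgt$channel,
                          mz = tgt$target_mz, intensity = 1) |>
    dplyr::arrange(channel, mz)
  got <- annotate(peaks, lib)
  expect_equal(nrow(got), nrow(tgt))
  expect_equal(got$ppm_error, rep(0, nrow(tgt)))
  expect_setequal(got$variable, paste0(tgt$name, "[", tgt$adduct, "]"))
})

test_that("annotation is deterministic", {
  spec <- cohort_spec(seed = 3)
  lib <- simulate_library(spec)
  pl <- simulate_peaklists(simulate_cohort(spec, library = lib))
  a1 <- annotate(pl$peaks, lib)
  a2 <- annotate(pl$peaks, lib)
  expect_identical(a1, a2)
})

test_that("isobars resolve by the mode-specific class priority", {
  # positive mode: PC wins over the isobaric PE at equal ppm error
  pos <- resolve_isobar(
    tibble::tibble(name = c("PE(37:1)", "PC(34:1)"), adduct = "M+H",
                   ppm_error = c(1.5, 1.5)),
    channel = "positive")
  expect_equal(pos$name, "PC(34:1)")
  expect_true(pos$ambiguous)
  # negative mode: PC wins over PS
  neg <- resolve_isobar(
    tibble::tibble(name = c("PS(31:2)", "PC(34:2)"), adduct = "M-H",
                   ppm_error = c(-2, -2)),
    channel = "negative")
  expect_equal(neg$name, "PC(34:2)")
  # a single candidate is returned unchanged and unambiguous
  one <- resolve_isobar(tibble::tibble(name = "SM(34:1)", adduct = "M+H",
                                       ppm_error = 3), channel = "positive")
  expect_equal(one$name, "SM(34:1)")
  expect_false(one$ambiguous)
  # among equal-priority candidates the smaller |ppm| wins
  close <- resolve_isobar(
    tibble::tibble(name = c("TG(50:2)", "TG(52:1)"), adduct = "M+NH4",
                   ppm_error = c(4, -1)),
    channel = "positive")
  expect_equal(close$name, "TG(52:1)")
})

test_that("isobar resolution is a total order", {
  set.seed(91)
  classes <- c("PC", "PE", "PS", "SM", "TG", "CER")
  for (i in 1:50) {
    n <- sample(2:5, 1)
    cand <- tibble::tibble(
      name = sprintf("%s(%d:%d)", sample(classes, n, replace = TRUE),
                     sample(seq(30, 50, 2), n, replace = TRUE),
                     sample(0:4, n, replace = TRUE)),
      adduct = sample(c("M+H", "M+NH4"), n, replace = TRUE),
      ppm_error = round(runif(n, -9, 9), 2)
    )
    cand <- dplyr::distinct(cand)
    ch <- sample(c("positive", "negative"), 1)
    winner <- resolve_isobar(cand, ch)
    # permutation invariance
    perm <- cand[sample(nrow(cand)), , drop = FALSE]
    expect_equal(resolve_isobar(perm, ch)$name, winner$name)
    expect_equal(resolve_isobar(perm, ch)$adduct, winner$adduct)
    # the winner beats every other candidate pairwise (antisymmetry +
    # transitivity of the underlying order)
    for (j in seq_len(nrow(cand))) {
      pair <- dplyr::bind_rows(winner[, c("name", "adduct", "ppm_error")],
                               cand[j, ])
      w2 <- resolve_isobar(pair, ch)
      expect_equal(w2$name, winner$name)
    }
  }
})

test_that("planted library isobars always resolve to PC", {
  spec <- cohort_spec(seed = 5, plant_isobars = TRUE)
  lib <- simulate_library(spec)
  pc_pos <- adduct_mz(lib$neutral_mass_da[lib$name == "PC(34:1)"], "M+H")
  pc_neg <- adduct_mz(lib$neutral_mass_da[lib$name == "PC(34:2)"], "M-H")
  for (jit in c(-6e-6, 0, 4e-6)) {
    pos <- annotate(tibble::tibble(sample_id = "s", channel = "positive",
                                   mz = pc_pos * (1 + jit), intensity = 1),
                    lib)
    expect_equal(pos$name, "PC(34:1)")
    expect_true(pos$ambiguous)
    neg <- annotate(tibble::tibble(sample_id = "s", channel = "negative",
                                   mz = pc_neg * (1 + jit), intensity = 1),
                    lib)
    expect_equal(neg$name, "PC(34:2)")
    expect_true(neg$ambiguous)
  }
})

test_that("duplicate assignments collapse into summed intensities", {
  ann <- tibble::tibble(
    sample_id = c("s", "s", "s"), channel = "positive",
    mz = c(700.001, 700.002, 710), intensity = c(5, 7, 2),
    name = c("PC(34:1)", "PC(34:1)", "SM(34:1)"), adduct = "M+H",
    variable = c("PC(34:1)[M+H]", "PC(34:1)[M+H]", "SM(34:1)[M+H]"),
    ppm_error = 0, ambiguous = FALSE
  )
  got <- annotation_intensities(ann)
  expect_equal(nrow(got), 2)
  expect_equal(got$intensity[got$variable == "PC(34:1)[M+H]"], 12)
})
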