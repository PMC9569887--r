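long1 <- function(vals, sample = "s1", channel = "positive") {
  tibble::tibble(sample_id = sample, channel = channel,
                 variable = paste0("v", seq_along(vals)), intensity = vals)
}

test_that("per-mille normalization scales rows to 1000", {
  expect_equal(normalize_per_mille(long1(c(2, 3, 5)))$per_mille,
               c(200, 300, 500))
  expect_equal(normalize_per_mille(long1(7))$per_mille, 1000)
  # scale invariance
  a <- normalize_per_mille(long1(c(1.2, 8, 33)))
  b <- normalize_per_mille(long1(c(1.2, 8, 33) * 17.3))
  expect_equal(a$per_mille, b$per_mille)
  # channels normalize independently
  two <- dplyr::bind_rows(long1(c(1, 1)), long1(c(3, 1), channel = "negative"))
  got <- normalize_per_mille(two)
  expect_equal(got$per_mille, c(500, 500, 750, 250))
  expect_error(normalize_per_mille(long1(c(0, 0))), "zero total.*s1")
})

test_that("a gross outlier sample is flagged by the PCA screen", {
  set.seed(1001)
  n <- 21; v <- 10
  x <- matrix(exp(rnorm(n * v, log(50), 0.3)), n, v)
  x[21, 1] <- x[21, 1] * 50
  long <- tibble::tibble(
    sample_id = rep(sprintf("s%02d", 1:n), v),
    channel = "positive",
    variable = rep(paste0("v", 1:v), each = n),
    intensity = as.vector(x)
  )
  nm <- normalize_per_mille(long)
  scores <- pca_outlier_screen(nm)
  expect_equal(scores$sample_id[scores$outlier], "s21")
  expect_equal(pca_outliers(nm), "s21")
  # flagging is invariant to variable order
  nm_perm <- nm[order(nm$variable, decreasing = TRUE), , drop = FALSE]
  expect_equal(pca_outliers(nm_perm), "s21")
})

test_that("degenerate matrices yield no outliers, with a warning", {
  flat <- tibble::tibble(sample_id = rep(c("a", "b", "c"), 2),
                         channel = "positive",
                         variable = rep(c("v1", "v2"), each = 3),
                         per_mille = rep(c(400, 600), each = 3))
  expect_warning(got <- pca_outlier_screen(flat), "degenerate")
  expect_false(any(got$outlier))
})

test_that("median motility split puts the median itself in the high group", {
  d <- tibble::tibble(participant_id = paste0("P", 1:5),
                      motility_pct = c(24, 40, 50, 58, 68))
  got <- split_by_median_motility(d)
  expect_equal(got$motility_group,
               c("low", "low", "high", "high", "high"))
  # all-equal motilities: everyone is at the median, hence high
  same <- split_by_median_motility(
    tibble::tibble(participant_id = paste0("P", 1:4), motility_pct = 50))
  expect_equal(unique(same$motility_group), "high")
  expect_error(split_by_median_motility(
    tibble::tibble(participant_id = "P1", motility_pct = NA_real_)),
    "motility must be known")
})

paired_fixture <- function(a, b, extra_var = NULL) {
  design <- tibble::tibble(
    sample_id = c(paste0("P", seq_along(a), "_sperm"),
                  paste0("P", seq_along(b), "_serum")),
    participant_id = rep(paste0("P", seq_along(a)), 2),
    compartment = rep(c("sperm", "serum"), each = length(a))
  )
  nm <- tibble::tibble(
    sample_id = design$sample_id, channel = "positive", variable = "v1",
    per_mille = c(a, b)
  )
  list(nm = nm, design = design)
}

test_that("paired compartment test matches the closed-form oracle", {
  fx <- paired_fixture(c(2, 3, 5), c(1, 2, 3))
  got <- test_compartments(fx$nm, fx$design, c("sperm", "serum"))
  want <- oracle_paired_t(c(2, 3, 5), c(1, 2, 3))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$n, 3L)
  expect_equal(got$log2fc, log2(mean(c(2, 3, 5)) / mean(c(1, 2, 3))))
})

test_that("paired test null identity and scale equivariance hold", {
  fx <- paired_fixture(c(4, 7, 9, 2), c(4, 7, 9, 2))
  got <- test_compartments(fx$nm, fx$design, c("sperm", "serum"))
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)
  expect_equal(got$log2fc, 0)
  a <- c(2.5, 3.5, 6)
  b <- c(1, 2.2, 3.3)
  g1 <- test_compartments(paired_fixture(a, b)$nm,
                          paired_fixture(a, b)$design,
                          c("sperm", "serum"))
  g2 <- test_compartments(paired_fixture(2 * a, b)$nm,
                          paired_fixture(2 * a, b)$design,
                          c("sperm", "serum"))
  expect_equal(g2$log2fc, g1$log2fc + 1, tolerance = 1e-12)
})

test_that("incomplete pairs are dropped variable-wise or flagged", {
  fx <- paired_fixture(c(2, 3, 5), c(1, 2, 3))
  # remove one serum sample: the pair is dropped for that variable
  nm <- fx$nm[fx$nm$sample_id != "P3_serum", , drop = FALSE]
  got <- test_compartments(nm, fx$design, c("sperm", "serum"))
  expect_equal(got$n, 2L)
  # fewer than 2 complete pairs: untestable
  nm2 <- fx$nm[!fx$nm$sample_id %in% c("P3_serum", "P2_sperm"), ,
               drop = FALSE]
  got2 <- test_compartments(nm2, fx$design, c("sperm", "serum"))
  expect_true(is.na(got2$p))
  expect_match(got2$untestable_reason, "fewer than 2 complete pairs")
  expect_false(got2$significant)
})

unpaired_fixture <- function(hi, lo, compartment = "sperm") {
  n <- length(hi) + length(lo)
  design <- tibble::tibble(
    sample_id = paste0("P", 1:n, "_", compartment),
    participant_id = paste0("P", 1:n),
    compartment = compartment,
    motility_pct = c(rep(80, length(hi)), rep(10, length(lo))),
    motility_group = c(rep("high", length(hi)), rep("low", length(lo)))
  )
  nm <- tibble::tibble(sample_id = design$sample_id, channel = "positive",
                       variable = "v1", per_mille = c(hi, lo))
  list(nm = nm, design = design)
}

test_that("unpaired Welch test matches the closed-form oracle", {
  fx <- unpaired_fixture(c(4, 5, 6), c(1, 2, 3))
  got <- test_motility_groups(fx$nm, fx$design, "sperm")
  want <- oracle_welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$log2fc, log2(5 / 2))
  # identical group values give p = 1
  same <- unpaired_fixture(c(1, 2, 3), c(1, 2, 3))
  expect_equal(test_motility_groups(same$nm, same$design, "sperm")$p, 1)
})

test_that("swapping group labels flips log2FC and preserves p", {
  hi <- c(3, 8, 6, 4); lo <- c(1, 2, 2.5, 5)
  a <- unpaired_fixture(hi, lo)
  b <- unpaired_fixture(lo, hi)
  ra <- test_motility_groups(a$nm, a$design, "sperm")
  rb <- test_motility_groups(b$nm, b$design, "sperm")
  expect_equal(ra$log2fc, -rb$log2fc, tolerance = 1e-12)
  expect_equal(ra$p, rb$p, tolerance = 1e-12)
  expect_equal(ra$t, -rb$t, tolerance = 1e-12)
})

test_that("a group with fewer than two values is untestable", {
  fx <- unpaired_fixture(c(4, 5, 6), c(1, 2, 3))
  nm <- fx$nm[fx$nm$sample_id != "P5_sperm", , drop = FALSE]
  nm <- nm[nm$sample_id != "P6_sperm", , drop = FALSE]
  got <- test_motility_groups(nm, fx$design, "sperm")
  expect_true(is.na(got$p))
  expect_match(got$untestable_reason, "fewer than 2 values")
  expect_error(test_motility_groups(
    fx$nm, dplyr::select(fx$design, -"motility_group"), "sperm"),
    "motility_group")
})

test_that("significance is strict at the limit", {
  res <- tibble::tibble(p = c(0.0009, 0.001, 0.5, NA))
  got <- significance_mask(res)
  expect_equal(got$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(significance_mask(res, alpha = 1)$significant[1:3]))
})

test_that("class aggregation sums members and splits FA categories", {
  nm <- tibble::tibble(
    sample_id = "s1", channel = "positive",
    variable = c("SM(34:1)[M+H]", "SM(42:2)[M+H]", "PC(34:1)[M+H]"),
    per_mille = c(10, 5, 20)
  )
  got <- aggregate_by_class(nm)
  expect_equal(got$per_mille[got$class == "SM"], 15)
  expect_equal(got$per_mille[got$class == "PC"], 20)

  fa <- tibble::tibble(
    sample_id = "s1", channel = "negative_cid",
    variable = c("FA(16:0)[M-H]", "FA(18:1)[M-H]", "FA(18:2)[M-H]",
                 "FA(22:6)[M-H]"),
    per_mille = c(7, 3, 4, 6)
  )
  gfa <- aggregate_by_class(fa)
  expect_equal(gfa$per_mille[gfa$class == "SFA"], 7)
  expect_equal(gfa$per_mille[gfa$class == "MUFA"], 3)
  expect_equal(gfa$per_mille[gfa$class == "EFA"], 4)   # FA(18:2)
  expect_equal(gfa$per_mille[gfa$class == "PUFA"], 6)  # FA(22:6)
  expect_equal(sum(gfa$per_mille), 20)

  # one class only: conservation at 1000
  one <- normalize_per_mille(tibble::tibble(
    sample_id = "s", channel = "positive",
    variable = c("TG(50:2)[M+NH4]", "TG(52:3)[M+NH4]"),
    intensity = c(4, 6)))
  expect_equal(aggregate_by_class(one)$per_mille, 1000)
  expect_error(aggregate_by_class(tibble::tibble(
    sample_id = "s", channel = "positive", variable = "nonsense",
    per_mille = 1)), "unknown lipid class")
})

test_that("volcano table carries testable points and lists exclusions", {
  res <- tibble::tibble(
    variable = c("a", "b", "c", "d"), channel = "positive",
    comparison = "x vs y (paired)", n = c(10L, 10L, 1L, 10L),
    log2fc = c(0, 2, NA, Inf), t = c(0, 5, NA, Inf),
    p = c(1, 0.001, NA, 0), significant = c(FALSE, FALSE, FALSE, TRUE),
    untestable_reason = c(NA, NA, "fewer than 2 complete pairs", NA)
  )
  got <- volcano_table(res)
  expect_equal(nrow(got), 2)
  expect_equal(got$neg_log10_p[got$variable == "b"], 3)  # p = 0.001
  expect_equal(got$log2fc[got$variable == "a"], 0)
  expect_equal(got$neg_log10_p[got$variable == "a"], 0)  # origin point
  exc <- volcano_excluded(got)
  expect_setequal(exc$variable, c("c", "d"))
  expect_equal(exc$reason[exc$variable == "d"], "infinite fold change")
})

test_that("plot helpers return ggplot objects", {
  fx <- unpaired_fixture(c(4, 5, 6), c(1, 2, 3))
  res <- test_motility_groups(fx$nm, fx$design, "sperm")
  expect_s3_class(plot_volcano(res), "ggplot")
  ct <- tibble::tibble(sample_id = c("s1", "s2"), channel = "positive",
                       class = c("PC", "SM"), per_mille = c(600, 400))
  expect_s3_class(plot_class_abundance(ct), "ggplot")
})
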