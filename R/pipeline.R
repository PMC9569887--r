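#' Configuration of a pipeline run
#'
#' Collects the file paths and analysis parameters of one end-to-end run.
#' The defaults are the pipeline's canonical settings: 9 ppm annotation
#' tolerance, S/N minimum 3, presence minimum 50%, QC linearity r
#' threshold 0.75, significance limit p < 0.001, and the mode-specific
#' isobar priorities.
#'
#' @param library_path Lipid library CSV.
#' @param peaklists_dir Directory of per-sample peak-list CSVs.
#' @param metadata_path Sample metadata CSV.
#' @param out_dir Output directory for result tables.
#' @param tolerance_ppm,snr_min,presence_min,r_min,alpha Analysis
#'   thresholds.
#' @param priorities Isobar priorities, see [isobar_priorities()].
#' @param pca_sd_limit PCA outlier threshold in standard deviations.
#' @return A `run_config` list.
#' @export
run_config <- function(library_path, peaklists_dir, metadata_path, out_dir,
                       tolerance_ppm = 9, snr_min = 3, presence_min = 0.5,
                       r_min = 0.75, alpha = 0.001,
                       priorities = isobar_priorities(),
                       pca_sd_limit = 3) {
  stopifnot(tolerance_ppm > 0, snr_min > 0, presence_min > 0, r_min > 0,
            alpha > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Read and validate the inputs of a run
#'
#' @param config A [run_config()].
#' @return A list with `library`, `peaks` and `metadata`.
#' @export
read_run_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  library <- read_lipid_library(config$library_path)
  peaks <- read_peak_lists(config$peaklists_dir)
  metadata <- read_sample_metadata(config$metadata_path)
  unknown <- setdiff(unique(peaks$sample_id), metadata$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("peak lists for sample(s) absent from metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  list(library = library, peaks = peaks, metadata = metadata)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full DIMS lipidomics pipeline
#'
#' Executes annotation, signal-quality filtering, per-mille
#' normalization, PCA outlier screening, the median motility split,
#' paired between-compartment and unpaired between-group differential
#' tests, lipid-class aggregation and volcano tables, and writes every
#' result table plus a run manifest into `config$out_dir`. Output files
#' are written deterministically: identical inputs and config reproduce
#' identical files.
#'
#' Output files: `filter_report.tsv`, `normalized.tsv`,
#' `pca_scores.tsv`, `design.tsv`, `differential_results.tsv`,
#' `class_abundance.tsv`, `volcano.csv`, `volcano_excluded.csv`,
#' `manifest.txt`.
#'
#' @param config A [run_config()].
#' @return An object of class `dims_run` (invisibly): a list with the
#'   in-memory result tables (`annotations`, `filter`, `normalized`,
#'   `pca_scores`, `excluded_samples`, `design`, `results`, `classes`,
#'   `volcano`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- .stage("read_inputs", read_run_inputs(config))

  ann <- .stage("annotate",
                annotate(inputs$peaks, inputs$library,
                         tolerance_ppm = config$tolerance_ppm,
                         priorities = config$priorities))
  intens <- annotation_intensities(ann)

  filt <- .stage("filter",
                 apply_filters(intens, inputs$metadata,
                               snr_min = config$snr_min,
                               presence_min = config$presence_min,
                               r_min = config$r_min))

  study_ids <- inputs$metadata$sample_id[inputs$metadata$role == "study"]
  normalized <- .stage("normalize", normalize_per_mille(
    filt$data[filt$data$sample_id %in% study_ids, , drop = FALSE]))

  pca_scores <- .stage("pca_screen", pca_outlier_screen(
    normalized, sd_limit = config$pca_sd_limit))
  excluded <- unique(pca_scores$sample_id[pca_scores$outlier])
  normalized <- normalized[!normalized$sample_id %in% excluded, ,
                           drop = FALSE]

  md_study <- inputs$metadata[inputs$metadata$role == "study" &
                                !inputs$metadata$sample_id %in% excluded, ,
                              drop = FALSE]
  design <- md_study[, c("sample_id", "participant_id", "compartment",
                         "motility_pct")]
  has_motility <- !anyNA(design$motility_pct)
  if (has_motility) design <- split_by_median_motility(design)

  cps <- sort(unique(design$compartment))
  pairs <- utils::combn(cps, 2, simplify = FALSE)
  results <- .stage("differential_tests", dplyr::bind_rows(
    purrr::map(pairs, function(pr) {
      test_compartments(normalized, design, compartments = pr,
                        alpha = config$alpha)
    }),
    if (has_motility) purrr::map(cps, function(cp) {
      test_motility_groups(normalized, design, compartment = cp,
                           alpha = config$alpha)
    })
  ))

  classes <- .stage("class_aggregation", aggregate_by_class(normalized))
  volcano <- volcano_table(results)

  counts <- filt$report |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(n_annotated = dplyr::n(), n_kept = sum(.data$kept),
                     .groups = "drop")
  manifest <- c(
    paste0("lipidims_version=", as.character(utils::packageVersion("lipidims"))),
    paste0("library=", config$library_path),
    paste0("peaklists=", config$peaklists_dir),
    paste0("metadata=", config$metadata_path),
    paste0("tolerance_ppm=", config$tolerance_ppm),
    paste0("snr_min=", config$snr_min),
    paste0("presence_min=", config$presence_min),
    paste0("r_min=", config$r_min),
    paste0("alpha=", config$alpha),
    paste0("pca_sd_limit=", config$pca_sd_limit),
    paste0("priorities_positive=",
           paste(config$priorities$positive, collapse = ";")),
    paste0("priorities_negative=",
           paste(config$priorities$negative, collapse = ";")),
    paste0("n_samples_study=", length(study_ids)),
    paste0("n_samples_excluded_pca=", length(excluded)),
    paste0("variables_pre_filter_", counts$channel, "=",
           counts$n_annotated),
    paste0("variables_post_filter_", counts$channel, "=", counts$n_kept)
  )

  out <- config$out_dir
  readr::write_tsv(filt$report, file.path(out, "filter_report.tsv"),
                   progress = FALSE)
  readr::write_tsv(normalized, file.path(out, "normalized.tsv"),
                   progress = FALSE)
  readr::write_tsv(pca_scores, file.path(out, "pca_scores.tsv"),
                   progress = FALSE)
  readr::write_tsv(design, file.path(out, "design.tsv"), progress = FALSE)
  readr::write_tsv(results, file.path(out, "differential_results.tsv"),
                   progress = FALSE)
  readr::write_tsv(classes, file.path(out, "class_abundance.tsv"),
                   progress = FALSE)
  readr::write_csv(volcano, file.path(out, "volcano.csv"),
                   progress = FALSE)
  readr::write_csv(volcano_excluded(volcano),
                   file.path(out, "volcano_excluded.csv"), progress = FALSE)
  writeLines(manifest, file.path(out, "manifest.txt"))

  invisible(structure(
    list(annotations = ann, filter = filt, normalized = normalized,
         pca_scores = pca_scores, excluded_samples = excluded,
         design = design, results = results, classes = classes,
         volcano = volcano, manifest = manifest, config = config),
    class = "dims_run"))
}

#' @export
print.dims_run <- function(x, ...) {
  cat("<dims_run>\n")
  cat(" ", nrow(x$filter$report), "annotated variables,",
      sum(x$filter$report$kept), "kept\n")
  cat(" ", length(unique(x$normalized$sample_id)), "study samples (",
      length(x$excluded_samples), "excluded by PCA )\n")
  cat(" ", nrow(x$results), "differential tests,",
      sum(x$results$significant), "significant\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `dims_run`.
#' @param ... Unused.
#' @export
glance.dims_run <- function(x, ...) {
  tibble::tibble(
    n_variables_annotated = nrow(x$filter$report),
    n_variables_kept = sum(x$filter$report$kept),
    n_samples = length(unique(x$normalized$sample_id)),
    n_excluded_pca = length(x$excluded_samples),
    n_tests = nrow(x$results),
    n_significant = sum(x$results$significant)
  )
}

#' @rdname run_pipeline
#' @export
tidy.dims_run <- function(x, ...) x$results
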