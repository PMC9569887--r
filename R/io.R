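#' Read and write lipid library CSVs
#'
#' The library interchange format is a UTF-8 CSV with a header row and
#' columns `name`, `neutral_mass_da`, `channels` (semicolon-separated)
#' and `adducts` (semicolon-separated).
#'
#' @param path File path.
#' @param library A library tibble.
#' @return `read_lipid_library()` returns the validated library tibble;
#'   `write_lipid_library()` returns `path` invisibly.
#' @export
read_lipid_library <- function(path) {
  lib <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("name", "neutral_mass_da", "channels", "adducts")
  if (!all(need %in% names(lib))) {
    abort(paste0(path, ": library must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (any(lib$neutral_mass_da <= 0)) {
    abort(paste0(path, ": non-positive neutral mass"))
  }
  parse_lipid_name(lib$name)  # every name must be parseable
  tibble::as_tibble(lib)
}

#' @rdname read_lipid_library
#' @export
write_lipid_library <- function(library, path) {
  readr::write_csv(library, path, progress = FALSE)
  invisible(path)
}

#' Read and write per-sample peak-list CSVs
#'
#' Each sample and channel is one CSV named
#' `<sample_id>__<channel>.csv` with columns `mz`, `intensity`. An empty
#' peak-list file yields no peaks for that sample, with a warning.
#'
#' @param dir Directory holding the peak-list files.
#' @param peaks A long peak table (`sample_id`, `channel`, `mz`,
#'   `intensity`).
#' @return `read_peak_lists()` returns the combined long peak tibble,
#'   sorted by m/z within sample and channel; `write_peak_lists()`
#'   returns `dir` invisibly.
#' @export
read_peak_lists <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("no peak-list CSVs in ", dir))
  out <- purrr::map(files, function(f) {
    key <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(key, "__", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      abort(paste0(f, ": file name must be <sample_id>__<channel>.csv"))
    }
    d <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    if (nrow(d) == 0) {
      warn(paste0(f, ": empty peak list"))
      return(NULL)
    }
    if (!all(c("mz", "intensity") %in% names(d))) {
      abort(paste0(f, ": peak list needs columns mz, intensity"))
    }
    if (any(d$mz <= 0) || any(d$intensity < 0)) {
      abort(paste0(f, ": invalid mz or intensity values"))
    }
    tibble::tibble(sample_id = parts[1], channel = parts[2],
                   mz = d$mz, intensity = d$intensity)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$sample_id, .data$channel, .data$mz)
}

#' @rdname read_peak_lists
#' @export
write_peak_lists <- function(peaks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::walk(split(peaks, paste0(peaks$sample_id, "__", peaks$channel)),
              function(d) {
    f <- file.path(dir, paste0(d$sample_id[1], "__", d$channel[1], ".csv"))
    readr::write_csv(d[order(d$mz), c("mz", "intensity")], f,
                     progress = FALSE)
  })
  invisible(dir)
}

#' Read and validate sample metadata
#'
#' Metadata is a CSV with columns `sample_id`, `participant_id`,
#' `compartment`, `role` (`study`/`qc`/`blank`), `dilution` (QC rows) and
#' `motility_pct`. Duplicate sample ids, unknown roles, unknown
#' compartment labels and QC rows without a dilution factor are hard
#' errors.
#'
#' @param path File path.
#' @param compartments Allowed compartment labels.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path,
                                 compartments = c("serum", "seminal_fluid",
                                                  "sperm")) {
  md <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "participant_id", "compartment", "role",
            "dilution", "motility_pct")
  if (!all(need %in% names(md))) {
    abort(paste0(path, ": metadata must have columns ",
                 paste(need, collapse = ", ")))
  }
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup) > 0) {
    abort(paste0(path, ": duplicated sample id(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!all(md$role %in% c("study", "qc", "blank"))) {
    abort(paste0(path, ": unknown role(s): ",
                 paste(setdiff(unique(md$role),
                               c("study", "qc", "blank")), collapse = ", ")))
  }
  bad_cp <- setdiff(stats::na.omit(md$compartment[md$role == "study"]),
                    compartments)
  if (length(bad_cp) > 0 ||
      anyNA(md$compartment[md$role == "study"])) {
    abort(paste0(path, ": unknown or missing compartment label(s): ",
                 paste(bad_cp, collapse = ", ")))
  }
  if (anyNA(md$dilution[md$role == "qc"])) {
    abort(paste0(path, ": QC rows must carry a dilution factor"))
  }
  tibble::as_tibble(md)
}

#' @rdname read_sample_metadata
#' @param metadata A metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_csv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Write a complete simulated run directory
#'
#' Generates a library, cohort and peak lists from `spec` and writes the
#' full input set for [run_pipeline()]: `library.csv`, `metadata.csv`,
#' per-sample peak lists under `peaklists/`, plus the ground truth
#' (`ground_truth.tsv`, `design.tsv`) and the flat spec capture
#' (`spec.txt`) for provenance.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return The `sim_cohort` object, invisibly.
#' @export
simulate_run <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(spec)
  rendered <- simulate_peaklists(cohort)
  write_lipid_library(cohort$library, file.path(dir, "library.csv"))
  write_sample_metadata(rendered$metadata, file.path(dir, "metadata.csv"))
  write_peak_lists(rendered$peaks, file.path(dir, "peaklists"))
  readr::write_tsv(cohort$truth, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$design, file.path(dir, "design.tsv"),
                   progress = FALSE)
  flat <- spec[!vapply(spec, is.null, logical(1))]
  flat <- flat[!names(flat) %in% "spikes"]
  writeLines(paste0(names(flat), "=",
                    vapply(flat, function(x) paste(x, collapse = ";"),
                           character(1))),
             file.path(dir, "spec.txt"))
  if (!is.null(spec$spikes)) {
    readr::write_tsv(tibble::as_tibble(spec$spikes),
                     file.path(dir, "spikes.tsv"), progress = FALSE)
  }
  invisible(cohort)
}
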