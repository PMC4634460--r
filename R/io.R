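#' Read a PPG signal from CSV
#'
#' Reads a two-column CSV of `(time_s, amplitude)`. Lines starting with `#`
#' are comments. The sampling rate is inferred from the median time step
#' unless overridden.
#'
#' @param path CSV file path.
#' @param fs_override Optional sampling rate in Hz, bypassing inference.
#' @param subject_id,stage Metadata attached to the record.
#' @return A [ppg_record()].
#' @export
read_ppg_record <- function(path, fs_override = NULL, subject_id = "S01", stage = "BE") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double())),
    error = function(e) stop("cannot parse signal CSV: ", conditionMessage(e), call. = FALSE)
  )
  if (ncol(df) < 2L || nrow(df) < 3L) {
    stop("signal CSV must have 2 numeric columns and at least 3 rows", call. = FALSE)
  }
  tm <- df[[1L]]
  amp <- df[[2L]]
  if (anyNA(tm) || anyNA(amp)) stop("signal CSV contains non-numeric values", call. = FALSE)
  dt <- diff(tm)
  if (any(dt <= 0)) stop("time column must be strictly increasing", call. = FALSE)
  fs <- fs_override %||% (1 / median(dt))
  ppg_record(amp, fs, subject_id = subject_id, stage = stage)
}

#' Write a PPG record to CSV
#'
#' Two columns `time_s, amplitude`; a `#` comment header records the
#' sampling rate and metadata.
#'
#' @param record A [ppg_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ppg_record <- function(record, path) {
  stopifnot(inherits(record, "ppg_record"))
  hdr <- c(sprintf("# fs_hz: %.10g", record$fs),
           sprintf("# subject_id: %s", record$subject_id),
           sprintf("# stage: %s", record$stage))
  writeLines(hdr, path)
  df <- tibble::tibble(time_s = (seq_len(record$n_samples) - 1) / record$fs,
                       amplitude = record$samples)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a/b-wave annotations from CSV
#'
#' Columns `beat_index, a_index, b_index` with 0-based sample indices; `#`
#' lines are comments; the final beat's `b_index` may be empty. Indices are
#' validated against the record length and the a/b interleaving rule, and
#' an invalid file is rejected with an error naming the offending beat.
#'
#' @param path CSV file path.
#' @param n_samples Length of the record the annotations belong to.
#' @return A [fiducial_set()].
#' @export
read_fiducials <- function(path, n_samples) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  if (!all(c("beat_index", "a_index", "b_index") %in% names(df))) {
    stop("annotation CSV needs columns beat_index, a_index, b_index", call. = FALSE)
  }
  a <- df$a_index
  b <- df$b_index[!is.na(df$b_index)]
  if (any(a != round(a)) || any(b != round(b))) {
    stop("annotation indices must be integers", call. = FALSE)
  }
  fiducial_set(a, b, n_samples = n_samples)
}

#' Write a/b-wave annotations to CSV
#'
#' @param fiducials A [fiducial_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  writeLines("# 0-based sample indices; b_index of the final beat may be empty", path)
  b <- fiducials$b
  if (length(b) < fiducials$n_beats) b <- c(b, NA_integer_)
  df <- tibble::tibble(beat_index = seq_len(fiducials$n_beats) - 1L,
                       a_index = fiducials$a, b_index = b)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Writes one signal CSV and one annotation CSV per record plus a manifest
#' CSV (`subject_id, stage, signal_path, annotation_path`) that
#' [read_cohort()] consumes.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::pmap(cohort, function(subject_id, stage, record, fiducials, ...) {
    base <- sprintf("%s_%s", subject_id, stage)
    sp <- file.path(dir, paste0(base, "_signal.csv"))
    ap <- file.path(dir, paste0(base, "_ab.csv"))
    write_ppg_record(record, sp)
    write_fiducials(fiducials, ap)
    tibble::tibble(subject_id = subject_id, stage = as.character(stage),
                   signal_path = basename(sp), annotation_path = basename(ap))
  }) |> purrr::list_rbind()
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(entries, manifest)
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a manifest CSV written by [write_cohort()];
#'   relative signal/annotation paths resolve against its directory.
#' @return Cohort tibble with columns `subject_id`, `stage`, `record`,
#'   `fiducials`.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  need <- c("subject_id", "stage", "signal_path", "annotation_path")
  if (!all(need %in% names(man))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(man[, c("subject_id", "stage")])) {
    stop("duplicate (subject_id, stage) entries in manifest", call. = FALSE)
  }
  root <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  out <- purrr::pmap(man, function(subject_id, stage, signal_path, annotation_path, ...) {
    rec <- read_ppg_record(resolve(signal_path), subject_id = subject_id, stage = stage)
    fid <- read_fiducials(resolve(annotation_path), n_samples = rec$n_samples)
    tibble::tibble(subject_id = subject_id, stage = stage,
                   record = list(rec), fiducials = list(fid))
  }) |> purrr::list_rbind()
  out$stage <- factor(out$stage, levels = intersect(ppg_stages(), unique(out$stage)))
  out
}
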