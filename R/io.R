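#' Subject metadata
#'
#' @param subject_id Identifier string.
#' @param age Years. @param height Centimetres. @param weight Kilograms.
#' @param gender Free text, preserved verbatim.
#' @return A list of class `subject_metadata`.
#' @export
subject_metadata <- function(subject_id, age = NA_real_, height = NA_real_,
                             weight = NA_real_, gender = NA_character_) {
  for (v in c(age = age, height = height, weight = weight)) {
    if (!is.na(v) && v < 0) abort("Metadata numerics must be non-negative.")
  }
  structure(
    list(
      subject_id = subject_id, age = age, height = height,
      weight = weight, gender = gender
    ),
    class = "subject_metadata"
  )
}

rec_filename <- function(rec) {
  paste0(rec_scenario(rec), "_", rec_channel(rec), ".csv")
}

#' Write a session to the canonical on-disk layout
#'
#' Layout: `dir_path/<subject_id>/<scenario>_<channel>.csv` (columns
#' `t_seconds,mv`, header row, `.` decimal), `meta.yaml` with the subject
#' metadata and sampling rate, and `manifest.csv` listing every signal file
#' with its SHA-256 checksum so readers can verify integrity.
#'
#' @param recordings Named list of [new_recording()] objects sharing one
#'   subject id.
#' @param metadata A [subject_metadata()] (defaults to id-only metadata).
#' @param dir_path Output directory; the subject subdirectory is created.
#' @param overwrite Allow writing into an existing non-empty subject
#'   directory.
#' @return Path of the written manifest, invisibly usable in pipelines.
#' @export
write_session <- function(recordings, metadata = NULL, dir_path,
                          overwrite = FALSE) {
  ids <- unique(vapply(recordings, rec_subject, character(1)))
  if (length(ids) != 1) abort("All recordings must share one subject_id.")
  metadata <- metadata %||% subject_metadata(ids)
  sub_dir <- file.path(dir_path, ids)
  if (dir.exists(sub_dir) && length(dir(sub_dir)) > 0 && !overwrite) {
    abort(sprintf(
      "Directory '%s' is not empty; use `overwrite = TRUE` to replace it.", sub_dir
    ))
  }
  dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (rec in recordings) {
    f <- rec_filename(rec)
    readr::write_csv(tibble(t_seconds = rec$t_seconds, mv = rec$mv),
      file.path(sub_dir, f)
    )
    files <- c(files, f)
  }
  fs_all <- unique(vapply(recordings, rec_fs, numeric(1)))
  yaml::write_yaml(
    list(
      subject_id = metadata$subject_id, age = metadata$age,
      height = metadata$height, weight = metadata$weight,
      gender = metadata$gender, fs = fs_all[[1]]
    ),
    file.path(sub_dir, "meta.yaml")
  )
  manifest <- tibble(
    file = files,
    sha256 = vapply(files, function(f) {
      digest::digest(file = file.path(sub_dir, f), algo = "sha256")
    }, character(1))
  )
  manifest_path <- file.path(sub_dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  invisible(manifest_path)
}

parse_signal_file <- function(path, fs, subject_id) {
  header <- readLines(path, n = 1)
  if (!identical(header, "t_seconds,mv")) {
    abort(sprintf(
      "Malformed header in '%s' (line 1: '%s'); expected 't_seconds,mv'.",
      basename(path), header
    ))
  }
  base <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  dat <- readr::read_csv(path,
    col_types = readr::cols(
      t_seconds = readr::col_double(), mv = readr::col_double()
    ), progress = FALSE
  )
  mv <- dat$mv
  dropouts <- tibble(start_sample = integer(0), end_sample = integer(0))
  if (anyNA(mv)) {
    # NaN dialect for contact loss: zero the samples and record the spans
    na_run <- rle(is.na(mv))
    ends <- cumsum(na_run$lengths)
    starts <- ends - na_run$lengths + 1L
    keep <- na_run$values
    dropouts <- tibble(
      start_sample = starts[keep], end_sample = ends[keep] + 1L
    )
    mv[is.na(mv)] <- 0
  }
  rec <- new_recording(mv,
    fs = fs, channel = parts[2], scenario = parts[1],
    subject_id = subject_id
  )
  list(rec = rec, dropouts = dropouts)
}

#' Read a session from the canonical layout
#'
#' Inverse of [write_session()]. Every file listed in the manifest is
#' checksum-verified before parsing; a mismatch raises an integrity error
#' naming the file. Missing scenario files produce a partial-session warning
#' and the remaining recordings are returned. `NaN` samples on the wheel
#' channel are converted to 0 mV and reported as synthetic dropout spans.
#'
#' @param sub_dir A subject directory written by [write_session()].
#' @return A list: `recordings` (named list), `metadata`
#'   ([subject_metadata()]), `dropouts` (tibble `file`, `start_sample`,
#'   `end_sample`).
#' @export
read_session <- function(sub_dir) {
  meta_path <- file.path(sub_dir, "meta.yaml")
  manifest_path <- file.path(sub_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    warn(sprintf("No manifest in '%s'; returning an empty session.", sub_dir))
    return(list(
      recordings = list(), metadata = NULL,
      dropouts = tibble(file = character(0), start_sample = integer(0), end_sample = integer(0))
    ))
  }
  meta_raw <- yaml::read_yaml(meta_path)
  fs <- meta_raw$fs %||% 500
  if (!is.numeric(fs) || fs <= 0) {
    abort(sprintf("Stated sampling rate (%s) must be positive.", format(fs)))
  }
  metadata <- subject_metadata(
    meta_raw$subject_id,
    age = meta_raw$age %||% NA_real_, height = meta_raw$height %||% NA_real_,
    weight = meta_raw$weight %||% NA_real_,
    gender = meta_raw$gender %||% NA_character_
  )
  manifest <- readr::read_csv(manifest_path,
    col_types = readr::cols(
      file = readr::col_character(), sha256 = readr::col_character()
    ), progress = FALSE
  )
  recordings <- list()
  dropouts <- list()
  for (i in seq_len(nrow(manifest))) {
    f <- manifest$file[i]
    path <- file.path(sub_dir, f)
    if (!file.exists(path)) {
      warn(sprintf("Missing signal file '%s'; returning a partial session.", f))
      next
    }
    observed <- digest::digest(file = path, algo = "sha256")
    if (!identical(observed, manifest$sha256[i])) {
      abort(sprintf("Checksum mismatch for '%s'; file is corrupt or modified.", f))
    }
    parsed <- parse_signal_file(path, fs, metadata$subject_id)
    recordings[[sub("\\.csv$", "", f)]] <- parsed$rec
    if (nrow(parsed$dropouts)) {
      dropouts[[f]] <- mutate(parsed$dropouts, file = f, .before = 1)
    }
  }
  list(
    recordings = recordings, metadata = metadata,
    dropouts = if (length(dropouts)) {
      bind_rows(dropouts)
    } else {
      tibble(file = character(0), start_sample = integer(0), end_sample = integer(0))
    }
  )
}

#' Write / read beat annotations as CSV
#'
#' Two columns, `sample_index` (1-based) and `provenance`; the round trip is
#' exact. Unsorted or duplicated indices are rejected.
#'
#' @param ann A [new_annotation()].
#' @param path CSV path.
#' @return `path`, invisibly (writer); a [new_annotation()] (reader).
#' @export
write_annotations <- function(ann, path) {
  idx <- ann_peaks(ann)
  if (length(idx) > 1 && any(diff(idx) <= 0)) {
    abort("Annotation indices must be strictly increasing.")
  }
  readr::write_csv(
    tibble(sample_index = idx, provenance = ann$provenance),
    path
  )
  invisible(path)
}

#' @rdname write_annotations
#' @param fs Sampling rate to attach to the annotation read back.
#' @export
read_annotations <- function(path, fs = 500) {
  dat <- readr::read_csv(path,
    col_types = readr::cols(
      sample_index = readr::col_integer(), provenance = readr::col_character()
    ), progress = FALSE
  )
  ann <- new_annotation(dat$sample_index, fs,
    provenance = if (nrow(dat)) dat$provenance[[1]] else "truth"
  )
  ann$provenance <- dat$provenance
  ann
}

#' Adapter stub for the deposited study recordings
#'
#' The published steering-wheel ECG dataset's on-disk structure is not part
#' of this package's canonical format; importing it requires a custom
#' adapter. This stub documents the extension point: implement a converter
#' from the deposited files to [new_recording()] objects and pass the result
#' to the pipeline functions directly.
#'
#' @param dir Path to a local copy of the deposited dataset.
#' @export
import_external_session <- function(dir) {
  abort(paste(
    "No adapter for the deposited dataset is bundled: its file structure is",
    "not part of the canonical format. Convert the files to",
    "`new_recording()` objects (or the `write_session()` layout) and use",
    "the pipeline functions directly."
  ))
}
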