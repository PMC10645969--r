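#' Write a cohort to CSV files
#'
#' The canonical on-disk format is a pair of CSV files: a spectra file whose
#' header row carries the wavenumber grid and whose data rows are
#' `(patient_id, replicate_index, absorbances...)`, and a metadata file with
#' one row per patient `(patient_id, group, stage, sex, age)`. Absorbances
#' are serialized with 12 significant digits, so a write/read round trip
#' reproduces the cohort to well below 1e-9 absorbance.
#'
#' @param cohort A `cohort`.
#' @param spectra_path,metadata_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, spectra_path, metadata_path) {
  if (!inherits(cohort, "cohort")) stop("`cohort` must be a cohort object")
  grid <- as.numeric(cohort$grid)
  con <- file(spectra_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("patient_id", "replicate_index",
                     format(grid, trim = TRUE, digits = 9)), collapse = ","),
             con)
  for (p in cohort$patients) {
    for (j in seq_len(nrow(p$spectra))) {
      vals <- formatC(p$spectra[j, ], digits = 12, format = "g")
      writeLines(paste(c(p$patient_id, j, vals), collapse = ","), con)
    }
  }
  meta <- cohort_metadata(cohort)
  utils::write.csv(meta[, c("patient_id", "group", "stage", "sex", "age")],
                   metadata_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(spectra_path, metadata_path))
}

#' Read a cohort from CSV files
#'
#' Validates the files into the domain model: the wavenumber header must be
#' strictly descending and positive, absorbances must be finite, every
#' spectrum's patient must appear in the metadata file, and
#' `(patient_id, replicate_index)` pairs must be unique. In strict mode all
#' patients must carry the same number of replicate spectra (the configured
#' count if given, otherwise the most common count in the file).
#'
#' @param spectra_path,metadata_path Input CSV paths, as written by
#'   [write_cohort()].
#' @param spectra_per_patient Expected replicate count, or `NULL` to infer.
#' @param strict If `TRUE` (default), unequal replicate counts are an error
#'   naming the offending patients; if `FALSE`, ragged cohorts are allowed.
#' @return A `cohort`.
#' @export
read_cohort <- function(spectra_path, metadata_path,
                        spectra_per_patient = NULL, strict = TRUE) {
  spec <- utils::read.csv(spectra_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(spec) < 4 ||
      !identical(names(spec)[1:2], c("patient_id", "replicate_index"))) {
    stop("spectra file must start with patient_id,replicate_index columns")
  }
  grid <- suppressWarnings(as.numeric(names(spec)[-(1:2)]))
  if (any(is.na(grid))) stop("spectra header contains non-numeric wavenumbers")
  if (any(diff(grid) >= 0)) {
    stop("wavenumber grid in spectra file is not strictly descending")
  }
  grid <- validate_grid(grid)
  vals <- as.matrix(spec[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(!is.finite(vals))) stop("spectra contain non-finite absorbances")
  key <- paste(spec$patient_id, spec$replicate_index)
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, replicate_index): ", key[duplicated(key)][1])
  }
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE, na = "")
  need <- c("patient_id", "group", "stage", "sex", "age")
  if (!all(need %in% names(meta))) {
    stop("metadata file must contain columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(unique(spec$patient_id), meta$patient_id)
  if (length(missing)) {
    stop("patients present in spectra but missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  counts <- table(spec$patient_id)
  expected <- if (!is.null(spectra_per_patient)) spectra_per_patient
              else as.integer(names(sort(table(counts), decreasing = TRUE))[1])
  if (strict && any(counts != expected)) {
    bad <- names(counts)[counts != expected]
    stop("replicate count differs from ", expected, " for patient(s): ",
         paste(bad, collapse = ", "))
  }
  meta <- meta[meta$patient_id %in% spec$patient_id, , drop = FALSE]
  patients <- lapply(seq_len(nrow(meta)), function(i) {
    rows <- which(spec$patient_id == meta$patient_id[i])
    rows <- rows[order(spec$replicate_index[rows])]
    stage <- meta$stage[i]
    structure(list(patient_id = meta$patient_id[i], group = meta$group[i],
                   stage = if (is.na(stage) || stage == "") NA_character_
                           else stage,
                   sex = meta$sex[i], age = meta$age[i],
                   spectra = vals[rows, , drop = FALSE]),
              class = "patient_record")
  })
  names(patients) <- meta$patient_id
  new_cohort(grid, patients)
}

#' Export one spectrum as JCAMP-DX
#'
#' Minimal JCAMP-DX 4.24 writer (`##XYDATA=(XY..XY)` untabulated pairs) for
#' interoperability with spectroscopy viewers. One spectrum per file.
#'
#' @param values Absorbance vector.
#' @param grid Matching `wavenumber_grid`.
#' @param path Output path.
#' @param title Spectrum title recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_jcampdx <- function(values, grid, path, title = "spectrum") {
  grid <- validate_grid(grid)
  if (length(values) != length(grid)) stop("values/grid length mismatch")
  lines <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    paste0("##FIRSTX=", format(grid[1], digits = 9)),
    paste0("##LASTX=", format(grid[length(grid)], digits = 9)),
    paste0("##NPOINTS=", length(grid)),
    "##XYDATA=(XY..XY)",
    paste(format(as.numeric(grid), trim = TRUE, digits = 9),
          formatC(values, digits = 9, format = "g"), sep = ", "),
    "##END="
  )
  writeLines(lines, path)
  invisible(path)
}
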