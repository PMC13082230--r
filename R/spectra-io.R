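#' Construct a single-cell Raman spectrum
#'
#' A spectrum is one cell's wavenumber/intensity trace plus acquisition
#' metadata and a provenance record of applied preprocessing steps.
#'
#' @param wavenumber numeric, strictly increasing Raman shift axis (cm^-1).
#' @param intensity numeric, same length as `wavenumber`, arbitrary units.
#' @param cell_id cell identifier, unique within a set.
#' @param sample_group free-text sample/group label.
#' @param isotope_condition one of `"none"`, `"12C"`, `"13C"` — the carbon
#'   source the cell was incubated with.
#' @param preprocessing_steps character vector of already-applied step names.
#' @return an object of class `raman_spectrum`.
#' @export
#' @examples
#' s <- raman_spectrum(500:520, runif(21), cell_id = "c1")
#' s
raman_spectrum <- function(wavenumber, intensity, cell_id = "cell",
                           sample_group = NA_character_,
                           isotope_condition = "none",
                           preprocessing_steps = character()) {
  s <- structure(
    list(
      cell_id = as.character(cell_id)[1L],
      wavenumber = as.numeric(wavenumber),
      intensity = as.numeric(intensity),
      meta = list(
        sample_group = as.character(sample_group)[1L],
        isotope_condition = isotope_condition,
        preprocessing_steps = as.character(preprocessing_steps)
      )
    ),
    class = "raman_spectrum"
  )
  validate_spectrum(s)
}

#' Validate a raman_spectrum
#'
#' Checks finiteness, equal axis/intensity lengths, a strictly increasing
#' axis, and a recognized isotope condition. Returns the object invisibly
#' unchanged so it can be used in pipelines.
#'
#' @param s a `raman_spectrum`.
#' @return `s`, invisibly.
#' @export
validate_spectrum <- function(s) {
  if (!inherits(s, "raman_spectrum"))
    abort("not a raman_spectrum", "sipraman_validation_error")
  x <- s$wavenumber
  y <- s$intensity
  if (length(x) != length(y))
    abort("axis and intensity lengths differ", "sipraman_validation_error")
  if (length(x) < 2L)
    abort("spectrum needs at least 2 points", "sipraman_validation_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    abort("non-finite values in spectrum", "sipraman_validation_error")
  if (any(diff(x) <= 0))
    abort("wavenumber axis must be strictly increasing",
          "sipraman_validation_error")
  if (!s$meta$isotope_condition %in% c("none", "12C", "13C"))
    abort("isotope_condition must be one of none/12C/13C",
          "sipraman_validation_error")
  invisible(s)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum> cell '%s': %d points, %.1f-%.1f cm-1, condition %s\n",
    x$cell_id, length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
    x$meta$isotope_condition))
  if (length(x$meta$preprocessing_steps))
    cat("  preprocessing:", paste(x$meta$preprocessing_steps, collapse = " -> "),
        "\n")
  invisible(x)
}

append_step <- function(s, step) {
  s$meta$preprocessing_steps <- c(s$meta$preprocessing_steps, step)
  s
}

#' Construct a set of single-cell spectra
#'
#' @param spectra list of `raman_spectrum` objects with unique cell ids
#'   (may be empty).
#' @param set_id identifier for the cohort.
#' @param provenance optional list of free-form provenance notes (e.g.
#'   simulator seed and configuration).
#' @return an object of class `raman_set`.
#' @export
raman_set <- function(spectra = list(), set_id = "set", provenance = NULL) {
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  for (s in spectra) validate_spectrum(s)
  ids <- vapply(spectra, function(s) s$cell_id, character(1))
  if (anyDuplicated(ids))
    abort("cell_ids must be unique within a set", "sipraman_validation_error")
  names(spectra) <- ids
  structure(list(spectra = spectra, set_id = set_id, provenance = provenance),
            class = "raman_set")
}

#' @export
print.raman_set <- function(x, ...) {
  cat(sprintf("<raman_set> '%s': %d cells\n", x$set_id, length(x$spectra)))
  cond <- table(vapply(x$spectra, function(s) s$meta$isotope_condition,
                       character(1)))
  if (length(cond))
    cat("  isotope conditions:",
        paste(sprintf("%s=%d", names(cond), cond), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.raman_set <- function(x) length(x$spectra)

manifest_path_for <- function(path) {
  if (grepl("\\.(csv|tsv)$", path, ignore.case = TRUE))
    sub("\\.(csv|tsv)$", ".manifest.json", path, ignore.case = TRUE)
  else paste0(path, ".manifest.json")
}

set_manifest <- function(set) {
  cells <- lapply(set$spectra, function(s) list(
    sample_group = s$meta$sample_group,
    isotope_condition = s$meta$isotope_condition,
    preprocessing_steps = as.list(s$meta$preprocessing_steps)
  ))
  list(set_id = set$set_id, cells = cells,
       provenance = set$provenance)
}

#' Write a spectrum set to long-format CSV with a sibling JSON manifest
#'
#' Rows are ordered deterministically by `cell_id`, then wavenumber. Values
#' round-trip at full double precision. The manifest (set id, per-cell
#' metadata, provenance) is written next to the CSV as
#' `<stem>.manifest.json`.
#'
#' @param set a `raman_set`.
#' @param path output CSV path (`.tsv` extension switches to tab-separated).
#' @return the manifest path, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  if (!inherits(set, "raman_set"))
    abort("set must be a raman_set", "sipraman_validation_error")
  if (!dir.exists(dirname(path)))
    abort(sprintf("directory does not exist: %s", dirname(path)),
          "sipraman_io_error")
  if (length(set$spectra)) {
    ids <- sort(names(set$spectra))
    df <- do.call(rbind, lapply(ids, function(id) {
      s <- set$spectra[[id]]
      data.frame(cell_id = id, wavenumber_cm1 = s$wavenumber,
                 intensity = s$intensity, stringsAsFactors = FALSE)
    }))
  } else {
    df <- data.frame(cell_id = character(), wavenumber_cm1 = numeric(),
                     intensity = numeric())
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("cannot write %s", path), "sipraman_io_error")
  mpath <- manifest_path_for(path)
  jsonlite::write_json(set_manifest(set), mpath, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(mpath)
}

#' Read single-cell spectra from long-format CSV/TSV
#'
#' Expects columns `cell_id`, `wavenumber_cm1`, `intensity`. Per-cell axes
#' are sorted ascending; metadata is merged from the JSON manifest when one
#' is given or found next to the file (`<stem>.manifest.json`).
#'
#' @param path CSV or TSV file.
#' @param manifest_path optional manifest JSON; defaults to the sibling
#'   manifest if it exists.
#' @return a `raman_set`.
#' @export
read_spectra_csv <- function(path, manifest_path = NULL) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "sipraman_io_error")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "wavenumber_cm1", "intensity")
  if (!all(need %in% names(df)))
    abort(sprintf("missing column(s): %s",
                  paste(setdiff(need, names(df)), collapse = ", ")),
          "sipraman_format_error")
  manifest <- NULL
  if (is.null(manifest_path)) {
    mp <- manifest_path_for(path)
    if (file.exists(mp)) manifest_path <- mp
  }
  if (!is.null(manifest_path) && file.exists(manifest_path))
    manifest <- jsonlite::read_json(manifest_path)
  if (nrow(df) == 0L)
    return(raman_set(list(),
                     set_id = manifest$set_id %||%
                       tools::file_path_sans_ext(basename(path)),
                     provenance = manifest$provenance))
  if (!is.numeric(df$wavenumber_cm1) || !is.numeric(df$intensity) ||
      !all(is.finite(df$wavenumber_cm1)) || !all(is.finite(df$intensity)))
    abort("non-finite or non-numeric wavenumber/intensity values",
          "sipraman_validation_error")
  if (anyDuplicated(df[c("cell_id", "wavenumber_cm1")]))
    abort("duplicate (cell_id, wavenumber) rows", "sipraman_validation_error")
  spectra <- lapply(sort(unique(df$cell_id)), function(id) {
    sub <- df[df$cell_id == id, ]
    o <- order(sub$wavenumber_cm1)
    meta <- manifest$cells[[id]]
    raman_spectrum(
      sub$wavenumber_cm1[o], sub$intensity[o], cell_id = id,
      sample_group = meta$sample_group %||% NA_character_,
      isotope_condition = meta$isotope_condition %||% "none",
      preprocessing_steps = unlist(meta$preprocessing_steps) %||% character()
    )
  })
  raman_set(spectra,
            set_id = manifest$set_id %||%
              tools::file_path_sans_ext(basename(path)),
            provenance = manifest$provenance)
}
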