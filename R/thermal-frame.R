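#' Thermal frame: a per-pixel temperature grid with sample metadata
#'
#' A `thermal_frame` wraps a numeric matrix of surface temperatures (degrees
#' Celsius), row-major with row 1 the top image row, together with a sample
#' identifier and treatment metadata. It is the raw input of the pipeline:
#' one frame per leaf image, typically 480 rows by 640 columns as exported
#' by radiometric thermal cameras.
#'
#' @param values Numeric matrix of temperatures in degrees Celsius. Grids of
#'   any rectangular shape parse; the spectral and gradient stages
#'   additionally require at least 8 x 8 pixels.
#' @param sample_id Character scalar identifying the sample.
#' @param genotype,treatment,timepoint,drought_stage Sample metadata.
#'   `treatment` must be one of `"WW"`, `"DD"`, `"unknown"`; `timepoint` one
#'   of `"predawn"`, `"midday"`, `"unknown"`; `drought_stage` one of
#'   `"mild"`, `"severe"`, `"none"`, `"unknown"`.
#' @param range_check Length-2 numeric giving the plausible temperature range
#'   in degrees Celsius, or `NULL` to disable the check. Rejects mis-parsed
#'   files (e.g. raw sensor counts read as temperatures).
#'
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(values, sample_id = "sample",
                          genotype = "unknown", treatment = "unknown",
                          timepoint = "unknown", drought_stage = "unknown",
                          range_check = c(-40, 120)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix.", class = "thermoleaf_format_error")
  }
  if (length(values) == 0L) {
    rlang::abort("frame must be non-empty", class = "thermoleaf_size_error")
  }
  if (!all(is.finite(values))) {
    rlang::abort("frame contains non-finite temperatures", class = "thermoleaf_validation_error")
  }
  if (!is.null(range_check)) {
    bad <- values < range_check[1] | values > range_check[2]
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      rlang::abort(
        sprintf(
          "temperature %.3f at (row %d, col %d) outside plausible range [%g, %g] degC",
          values[idx[1], idx[2]], idx[1], idx[2], range_check[1], range_check[2]
        ),
        class = "thermoleaf_validation_error"
      )
    }
  }
  treatment <- rlang::arg_match0(treatment, c("WW", "DD", "unknown"))
  timepoint <- rlang::arg_match0(timepoint, c("predawn", "midday", "unknown"))
  drought_stage <- rlang::arg_match0(drought_stage, c("mild", "severe", "none", "unknown"))
  structure(
    list(
      values = unname(values),
      sample_id = as.character(sample_id),
      metadata = list(
        genotype = as.character(genotype), treatment = treatment,
        timepoint = timepoint, drought_stage = drought_stage
      )
    ),
    class = "thermal_frame"
  )
}

#' @export
print.thermal_frame <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<thermal_frame> %s: %d x %d px, %.1f-%.1f degC (treatment %s)\n",
    x$sample_id, nrow(v), ncol(v), min(v), max(v), x$metadata$treatment
  ))
  invisible(x)
}

#' @export
dim.thermal_frame <- function(x) dim(x$values)

#' Read a per-pixel thermal CSV grid
#'
#' Parses a plain-text grid of temperatures: H rows by W delimited numeric
#' columns, no header by default. Radiometric export tools write these grids
#' in locale-dependent dialects, so the delimiter and decimal mark are
#' configurable (`delim = ";"` with `decimal = ","` covers decimal-comma
#' locales).
#'
#' @param path Path to the CSV file.
#' @param delim Field delimiter, `","` by default.
#' @param decimal Decimal mark, `"."` by default.
#' @param skip Number of header lines to skip before the grid.
#' @param range_check Passed to [thermal_frame()]; `NULL` disables the
#'   plausibility check.
#' @inheritParams thermal_frame
#'
#' @return A [thermal_frame()].
#' @export
parse_thermal_csv <- function(path, delim = ",", decimal = ".", skip = 0L,
                              sample_id = NULL,
                              genotype = "unknown", treatment = "unknown",
                              timepoint = "unknown", drought_stage = "unknown",
                              range_check = c(-40, 120)) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "thermoleaf_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (skip > 0L) lines <- lines[-seq_len(skip)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    rlang::abort(sprintf("no data rows in %s", path), class = "thermoleaf_format_error")
  }
  cells <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    rlang::abort(
      sprintf(
        "ragged grid in %s: row %d has %d fields, expected %d",
        path, bad, widths[bad], widths[1]
      ),
      class = "thermoleaf_format_error"
    )
  }
  flat <- unlist(cells, use.names = FALSE)
  if (decimal != ".") flat <- gsub(decimal, ".", flat, fixed = TRUE)
  vals <- suppressWarnings(as.numeric(flat))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    r <- (bad - 1L) %/% widths[1] + 1L
    c_ <- (bad - 1L) %% widths[1] + 1L
    rlang::abort(
      sprintf("non-numeric cell '%s' at (row %d, col %d) in %s", flat[bad], r, c_, path),
      class = "thermoleaf_parse_error"
    )
  }
  m <- matrix(vals, nrow = length(lines), ncol = widths[1], byrow = TRUE)
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  thermal_frame(m, sample_id = sample_id, genotype = genotype,
                treatment = treatment, timepoint = timepoint,
                drought_stage = drought_stage, range_check = range_check)
}

#' Write a thermal frame as a plain CSV grid
#'
#' The written grid round-trips through [parse_thermal_csv()] to within
#' 1e-6 degrees Celsius.
#'
#' @param frame A [thermal_frame()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @param decimal Decimal mark.
#' @return `path`, invisibly.
#' @export
write_thermal_csv <- function(frame, path, delim = ",", decimal = ".") {
  stopifnot(inherits(frame, "thermal_frame"))
  rows <- apply(frame$values, 1L, function(r) {
    s <- formatC(r, format = "f", digits = 6)
    if (decimal != ".") s <- gsub(".", decimal, s, fixed = TRUE)
    paste(s, collapse = delim)
  })
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) rlang::abort(sprintf("cannot write %s", path), class = "thermoleaf_io_error")
  invisible(path)
}

#' Load and validate a sample manifest
#'
#' The manifest is a CSV with header
#' `sample_id,path,genotype,treatment,timepoint,drought_stage,replicate`;
#' it carries the experiment labels for each thermal CSV. Treatment tokens
#' are normalized case-insensitively to `WW`/`DD`.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with one validated row per sample.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("manifest not found: %s", path), class = "thermoleaf_io_error")
  }
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "path", "genotype", "treatment",
                "timepoint", "drought_stage", "replicate")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    rlang::abort(
      sprintf("manifest missing columns: %s", paste(missing, collapse = ", ")),
      class = "thermoleaf_format_error"
    )
  }
  dup <- m$sample_id[duplicated(m$sample_id)]
  if (length(dup) > 0L) {
    rlang::abort(
      sprintf("duplicated sample_id in manifest: %s", paste(unique(dup), collapse = ", ")),
      class = "thermoleaf_validation_error"
    )
  }
  trt <- toupper(trimws(as.character(m$treatment)))
  bad <- !(trt %in% c("WW", "DD"))
  if (any(bad)) {
    rlang::abort(
      sprintf("unknown treatment token(s): %s (expected WW or DD)",
              paste(unique(m$treatment[bad]), collapse = ", ")),
      class = "thermoleaf_validation_error"
    )
  }
  m$treatment <- trt
  tibble::as_tibble(m[required])
}
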