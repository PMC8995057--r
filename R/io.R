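#' Read a single-channel grayscale image
#'
#' Loads an 8- or 16-bit single-channel TIFF or PNG as a [gray_image()].
#' The physical pixel size always comes from the caller (instrument TIFF
#' metadata dialects are unreliable), never from file metadata.
#'
#' @param path TIFF (.tif/.tiff) or PNG (.png) file.
#' @param pixel_size nm per pixel to attach.
#' @param bit_depth intensity scale of the file, 8 or 16 (TIFF files
#'   carrying their own sample depth are validated against it).
#' @return a [gray_image()].
#' @export
read_gray_image <- function(path, pixel_size = 1, bit_depth = 8L) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3L)
      stop("multi-channel image not supported: ", path)
    if (max(x) > 2^bit_depth - 1)
      stop(sprintf("%s: intensities exceed the %d-bit range", path,
                   bit_depth))
    img <- matrix(as.numeric(x), nrow(x), ncol(x))
  } else if (ext == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L)
      stop("multi-channel image not supported: ", path)
    img <- matrix(round(as.numeric(x) * (2^bit_depth - 1)),
                  nrow(x), ncol(x))
  } else stop("unsupported image format: ", path)
  gray_image(img, pixel_size = pixel_size, bit_depth = as.integer(bit_depth))
}

#' Write a grayscale image
#'
#' @param img a [gray_image()].
#' @param path output TIFF or PNG path; format follows the extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  bits <- attr(img, "bit_depth") %||% 8L
  scale <- 2^bits - 1
  m <- matrix(as.numeric(img), nrow(img), ncol(img)) / scale
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(m, path, bits.per.sample = bits)
  else if (ext == "png") png::writePNG(m, path)
  else stop("unsupported image format: ", path)
  invisible(path)
}

#' Read and write binary masks as 0/255 PNG
#'
#' Masks round-trip losslessly: silver pixels are stored at full intensity,
#' gaps at zero.
#'
#' @param mask a [binary_mask()].
#' @param path PNG file.
#' @param pixel_size nm per pixel to attach on read.
#' @return `write_mask` returns `path` invisibly; `read_mask` a
#'   [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(as_mask_matrix(mask)),
                       nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, pixel_size = 1) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) stop("mask PNG must be single-channel: ", path)
  binary_mask(matrix(as.integer(x > 0.5), nrow(x), ncol(x)),
              pixel_size = pixel_size)
}

# Column schemas for the tabular inputs.
table_schemas <- list(
  calibration = c("concentration", "signal"),
  cv          = c("level", "run", "signal"),
  cohort      = c("subject", "label", "score"),
  paired      = c("subject", "score_a", "score_b"),
  enhancement = c("condition", "channel", "fi_sample", "bkgd_sample",
                  "fi_ref", "bkgd_ref")
)

# which schema columns must parse as numbers
numeric_cols <- list(
  calibration = c("concentration", "signal"),
  cv          = c("signal"),
  cohort      = c("score"),
  paired      = c("score_a", "score_b"),
  enhancement = c("fi_sample", "bkgd_sample", "fi_ref", "bkgd_ref")
)

#' Read and validate a CSV table against a named schema
#'
#' @param path CSV file with a header row.
#' @param schema one of `"calibration"`, `"cv"`, `"cohort"`, `"paired"`,
#'   `"enhancement"`.
#' @return validated data.frame.  Missing required columns, empty files,
#'   and non-numeric cells in numeric columns raise errors naming the
#'   offending column (and row).
#' @export
read_table_checked <- function(path, schema) {
  schema <- match.arg(schema, names(table_schemas))
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty table: ", path)
  miss <- setdiff(table_schemas[[schema]], names(tab))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  for (col in numeric_cols[[schema]]) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s', row %d", path,
                   col, bad[1L]))
    tab[[col]] <- v
  }
  tab
}

#' Wrap a module payload in a provenance envelope and write it as JSON
#'
#' Every pipeline run records the tool version, a timestamp, the echoed
#' configuration (including any RNG seed) and collected warnings next to
#' the payload, so results are reproducible from the sidecar alone.
#'
#' @param payload named list of module results.
#' @param config named list echoing the run configuration.
#' @param warnings character vector of collected warnings.
#' @param path output JSON file; when `NULL` the envelope list is returned
#'   without writing.
#' @return the envelope list, invisibly when written.
#' @export
result_envelope <- function(payload, config = list(), warnings = character(),
                            path = NULL) {
  env <- list(tool = "nanomef",
              version = as.character(packageVersion("nanomef")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = config,
              payload = payload,
              warnings = warnings)
  if (is.null(path)) return(env)
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(env)
}
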