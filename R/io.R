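# On-disk dialects: multi-page TIFF + JSON sidecar for cubes, 16-bit TIFF
# for masks, CSV for labels and reference spectra.

#' Write a spectral cube to disk
#'
#' Pixel data go to a multi-page 32-bit TIFF (page k = channel k), scaled by
#' a single per-cube factor recorded in the JSON sidecar along with the full
#' channel table, processing stage, field id and any calibration gains.
#'
#' @param cube a [spectral_cube()].
#' @param path_stack output TIFF path.
#' @param path_meta output JSON sidecar path.
#' @return invisibly, the sidecar list.
#' @export
write_cube <- function(cube, path_stack, path_meta) {
  d <- dim(cube$pixels)
  scale <- max(cube$pixels, 1e-300)
  pages <- lapply(seq_len(d[3]), function(k) cube$pixels[, , k] / scale)
  ok <- tryCatch(tiff::writeTIFF(pages, path_stack, bits.per.sample = 32L,
                                 compression = "none", reduce = FALSE),
                 error = function(e) stopf("cannot write '%s': %s",
                                           path_stack, conditionMessage(e)))
  meta <- list(field_id = cube$field_id, stage = cube$stage,
               steps = cube$steps, scale = scale,
               pixel_size_um = cube$pixel_size_um,
               n_channels = d[3], height = d[1], width = d[2],
               gains = cube$gains, channels = cube$channels)
  jsonlite::write_json(meta, path_meta, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(meta)
}

#' Read a spectral cube from disk
#'
#' @param path_stack multi-page TIFF written by [write_cube()] (or any
#'   page-ordered TIFF whose page count matches the sidecar).
#' @param path_meta JSON sidecar path.
#' @return a [spectral_cube()].
#' @export
read_cube <- function(path_stack, path_meta) {
  if (!file.exists(path_stack)) stopf("no such file: %s", path_stack)
  if (!file.exists(path_meta)) stopf("no such file: %s", path_meta)
  meta <- jsonlite::read_json(path_meta, simplifyVector = TRUE)
  pages <- tryCatch(tiff::readTIFF(path_stack, all = TRUE, info = FALSE),
                    error = function(e) stopf("cannot read '%s': %s",
                                              path_stack, conditionMessage(e)))
  if (length(pages) != meta$n_channels)
    stopf("format error: stack has %d pages but sidecar declares %d channels",
          length(pages), meta$n_channels)
  scale <- meta$scale %||% 1
  px <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) px[, , k] <- pages[[k]] * scale
  channels <- as.data.frame(meta$channels)
  cube <- spectral_cube(px, channels = channels,
                        field_id = meta$field_id %||% "field",
                        pixel_size_um = meta$pixel_size_um,
                        stage = meta$stage %||% "raw",
                        steps = as.character(meta$steps %||% character()))
  if (!is.null(meta$gains)) cube$gains <- as.numeric(meta$gains)
  cube
}

#' Write a cell mask as 16-bit TIFF
#' @param mask a [mask_image()].
#' @param path output TIFF path.
#' @export
write_mask <- function(mask, path) {
  if (max(mask$labels) > 65535L) stopf("mask labels exceed 16-bit range")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a cell mask from 16-bit TIFF
#' @param path TIFF path written by [write_mask()].
#' @param field_id field identifier to attach.
#' @return a [mask_image()].
#' @export
read_mask <- function(path, field_id = "field") {
  m <- tiff::readTIFF(path)
  mask_image(matrix(as.integer(round(m * 65535)), nrow(m)), field_id = field_id)
}

.label_enums <- list(
  stro1 = c("pos", "neg"),
  alp = c("pos", "neg"),
  senescent = c("pos", "neg"),
  cycle_phase = c("G1", "S", "G2", "M")
)
.label_optional <- c("stro1", "alp", "senescent", "cycle_phase",
                     "dapi_total", "line_id", "passage",
                     "doublings_remaining")

#' Read per-cell assay labels from CSV
#'
#' Required columns: `cell_id`, `field_id`. Optional columns: `stro1`,
#' `alp`, `senescent` (each `pos`/`neg`), `cycle_phase` (`G1`/`S`/`G2`/`M`),
#' `dapi_total`, `line_id`, `passage`, `doublings_remaining`. Enumerated
#' columns are validated; offending rows are reported.
#'
#' @param path CSV path.
#' @return a `data.frame` of label records.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "field_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("label CSV missing required columns: %s",
                          paste(miss, collapse = ", "))
  for (col in intersect(names(.label_enums), names(df))) {
    vals <- df[[col]]
    bad <- which(!is.na(vals) & vals != "" & !vals %in% .label_enums[[col]])
    if (length(bad))
      stopf("validation error: column '%s' has unknown value(s) %s in row(s) %s",
            col, paste(unique(vals[bad]), collapse = ", "),
            paste(bad, collapse = ", "))
  }
  df
}

#' Write per-cell assay labels to CSV
#' @param labels label `data.frame` (see [read_labels()]).
#' @param path output CSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read reference spectra from CSV
#'
#' Expects columns `channel_id`, `water_mean`, `calib_measured`,
#' `calib_reference`, one row per channel in channel order.
#'
#' @param path CSV path.
#' @return a [reference_spectra()].
#' @export
read_reference_spectra <- function(path) {
  df <- utils::read.csv(path)
  req <- c("channel_id", "water_mean", "calib_measured", "calib_reference")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("reference CSV missing columns: %s",
                          paste(miss, collapse = ", "))
  df <- df[order(df$channel_id), ]
  reference_spectra(df$water_mean, df$calib_measured, df$calib_reference)
}

#' Write reference spectra to CSV
#' @param refs a [reference_spectra()].
#' @param path output CSV path.
#' @export
write_reference_spectra <- function(refs, path) {
  n <- length(refs$water_mean)
  utils::write.csv(data.frame(channel_id = seq_len(n) - 1L,
                              water_mean = refs$water_mean,
                              calib_measured = refs$calib_measured,
                              calib_reference = refs$calib_reference),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
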