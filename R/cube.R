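# Core containers: spectral cube, mask image, reference spectra.

.cube_stages <- c("raw", "preprocessed", "calibrated")

#' Construct a spectral data cube
#'
#' A cube holds one imaged field of view: a height x width x n_channels
#' array of non-negative intensities together with the ordered channel
#' table describing each excitation/emission pair.
#'
#' @param pixels numeric array `height x width x n_channels`, finite and
#'   non-negative.
#' @param channels channel table (see [default_channel_table()]); the third
#'   array dimension must equal its row count.
#' @param field_id identifier of the field of view.
#' @param pixel_size_um physical pixel size in micrometres, or `NULL`.
#' @param stage processing stage, one of `"raw"`, `"preprocessed"`,
#'   `"calibrated"`.
#' @param steps character vector of preprocessing steps already applied
#'   (internal bookkeeping for pipeline-order enforcement).
#' @return an object of class `spectral_cube`.
#' @export
spectral_cube <- function(pixels, channels = default_channel_table(),
                          field_id = "field", pixel_size_um = NULL,
                          stage = "raw", steps = character()) {
  if (length(dim(pixels)) != 3L)
    stopf("pixels must be a 3-D array (height x width x channels)")
  if (dim(pixels)[3] != nrow(channels))
    stopf("cube has %d planes but the channel table has %d rows",
          dim(pixels)[3], nrow(channels))
  if (!all(is.finite(pixels))) stopf("cube pixels must all be finite")
  if (min(pixels) < 0) stopf("cube pixels must be non-negative")
  stage <- match.arg(stage, .cube_stages)
  validate_channel_table(channels)
  structure(list(pixels = pixels, channels = channels, field_id = field_id,
                 pixel_size_um = pixel_size_um, stage = stage,
                 steps = steps, gains = NULL),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<spectral_cube> field '%s': %d x %d px, %d channels, stage=%s\n",
              x$field_id, d[1], d[2], d[3], x$stage))
  if (length(x$steps))
    cat("  steps applied:", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$pixels)

# Forward-only stage transitions.
advance_stage <- function(cube, to) {
  from <- match(cube$stage, .cube_stages)
  toi <- match(to, .cube_stages)
  if (is.na(toi)) stopf("unknown stage '%s'", to)
  if (toi < from)
    stopf("stage may only advance forward (%s -> %s refused)", cube$stage, to)
  cube$stage <- to
  cube
}

# Enforce preprocessing order; `require_step` names the step that must
# already have run, `this_step` the step about to run.
check_step_order <- function(cube, this_step, require_step = NULL) {
  if (this_step %in% cube$steps)
    stopf("step '%s' has already been applied to field '%s'",
          this_step, cube$field_id)
  if (!is.null(require_step) && !require_step %in% cube$steps)
    stopf("step '%s' requires '%s' to have run first (field '%s')",
          this_step, require_step, cube$field_id)
  invisible(TRUE)
}

#' Construct a mask (label) image
#'
#' @param labels integer matrix on the cube's pixel grid; 0 is background,
#'   positive integers are cell identifiers (not necessarily contiguous).
#' @param field_id identifier of the matching field of view.
#' @return an object of class `mask_image`.
#' @export
mask_image <- function(labels, field_id = "field") {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  if (any(labels < 0) || any(labels != round(labels)))
    stopf("labels must be non-negative integers")
  structure(list(labels = matrix(as.integer(labels), nrow(labels)),
                 field_id = field_id),
            class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<mask_image> field '%s': %d x %d px, %d cells\n",
              x$field_id, nrow(x$labels), ncol(x$labels), length(ids)))
  invisible(x)
}

#' Cell identifiers present in a mask
#' @param mask a [mask_image()].
#' @return sorted integer vector of nonzero labels.
#' @export
mask_cell_ids <- function(mask) sort(setdiff(unique(as.vector(mask$labels)), 0L))

#' Construct reference spectra for calibration
#'
#' Bundles the water blank, the imaged calibration-fluid spectrum, and the
#' spectrofluorometer truth spectrum used to derive per-channel gains.
#'
#' @param water_mean per-channel blank signal (non-negative).
#' @param calib_measured per-channel imaged calibration-fluid signal.
#' @param calib_reference per-channel reference-instrument spectrum
#'   (positive).
#' @return an object of class `reference_spectra`.
#' @export
reference_spectra <- function(water_mean, calib_measured, calib_reference) {
  n <- length(water_mean)
  if (length(calib_measured) != n || length(calib_reference) != n)
    stopf("reference spectra must share one length")
  if (any(water_mean < 0)) stopf("water_mean must be non-negative")
  if (any(calib_reference <= 0)) stopf("calib_reference must be positive")
  structure(list(water_mean = as.numeric(water_mean),
                 calib_measured = as.numeric(calib_measured),
                 calib_reference = as.numeric(calib_reference)),
            class = "reference_spectra")
}
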