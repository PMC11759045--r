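## Plot-scale hyperspectral cube container and the cleaning pipeline applied
## to it before any spectral metric is computed: band filtering, NDVI and
## brightness masking, and vector normalization.  The validity mask only ever
## shrinks; every filter appends a parameterized entry to the provenance log.

#' Construct a plot cube
#'
#' @param reflectance pixel x band matrix (pixels in row-major grid order).
#' @param wavelength band centres in nm, strictly increasing.
#' @param nrow,ncol pixel grid dimensions; `nrow * ncol` must match rows.
#' @param mask logical validity flag per pixel (default all valid).
#' @return an object of class `plot_cube`.
#' @export
plot_cube <- function(reflectance, wavelength, nrow, ncol,
                      mask = rep(TRUE, base::nrow(reflectance))) {
  reflectance <- as.matrix(reflectance)
  if (length(wavelength) != ncol(reflectance))
    stop("one wavelength per band required", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (nrow * ncol != base::nrow(reflectance))
    stop("grid dimensions do not match pixel count", call. = FALSE)
  structure(list(reflectance = reflectance, wavelength = as.numeric(wavelength),
                 mask = as.logical(mask), nrow = as.integer(nrow),
                 ncol = as.integer(ncol), log = character(0)),
            class = "plot_cube")
}

#' @export
print.plot_cube <- function(x, ...) {
  cat(sprintf("plot_cube: %d x %d pixels (%d valid), %d bands [%g-%g nm]\n",
              x$nrow, x$ncol, sum(x$mask), length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  if (length(x$log)) cat("filters:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

log_filter <- function(cube, entry) {
  cube$log <- c(cube$log, entry)
  cube
}

#' Remove atmospheric water-absorption and edge bands
#'
#' Drops bands with wavelength in the closed intervals [1340, 1445] or
#' [1790, 1955] nm and all bands <= 400 or >= 2450 nm; band order is
#' preserved.
#'
#' @param cube a [plot_cube].
#' @return the cube with the reduced band set.
#' @export
filter_bands <- function(cube) {
  wl <- cube$wavelength
  drop <- (wl >= 1340 & wl <= 1445) | (wl >= 1790 & wl <= 1955) |
    wl <= 400 | wl >= 2450
  if (all(drop)) stop("no bands remain", call. = FALSE)
  cube$reflectance <- cube$reflectance[, !drop, drop = FALSE]
  cube$wavelength <- wl[!drop]
  log_filter(cube, sprintf("filter_bands[removed=%d]", sum(drop)))
}

#' Per-pixel NDVI of a cube
#'
#' Band-window means: red 660-680 nm, NIR 800-860 nm.
#'
#' @param cube a [plot_cube].
#' @return numeric NDVI per pixel (all pixels, valid or not).
#' @export
cube_ndvi <- function(cube) {
  wl <- cube$wavelength
  red_i <- wl >= 660 & wl <= 680
  nir_i <- wl >= 800 & wl <= 860
  if (!any(red_i) || !any(nir_i))
    stop("red (660-680 nm) or NIR (800-860 nm) window missing", call. = FALSE)
  red <- rowMeans(cube$reflectance[, red_i, drop = FALSE])
  nir <- rowMeans(cube$reflectance[, nir_i, drop = FALSE])
  (nir - red) / (nir + red)
}

#' Mask non-vegetation pixels by NDVI threshold
#'
#' Threshold 0.5 for high vegetation cover, 0.2 for low; pixels with NDVI
#' exactly at the threshold are kept (`>=` retained).
#'
#' @param cube a [plot_cube].
#' @param cover_class `"high"` or `"low"`.
#' @return the cube with its validity mask shrunk.
#' @export
ndvi_mask <- function(cube, cover_class = c("high", "low")) {
  cover_class <- match.arg(cover_class)
  thr <- if (cover_class == "high") 0.5 else 0.2
  ndvi <- cube_ndvi(cube)
  cube$mask <- cube$mask & (ndvi >= thr)
  log_filter(cube, sprintf("ndvi_mask[class=%s,thr=%g]", cover_class, thr))
}

#' Mask brightness outliers (Tukey fences)
#'
#' Brightness is the mean reflectance across retained bands per pixel; valid
#' pixels outside `[Q1 - k IQR, Q3 + k IQR]` are masked.  The low fence
#' removes shaded pixels; the default two-sided rule also removes glint
#' (`side = "low"` restricts to shade).
#'
#' Quartiles are computed over the currently valid pixels; re-applying the
#' same mask (same parameters) is a no-op, tracked through the provenance
#' log, so the filter is idempotent.
#'
#' @param cube a [plot_cube].
#' @param k Tukey multiplier (default 1.5).
#' @param side `"both"` or `"low"`.
#' @return the cube with its validity mask shrunk.
#' @export
brightness_mask <- function(cube, k = 1.5, side = c("both", "low")) {
  side <- match.arg(side)
  entry <- sprintf("brightness_mask[k=%g,side=%s]", k, side)
  if (entry %in% cube$log) return(cube)
  valid <- which(cube$mask)
  if (length(valid) < 4) {
    warning("fewer than 4 valid pixels; brightness mask skipped")
    return(log_filter(cube, "brightness_mask[skipped]"))
  }
  bright <- rowMeans(cube$reflectance)
  q <- stats::quantile(bright[valid], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  out <- bright < lo | (side == "both" & bright > hi)
  cube$mask <- cube$mask & !out
  log_filter(cube, entry)
}

#' Scale every valid pixel spectrum to unit Euclidean norm
#'
#' Zero-norm pixels are masked with a warning.
#'
#' @param cube a [plot_cube].
#' @return the cube with normalized valid pixels.
#' @export
vector_normalize <- function(cube) {
  norms <- sqrt(rowSums(cube$reflectance^2))
  zero <- cube$mask & norms == 0
  if (any(zero)) {
    warning(sum(zero), " zero-norm pixel(s) masked")
    cube$mask <- cube$mask & !zero
  }
  idx <- which(cube$mask)
  cube$reflectance[idx, ] <- cube$reflectance[idx, , drop = FALSE] / norms[idx]
  log_filter(cube, "vector_normalize")
}

#' Assign the vegetation cover class of a plot
#'
#' `"high"` when at least half of the pixels reach NDVI >= 0.2, else `"low"`.
#'
#' @param cube a [plot_cube].
#' @return `"high"` or `"low"`.
#' @export
assign_cover_class <- function(cube) {
  if (mean(cube_ndvi(cube) >= 0.2) >= 0.5) "high" else "low"
}

#' Full spectral cleaning pipeline for one plot
#'
#' Applies [filter_bands()], [ndvi_mask()], [brightness_mask()] and
#' [vector_normalize()] in that order.  Plots whose valid-pixel fraction
#' falls below `min_valid_fraction` are rejected: rejection is a typed
#' outcome (class `plot_rejection`), not an error.
#'
#' @param cube a raw [plot_cube].
#' @param cover_class `"high"`, `"low"`, or `"auto"` (assigned from the NDVI
#'   distribution via [assign_cover_class()]).
#' @param min_valid_fraction minimum retained pixel fraction (default 0.25).
#' @param k Tukey multiplier for the brightness mask.
#' @return a cleaned [plot_cube], or a `plot_rejection` object.
#' @export
clean_plot_pipeline <- function(cube, cover_class = "auto",
                                min_valid_fraction = 0.25, k = 1.5) {
  cube <- filter_bands(cube)
  if (identical(cover_class, "auto")) cover_class <- assign_cover_class(cube)
  cube <- ndvi_mask(cube, cover_class)
  cube <- brightness_mask(cube, k = k)
  cube <- suppressWarnings(vector_normalize(cube))
  frac <- mean(cube$mask)
  if (frac < min_valid_fraction) {
    return(structure(list(valid_fraction = frac, log = cube$log,
                          reason = sprintf(
                            "valid fraction %.3f < %.3f", frac,
                            min_valid_fraction)),
                     class = "plot_rejection"))
  }
  cube
}

#' @export
print.plot_rejection <- function(x, ...) {
  cat("plot rejected:", x$reason, "\n")
  invisible(x)
}

#' Matrix of valid, processed pixel spectra
#'
#' @param cube a [plot_cube].
#' @return matrix of valid pixel rows.
#' @export
valid_pixels <- function(cube) {
  cube$reflectance[cube$mask, , drop = FALSE]
}
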