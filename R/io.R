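#' Polar-coordinate OCT image
#'
#' Container for a polar B-scan: rows are A-lines (one per beam angle, row 1
#' at angle 0 degrees, angles increasing counter-clockwise), columns are
#' depth samples (column 1 at the catheter surface; physical depth of column
#' `j` is `(j - 1) * axial_spacing` mm).  Intensities are linear-scale,
#' non-negative.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param axial_spacing depth sampling interval, mm per pixel (> 0).
#' @param angular_step degrees per A-line; must satisfy
#'   `nrow(pixels) * angular_step == 360`.
#' @return an object of class `polar_image` with fields `pixels`,
#'   `axial_spacing`, `angular_step`.
#' @export
polar_image <- function(pixels, axial_spacing,
                        angular_step = 360 / nrow(pixels)) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("pixels must be a finite numeric matrix")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (!is.numeric(axial_spacing) || axial_spacing <= 0)
    stop("axial_spacing must be > 0")
  if (abs(nrow(pixels) * angular_step - 360) > 1e-6)
    stop("rows * angular_step must equal 360 degrees")
  structure(list(pixels = pixels, axial_spacing = axial_spacing,
                 angular_step = angular_step),
            class = "polar_image")
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("<polar_image> %d A-lines x %d depth px (%.4g mm/px, %.3g deg/A-line)\n",
              nrow(x$pixels), ncol(x$pixels), x$axial_spacing, x$angular_step))
  invisible(x)
}

#' @export
dim.polar_image <- function(x) dim(x$pixels)

#' Tissue label map
#'
#' Integer raster with the same geometry as its companion [polar_image()],
#' holding per-pixel tissue labels: 0 background, 1 fibrous, 2 calcified,
#' 3 lipid (see [TISSUE_LABELS]).
#'
#' @param labels integer matrix with values in `0:3`.
#' @return an object of class `tissue_label_map`.
#' @export
tissue_label_map <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), TISSUE_LABELS)
  if (length(bad))
    stop("illegal label value(s): ", paste(sort(bad), collapse = ", "),
         " (legal: 0,1,2,3)")
  structure(list(labels = labels, color_table = TISSUE_COLORS),
            class = "tissue_label_map")
}

#' @export
dim.tissue_label_map <- function(x) dim(x$labels)

label_map_to_rgb <- function(labels) {
  pal <- grDevices::col2rgb(TISSUE_COLORS) / 255
  arr <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  for (k in seq_along(TISSUE_LABELS)) {
    idx <- labels == TISSUE_LABELS[[k]]
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[idx] <- pal[ch, k]
      arr[, , ch] <- plane
    }
  }
  arr
}

#' Write an OCT dataset directory
#'
#' Writes `image.tiff` (single-frame 16-bit grayscale; intensities are
#' integer counts in 0..65535), `meta.json` (axial spacing, A-line count and
#' any known beam parameters), and optionally `labels.png` (8-bit grayscale
#' holding raw label values), `overlay.png` (color-coded tissue map:
#' green/white/pink on black) and `boundary.csv`
#' (`aline_index,radius_px,shadowed_flag`).
#'
#' Intensities are clamped to `[0, 65535]` and rounded to integers before
#' writing, so a write/read round trip is pixel-exact for integer-valued
#' rasters.
#'
#' @param path output directory (created if absent).
#' @param image a [polar_image()].
#' @param labels optional [tissue_label_map()].
#' @param boundary optional integer vector of per-A-line lumen radii (px), or
#'   a data.frame with columns `aline_index`, `radius_px`, `shadowed_flag`.
#' @param sys optional [system_params()]; its beam parameters go into
#'   `meta.json`.
#' @return `path`, invisibly.
#' @export
write_oct_dataset <- function(path, image, labels = NULL, boundary = NULL,
                              sys = NULL) {
  stopifnot(inherits(image, "polar_image"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  px <- round(pmin(pmax(image$pixels, 0), 65535))
  tiff::writeTIFF(px / 65535, file.path(path, "image.tiff"),
                  bits.per.sample = 16, compression = "none")
  meta <- list(axial_spacing_mm = image$axial_spacing,
               n_alines = nrow(image$pixels),
               n_depth = ncol(image$pixels))
  if (!is.null(sys)) {
    meta$z0_mm <- sys$z0; meta$zR_mm <- sys$zR
    meta$zC_mm <- sys$zC; meta$zW_mm <- sys$zW
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "tissue_label_map"))
    if (!identical(dim(labels$labels), dim(image$pixels)))
      stop("label map geometry does not match image")
    png::writePNG(labels$labels / 255, file.path(path, "labels.png"))
    png::writePNG(label_map_to_rgb(labels$labels),
                  file.path(path, "overlay.png"))
  }
  if (!is.null(boundary)) {
    if (!is.data.frame(boundary))
      boundary <- data.frame(aline_index = seq_along(boundary) - 1L,
                             radius_px = as.integer(boundary),
                             shadowed_flag = 0L)
    write.csv(boundary, file.path(path, "boundary.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an OCT dataset directory
#'
#' Expects `image.tiff` and `meta.json`; `labels.png` and `boundary.csv` are
#' optional and yield `NULL` fields when absent.
#'
#' @param path dataset directory.
#' @return list with fields `image` ([polar_image()]), `labels`
#'   ([tissue_label_map()] or `NULL`), `boundary` (data.frame or `NULL`) and
#'   `meta` (named list).
#' @export
read_oct_dataset <- function(path) {
  meta_file <- file.path(path, "meta.json")
  tiff_file <- file.path(path, "image.tiff")
  if (!file.exists(meta_file)) stop("missing meta.json in ", path)
  if (!file.exists(tiff_file)) stop("missing image.tiff in ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  px <- round(tiff::readTIFF(tiff_file) * 65535)
  if (!is.null(meta$n_alines) && nrow(px) != meta$n_alines)
    stop("TIFF row count ", nrow(px), " does not match meta n_alines ",
         meta$n_alines)
  img <- polar_image(px, axial_spacing = meta$axial_spacing_mm)
  labels <- NULL
  png_file <- file.path(path, "labels.png")
  if (file.exists(png_file)) {
    lab <- png::readPNG(png_file)
    if (length(dim(lab)) == 3) lab <- lab[, , 1]
    lab <- round(lab * 255)
    if (!identical(dim(lab), dim(px)))
      stop("labels.png shape ", paste(dim(lab), collapse = "x"),
           " does not match image.tiff ", paste(dim(px), collapse = "x"))
    labels <- tissue_label_map(lab)
  }
  boundary <- NULL
  bfile <- file.path(path, "boundary.csv")
  if (file.exists(bfile)) boundary <- read.csv(bfile)
  list(image = img, labels = labels, boundary = boundary, meta = meta)
}

#' Polar to Cartesian scan conversion
#'
#' Nearest-neighbor conversion of a polar B-scan to a square cross-sectional
#' raster for visualization.  The catheter center sits at the raster center;
#' angle 0 points along +x, angles increase counter-clockwise; the full
#' imaging depth maps to half the output side, and pixels beyond the maximum
#' depth are 0.
#'
#' @param img a [polar_image()].
#' @param out_size output side length in pixels (>= 16).
#' @return `out_size` x `out_size` numeric matrix.
#' @export
scan_convert <- function(img, out_size) {
  stopifnot(inherits(img, "polar_image"))
  if (out_size < 16) stop("out_size must be >= 16")
  px <- img$pixels
  n_al <- nrow(px); n_cols <- ncol(px)
  ctr <- (out_size + 1) / 2
  scale <- (out_size / 2) / n_cols          # cartesian px per depth px
  step_rad <- img$angular_step * pi / 180
  xs <- matrix(rep(seq_len(out_size) - ctr, each = out_size),
               nrow = out_size)              # column offset
  ys <- matrix(rep(ctr - seq_len(out_size), times = out_size),
               nrow = out_size)              # row offset, y up
  rad <- sqrt(xs^2 + ys^2)
  ang <- atan2(ys, xs) %% (2 * pi)
  k <- floor(rad / scale)                    # 0-based depth index
  a <- round(ang / step_rad) %% n_al         # 0-based A-line index
  out <- matrix(0, out_size, out_size)
  inside <- k < n_cols
  out[inside] <- px[cbind(a[inside] + 1L, k[inside] + 1L)]
  out
}
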