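#' Binary microCT slice stack
#'
#' An `image_stack` is an ordered set of binary 2-D slices (1 = bone,
#' 0 = marrow/background) together with the acquisition metadata needed to
#' interpret it physically: the in-plane pixel size and the axial slice
#' increment, both in micrometres. An optional in-plane mask restricts the
#' region of interest (e.g. the cylindrical core cut from a femoral head).
#'
#' @param slices 3-D array, dimensions `c(nx, ny, n_slices)`, values in
#'   `{0, 1}`. The third dimension is the slice (axial) direction.
#' @param pixel_size In-plane pixel edge length in micrometres (square pixels).
#' @param slice_increment Axial distance between consecutive slices, in
#'   micrometres.
#' @param mask Optional `nx` by `ny` binary matrix; every bone pixel must lie
#'   inside the mask.
#'
#' @return An object of class `image_stack`: a list with elements `slices`
#'   (integer 3-D array), `pixel_size`, `slice_increment`, `mask`.
#' @examples
#' stk <- image_stack(array(1L, c(4, 4, 3)), 36, 36)
#' dim(stk$slices)
#' @export
image_stack <- function(slices, pixel_size, slice_increment, mask = NULL) {
  if (!is.array(slices) || length(dim(slices)) != 3L)
    stop("`slices` must be a 3-D array (nx, ny, n_slices)", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um)", call. = FALSE)
  if (!is.numeric(slice_increment) || length(slice_increment) != 1L ||
      slice_increment <= 0)
    stop("`slice_increment` must be a single positive number (um)",
         call. = FALSE)
  vals <- unique(as.vector(slices))
  if (!all(vals %in% c(0, 1)))
    stop("`slices` must be strictly binary (0/1)", call. = FALSE)
  storage.mode(slices) <- "integer"
  if (!is.null(mask)) {
    if (!is.matrix(mask) || !all(dim(mask) == dim(slices)[1:2]))
      stop("`mask` must be an nx-by-ny binary matrix", call. = FALSE)
    storage.mode(mask) <- "integer"
    outside <- sweep(slices, 1:2, mask, function(s, m) s * (1L - m))
    if (any(outside == 1L))
      stop("bone pixels found outside the mask", call. = FALSE)
  }
  structure(
    list(slices = slices, pixel_size = pixel_size,
         slice_increment = slice_increment, mask = mask),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf(
    "<image_stack> %d x %d pixels, %d slices | pixel %g um, increment %g um\n",
    d[1], d[2], d[3], x$pixel_size, x$slice_increment))
  cat(sprintf("  bone fraction: %.4f%s\n", mean(x$slices),
              if (is.null(x$mask)) "" else "  (masked)"))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$slices)

#' Number of slices in a stack
#' @param stack An `image_stack`.
#' @return Integer slice count.
#' @export
n_slices <- function(stack) dim(stack$slices)[3]

sidecar_name <- "stack.yml"

#' Write a slice stack to disk
#'
#' Writes one greyscale PNG per slice (`slice_0000.png`, ...) plus a plain-text
#' YAML sidecar carrying `pixel_size_um` and `slice_increment_um` (and the
#' mask, if present, as `mask.png`). The representation is lossless for binary
#' data and readable back with [read_stack()].
#'
#' @param stack An `image_stack`.
#' @param path Directory to create/write into.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", path, call. = FALSE)
  }
  nz <- n_slices(stack)
  for (k in seq_len(nz)) {
    f <- file.path(path, sprintf("slice_%04d.png", k - 1L))
    png::writePNG(stack$slices[, , k] + 0, f)  # writePNG wants doubles
  }
  meta <- list(pixel_size_um = stack$pixel_size,
               slice_increment_um = stack$slice_increment,
               n_slices = nz)
  if (!is.null(stack$mask)) {
    png::writePNG(stack$mask + 0, file.path(path, "mask.png"))
    meta$mask_file <- "mask.png"
  }
  yaml::write_yaml(meta, file.path(path, sidecar_name))
  invisible(path)
}

#' Read a slice stack from disk
#'
#' Reads either a directory of numbered single-slice PNGs produced by
#' [write_stack()] (slices ordered by the numeric part of their filenames)
#' or a multi-page TIFF; a YAML sidecar (`stack.yml` in the directory, or
#' `<basename>.yml` next to a TIFF) must supply `pixel_size_um` and
#' `slice_increment_um`. Pixel values are strictly binarized: >= 0.5 is bone.
#'
#' @param path Directory of PNGs or path to a multi-page TIFF file.
#' @param format_hint `"auto"` (default), `"png_dir"` or `"tiff"`.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, format_hint = c("auto", "png_dir", "tiff")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "auto")
    format_hint <- if (dir.exists(path)) "png_dir" else "tiff"
  if (format_hint == "png_dir") {
    meta_file <- file.path(path, sidecar_name)
    if (!file.exists(meta_file))
      stop("missing metadata sidecar: ", meta_file, call. = FALSE)
    meta <- yaml::read_yaml(meta_file)
    files <- list.files(path, pattern = "^slice_.*\\.png$", full.names = TRUE)
    if (length(files) == 0L)
      stop("no slice PNGs found under ", path, call. = FALSE)
    idx <- as.integer(gsub("\\D", "", basename(files)))
    files <- files[order(idx)]
    slices <- lapply(files, function(f) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 3L) im <- im[, , 1]
      im
    })
    shp <- dim(slices[[1]])
    if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
      stop("inconsistent slice shapes in ", path, call. = FALSE)
    arr <- array(0L, c(shp, length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- (slices[[k]] >= 0.5) + 0L
    mask <- NULL
    if (!is.null(meta$mask_file)) {
      m <- png::readPNG(file.path(path, meta$mask_file))
      if (length(dim(m)) == 3L) m <- m[, , 1]
      mask <- (m >= 0.5) + 0L
    }
  } else {
    meta_file <- file.path(dirname(path),
                           paste0(sub("\\.[^.]+$", "", basename(path)), ".yml"))
    if (!file.exists(meta_file))
      stop("missing metadata sidecar: ", meta_file, call. = FALSE)
    meta <- yaml::read_yaml(meta_file)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(im) {
      if (length(dim(im)) == 3L) im[, , 1] else im
    })
    shp <- dim(pages[[1]])
    if (!all(vapply(pages, function(s) identical(dim(s), shp), logical(1))))
      stop("inconsistent slice shapes in ", path, call. = FALSE)
    arr <- array(0L, c(shp, length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- (pages[[k]] >= 0.5) + 0L
    mask <- NULL
  }
  if (is.null(meta$pixel_size_um) || is.null(meta$slice_increment_um))
    stop("sidecar must define pixel_size_um and slice_increment_um",
         call. = FALSE)
  image_stack(arr, meta$pixel_size_um, meta$slice_increment_um, mask = mask)
}

#' Binarize a grey-value stack
#'
#' A pixel is classified bone when its grey value is greater than or equal to
#' the threshold. The threshold is a required user input: scanner calibration
#' determines it and it is not recoverable from the image data alone.
#'
#' @param grey 3-D numeric array of grey values (nx, ny, n_slices).
#' @param threshold Scalar; must lie within the grey-value range of the data.
#' @param pixel_size,slice_increment Metadata in micrometres.
#' @return An [image_stack()].
#' @export
threshold_stack <- function(grey, threshold, pixel_size = 36,
                            slice_increment = 36) {
  if (!is.array(grey) || length(dim(grey)) != 3L)
    stop("`grey` must be a 3-D array", call. = FALSE)
  rng <- range(grey)
  if (threshold < rng[1] || threshold > rng[2])
    stop(sprintf("threshold %g outside grey range [%g, %g]",
                 threshold, rng[1], rng[2]), call. = FALSE)
  image_stack((grey >= threshold) + 0L, pixel_size, slice_increment)
}

#' Apply a centred cylindrical region-of-interest mask
#'
#' Keeps only bone pixels whose centres lie within the centred disc of the
#' given diameter (the physical cross-section of the cored specimen); the
#' disc membership rule is pixel-centre-in-disc. The mask is stored on the
#' returned stack so downstream volume fractions and nominal areas refer to
#' the cylinder, not the bounding box.
#'
#' @param stack An [image_stack()].
#' @param diameter_mm Cylinder diameter in millimetres; the disc must fit
#'   inside the imaged field of view.
#' @return A masked [image_stack()].
#' @export
apply_cylinder_mask <- function(stack, diameter_mm) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$slices)
  px_mm <- stack$pixel_size / 1000
  extent <- c(d[1], d[2]) * px_mm
  if (diameter_mm > min(extent) + 1e-9)
    stop(sprintf("disc diameter %g mm exceeds field of view %g x %g mm",
                 diameter_mm, extent[1], extent[2]), call. = FALSE)
  cx <- extent[1] / 2
  cy <- extent[2] / 2
  xc <- (seq_len(d[1]) - 0.5) * px_mm
  yc <- (seq_len(d[2]) - 0.5) * px_mm
  r2 <- outer((xc - cx)^2, (yc - cy)^2, `+`)
  mask <- (r2 <= (diameter_mm / 2)^2) + 0L
  slices <- sweep(stack$slices, 1:2, mask, `*`)
  storage.mode(slices) <- "integer"
  image_stack(slices, stack$pixel_size, stack$slice_increment, mask = mask)
}
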