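#' Voxel model of trabecular bone
#'
#' A `voxel_model` is a 3-D bone-occupancy grid with (possibly anisotropic)
#' voxel dimensions. The basic model has cubic voxels equal to the microCT
#' resolution; coarsened models have either larger cubes (Hexahedral method)
#' or elongated 36 x 36 x d voxels (slice-pairing methods).
#'
#' @param occupancy 3-D binary array `(nx, ny, n_layers)`.
#' @param dx,dy,dz Voxel edge lengths in micrometres along x, y and the
#'   slice axis.
#' @param provenance List with elements `method` (one of `"basic"`, `"H"`,
#'   `"FL"`, `"FS"`, `"FT"`) and `param` (the cuberrille side `s` or voxel
#'   length `d` in micrometres; `NA` for the basic model).
#' @param mask Optional in-plane binary matrix at the model's resolution.
#' @return An object of class `voxel_model`.
#' @export
voxel_model <- function(occupancy, dx, dy, dz,
                        provenance = list(method = "basic", param = NA_real_),
                        mask = NULL) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L)
    stop("`occupancy` must be a 3-D array", call. = FALSE)
  if (!all(unique(as.vector(occupancy)) %in% c(0, 1)))
    stop("`occupancy` must be binary", call. = FALSE)
  stopifnot(dx > 0, dy > 0, dz > 0)
  storage.mode(occupancy) <- "integer"
  if (!is.null(mask)) {
    stopifnot(is.matrix(mask), all(dim(mask) == dim(occupancy)[1:2]))
    storage.mode(mask) <- "integer"
  }
  structure(list(occupancy = occupancy, dx = dx, dy = dy, dz = dz,
                 provenance = provenance, mask = mask),
            class = "voxel_model")
}

#' @export
print.voxel_model <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "<voxel_model> %d x %d x %d voxels (%g x %g x %g um) | method %s",
    d[1], d[2], d[3], x$dx, x$dy, x$dz, x$provenance$method))
  if (!is.na(x$provenance$param))
    cat(sprintf(" (%g um)", x$provenance$param))
  cat(sprintf("\n  bone fraction: %.4f\n", mean(x$occupancy)))
  invisible(x)
}

#' @export
dim.voxel_model <- function(x) dim(x$occupancy)

#' Build the basic (full-resolution) voxel model
#'
#' N slices give N - 1 voxel layers; voxel (i, j, k) is bone exactly when
#' pixel (i, j) is bone in slice k and in slice k + 1 (the AND rule). The
#' resulting voxels are cubes with edge equal to the pixel size, so the
#' stack's slice increment must equal its pixel size.
#'
#' @param stack An [image_stack()] with at least two slices.
#' @return A `voxel_model` with `method = "basic"`.
#' @export
build_basic_model <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_slices(stack)
  if (nz < 2L) stop("need at least 2 slices to build a voxel model",
                    call. = FALSE)
  if (abs(stack$slice_increment - stack$pixel_size) > 1e-9)
    stop("basic model requires slice_increment == pixel_size (cubic voxels)",
         call. = FALSE)
  s <- stack$slices
  occ <- s[, , -nz, drop = FALSE] * s[, , -1L, drop = FALSE]
  voxel_model(occ, stack$pixel_size, stack$pixel_size, stack$pixel_size,
              provenance = list(method = "basic", param = stack$pixel_size),
              mask = stack$mask)
}

#' Hexahedral (cuberrille majority) coarsening
#'
#' Tiles the basic model's grid by s x s x s cuberrilles anchored at the
#' origin; an output voxel is bone exactly when strictly more than half of
#' the full nominal cuberrille volume is filled with bone voxels. Partial
#' cuberrilles at the boundary are evaluated against the full nominal volume
#' (sub-voxels beyond the grid count as empty).
#'
#' @param model A cubic-voxel `voxel_model` (the basic model).
#' @param s Cuberrille side in micrometres; a multiple of the base voxel
#'   size, conventionally 72-288.
#' @param enforce_range Error when `s` falls outside 72-288 um (the study's
#'   experimental range); set `FALSE` to lift the restriction.
#' @return A `voxel_model` with cubic voxels of edge `s`.
#' @export
coarsen_h <- function(model, s, enforce_range = TRUE) {
  stopifnot(inherits(model, "voxel_model"))
  base <- model$dx
  if (abs(model$dy - base) > 1e-9 || abs(model$dz - base) > 1e-9)
    stop("Hexahedral coarsening requires a cubic-voxel basic model",
         call. = FALSE)
  f <- s / base
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("`s` must be a positive multiple of the base voxel size",
         call. = FALSE)
  f <- as.integer(round(f))
  if (enforce_range && (s < 2 * base || s > 8 * base))
    stop(sprintf("`s` = %g um outside the conventional range [%g, %g] um; ",
                 s, 2 * base, 8 * base),
         "use enforce_range = FALSE to override", call. = FALSE)
  occ <- model$occupancy
  sums <- block_sum3(occ, c(f, f, f))
  out <- (2L * sums > f^3) + 0L
  mask_out <- NULL
  if (!is.null(model$mask)) {
    msum <- block_sum2(model$mask, c(f, f))
    mask_out <- (2L * msum > f^2) + 0L
  }
  voxel_model(out, s, s, s, provenance = list(method = "H", param = s),
              mask = mask_out)
}

# block sums of a 3-D integer array over f-sized tiles, zero-padded at the end
block_sum3 <- function(a, f) {
  d <- dim(a)
  nb <- ceiling(d / f)
  pad <- nb * f
  if (any(pad != d)) {
    b <- array(0L, pad)
    b[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    a <- b
  }
  # sum over axis 1 tiles, then 2, then 3
  dim(a) <- c(f[1], nb[1], pad[2], pad[3])
  a <- colSums(a)                      # nb1 x pad2 x pad3
  a <- aperm(a, c(2, 1, 3))            # pad2 x nb1 x pad3
  dim(a) <- c(f[2], nb[2], nb[1], pad[3])
  a <- colSums(a)                      # nb2 x nb1 x pad3
  a <- aperm(a, c(3, 2, 1))            # pad3 x nb1 x nb2
  dim(a) <- c(f[3], nb[3], nb[1], nb[2])
  a <- colSums(a)                      # nb3 x nb1 x nb2
  aperm(a, c(2, 3, 1))
}

block_sum2 <- function(m, f) {
  a <- array(m, c(dim(m), 1L))
  drop3 <- block_sum3(a, c(f, 1L))
  matrix(drop3, dim(drop3)[1], dim(drop3)[2])
}

# shared machinery for the slice-pairing coarsenings: layer k (0-based) is
# the AND of slices first_idx(k) and second_idx(k), extruded to length d
pair_coarsen <- function(stack, d, method, offset2, enforce_range) {
  stopifnot(inherits(stack, "image_stack"))
  inc <- stack$slice_increment
  m <- d / inc
  if (abs(m - round(m)) > 1e-9 || m < 1)
    stop("`d` must be a positive multiple of the slice increment",
         call. = FALSE)
  m <- as.integer(round(m))
  if (enforce_range && (d < 2 * inc || d > 30 * inc))
    stop(sprintf("`d` = %g um outside the conventional range [%g, %g] um; ",
                 d, 2 * inc, 30 * inc),
         "use enforce_range = FALSE to override", call. = FALSE)
  nz <- n_slices(stack)
  min_slices <- switch(method, FT = m + 2L, m + 1L)
  if (nz < min_slices)
    stop(sprintf("method %s with d = %g um needs at least %d slices, got %d",
                 method, d, min_slices, nz), call. = FALSE)
  n_layers <- (nz - 1L) %/% m
  s <- stack$slices
  first <- (seq_len(n_layers) - 1L) * m + 1L
  second <- if (offset2 == 0L) first + m else first + offset2
  occ <- s[, , first, drop = FALSE] * s[, , second, drop = FALSE]
  voxel_model(occ, stack$pixel_size, stack$pixel_size, d,
              provenance = list(method = method, param = d),
              mask = stack$mask)
}

#' First-Last slice-pairing coarsening
#'
#' Layer k is built from the slices at its bottom and top faces, d apart
#' (slices k*m and (k+1)*m, m = d / slice increment): a voxel of size
#' 36 x 36 x d is bone exactly when the pixel is bone in both slices.
#' Trailing slices that do not fill a whole layer are dropped.
#'
#' @param stack An [image_stack()].
#' @param d Voxel length in micrometres; a multiple of the slice increment,
#'   conventionally 72-1080.
#' @param enforce_range Error outside the conventional range (override with
#'   `FALSE`).
#' @return A `voxel_model` with `method = "FL"`.
#' @export
coarsen_fl <- function(stack, d, enforce_range = TRUE) {
  pair_coarsen(stack, d, "FL", 0L, enforce_range)
}

#' First-Second slice-pairing coarsening
#'
#' Layer k is built from the two successive slices at the layer's start
#' (slices k*m and k*m + 1, one slice increment apart), AND-combined and
#' extruded to length d. The remaining slices of each layer are discarded,
#' which is what makes this scheme attractive for dose reduction.
#'
#' @inheritParams coarsen_fl
#' @return A `voxel_model` with `method = "FS"`.
#' @export
coarsen_fs <- function(stack, d, enforce_range = TRUE) {
  pair_coarsen(stack, d, "FS", 1L, enforce_range)
}

#' First-Third slice-pairing coarsening
#'
#' Layer k is built from two slices two increments (72 um at the study's
#' resolution) apart: slices k*m and k*m + 2, AND-combined and extruded to
#' length d. `d` must therefore be a multiple of twice the slice increment.
#'
#' @inheritParams coarsen_fl
#' @return A `voxel_model` with `method = "FT"`.
#' @export
coarsen_ft <- function(stack, d, enforce_range = TRUE) {
  inc <- stack$slice_increment
  if (abs(d / (2 * inc) - round(d / (2 * inc))) > 1e-9)
    stop("`d` must be a multiple of twice the slice increment for the ",
         "First-Third method", call. = FALSE)
  pair_coarsen(stack, d, "FT", 2L, enforce_range)
}
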