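#' Deterministic and stochastic trabecular phantoms
#'
#' The phantom generators stand in for patient microCT scans. The three
#' deterministic phantoms have closed-form mechanics and morphometry and are
#' used as analytic fixtures; the Gaussian-random-field (GRF) phantom
#' emulates the statistical structure of femoral-head trabecular cores, with
#' a controllable bone volume fraction spanning the range observed in
#' osteoporotic and coxarthrotic specimens (roughly 0.07-0.39).
#'
#' @name phantoms
NULL

#' Fully solid block phantom
#'
#' @param shape Integer vector `c(nx, ny, n_slices)`.
#' @param pixel_size,slice_increment Micrometres.
#' @return An [image_stack()] with every pixel bone.
#' @export
make_solid_block <- function(shape, pixel_size = 36, slice_increment = 36) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  image_stack(array(1L, shape), pixel_size, slice_increment)
}

#' Rectangular prism column phantom
#'
#' Every slice contains one axis-aligned solid rectangle occupying exactly
#' the fraction `phi` of the slice area; the column spans all slices. Under
#' prescribed axial strain with frictionless platens the apparent modulus of
#' this phantom is exactly `phi` times the tissue modulus, which makes it the
#' analytic fixture for the full pipeline.
#'
#' @param shape `c(nx, ny, n_slices)`.
#' @param phi Area fraction in (0, 1]; must be exactly representable as a
#'   whole-pixel rectangle on the given grid.
#' @param pixel_size,slice_increment Micrometres.
#' @return An [image_stack()].
#' @export
make_prism_column <- function(shape, phi, pixel_size = 36,
                              slice_increment = 36) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (phi <= 0 || phi > 1) stop("`phi` must be in (0, 1]", call. = FALSE)
  target <- phi * shape[1] * shape[2]
  if (abs(target - round(target)) > 1e-9)
    stop("`phi` does not correspond to a whole number of pixels",
         call. = FALSE)
  target <- as.integer(round(target))
  # prefer the most compact exact rectangle a x b with a | target
  a_all <- seq_len(min(shape[1], target))
  a_ok <- a_all[target %% a_all == 0L & target / a_all <= shape[2]]
  if (length(a_ok) == 0L)
    stop("`phi` not representable as an axis-aligned rectangle on this grid",
         call. = FALSE)
  a <- a_ok[which.min(abs(a_ok - sqrt(target)))]
  b <- target %/% a
  slice <- matrix(0L, shape[1], shape[2])
  slice[seq_len(a), seq_len(b)] <- 1L
  image_stack(array(slice, shape), pixel_size, slice_increment)
}

#' Parallel-plate lattice phantom
#'
#' Solid slabs of thickness `thickness_px` repeating with period `period_px`
#' along the first in-plane axis, constant along the other two axes. This is
#' the plate-model fixture for the morphometric indices: BV/TV = t/p,
#' Tb.Th = t * pixel_size and Tb.N = (BV/TV)/Tb.Th.
#'
#' @param shape `c(nx, ny, n_slices)`.
#' @param thickness_px,period_px Slab thickness and repeat period in pixels,
#'   `thickness_px < period_px <= nx`.
#' @param pixel_size,slice_increment Micrometres.
#' @return An [image_stack()].
#' @export
make_plate_lattice <- function(shape, thickness_px, period_px,
                               pixel_size = 36, slice_increment = 36) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (thickness_px >= period_px)
    stop("`thickness_px` must be smaller than `period_px`", call. = FALSE)
  if (period_px > shape[1])
    stop("`period_px` exceeds the in-plane extent", call. = FALSE)
  col <- as.integer((seq_len(shape[1]) - 1L) %% period_px < thickness_px)
  slice <- matrix(col, shape[1], shape[2])
  image_stack(array(slice, shape), pixel_size, slice_increment)
}

#' Gaussian-random-field trabecular phantom
#'
#' Seeded white noise is smoothed with a (periodic) Gaussian kernel to the
#' requested correlation length and thresholded at the empirical quantile, so
#' the realized bone volume fraction matches `target_bvtv` to within one
#' voxel in the total count. The default field is isotropic. Setting
#' `anisotropy > 1` adds an axially elongated component (weighted by
#' `oriented_fraction`), emulating the preferential alignment of the femoral
#' head's primary compressive trabeculae; this stiffens and stabilises the
#' axial load path at the cost of the trabecular obliqueness that drives
#' coarsening-induced stiffness loss. On desk-scale grids, isotropic
#' realizations near physiological volume fractions can lack a spanning
#' load path altogether; cohort studies should screen realizations for a
#' nonzero basic-model reaction force, as physical specimens are implicitly
#' screened by their very existence.
#'
#' @param shape `c(nx, ny, n_slices)`.
#' @param target_bvtv Target bone volume fraction, in (0.02, 0.6).
#' @param correlation_length In-plane Gaussian smoothing length in
#'   micrometres (trabecular spacing analogue).
#' @param seed Integer seed; the phantom is bit-reproducible per seed.
#' @param pixel_size,slice_increment Micrometres.
#' @param anisotropy Axial-to-in-plane correlation length ratio of the
#'   oriented component.
#' @param oriented_fraction Amplitude weight of the oriented component
#'   relative to the isotropic one, in `[0, 1]`.
#' @return An [image_stack()].
#' @export
make_grf_phantom <- function(shape, target_bvtv, correlation_length = 100,
                             seed = 1, pixel_size = 36, slice_increment = 36,
                             anisotropy = 1, oriented_fraction = 0.5) {
  stopifnot(length(shape) == 3L, all(shape >= 2))
  if (target_bvtv <= 0.02 || target_bvtv >= 0.6)
    stop("`target_bvtv` must lie in (0.02, 0.6)", call. = FALSE)
  if (correlation_length <= 0)
    stop("`correlation_length` must be positive", call. = FALSE)
  n_vox <- prod(shape)
  if (n_vox < 1 / 0.01)
    stop("grid too small to realize the target volume fraction to +/-0.01",
         call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  noise <- array(stats::rnorm(n_vox), shape)
  sig_iso <- rep(correlation_length, 3) / c(pixel_size, pixel_size,
                                            slice_increment)
  if (abs(anisotropy - 1) < 1e-12 || oriented_fraction <= 0) {
    field <- gaussian_smooth_periodic(noise, sig_iso)
  } else if (oriented_fraction >= 1) {
    field <- gaussian_smooth_periodic(noise, sig_iso * c(1, 1, anisotropy))
  } else {
    # two-component architecture: axially oriented primary trabeculae plus
    # an isotropic secondary network, as a mixture smoothing kernel
    f_or <- gaussian_smooth_periodic(noise, sig_iso * c(1, 1, anisotropy))
    f_is <- gaussian_smooth_periodic(noise, sig_iso)
    w <- oriented_fraction
    field <- w * f_or / stats::sd(f_or) + (1 - w) * f_is / stats::sd(f_is)
  }
  thr <- stats::quantile(field, probs = 1 - target_bvtv, type = 7,
                         names = FALSE)
  image_stack((field > thr) + 0L, pixel_size, slice_increment)
}

# Periodic Gaussian smoothing of a 3-D array by FFT; sigma in voxels per axis.
gaussian_smooth_periodic <- function(x, sigma) {
  d <- dim(x)
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    i <- seq_len(n) - 1L
    # periodic (wrapped) distance along the axis
    dist <- pmin(i, n - i)
    k <- exp(-dist^2 / (2 * s^2))
    k / sum(k)
  }
  kx <- kern1(d[1], sigma[1])
  ky <- kern1(d[2], sigma[2])
  kz <- kern1(d[3], sigma[3])
  kern <- outer(outer(kx, ky), kz)
  dim(kern) <- d
  out <- Re(stats::fft(stats::fft(x) * stats::fft(kern), inverse = TRUE)) /
    prod(d)
  out
}
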