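#' Structural indices of a voxel model
#'
#' Computes the classical histomorphometric indices of trabecular bone from
#' a binary voxel model: bone volume fraction (BV/TV), trabecular thickness
#' (Tb.Th, local-thickness method), trabecular number (Tb.N, plate-model
#' ratio) and the mean bone volume per model layer (Vm).
#'
#' @param model A [voxel_model()].
#' @param boundary Passed to [compute_tbth()].
#' @return A one-row tibble with columns `bv_tv`, `tb_th_mm`, `tb_n_per_mm`,
#'   `vm_mm3`.
#' @export
compute_indices <- function(model, boundary = "background") {
  tb_th <- compute_tbth(model, boundary = boundary)
  bv_tv <- compute_bvtv(model)
  tibble::tibble(
    bv_tv = bv_tv,
    tb_th_mm = tb_th,
    tb_n_per_mm = bv_tv / tb_th,
    vm_mm3 = compute_vm(model)
  )
}

#' Bone volume fraction (BV/TV)
#'
#' Bone voxel volume over the total examined volume. When the model carries
#' an in-plane mask (the cored cylinder), the denominator is the masked
#' volume; otherwise it is the bounding box.
#'
#' @param model A [voxel_model()].
#' @return Fraction in `[0, 1]`.
#' @export
compute_bvtv <- function(model) {
  stopifnot(inherits(model, "voxel_model"))
  d <- dim(model$occupancy)
  if (prod(d) == 0) stop("model has zero volume", call. = FALSE)
  n_bone <- sum(model$occupancy)
  if (is.null(model$mask)) return(n_bone / prod(d))
  denom <- sum(model$mask) * d[3]
  if (denom == 0) stop("mask has zero area", call. = FALSE)
  n_bone / denom
}

#' Trabecular thickness (Tb.Th) by local thickness
#'
#' Mean, over bone voxels, of the diameter of the largest inscribed sphere
#' containing each voxel. Sphere centres live on a half-voxel-pitch lattice
#' (voxel centres, face centres, edge midpoints and corners of the voxel
#' grid), a centre's radius is its distance to the nearest non-bone lattice
#' node minus half the lattice pitch (placing the bone surface halfway
#' between bone and background samples), and a voxel's thickness is twice
#' the largest radius among spheres that cover its centre. On an extended
#' slab of thickness t voxels this evaluates exactly to t times the voxel
#' size, and an isolated voxel gets the voxel size itself.
#'
#' @param model A [voxel_model()].
#' @param boundary `"background"` (default) treats space beyond the grid as
#'   marrow, `"solid"` as bone (used to suppress edge effects on periodic
#'   fixtures). May be length 3 for per-axis control.
#' @return Mean thickness in millimetres.
#' @export
compute_tbth <- function(model, boundary = "background") {
  stopifnot(inherits(model, "voxel_model"))
  th <- local_thickness_um(model, boundary)
  occ <- model$occupancy == 1L
  if (!any(occ)) stop("model contains no bone voxels", call. = FALSE)
  mean(th[occ]) / 1000
}

#' Trabecular number (Tb.N) by the plate-model ratio
#'
#' Parfitt's plate-model identity Tb.N = (BV/TV) / Tb.Th.
#'
#' @param model A [voxel_model()].
#' @param tb_th Optionally a precomputed Tb.Th (mm) to reuse.
#' @param boundary Passed to [compute_tbth()] when `tb_th` is missing.
#' @return Trabeculae per millimetre.
#' @export
compute_tbn <- function(model, tb_th = NULL, boundary = "background") {
  if (is.null(tb_th)) tb_th <- compute_tbth(model, boundary = boundary)
  if (!is.numeric(tb_th) || tb_th <= 0)
    stop("degenerate trabecular thickness", call. = FALSE)
  compute_bvtv(model) / tb_th
}

#' Mean bone volume per model layer (Vm)
#'
#' Mean over the model's layers of (bone voxel count in the layer times the
#' voxel volume), in cubic millimetres.
#'
#' @param model A [voxel_model()].
#' @return Volume in mm^3.
#' @export
compute_vm <- function(model) {
  stopifnot(inherits(model, "voxel_model"))
  occ <- model$occupancy
  vox_mm3 <- (model$dx / 1000) * (model$dy / 1000) * (model$dz / 1000)
  counts <- apply(occ, 3, sum)
  mean(counts) * vox_mm3
}

#' Summary statistics over a sample cohort
#'
#' Per-index minimum, maximum, mean, sample standard deviation and relative
#' standard deviation. The RSD is reported as 100 * SD / mean, in percent.
#'
#' @param samples Data frame with one row per sample and one numeric column
#'   per index (e.g. the output of [compute_indices()] row-bound over
#'   samples). Non-numeric columns are ignored.
#' @return A tibble with columns `index`, `min`, `max`, `mean`, `sd`,
#'   `rsd_percent`.
#' @export
summarize_indices <- function(samples) {
  samples <- as.data.frame(samples)
  num <- samples[vapply(samples, is.numeric, logical(1))]
  if (nrow(num) < 2L)
    stop("need at least 2 samples to summarize", call. = FALSE)
  if (ncol(num) == 0L) stop("no numeric index columns", call. = FALSE)
  purrr::map_dfr(names(num), function(nm) {
    x <- num[[nm]]
    m <- mean(x)
    s <- stats::sd(x)
    tibble::tibble(index = nm, min = min(x), max = max(x), mean = m, sd = s,
                   rsd_percent = if (m == 0) NA_real_ else 100 * s / m)
  })
}

# ---- local thickness internals ----------------------------------------------

# Thickness map (um) over the voxel grid of `model`.
local_thickness_um <- function(model, boundary = "background") {
  occ <- model$occupancy == 1L
  if (!any(occ)) stop("model contains no bone voxels", call. = FALSE)
  if (length(boundary) == 1L) boundary <- rep(boundary, 3L)
  stopifnot(all(boundary %in% c("background", "solid")))
  d <- dim(occ)
  hf <- c(model$dx, model$dy, model$dz) / 2  # fine lattice pitch per axis
  # fine node lattice (2n+1 per axis); node is bone iff it touches a bone voxel
  B <- node_bone_lattice(occ)
  # pad with a background layer where the outside counts as marrow
  pad <- ifelse(boundary == "background", 1L, 0L)
  fd <- dim(B)
  P <- array(FALSE, fd + 2L * pad)
  P[pad[1] + seq_len(fd[1]), pad[2] + seq_len(fd[2]),
    pad[3] + seq_len(fd[3])] <- B
  if (!any(!P))
    stop("no bone-marrow interface: thickness undefined for an all-bone ",
         "model with solid boundaries", call. = FALSE)
  sq <- edt_squared(P, hf)
  sq <- sq[pad[1] + seq_len(fd[1]), pad[2] + seq_len(fd[2]),
           pad[3] + seq_len(fd[3]), drop = FALSE]
  r <- sqrt(sq) - min(hf)   # radius: distance to surface, offset half a pitch
  r[!B] <- 0
  thickness_from_radii(B, r, hf, d)
}

# Dilate voxel occupancy onto the (2n+1)^3 fine node lattice.
node_bone_lattice <- function(occ) {
  d <- dim(occ)
  fd <- 2L * d + 1L
  B <- array(FALSE, fd)
  # voxel (i,j,k) touches fine nodes (2i-1..2i+1, 2j-1..2j+1, 2k-1..2k+1)
  idx <- which(occ, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(B)
  for (ox in 0:2) for (oy in 0:2) for (oz in 0:2) {
    B[cbind(2L * idx[, 1] - 1L + ox,
            2L * idx[, 2] - 1L + oy,
            2L * idx[, 3] - 1L + oz)] <- TRUE
  }
  B
}

# Exact squared Euclidean distance (anisotropic spacing) from every node to
# the nearest FALSE node; Felzenszwalb-Huttenlocher separable transform.
edt_squared <- function(B, spacing) {
  d <- dim(B)
  INF <- sum((d * spacing)^2) * 4 + 1
  f <- array(ifelse(B, INF, 0), d)
  for (ax in 1:3) {
    f <- aperm(f, c(ax, setdiff(1:3, ax)))
    dd <- dim(f)
    m <- matrix(f, dd[1])
    m <- dt1d_cols(m, spacing[ax], INF)
    f <- array(m, dd)
    f <- aperm(f, order(c(ax, setdiff(1:3, ax))))
  }
  f
}

# 1-D squared-distance transform applied to every column of m; pitch w.
dt1d_cols <- function(m, w, INF) {
  n <- nrow(m)
  if (n == 1L) return(m)
  x <- (seq_len(n) - 1) * w
  for (j in seq_len(ncol(m))) {
    fcol <- m[, j]
    if (all(fcol == 0) || all(fcol >= INF)) next
    m[, j] <- dt1d(fcol, x, INF)
  }
  m
}

dt1d <- function(f, x, INF) {
  n <- length(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= z[k]) { k <- k - 1L; if (k == 0L) { k <- 1L; v[1] <- q
        z[1] <- -Inf; z[2] <- Inf; break } } else {
        k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf; break
      }
    }
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    p <- v[k]
    out[q] <- (x[q] - x[p])^2 + f[p]
  }
  out
}

# Sphere-painting: thickness at each voxel centre = 2 * max radius among
# candidate spheres covering it. Candidate centres are reduced to the
# distance ridge (a centre whose sphere lies inside a neighbour's is
# dropped), then processed in descending radius.
thickness_from_radii <- function(B, r, hf, vox_dim) {
  fd <- dim(B)
  cand <- which(B & r > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(array(0, vox_dim))
  rc <- r[cand]
  keep <- rep(TRUE, nrow(cand))
  # dominance filter against the 26-neighbourhood
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    if (ox == 0 && oy == 0 && oz == 0) next
    ni <- cand[, 1] + ox; nj <- cand[, 2] + oy; nk <- cand[, 3] + oz
    ok <- ni >= 1 & ni <= fd[1] & nj >= 1 & nj <= fd[2] & nk >= 1 & nk <= fd[3]
    if (!any(ok)) next
    dn <- sqrt((ox * hf[1])^2 + (oy * hf[2])^2 + (oz * hf[3])^2)
    rn <- rep(-Inf, nrow(cand))
    rn[ok] <- r[cbind(ni[ok], nj[ok], nk[ok])]
    keep <- keep & !(rn >= rc + dn - 1e-9)
  }
  cand <- cand[keep, , drop = FALSE]
  rc <- rc[keep]
  ord <- order(rc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  rc <- rc[ord]
  th <- array(0, vox_dim)
  # voxel centre (i,j,k) sits at fine index (2i, 2j, 2k)
  for (t in seq_len(nrow(cand))) {
    rt <- rc[t]
    ci <- cand[t, 1]; cj <- cand[t, 2]; ck <- cand[t, 3]
    # voxel-centre index ranges within the sphere's bounding box
    ir <- ceiling((ci - rt / hf[1]) / 2):floor((ci + rt / hf[1]) / 2)
    jr <- ceiling((cj - rt / hf[2]) / 2):floor((cj + rt / hf[2]) / 2)
    kr <- ceiling((ck - rt / hf[3]) / 2):floor((ck + rt / hf[3]) / 2)
    ir <- ir[ir >= 1 & ir <= vox_dim[1]]
    jr <- jr[jr >= 1 & jr <= vox_dim[2]]
    kr <- kr[kr >= 1 & kr <= vox_dim[3]]
    if (!length(ir) || !length(jr) || !length(kr)) next
    dx2 <- ((2 * ir - ci) * hf[1])^2
    dy2 <- ((2 * jr - cj) * hf[2])^2
    dz2 <- ((2 * kr - ck) * hf[3])^2
    dist2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    cover <- dist2 <= rt^2 + 1e-9
    sub <- th[ir, jr, kr, drop = FALSE]
    upd <- cover & (sub < 2 * rt)
    if (any(upd)) {
      sub[upd] <- 2 * rt
      th[ir, jr, kr] <- sub
    }
  }
  th
}
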