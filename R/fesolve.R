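#' Material properties of the bone tissue
#'
#' Homogeneous isotropic linear elasticity for the solid (tissue) phase.
#' The defaults are the values conventionally used for human trabecular
#' tissue in voxel-based micro-FE: E = 10 GPa, nu = 0.3.
#'
#' @param e_tissue_gpa Tissue Young's modulus in GPa (> 0).
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @return A list of class `material_props`.
#' @export
material_props <- function(e_tissue_gpa = 10, nu = 0.3) {
  if (!is.numeric(e_tissue_gpa) || e_tissue_gpa <= 0)
    stop("`e_tissue_gpa` must be positive", call. = FALSE)
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5)
    stop("`nu` must lie in [0, 0.5)", call. = FALSE)
  structure(list(e_tissue_gpa = e_tissue_gpa, nu = nu),
            class = "material_props")
}

#' Uniaxial compression load case
#'
#' Kinematic compression along the slice axis: the bottom base gets zero
#' axial displacement, the top base gets a prescribed axial displacement of
#' `-strain * height`; lateral displacements on both bases are free apart
#' from a minimal rigid-body suppression.
#'
#' @param strain Compressive strain (dimensionless), in (0, 0.05). The study
#'   convention is 0.8 percent.
#' @return A list of class `load_case`.
#' @export
load_case <- function(strain = 0.008) {
  if (!is.numeric(strain) || strain <= 0 || strain >= 0.05)
    stop("`strain` must lie in (0, 0.05)", call. = FALSE)
  structure(list(strain = strain, axis = 3L), class = "load_case")
}

#' Stiffness matrix of a cubic 8-node trilinear hexahedron
#'
#' 24 x 24 symmetric stiffness of a cube of edge `h` with isotropic material,
#' integrated with 2 x 2 x 2 Gauss quadrature (exact for the trilinear
#' element on an undistorted cube). All elements in a mesh share this one
#' matrix, so it is computed once per solve.
#'
#' @param mat A [material_props()].
#' @param h Element edge length in micrometres.
#' @param ngauss Gauss points per direction (default 2).
#' @return 24 x 24 numeric matrix in N/mm (displacements in mm).
#' @export
element_stiffness <- function(mat, h, ngauss = 2L) {
  stopifnot(inherits(mat, "material_props"), h > 0)
  h_mm <- h / 1000
  e_mpa <- mat$e_tissue_gpa * 1000
  D <- iso_elasticity_matrix(e_mpa, mat$nu)
  gp <- gauss_points(ngauss)
  K <- matrix(0, 24, 24)
  half <- h_mm / 2
  detJ <- half^3
  for (a in seq_len(nrow(gp))) {
    xi <- gp[a, 1]; eta <- gp[a, 2]; zeta <- gp[a, 3]; w <- gp[a, 4]
    dN <- hex8_dshape(xi, eta, zeta) / half  # derivatives w.r.t. x,y,z (mm)
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- dN[i, 1]
      B[2, c0 + 2] <- dN[i, 2]
      B[3, c0 + 3] <- dN[i, 3]
      B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
      B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
      B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
    }
    K <- K + t(B) %*% D %*% B * detJ * w
  }
  (K + t(K)) / 2
}

iso_elasticity_matrix <- function(e, nu) {
  lam <- e * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- e / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# natural-coordinate corner signs matching the mesh node ordering
hex8_corners <- function() {
  rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
        c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
}

# dN_i/d(xi, eta, zeta) at one natural point, 8 x 3
hex8_dshape <- function(xi, eta, zeta) {
  s <- hex8_corners()
  cbind(s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta),
        (1 + s[, 1] * xi) * s[, 2] * (1 + s[, 3] * zeta),
        (1 + s[, 1] * xi) * (1 + s[, 2] * eta) * s[, 3]) / 8
}

gauss_points <- function(n) {
  g1 <- switch(as.character(n),
    "1" = list(x = 0, w = 2),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9),
    "4" = {
      a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5))
      b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
      wa <- (18 + sqrt(30)) / 36
      wb <- (18 - sqrt(30)) / 36
      list(x = c(-b, -a, a, b), w = c(wb, wa, wa, wb))
    },
    stop("unsupported quadrature order", call. = FALSE))
  pts <- expand.grid(xi = g1$x, eta = g1$x, zeta = g1$x)
  w <- expand.grid(g1$w, g1$w, g1$w)
  cbind(as.matrix(pts), w = w[, 1] * w[, 2] * w[, 3])
}

#' Solve uniaxial compression on a hexahedral mesh
#'
#' Assembles the global sparse stiffness, applies the kinematic boundary
#' conditions (axial displacement zero on the bottom face, `-strain * H` on
#' the top face, lateral displacements free apart from a minimal 3-DOF
#' rigid-body suppression on the bottom face) and solves the linear system.
#' The compressive axial force F is the sum of axial reactions on the driven
#' face; the apparent modulus is (F / A_nominal) / strain with A_nominal the
#' nominal (masked or bounding-box) cross-section.
#'
#' @param mesh A filtered, face-connected `hex_mesh` (see
#'   [filter_connectivity()]).
#' @param mat A [material_props()].
#' @param load A [load_case()].
#' @param solver `"auto"` (direct), `"direct"` (sparse Cholesky) or `"cg"`
#'   (Jacobi-preconditioned conjugate gradients).
#' @param tol Relative residual tolerance for the iterative solver.
#' @param max_iter Iteration cap for the iterative solver.
#' @return An object of class `fe_result`: list with `displacements_mm`
#'   (n x 3), `force_n` (compressive axial force, N), `e_app_gpa`,
#'   `area_mm2`, `height_mm`, `strain`, `diagnostics` (list: solver,
#'   iterations, relative residual, equilibrium gap).
#' @export
assemble_and_solve <- function(mesh, mat = material_props(),
                               load = load_case(),
                               solver = c("auto", "direct", "cg"),
                               tol = 1e-8, max_iter = 20000L) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(mat, "material_props"),
            inherits(load, "load_case"))
  solver <- match.arg(solver)
  nodes_mm <- mesh$nodes / 1000
  nn <- nrow(nodes_mm)
  z <- nodes_mm[, 3]
  # the platens sit at the *model's* bases, not at the extent of whatever
  # survived connectivity filtering: a mesh that does not reach both bases
  # carries no load and is a structural error
  z_min <- 0
  z_max <- mesh$height_um / 1000
  height_mm <- z_max - z_min
  ztol <- mesh$h / 1000 * 1e-6
  fixed_nodes <- which(abs(z - z_min) < ztol)
  driven_nodes <- which(abs(z - z_max) < ztol)
  if (length(fixed_nodes) == 0L || length(driven_nodes) == 0L)
    stop("mesh has no nodes on a loading face (load path does not span ",
         "the specimen)", call. = FALSE)
  u_top <- -load$strain * height_mm

  Ke <- element_stiffness(mat, mesh$h)
  K <- assemble_global(mesh$elems, Ke, nn)

  dof_z <- function(n) 3L * (n - 1L) + 3L
  presc_idx <- c(dof_z(fixed_nodes), dof_z(driven_nodes))
  presc_val <- c(rep(0, length(fixed_nodes)),
                 rep(u_top, length(driven_nodes)))
  # minimal rigid-body suppression on the fixed face: pin node A in x and y,
  # and a second node sharing A's y-coordinate in y only (kills the rotation
  # about the load axis without constraining lateral expansion)
  fx <- nodes_mm[fixed_nodes, 1]; fy <- nodes_mm[fixed_nodes, 2]
  ordA <- order(fx, fy)
  A <- fixed_nodes[ordA[1]]
  sameY <- fixed_nodes[abs(fy - nodes_mm[A, 2]) < ztol & fixed_nodes != A]
  B <- if (length(sameY) > 0)
    sameY[which.max(abs(nodes_mm[sameY, 1] - nodes_mm[A, 1]))]
  else fixed_nodes[fixed_nodes != A][1]
  pin_idx <- c(3L * (A - 1L) + 1L, 3L * (A - 1L) + 2L)
  if (!is.na(B) && length(B) == 1L)
    pin_idx <- c(pin_idx, 3L * (B - 1L) + 2L)
  presc_idx <- c(presc_idx, pin_idx)
  presc_val <- c(presc_val, rep(0, length(pin_idx)))

  ndof <- 3L * nn
  is_presc <- rep(FALSE, ndof)
  is_presc[presc_idx] <- TRUE
  free <- which(!is_presc)

  up <- numeric(ndof)
  up[presc_idx] <- presc_val
  rhs <- -as.numeric((K %*% up)[free])
  Kff <- K[free, free, drop = FALSE]
  u <- up
  it <- NA_integer_
  if (solver %in% c("auto", "direct")) {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                           super = TRUE)
    uf <- Matrix::solve(ch, rhs, system = "A")
    u[free] <- as.numeric(uf)
    solver_used <- "direct"
  } else {
    cgres <- jacobi_cg(Kff, rhs, tol = tol, max_iter = max_iter)
    u[free] <- cgres$x
    it <- cgres$iterations
    solver_used <- "cg"
    if (!cgres$converged)
      stop(sprintf(
        "CG failed to converge in %d iterations (relative residual %.3g)",
        cgres$iterations, cgres$rel_residual), call. = FALSE)
  }
  r_all <- as.numeric(K %*% u)
  res_free <- sqrt(sum(r_all[free]^2))
  ref <- sqrt(sum((K %*% up)[free]^2))
  rel_res <- if (ref > 0) res_free / ref else res_free

  driven_z <- dof_z(driven_nodes)
  fixed_z <- dof_z(fixed_nodes)
  f_driven <- sum(r_all[driven_z])
  f_fixed <- sum(r_all[fixed_z])
  force_n <- abs(f_driven)
  eq_gap <- if (force_n > 0) abs(f_fixed + f_driven) / force_n else 0
  e_app <- apparent_modulus(force_n, mesh$area_mm2, load$strain)
  structure(list(
    displacements_mm = matrix(u, ncol = 3, byrow = TRUE),
    force_n = force_n,
    e_app_gpa = e_app,
    area_mm2 = mesh$area_mm2,
    height_mm = height_mm,
    strain = load$strain,
    diagnostics = list(solver = solver_used, iterations = it,
                       rel_residual = rel_res, equilibrium_gap = eq_gap,
                       n_elements = nrow(mesh$elems), n_nodes = nn)
  ), class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf(
    "<fe_result> F = %.6g N | E_app = %.6g GPa | %d elements, %d nodes\n",
    x$force_n, x$e_app_gpa, x$diagnostics$n_elements, x$diagnostics$n_nodes))
  cat(sprintf("  solver %s, rel. residual %.2e, equilibrium gap %.2e\n",
              x$diagnostics$solver, x$diagnostics$rel_residual,
              x$diagnostics$equilibrium_gap))
  invisible(x)
}

#' Apparent elastic modulus from the axial reaction force
#'
#' `E_app = (F / A_nominal) / strain`, with `A_nominal` the nominal
#' (specimen) cross-section, not the bone area. A zero force on a nonempty
#' mesh signals a disconnected load path and is flagged with a warning.
#'
#' @param force_n Compressive axial force in newtons.
#' @param area_mm2 Nominal cross-section area in mm^2.
#' @param strain Applied compressive strain.
#' @return Apparent modulus in GPa.
#' @export
apparent_modulus <- function(force_n, area_mm2, strain) {
  if (!is.numeric(area_mm2) || area_mm2 <= 0)
    stop("`area_mm2` must be positive", call. = FALSE)
  if (!is.numeric(strain) || strain <= 0)
    stop("`strain` must be positive", call. = FALSE)
  if (force_n == 0)
    warning("zero reaction force: load path is disconnected", call. = FALSE)
  (force_n / area_mm2) / strain / 1000
}

# Global sparse stiffness from one shared element matrix.
assemble_global <- function(elems, Ke, n_nodes) {
  nel <- nrow(elems)
  dofs <- matrix(0L, nel, 24L)
  for (i in 1:8) {
    dofs[, 3 * i - 2] <- 3L * (elems[, i] - 1L) + 1L
    dofs[, 3 * i - 1] <- 3L * (elems[, i] - 1L) + 2L
    dofs[, 3 * i] <- 3L * (elems[, i] - 1L) + 3L
  }
  ii <- as.vector(dofs[, rep(seq_len(24), times = 24), drop = FALSE])
  jj <- as.vector(dofs[, rep(seq_len(24), each = 24), drop = FALSE])
  xx <- rep(as.vector(Ke), each = nel)
  # keep one triangle; the matrix is assembled directly as symmetric
  lower <- ii >= jj
  Matrix::sparseMatrix(i = ii[lower], j = jj[lower], x = xx[lower],
                       dims = c(3L * n_nodes, 3L * n_nodes),
                       symmetric = TRUE)
}

# Jacobi-preconditioned conjugate gradients for SPD sparse systems.
jacobi_cg <- function(A, b, tol = 1e-8, max_iter = 20000L) {
  dinv <- 1 / Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b^2))
  if (b_norm == 0) return(list(x = x, iterations = 0L, converged = TRUE,
                               rel_residual = 0))
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / b_norm
    if (rel <= tol)
      return(list(x = x, iterations = it, converged = TRUE,
                  rel_residual = rel))
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = max_iter, converged = FALSE,
       rel_residual = sqrt(sum(r^2)) / b_norm)
}

#' Apparent modulus of a voxel model (mesh, filter, solve)
#'
#' Convenience wrapper running [voxels_to_elements()],
#' [filter_connectivity()] and [assemble_and_solve()].
#'
#' @param model A [voxel_model()].
#' @param mat A [material_props()].
#' @param load A [load_case()].
#' @param ... Passed to [assemble_and_solve()].
#' @return An `fe_result`.
#' @export
solve_model <- function(model, mat = material_props(), load = load_case(),
                        ...) {
  mesh <- filter_connectivity(voxels_to_elements(model))
  assemble_and_solve(mesh, mat, load, ...)
}
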