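test_that("element stiffness is symmetric with exactly the rigid-body
           null space", {
  mat <- material_props(10, 0.3)
  K <- element_stiffness(mat, 36)
  expect_equal(K, t(K), tolerance = 1e-14)
  # rigid translations and infinitesimal rotations produce zero force
  corners <- trabfe:::hex8_corners()
  rigid <- list(
    cbind(rep(1, 8), 0, 0), cbind(0, rep(1, 8), 0), cbind(0, 0, rep(1, 8)),
    cbind(-corners[, 2], corners[, 1], 0),
    cbind(0, -corners[, 3], corners[, 2]),
    cbind(corners[, 3], 0, -corners[, 1]))
  for (rv in rigid) {
    v <- as.vector(t(rv))
    expect_lt(max(abs(K %*% v)), max(abs(K)) * 1e-12)
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < max(ev) * 1e-10), 6)
  expect_error(material_props(10, 0.5), "nu")
})

test_that("element stiffness matches refined-quadrature numerical
           integration", {
  for (nu in c(0, 0.3, 0.45)) {
    mat <- material_props(10, nu)
    K2 <- element_stiffness(mat, 36)
    K4 <- oracle_element_stiffness(mat, 36)
    expect_lt(max(abs(K2 - K4)) / max(abs(K4)), 1e-9)
  }
})

test_that("a single element under 0.8% strain passes the patch test", {
  mesh <- voxels_to_elements(voxel_model(array(1L, c(1, 1, 1)), 36, 36, 36))
  res <- assemble_and_solve(mesh, material_props(10, 0.3), load_case(0.008))
  # axial stress E * eps = 80 MPa over 36 um x 36 um
  area_mm2 <- 0.036^2
  expect_equal(res$force_n, 80 * area_mm2, tolerance = 1e-10)
  expect_equal(res$e_app_gpa, 10, tolerance = 1e-10)
  # displacement field is linear: lateral Poisson expansion nu * eps
  u <- res$displacements_mm
  z <- mesh$nodes[, 3] / 1000
  expect_equal(u[, 3], -0.008 * z, tolerance = 1e-12)
})

test_that("solid blocks reproduce the tissue modulus for any Poisson ratio", {
  model <- voxel_model(array(1L, c(3, 2, 4)), 36, 36, 36)
  for (nu in c(0, 0.25, 0.49)) {
    res <- solve_model(model, material_props(10, nu))
    expect_equal(res$e_app_gpa, 10, tolerance = 1e-6)
  }
})

test_that("prism columns carry load over exactly their area fraction", {
  for (phi in c(0.25, 0.5)) {
    stk <- make_prism_column(c(8, 8, 5), phi)
    res <- solve_model(build_basic_model(stk))
    expect_equal(res$e_app_gpa, phi * 10, tolerance = 1e-6)
  }
})

test_that("sparse solve agrees with the dense direct oracle", {
  g <- build_basic_model(make_grf_phantom(c(6, 6, 8), 0.45, 100, seed = 12))
  mesh <- filter_connectivity(voxels_to_elements(g))
  expect_lte(nrow(mesh$elems), 200)
  mat <- material_props(10, 0.3)
  res <- assemble_and_solve(mesh, mat, load_case(0.008))
  orc <- oracle_dense_solve(mesh, mat, 0.008)
  u_pkg <- as.vector(t(res$displacements_mm))
  scale <- max(abs(orc$u))
  expect_lt(max(abs(u_pkg - orc$u)) / scale, 1e-8)
  expect_equal(res$force_n, orc$force_n, tolerance = 1e-8)
})

test_that("iterative and direct solvers agree", {
  g <- build_basic_model(make_grf_phantom(c(8, 8, 10), 0.4, 100, seed = 6))
  mesh <- filter_connectivity(voxels_to_elements(g))
  d <- assemble_and_solve(mesh, solver = "direct")
  i <- assemble_and_solve(mesh, solver = "cg", tol = 1e-10)
  expect_equal(i$force_n, d$force_n, tolerance = 1e-6)
  expect_gt(i$diagnostics$iterations, 0)
})

test_that("reactions are in equilibrium and invariant to mesh translation", {
  g <- build_basic_model(make_grf_phantom(c(8, 8, 10), 0.4, 100, seed = 14))
  mesh <- filter_connectivity(voxels_to_elements(g))
  res <- assemble_and_solve(mesh)
  expect_lt(res$diagnostics$equilibrium_gap, 1e-6)
  shifted <- mesh
  shifted$nodes <- sweep(mesh$nodes, 2, c(500, -220, 0), `+`)
  res2 <- assemble_and_solve(shifted)
  expect_equal(res2$force_n, res$force_n, tolerance = 1e-9)
})

test_that("removing elements never stiffens the structure", {
  g <- build_basic_model(make_grf_phantom(c(8, 8, 10), 0.5, 100, seed = 18))
  mesh <- filter_connectivity(voxels_to_elements(g))
  full <- assemble_and_solve(mesh)
  # drop one interior element (keeping connectivity via re-filter)
  occ <- array(0L, dim = g$occupancy |> dim())
  occ[g$occupancy == 1L] <- 1L
  idx <- which(occ == 1L)
  occ[idx[length(idx) %/% 2]] <- 0L
  sub <- filter_connectivity(voxels_to_elements(voxel_model(occ, 36, 36, 36)))
  res_sub <- assemble_and_solve(sub)
  expect_lte(res_sub$e_app_gpa, full$e_app_gpa + 1e-12)
})

test_that("apparent modulus handles the degenerate zero-force case", {
  expect_warning(e0 <- apparent_modulus(0, 1, 0.008), "disconnected")
  expect_equal(e0, 0)
  expect_error(apparent_modulus(1, 0, 0.008), "area")
  expect_error(apparent_modulus(1, 1, 0), "strain")
})
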