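test_that("BV/TV is the exact voxel count ratio", {
  solid <- build_basic_model(make_solid_block(c(6, 6, 4)))
  expect_equal(compute_bvtv(solid), 1)
  prism <- build_basic_model(make_prism_column(c(8, 8, 4), 0.25))
  expect_equal(compute_bvtv(prism), 0.25)
  g <- make_grf_phantom(c(24, 24, 30), 0.3, 100, seed = 5)
  m <- build_basic_model(g)
  expect_equal(compute_bvtv(m), sum(m$occupancy) / prod(dim(m$occupancy)))
})

test_that("BV/TV uses the mask area as denominator when masked", {
  stk <- apply_cylinder_mask(make_solid_block(c(60, 60, 3)), 2)
  m <- build_basic_model(stk)
  # all in-mask pixels are bone, so the masked fraction is exactly 1
  expect_equal(compute_bvtv(m), 1)
  # unmasked fraction would be well below 1
  m_nomask <- voxel_model(m$occupancy, 36, 36, 36)
  expect_lt(compute_bvtv(m_nomask), 1)
})

test_that("local thickness reproduces slab and single-voxel closed forms", {
  # infinite-slab plate lattice, t = 2 voxels: Tb.Th = 72 um, with the
  # lateral/axial boundaries treated as bone to emulate periodic extension
  pl <- build_basic_model(make_plate_lattice(c(16, 8, 7), 2, 8))
  expect_equal(compute_tbth(pl, boundary = c("background", "solid", "solid")),
               0.072, tolerance = 1e-12)
  # a single isolated voxel is a 36 um sphere bound
  occ <- array(0L, c(5, 5, 5)); occ[3, 3, 3] <- 1L
  iso <- voxel_model(occ, 36, 36, 36)
  expect_equal(compute_tbth(iso), 0.036, tolerance = 1e-12)
  expect_error(compute_tbth(voxel_model(array(0L, c(3, 3, 3)), 36, 36, 36)),
               "no bone")
})

test_that("local thickness matches the brute-force inscribed-sphere oracle", {
  set.seed(17)
  occ <- array(rbinom(8^3, 1, 0.45), c(8, 8, 8))
  occ[4, 4, 4] <- 1L
  model <- voxel_model(occ, 36, 36, 36)
  th_pkg <- trabfe:::local_thickness_um(model)
  th_orc <- oracle_local_thickness(model)
  expect_equal(th_pkg, th_orc, tolerance = 1e-9)
})

test_that("Tb.N satisfies the plate-model identities", {
  pl <- build_basic_model(make_plate_lattice(c(16, 8, 7), 2, 8))
  tbth <- compute_tbth(pl, boundary = c("background", "solid", "solid"))
  tbn <- compute_tbn(pl, tb_th = tbth)
  expect_equal(tbn, 0.25 / 0.072, tolerance = 1e-12)
  # definitional identity tb_n * tb_th == bv_tv on an arbitrary model
  g <- build_basic_model(make_grf_phantom(c(20, 20, 24), 0.3, 100, seed = 2))
  tbth <- compute_tbth(g)
  expect_equal(compute_tbn(g, tb_th = tbth) * tbth, compute_bvtv(g),
               tolerance = 1e-14)
  expect_error(compute_tbn(g, tb_th = 0), "degenerate")
})

test_that("mean layer volume Vm follows the closed form and the per-layer
           counting oracle", {
  solid <- build_basic_model(make_solid_block(c(64, 64, 5)))
  expect_equal(compute_vm(solid), 64 * 64 * 0.036^3, tolerance = 1e-12)
  expect_equal(round(compute_vm(solid), 3), 0.191)
  empty <- voxel_model(array(0L, c(4, 4, 3)), 36, 36, 36)
  expect_equal(compute_vm(empty), 0)
  g <- build_basic_model(make_grf_phantom(c(16, 16, 20), 0.25, 100, seed = 3))
  counts <- vapply(seq_len(dim(g$occupancy)[3]),
                   function(k) sum(g$occupancy[, , k]), numeric(1))
  expect_equal(compute_vm(g), mean(counts) * 0.036^3, tolerance = 1e-12)
})

test_that("cohort summaries report RSD = 100 * SD / mean", {
  # two-point samples engineered to the printed (mean, SD) pairs
  mk <- function(mean, sd) c(mean - sd / sqrt(2), mean + sd / sqrt(2))
  df <- data.frame(bv_tv = mk(0.222, 0.079), tb_th = mk(0.151, 0.036),
                   tb_n = mk(1.436, 0.267))
  s <- summarize_indices(df)
  expect_equal(round(s$rsd_percent[s$index == "bv_tv"]), 36)
  expect_equal(round(s$rsd_percent[s$index == "tb_th"]), 24)
  expect_equal(round(s$rsd_percent[s$index == "tb_n"]), 19)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  # identical samples: SD and RSD are zero
  same <- summarize_indices(data.frame(x = c(2, 2, 2)))
  expect_equal(same$sd, 0)
  expect_equal(same$rsd_percent, 0)
  expect_error(summarize_indices(data.frame(x = 1)), "at least 2")
})
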