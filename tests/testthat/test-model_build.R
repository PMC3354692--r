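test_that("basic model is the AND of consecutive slices", {
  # two identical solid slices give one solid layer
  solid <- make_solid_block(c(4, 4, 2))
  m <- build_basic_model(solid)
  expect_equal(dim(m$occupancy), c(4, 4, 1))
  expect_true(all(m$occupancy == 1L))

  # bone in only one slice of a pair leaves the voxel empty
  arr <- array(0L, c(3, 3, 2))
  arr[2, 2, 1] <- 1L
  m <- build_basic_model(image_stack(arr, 36, 36))
  expect_equal(sum(m$occupancy), 0)

  # seeded random stack equals the elementwise AND oracle
  stk <- rand_stack(c(10, 10, 6), p = 0.5, seed = 21)
  m <- build_basic_model(stk)
  oracle <- oracle_pair_model(stk, 1:5, 2:6)
  expect_identical(m$occupancy, oracle)

  expect_error(build_basic_model(image_stack(array(1L, c(3, 3, 1)), 36, 36)),
               "at least 2 slices")
})

test_that("cuberrille majority rule is strict", {
  # 5/8 bone sub-voxels -> bone; exactly 4/8 -> empty
  occ <- array(0L, c(2, 2, 2))
  occ[c(1, 2, 3, 4, 5)] <- 1L
  m5 <- coarsen_h(voxel_model(occ, 36, 36, 36), 72)
  expect_equal(as.integer(m5$occupancy[1, 1, 1]), 1L)
  occ4 <- array(0L, c(2, 2, 2))
  occ4[c(1, 2, 3, 4)] <- 1L
  m4 <- coarsen_h(voxel_model(occ4, 36, 36, 36), 72)
  expect_equal(as.integer(m4$occupancy[1, 1, 1]), 0L)
})

test_that("hexahedral coarsening matches the exhaustive counting oracle", {
  solid <- build_basic_model(make_solid_block(c(4, 4, 5)))
  m <- coarsen_h(solid, 72)
  expect_equal(dim(m$occupancy), c(2, 2, 2))
  expect_true(all(m$occupancy == 1L))
  expect_equal(m$dz, 72)

  set.seed(31)
  occ <- array(rbinom(12^3, 1, 0.5), c(12, 12, 12))
  model <- voxel_model(occ, 36, 36, 36)
  for (s in c(72, 108, 144)) {
    f <- s / 36
    expect_identical(coarsen_h(model, s)$occupancy,
                     oracle_coarsen_h(occ, f),
                     info = paste("s =", s))
  }
  expect_error(coarsen_h(model, 100), "multiple")
  expect_error(coarsen_h(model, 360), "conventional range")
  expect_silent(coarsen_h(model, 360, enforce_range = FALSE))
})

test_that("slice-pairing methods match their index-pair enumeration oracles", {
  stk <- rand_stack(c(10, 10, 31), p = 0.5, seed = 41)
  # First-Last, d = 108: layers AND slices (0,3), (3,6), ... (0-based)
  m <- coarsen_fl(stk, 108)
  first <- seq(1, by = 3, length.out = 10)
  expect_identical(m$occupancy, oracle_pair_model(stk, first, first + 3))
  expect_equal(m$dz, 108)
  # First-Second, d = 144: pairs (0,1), (4,5), (8,9), ...
  m <- coarsen_fs(stk, 144)
  first <- seq(1, by = 4, length.out = 7)
  expect_identical(m$occupancy, oracle_pair_model(stk, first, first + 1))
  # First-Third, d = 216: pairs (0,2), (6,8), (12,14), ...
  m <- coarsen_ft(stk, 216)
  first <- seq(1, by = 6, length.out = 5)
  expect_identical(m$occupancy, oracle_pair_model(stk, first, first + 2))
})

test_that("pairing preconditions and step rules are enforced", {
  stk <- rand_stack(c(4, 4, 5), p = 0.5, seed = 2)
  expect_error(coarsen_fl(stk, 100), "multiple")
  expect_error(coarsen_ft(stk, 108), "twice the slice increment")
  expect_error(coarsen_fl(stk, 1116), "conventional range")
  short <- rand_stack(c(4, 4, 3), p = 0.5, seed = 2)
  expect_error(coarsen_fl(short, 144), "at least")
  expect_error(coarsen_ft(short, 72), "at least")
})

test_that("every method is the identity on solid stacks", {
  solid <- make_solid_block(c(6, 6, 13))
  for (d in c(72, 144)) {
    expect_true(all(coarsen_fl(solid, d)$occupancy == 1L))
    expect_true(all(coarsen_fs(solid, d)$occupancy == 1L))
    expect_true(all(coarsen_ft(solid, 144)$occupancy == 1L))
  }
  expect_true(all(coarsen_h(build_basic_model(solid), 72)$occupancy == 1L))
})

test_that("First-Third at 72 um coincides with First-Last at 72 um", {
  for (seed in 1:3) {
    stk <- rand_stack(c(8, 8, 15), p = 0.4, seed = seed)
    expect_identical(coarsen_ft(stk, 72)$occupancy,
                     coarsen_fl(stk, 72)$occupancy)
  }
})

test_that("First-Second at the base increment reproduces the basic model", {
  stk <- rand_stack(c(8, 8, 9), p = 0.5, seed = 7)
  m <- coarsen_fs(stk, 36, enforce_range = FALSE)
  expect_identical(m$occupancy, build_basic_model(stk)$occupancy)
})

test_that("pairing never creates bone where the first slice is empty", {
  stk <- rand_stack(c(8, 8, 13), p = 0.5, seed = 9)
  for (mk in list(function() coarsen_fl(stk, 144),
                  function() coarsen_fs(stk, 144),
                  function() coarsen_ft(stk, 144))) {
    m <- mk()
    nl <- dim(m$occupancy)[3]
    mfac <- 4
    for (k in seq_len(nl)) {
      first_slice <- stk$slices[, , (k - 1) * mfac + 1]
      expect_true(all(m$occupancy[, , k] <= first_slice))
    }
    # bone volume never exceeds the source stack volume fraction scale
    expect_lte(sum(m$occupancy), sum(stk$slices))
  }
})
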