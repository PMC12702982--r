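
test_that("solid block under 1% axial compression has uniform eps_eff 0.01", {
  ts <- solid_block(6)
  sf <- solve_microfe(ts, material_map(ts), load_case(0.01), rtol = 1e-10)
  eps <- sf[!is.na(sf)]
  expect_equal(max(abs(eps - 0.01)), 0, tolerance = 1e-8)
  # energy consistency: U = 1/2 F delta
  delta <- 0.01 * 6 * ts$spacing
  expect_equal(attr(sf, "strain_energy"),
               0.5 * attr(sf, "total_force") * delta, tolerance = 1e-8)
  # analytic reaction force: sigma A = E eps A
  expect_equal(attr(sf, "total_force"),
               10000 * 0.01 * (6 * 14)^2 * 1e-6, tolerance = 1e-6)
})

test_that("CG solution matches the dense direct-solve oracle on small meshes", {
  set.seed(8)
  vol <- array(0, c(5, 5, 6))
  vol[2:4, 2:4, ] <- 1            # spanning column
  vol[2:4, 2:4, 3] <- rep(c(1, 1, 0), 3)  # carve some heterogeneity
  vol[2, 2, ] <- 1
  ts <- tissue_state(vol * 1, vol * 1)
  ts$mineral[bone_mask(ts)] <- runif(sum(bone_mask(ts)), 0.5, 1)
  mat <- material_map(ts)
  ref <- dense_fe_reference(ts, mat, 0.01)
  sf <- solve_microfe(ts, mat, load_case(0.01), rtol = 1e-12)
  a <- unclass(sf)
  attributes(a) <- list(dim = dim(a))
  expect_equal(a, ref, tolerance = 1e-10)
})

test_that("strain field is linear in the load", {
  ts <- small_phantom(24, seed = 3, target_bvtv = 0.18)
  mat <- material_map(ts)
  s1 <- solve_microfe(ts, mat, load_case(0.01), rtol = 1e-9)
  s2 <- solve_microfe(ts, mat, load_case(0.02), rtol = 1e-9)
  ok <- !is.na(s1)
  expect_equal(unclass(s2)[ok], 2 * unclass(s1)[ok], tolerance = 1e-6)
})

test_that("two-material stack in series carries strain inversely to E", {
  n <- 4
  vol <- array(1, c(n, n, 6))
  ts <- tissue_state(vol, vol)
  ts$mineral[, , 1:3] <- 1    # E_max
  ts$mineral[, , 4:6] <- 0.5  # half stiffness
  mat <- material_map(ts, E_max = 10000, nu = 0) # nu = 0: pure 1D series
  sf <- solve_microfe(ts, mat, load_case(0.01), rtol = 1e-10)
  soft <- mean(sf[, , 5], na.rm = TRUE)
  stiff <- mean(sf[, , 2], na.rm = TRUE)
  expect_equal(soft / stiff, 2, tolerance = 1e-6)
})

test_that("rigid-body shift of the boundary data produces zero strain", {
  ts <- solid_block(5)
  mat <- material_map(ts)
  # equal displacement top and bottom = rigid translation
  mesh <- osteosim:::fe_mesh(bone_mask(ts))
  K0 <- osteosim:::hex8_stiffness(ts$spacing, mat$nu)
  ndof <- 3L * mesh$n_nodes
  edof <- matrix(0L, 24L, nrow(mesh$enodes))
  for (a in 1:8) {
    base <- 3L * (mesh$enodes[, a] - 1L)
    edof[3 * a - 2, ] <- base; edof[3 * a - 1, ] <- base + 1L
    edof[3 * a, ] <- base + 2L
  }
  fixed <- logical(ndof); ufix <- numeric(ndof)
  bottom <- which(mesh$node_k == 1L); top <- which(mesh$node_k == 6L)
  fixed[3 * (c(bottom, top) - 1) + 3] <- TRUE
  ufix[3 * (c(bottom, top) - 1) + 3] <- -5 # same shift both faces
  Evec <- rep(mat$E_max, nrow(mesh$enodes))
  sol <- osteosim:::cpp_fe_solve(edof, Evec, K0, ndof, fixed, ufix,
                                 numeric(ndof), 1e-10, 5000L)
  q <- osteosim:::cpp_fe_element_energy(edof, K0, sol$u)
  expect_lt(max(sqrt(pmax(q, 0) / ts$spacing^3)), 1e-7)
})

test_that("force-controlled load reproduces displacement control by linearity", {
  ts <- solid_block(5)
  mat <- material_map(ts)
  sd_ <- solve_microfe(ts, mat, load_case(0.01), rtol = 1e-10)
  f <- attr(sd_, "total_force")
  sfc <- solve_microfe(ts, mat, load_case(f, "force"), rtol = 1e-10)
  expect_equal(unclass(sfc), unclass(sd_), tolerance = 1e-8)
})

test_that("load scaling puts the strain histogram mode at the target", {
  ts <- small_phantom(32)
  mat <- material_map(ts)
  lc <- scale_load_to_peak(ts, mat, load_case(0.01), 2500, rtol = 1e-6)
  sf <- attr(lc, "strain")
  eps <- sf[!is.na(sf)] * 1e6
  breaks <- seq(0, max(eps) + 100, by = 100)
  counts <- tabulate(findInterval(eps, breaks), nbins = length(breaks))
  mode_ue <- breaks[which.max(counts)] + 50
  expect_lte(abs(mode_ue - 2500), 51)
  # uniform solid block: mode = mean = applied strain
  blk <- solid_block(5)
  expect_warning(lcb <- scale_load_to_peak(blk, material_map(blk),
                                           load_case(0.01), 2500,
                                           rtol = 1e-9),
                 "degenerate")
  expect_equal(attr(lcb, "scale"), 2500 / (0.01 * 1e6), tolerance = 1e-6)
})

test_that("disconnected structures are rejected with a load-path error", {
  vol <- array(0, c(6, 6, 6))
  vol[2:4, 2:4, 1:2] <- 1 # touches bottom only
  ts <- tissue_state(vol, vol)
  expect_error(solve_microfe(ts, material_map(ts), load_case(0.01)),
               "load path")
})
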