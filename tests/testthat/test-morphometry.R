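make_cylinder <- function(n = 48, r = 5.5) {
  vol <- array(0, c(n, n, n))
  cx <- (n + 1) / 2
  for (k in 1:n) {
    sl <- outer((1:n - cx)^2, (1:n - cx)^2, `+`) <= r^2
    vol[, , k][sl] <- 1
  }
  tissue_state(vol, vol)
}

make_plate <- function(n = 48, th = 7) {
  vol <- array(0, c(n, n, n))
  k0 <- floor((n - th) / 2)
  vol[, , (k0 + 1):(k0 + th)] <- 1
  tissue_state(vol, vol)
}

test_that("morphometry primitives match closed forms", {
  cyl <- make_cylinder()
  m <- static_morphometry(cyl)
  # ideal rod: SMI about 3; maximal-sphere thickness about the diameter
  expect_equal(m$SMI, 3, tolerance = 0.2)
  expect_lt(abs(m$Tb_Th - 2 * 5.5 * 14 / 1000), 1.6 * 14 / 1000)
  pl <- static_morphometry(make_plate())
  expect_lt(abs(pl$SMI), 0.45)
  expect_lt(abs(pl$Tb_Th - 7 * 14 / 1000), 1.6 * 14 / 1000)
  # sphere: SMI about 4
  vol <- array(0, c(40, 40, 40))
  co <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  vol[rowSums(sweep(co, 2, 20.5)^2) <= 100] <- 1
  sph <- static_morphometry(tissue_state(vol, vol))
  expect_equal(sph$SMI, 4, tolerance = 0.5)
  # cylinder surface area: 2 pi r L within voxelization error
  expect_equal(m$BS, 2 * pi * (5.5 * 0.014) * (48 * 0.014), tolerance = 0.1)
})

test_that("all-solid domain gives BV/TV 1 and vanishing BS/BV", {
  m <- static_morphometry(solid_block(12))
  expect_equal(m$BV_TV, 1)
  expect_lt(m$BS_BV / (6 / (12 * 0.014)), 0.2) # much less than the box faces
  expect_error(static_morphometry(
    tissue_state(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)))), "empty bone")
})

test_that("BS/BV decreases under uniform dilation of a convex solid", {
  small <- make_cylinder(40, r = 4)
  big <- make_cylinder(40, r = 8)
  expect_lt(static_morphometry(big)$BS_BV, static_morphometry(small)$BS_BV)
})

test_that("dynamic morphometry accounts volumes exactly", {
  ph <- small_phantom(32)
  expect_true(all(dynamic_morphometry(ph, ph, 10)[1, 1:4] == 0))
  # one voxel formed over 1 day
  ph2 <- ph
  mv <- which(!bone_mask(ph))[1]
  ph2$osteoid[mv] <- 1
  ph2$mineral[mv] <- 1
  dm <- dynamic_morphometry(ph, ph2, 1)
  expect_equal(dm$formed_um3, 14^3)
  expect_equal(dm$resorbed_um3, 0)
  m0 <- static_morphometry(ph)
  expect_equal(dm$BFR, 14^3 / (m0$BS * 1e6) / 1, tolerance = 1e-6)
  # volume accounting: formed - resorbed = change in osteoid volume
  set.seed(5)
  ph3 <- ph2
  loss <- sample(which(bone_mask(ph3)), 20)
  ph3$osteoid[loss] <- ph3$osteoid[loss] - 0.4
  ph3$mineral[loss] <- pmin(ph3$mineral[loss], ph3$osteoid[loss])
  dm2 <- dynamic_morphometry(ph2, ph3, 5)
  expect_equal(dm2$formed_um3 - dm2$resorbed_um3,
               (sum(ph3$osteoid) - sum(ph2$osteoid)) * 14^3,
               tolerance = 1e-9)
})

test_that("BMC is linear in mineral and zero on empty domains", {
  empty <- tissue_state(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)))
  expect_equal(bmc(empty), 0)
  ph <- small_phantom(32)
  ph2 <- ph
  ph2$mineral <- ph$mineral * 0.5
  expect_equal(bmc(ph2), 0.5 * bmc(ph))
  # binary option counts voxels regardless of mineral fraction
  expect_equal(bmc(ph2, mineral_weighted = FALSE), bmc(ph, mineral_weighted = FALSE))
})
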