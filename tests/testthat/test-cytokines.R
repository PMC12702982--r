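test_that("denosumab decays with a 26-day half-life", {
  ph <- small_phantom(24, seed = 4, target_bvtv = 0.15)
  f <- cytokine_field(ph)
  f$conc$denosumab[] <- 1000
  n <- cytokine_substeps(f, 1)
  conc <- numeric(60)
  for (t in 1:60) {
    for (s in seq_len(n)) f <- diffuse_decay_step(f, 1 / n)
    conc[t] <- mean(f$conc$denosumab)
  }
  hl <- approx(conc, 1:60, xout = 500)$y
  expect_equal(hl, 26, tolerance = 0.01)
  expect_equal(log(2) / 26, 0.026659, tolerance = 1e-4)
})

test_that("diffusion conserves mass and preserves uniformity", {
  ph <- small_phantom(24, seed = 4, target_bvtv = 0.15)
  f <- cytokine_field(ph)
  f$params$lambda[] <- 0
  f$conc$RANKL[5, 5, 5] <- 500
  s0 <- sum(f$conc$RANKL)
  u0 <- f$conc$OPG[1]
  for (i in 1:25) f <- diffuse_decay_step(f, 1)
  expect_lt(abs(sum(f$conc$RANKL) - s0) / s0, 1e-10)
  # a uniform field stays uniform
  expect_equal(max(f$conc$OPG), u0, tolerance = 1e-12)
  expect_equal(min(f$conc$OPG), u0, tolerance = 1e-12)
  # nonnegativity after a composite step
  expect_true(all(unlist(lapply(f$conc, min)) >= 0))
})

test_that("unstable explicit steps are rejected with sub-stepping advice", {
  ph <- small_phantom(24, seed = 4, target_bvtv = 0.15)
  f <- cytokine_field(ph)
  f$params$D[f$params$species == "RANKL"] <- 500
  expect_error(diffuse_decay_step(f, 1), "sub-step")
  expect_gte(cytokine_substeps(f, 1), 500 * 6 / 14^2)
})

test_that("binding conserves totals and reaches the mass-action equilibrium", {
  ph <- small_phantom(24, seed = 4, target_bvtv = 0.15)
  f <- cytokine_field(ph)
  bp <- binding_params()
  tot <- function(f) c(
    R = sum(f$conc$RANKL + f$conc$RANKL_OPG + f$conc$RANKL_dmab),
    O = sum(f$conc$OPG + f$conc$RANKL_OPG),
    D = sum(f$conc$denosumab + f$conc$RANKL_dmab))
  f$conc$denosumab[] <- 300
  t0 <- tot(f)
  for (i in 1:100) f <- react_bind_step(f, bp, 1)
  expect_equal(tot(f), t0, tolerance = 1e-9)
  # equilibrium ratio equals kon/koff in a well-mixed voxel
  r <- f$conc$RANKL_dmab[1] / (f$conc$RANKL[1] * f$conc$denosumab[1])
  expect_equal(r, bp$kon_RD / bp$koff_RD, tolerance = 1e-3)
  expect_error(react_bind_step({
    g <- f; g$conc$RANKL[1] <- -1; g
  }, bp, 1), "negative")
})

test_that("well-mixed binding matches a stiff ODE integrator", {
  skip_if_not_installed("deSolve")
  bp <- binding_params()
  ode_fun <- function(t, y, p) {
    v1 <- bp$kon_RO * y[1] * y[2] - bp$koff_RO * y[3]
    v2 <- bp$kon_RD * y[1] * y[4] - bp$koff_RD * y[5]
    list(c(-v1 - v2, -v1, v1, -v2, v2))
  }
  y0 <- c(R = 5, O = 12.3, C1 = 100, D = 50, C2 = 0)
  ref <- deSolve::lsoda(y0, c(0, 30), ode_fun, NULL, rtol = 1e-10,
                        atol = 1e-12)[2, -1]
  vol <- array(1, c(2, 2, 2))
  f <- cytokine_field(tissue_state(vol, vol))
  f$conc$RANKL[] <- 5; f$conc$RANKL_OPG[] <- 100
  f$conc$denosumab[] <- 50; f$conc$RANKL_dmab[] <- 0
  for (i in 1:300) f <- react_bind_step(f, bp, 0.1)
  # end states agree to the splitting order at equilibrium approach
  expect_equal(f$conc$RANKL[1], unname(ref["R"]), tolerance = 0.02)
  expect_equal(f$conc$RANKL_OPG[1], unname(ref["C1"]), tolerance = 0.02)
})

test_that("raising denosumab k_off raises free RANKL at equilibrium", {
  vol <- array(1, c(2, 2, 2))
  free_rankl <- function(koff) {
    f <- cytokine_field(tissue_state(vol, vol))
    f$conc$denosumab[] <- 5000
    bp <- binding_params(koff_RD = koff)
    for (i in 1:200) f <- react_bind_step(f, bp, 1)
    f$conc$RANKL[1]
  }
  expect_gt(free_rankl(0.5), free_rankl(0.05))
})

test_that("dosing pulses arrive per schedule and placebo leaves fields alone", {
  ph <- small_phantom(24, seed = 4, target_bvtv = 0.15)
  f <- cytokine_field(ph)
  placebo <- dose_schedule()
  expect_identical(apply_dose(f, placebo, 10, 1)$conc$denosumab,
                   f$conc$denosumab)
  # the 2-year treatment arm has 4 injections at months 0, 6, 12, 18
  cfg <- simulation_config(treatment_months = 24)
  expect_equal(cfg$schedule$times, 365.25 / 12 * c(0, 6, 12, 18))
  # pulses are additive and land on marrow voxels only
  sch <- dose_schedule(c(0, 0.5), peak_pM = 1000)
  f1 <- apply_dose(f, sch, 1, 1)
  mar <- f1$marrow
  expect_equal(unique(f1$conc$denosumab[mar]), 2000)
  expect_true(all(f1$conc$denosumab[!mar] == 0))
})

test_that("occupancy follows the binding ODE fixed point", {
  bp <- binding_params()
  kd <- bp$koff_RANK / bp$kon_RANK
  for (L in c(0.6, 5, 5000)) {
    o <- update_occupancy(0.2, L, bp, 1000)
    expect_equal(o, L / (L + kd), tolerance = 1e-9)
  }
  # zero ligand: exponential decay toward zero at koff
  o <- update_occupancy(0.8, 0, bp, 1)
  expect_equal(o, 0.8 * exp(-bp$koff_RANK), tolerance = 1e-12)
  expect_error(update_occupancy(1.2, 1, bp, 1), "0, 1")
  # identical parameters give identical trajectories for any lineage cell
  o1 <- update_occupancy(0.3, 2, bp, 0.5)
  o2 <- update_occupancy(0.3, 2, bp, 0.5)
  expect_identical(o1, o2)
})

test_that("strain-driven production is monotone, bounded, and localized", {
  sp <- seeded_population(32)
  f <- cytokine_field(sp$tissue)
  # Hill responses: monotone in strain, bounded by the plateau
  eps <- seq(0, 8000, by = 250) * 1e-6
  lo <- strain_response_low(eps)
  expect_true(all(diff(lo) <= 0))
  expect_true(all(lo >= 0 & lo <= 1))
  expect_equal(strain_response_low(2500e-6), 0.5)
  # no osteocytes: field unchanged
  empty <- sp$pop
  empty$agents <- empty$agents[empty$agents$type != "OCY", ]
  f2 <- strain_production_step(f, empty, sp$strain, 1,
                               list(p_RANKL = 1, p_SOST = 1, p_OPG = 1))
  expect_identical(f2$conc$RANKL, f$conc$RANKL)
  # a low-strain osteocyte produces strictly more RANKL and sclerostin
  expect_gt(strain_response_low(100e-6), strain_response_low(3000e-6))
  f3 <- strain_production_step(f, sp$pop, sp$strain, 1,
                               list(p_RANKL = 10, p_SOST = 10, p_OPG = 10))
  expect_gte(min(f3$conc$RANKL - f$conc$RANKL), 0)
})

test_that("RANKL internalization is a self-limiting exponential sink", {
  sp <- seeded_population(32)
  f <- cytokine_field(sp$tissue)
  f0 <- sum(f$conc$RANKL)
  f1 <- consume_rankl(f, sp$pop, c_int = 0.5, dt = 1)
  expect_lt(sum(f1$conc$RANKL), f0)
  expect_true(all(f1$conc$RANKL >= 0))
  # repeated application never crosses zero
  for (i in 1:50) f1 <- consume_rankl(f1, sp$pop, 5, 1)
  expect_true(all(f1$conc$RANKL >= 0))
})
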