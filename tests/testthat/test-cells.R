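test_that("seeding matches the reference densities and subregion rule", {
  sp <- seeded_population(32)
  cts <- cell_counts(sp$pop)
  bone <- bone_mask(sp$tissue)
  bv_mm3 <- sum(bone) * (sp$tissue$spacing / 1000)^3
  marrow_mm3 <- sum(!bone) * (sp$tissue$spacing / 1000)^3
  expect_equal(cts[["OCY"]] / bv_mm3, 18500, tolerance = 0.05)
  expect_equal(cts[["MSC"]] / marrow_mm3, 8000, tolerance = 0.05)
  expect_equal(cts[["HSC"]] / marrow_mm3, 6000, tolerance = 0.05)
  acc <- attr(sp$pop, "accepted_subregions")
  expect_true(all(acc$n_OBL >= 6 & acc$n_OBL <= 40))
  expect_true(all(acc$n_OCL >= 4 & acc$n_OCL <= 40))
  # osteoclast nuclei average about 5
  nuc <- sp$pop$agents$nuclei[sp$pop$agents$type == "OCL"]
  expect_equal(mean(nuc), 5, tolerance = 0.15)
  # placement invariants at seeding
  expect_true(check_placement(sp$pop, sp$tissue))
})

test_that("modelling-mode seeding uses the absolute strain thresholds", {
  sp <- seeded_population(32)
  # uniform strain at the physiologic peak: neither threshold is met
  flat <- sp$strain
  flat[!is.na(flat)] <- 2500e-6
  pop <- seed_initial_cells(sp$tissue, flat, mode = "modelling", seed = 1)
  cts <- cell_counts(pop)
  expect_equal(cts[["OBL"]], 0L)
  expect_equal(cts[["OCL"]], 0L)
  # threshold semantics: strain above 4000 ue seeds osteoblasts only
  hi <- sp$strain
  hi[!is.na(hi)] <- 5000e-6
  pop2 <- seed_initial_cells(sp$tissue, hi, mode = "modelling", seed = 1)
  expect_gt(cell_counts(pop2)[["OBL"]], 0L)
  expect_equal(cell_counts(pop2)[["OCL"]], 0L)
})

test_that("agent expectations match the population balance ODE", {
  skip_if_not_installed("deSolve")
  # small OB-lineage instance with constant fields (all effects = 1)
  params <- rate_params()
  params$G_MSCtoOB <- 0.02; params$G_lctoOB <- 0.005; params$G_OBtolc <- 0.01
  params$G_OBtoOCY <- 0.002; params$S_MSC <- 0; params$k_niche <- 0
  params$n0_MSC <- 60; params$S_HSC <- 0; params$G_HSCtoPre <- 0
  params$G_pre2ocl <- 0; params$n0_ocl_mass <- NA
  vol <- array(0, c(8, 8, 8)); vol[3:6, 3:6, 3:6] <- 1
  ts <- tissue_state(vol, vol)
  f <- cytokine_field(ts)
  d <- dim(vol)
  surf_idx <- which(extract_surface(ts))
  marrow_idx <- which(marrow_mask(ts))
  flags <- hypothesis_flags(coupling = FALSE)
  strain <- structure(array(NA_real_, d), class = "strain_field")
  make_pop <- function() {
    agents <- data.table::data.table(
      id = 1:110,
      type = c(rep("MSC", 60), rep("OBL", 30), rep("LC", 20)),
      i = 1L, j = 1L, k = 1L, age = 0, rank_occ = 0.5, tgfb_occ = 0.5,
      nuclei = 1L, origin = "seed")
    vi <- c(sample(marrow_idx, 60, TRUE), sample(surf_idx, 50, TRUE))
    co <- vox_coords(vi, d)
    agents$i <- co[, 1]; agents$j <- co[, 2]; agents$k <- co[, 3]
    cell_population(agents)
  }
  n_rep <- 200
  days <- 15
  set.seed(99)
  finals <- vapply(seq_len(n_rep), function(r) {
    pop <- make_pop()
    for (day in seq_len(days))
      pop <- step_differentiation(pop, f, strain, params, flags, 1, ts)
    cell_counts(pop)[["OBL"]]
  }, numeric(1))
  # ODE oracle for the same constant-rate system (per-day event fractions)
  ode <- deSolve::lsoda(
    c(M = 60, B = 30, L = 20),
    seq(0, days),
    function(t, y, p) {
      pm <- 1 - exp(-params$G_MSCtoOB)
      pl <- 1 - exp(-params$G_lctoOB)
      r_out <- params$G_OBtolc + params$G_OBtoOCY + params$A_OB / 7
      p_out <- 1 - exp(-r_out)
      w_lc <- params$G_OBtolc / r_out
      prolif <- 1 - exp(-params$P_OB / 7)
      list(c(-pm * y[1],
             pm * y[1] + pl * y[3] - p_out * y[2] + (1 - p_out) * prolif * y[2],
             w_lc * p_out * y[2] - pl * y[3]))
    }, NULL)[days + 1, -1]
  se <- sd(finals) / sqrt(n_rep)
  expect_lt(abs(mean(finals) - ode[["B"]]), 3 * se + 0.5)
})

test_that("gate-blocking accumulates HSCs under collapsed occupancy", {
  sp <- seeded_population(32)
  params <- calibrate_rates(rate_params(), sp$pop, sp$tissue)
  params$S_HSC <- params$S_HSC %||% 10
  f <- cytokine_field(sp$tissue)
  f$conc$RANKL[] <- 0.001 # sustained denosumab: free RANKL suppressed
  pop <- sp$pop
  pop$agents$rank_occ <- 0.01
  set.seed(11)
  counts <- numeric(20)
  for (day in 1:20) {
    pop <- step_differentiation(pop, f, sp$strain, params,
                                hypothesis_flags(gate_blocking = TRUE), 1,
                                sp$tissue)
    counts[day] <- cell_counts(pop)[["HSC"]]
  }
  # monotone increase in expectation: fit a positive trend
  expect_gt(coef(lm(counts ~ seq_along(counts)))[[2]], 0)
  # with the gate off the same scenario does not accumulate
  pop2 <- sp$pop
  pop2$agents$rank_occ <- 0.01
  for (day in 1:20)
    pop2 <- step_differentiation(pop2, f, sp$strain, params,
                                 hypothesis_flags(gate_blocking = FALSE), 1,
                                 sp$tissue)
  expect_lt(cell_counts(pop2)[["HSC"]], max(counts))
})

test_that("fission rate matches the 100 ng/mL reference calibration", {
  # surface tiled with osteoclasts at uniform RANKL 100 ng/mL (5000 pM with
  # the 20 kDa default): areal fission rate 0.6 OCL/hour/(100x100 um^2)
  n <- 20
  vol <- array(0, c(n, n, 8))
  vol[, , 1:4] <- 1 # slab: top surface is a full n x n sheet
  ts <- tissue_state(vol, vol)
  d <- dim(vol)
  surf <- extract_surface(ts)
  top <- which(surf & slice.index(array(TRUE, d), 3) == 4)
  agents <- data.table::data.table(
    id = seq_along(top), type = "OCL",
    vox_coords(top, d), age = 0,
    rank_occ = occupancy_equilibrium(5000), tgfb_occ = 0.5,
    nuclei = 5L, origin = "seed")
  pop0 <- cell_population(agents)
  params <- rate_params()
  params$k_fiss <- params$fiss_ref_rate /
    (1 - occupancy_equilibrium(params$fiss_ref_conc_pM))
  params$n0_ocl_mass <- NA # no crowding in this assay
  params$k_fus <- 0
  f <- cytokine_field(ts)
  set.seed(21)
  n_hours <- 24 * 10
  fissions <- 0
  for (h in seq_len(n_hours)) {
    pop2 <- step_fission_fusion(pop0, f, params, 1 / 24, ts)
    fissions <- fissions + attr(pop2, "fusion_events")[["fissions"]]
    # the tile is replenished each hour so the areal density stays fixed
  }
  tiles <- length(top) * 14^2 / 100^2 # surface area in (100 um)^2 patches
  areal_per_hour <- fissions / n_hours / tiles
  expect_equal(areal_per_hour, 0.6, tolerance = 0.1)
})

test_that("fission is blocked at full occupancy and osteomorphs die slowly", {
  sp <- seeded_population(32)
  params <- calibrate_rates(rate_params(), sp$pop, sp$tissue)
  pop <- sp$pop
  pop$agents$rank_occ[pop$agents$type == "OCL"] <- 1
  set.seed(31)
  pop2 <- step_fission_fusion(pop, cytokine_field(sp$tissue), params, 1,
                              sp$tissue)
  expect_equal(attr(pop2, "fusion_events")[["fissions"]], 0)
  # derived daily death probability for the 6-month half-life
  expect_equal(1 - 2^(-1 / 182.5), 0.0037909, tolerance = 1e-4)
})

test_that("motility drifts up a linear RANKL gradient at 14.4 um/day", {
  # all-marrow domain with a static linear gradient along z
  vol <- array(0, c(12, 12, 60))
  ts <- tissue_state(vol, vol)
  d <- dim(vol)
  f <- cytokine_field(ts)
  grad <- array(rep(seq(1, 60), each = 144), d)
  f$conc$RANKL <- grad
  n_cells <- 1000
  set.seed(41)
  agents <- data.table::data.table(
    id = 1:n_cells, type = "osteomorph",
    i = sample(1:12, n_cells, TRUE), j = sample(1:12, n_cells, TRUE),
    k = 5L, age = 0, rank_occ = 0.5, tgfb_occ = 0.5, nuclei = 1L,
    origin = "seed")
  pop <- cell_population(agents)
  k0 <- pop$agents$k
  days <- 50
  for (day in seq_len(days))
    pop <- step_motility(pop, f, 1, ts, rate_params())
  drift <- mean((pop$agents$k - k0) * ts$spacing) / days
  expect_equal(drift, 14.4, tolerance = 0.05)
  # zero gradient: unbiased walk with zero mean displacement
  f0 <- cytokine_field(ts)
  pop0 <- cell_population(agents)
  for (day in 1:25) pop0 <- step_motility(pop0, f0, 1, ts, rate_params())
  expect_lt(abs(mean(pop0$agents$k - k0) * ts$spacing) / 25, 1.5)
  # cells never enter bone (trivially true here; checked on a phantom)
  sp <- seeded_population(32)
  popm <- sp$pop
  fm <- cytokine_field(sp$tissue)
  for (day in 1:5) popm <- step_motility(popm, fm, 1, sp$tissue, rate_params())
  expect_true(check_placement(popm, sp$tissue))
})

test_that("resorption and formation respect clipping and accounting", {
  sp <- seeded_population(32)
  params <- calibrate_rates(rate_params(), sp$pop, sp$tissue)
  params$tgf_release <- 100
  # no osteoclasts or osteoblasts: nothing changes
  quiet <- sp$pop
  quiet$agents <- quiet$agents[!quiet$agents$type %in% c("OCL", "OBL"), ]
  rf0 <- step_resorption_formation(quiet, sp$tissue, cytokine_field(sp$tissue),
                                   params, 1)
  expect_equal(rf0$resorbed, 0)
  expect_equal(rf0$formed, 0)
  expect_identical(rf0$tissue$osteoid, sp$tissue$osteoid)
  # active population: fractions stay in range, TGF-beta release proportional
  set.seed(51)
  f <- cytokine_field(sp$tissue)
  tg0 <- sum(f$conc$TGFb)
  rf <- step_resorption_formation(sp$pop, sp$tissue, f, params, 1)
  expect_true(all(rf$tissue$osteoid >= 0 & rf$tissue$osteoid <= 1))
  expect_true(all(rf$tissue$mineral <= rf$tissue$osteoid + 1e-12))
  mineral_removed <- sum(sp$tissue$mineral) - sum(rf$tissue$mineral)
  expect_equal(sum(rf$fields$conc$TGFb) - tg0,
               params$tgf_release * mineral_removed, tolerance = 1e-9)
})

test_that("rate-limit audit flags excursions beyond the configured limit", {
  hist <- data.frame(time_days = rep(1:4, 2),
                     type = rep(c("OBL", "OCL"), each = 4),
                     count = c(100, 102, 101, 103, 50, 56, 55, 54))
  v <- audit_rate_limits(hist, limit = 0.05)
  # OCL jumps 50 -> 56 = 12%/day; OBL never exceeds 5%/day
  expect_true(all(v$type == "OCL"))
  expect_equal(nrow(v), 1L)
  expect_equal(v$rel_change, 6 / 50, tolerance = 1e-12)
  expect_equal(nrow(audit_rate_limits(
    data.frame(time_days = 1:5, type = "OBL", count = rep(7, 5)))), 0L)
  expect_error(audit_rate_limits(
    data.frame(time_days = 1, type = "OBL", count = 5)), "2 days")
})
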