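short_cfg <- function(...) {
  args <- list(treatment_months = 0, followup_months = 2,
               spin_up_days = 10, burn_in_days = 10,
               record_interval_days = 30, seed = 1, n_subregions = 64)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

test_that("identical config and seed reproduce bit-identical run tables", {
  ph <- small_phantom(24, seed = 5, target_bvtv = 0.16)
  r1 <- run_simulation(short_cfg(), ph)
  r2 <- run_simulation(short_cfg(), ph)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$history, r2$history)
})

test_that("the run table carries the validation timepoints and state stays sane", {
  ph <- small_phantom(24, seed = 5, target_bvtv = 0.16)
  cfg <- short_cfg(output_months = c(1, 2))
  res <- run_simulation(cfg, ph)
  expect_true(all(round(c(1, 2) * 365.25 / 12) %in% res$table$time_days))
  expect_equal(res$table$pct_BMC,
               100 * (res$table$BMC / res$baseline_bmc - 1))
  # fractions and concentrations stay in range all the way through
  expect_true(all(res$tissue$osteoid >= 0 & res$tissue$osteoid <= 1))
  expect_true(all(res$tissue$mineral <= res$tissue$osteoid + 1e-9))
  expect_true(all(vapply(res$fields$conc, min, numeric(1)) >= 0))
  expect_true(check_placement(res$pop, res$tissue))
})

test_that("hypothesis toggles gate their mechanisms", {
  ph <- small_phantom(24, seed = 5, target_bvtv = 0.16)
  # recycling off: no osteomorph cell type at all
  res_off <- run_simulation(short_cfg(
    flags = hypothesis_flags(recycling = FALSE)), ph)
  expect_true(all(res_off$history$osteomorph == 0L))
  expect_true(all(res_off$history$cum_ocl_morph == 0L))
  # recycling on: a standing osteomorph pool with re-fusion events
  res_on <- run_simulation(short_cfg(), ph)
  expect_gt(min(res_on$history$osteomorph), 0L)
  expect_gt(max(res_on$history$cum_ocl_morph), 0L)
})

test_that("factorial driver emits the labeled configuration grid", {
  ph <- small_phantom(24, seed = 5, target_bvtv = 0.16)
  cfg <- short_cfg(followup_months = 1, burn_in_days = 5, spin_up_days = 5)
  tab <- run_factorial(cfg, list(p1 = ph), configs = c("alpha", "zeta"))
  expect_setequal(unique(tab$run), c("alpha", "zeta"))
  expect_true(all(tab$phantom == "p1"))
  zeta <- unique(as.data.frame(tab)[tab$run == "zeta",
                                    c("P_A", "P_B", "P_C", "P_D")])
  expect_equal(unname(unlist(zeta)), c(1, 1, 0, 0))
  alpha <- unique(as.data.frame(tab)[tab$run == "alpha",
                                     c("P_A", "P_B", "P_C", "P_D")])
  expect_equal(unname(unlist(alpha)), c(0, 0, 0, 0))
  expect_true(all(c("BMC", "BL", "BFR", "BRR") %in% names(tab)))
})

test_that("recycling-on recovers osteoclasts faster under a RANKL ramp", {
  # module-level comparison under an identical post-discontinuation RANKL
  # recovery: time to rebuild half the baseline osteoclast pool
  sp <- seeded_population(32)
  params_on <- calibrate_rates(rate_params(), sp$pop, sp$tissue,
                               recycling = TRUE)
  params_off <- calibrate_rates(rate_params(), sp$pop, sp$tissue,
                                recycling = FALSE)
  t_on <- ocl_recovery_time(sp, params_on, TRUE, seed = 61)
  t_off <- ocl_recovery_time(sp, params_off, FALSE, seed = 61)
  expect_lt(t_on, t_off)
})
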