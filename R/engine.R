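#' Mechanistic hypothesis toggles
#'
#' The four proposed mechanisms for rapid bone loss after denosumab
#' discontinuation, each independently switchable (ceteris paribus): with a
#' toggle off, its modulation is replaced by the neutral constant 1.
#' * `gate_blocking`: HSC-to-preosteoclast differentiation gated by RANK
#'   occupancy, so precursors accumulate during treatment;
#' * `recycling`: osteoclasts fission into marrow osteomorphs that re-fuse
#'   when RANKL returns (off: no osteomorph cell type at all);
#' * `coupling`: resorption-released TGF-beta stimulates osteoblastogenesis;
#' * `mechanostat`: osteocyte cytokine production responds to local strain.
#'
#' @param gate_blocking,recycling,coupling,mechanostat logical flags.
#' @return A named list of class `hypothesis_flags`.
#' @export
hypothesis_flags <- function(gate_blocking = TRUE, recycling = TRUE,
                             coupling = TRUE, mechanostat = TRUE) {
  structure(list(gate_blocking = isTRUE(gate_blocking),
                 recycling = isTRUE(recycling),
                 coupling = isTRUE(coupling),
                 mechanostat = isTRUE(mechanostat)),
            class = "hypothesis_flags")
}

# The 16 factorial configurations in their canonical order and Greek labels.
factorial_table <- function() {
  flags <- rbind(
    c(0, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
    c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1), c(0, 1, 1, 0), c(0, 1, 0, 1),
    c(0, 0, 1, 1), c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 0, 1, 1), c(0, 1, 1, 1),
    c(1, 1, 1, 1))
  data.frame(label = c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                       "eta", "theta", "iota", "kappa", "lambda", "mu", "nu",
                       "xi", "omicron", "pi"),
             P_A = flags[, 1], P_B = flags[, 2], P_C = flags[, 3],
             P_D = flags[, 4], stringsAsFactors = FALSE)
}

#' Greek label of a factorial configuration
#'
#' @param flags a [hypothesis_flags()].
#' @return The run label (`"alpha"` ... `"pi"`).
#' @export
run_label <- function(flags) {
  tab <- factorial_table()
  hit <- tab$P_A == flags$gate_blocking & tab$P_B == flags$recycling &
    tab$P_C == flags$coupling & tab$P_D == flags$mechanostat
  tab$label[hit]
}

days_per_month <- 365.25 / 12

#' Simulation configuration
#'
#' @param flags a [hypothesis_flags()].
#' @param treatment_months duration of the denosumab arm (injections every
#'   6 months starting at day 0); 0 for placebo.
#' @param followup_months off-treatment follow-up duration.
#' @param dose_peak_pM marrow pulse per 60 mg injection.
#' @param cell_dt cell-behavior timestep in days.
#' @param fe_interval_days cadence at which the micro-FE solution is
#'   reconsidered.
#' @param fe_change_frac fraction of bone voxels that must have changed since
#'   the last solve before a re-solve is triggered at the cadence point.
#' @param fe_rtol solver tolerance used inside the engine loop.
#' @param E_max,nu material parameters, see [material_map()].
#' @param target_peak physiologic strain-histogram peak in microstrain.
#' @param annual_loss placebo net bone loss per year (fraction), the
#'   calibration constraint being 0.5-5% total over 4 years.
#' @param n_subregions subregion count for remodelling seeding.
#' @param seeding_mode `"remodelling"` or `"modelling"`.
#' @param record_interval_days cadence of output rows (besides the
#'   validation timepoints).
#' @param spin_up_days days of cytokine/occupancy equilibration before the
#'   cell dynamics start.
#' @param burn_in_days days of drug-free full dynamics before time zero: the
#'   coupled loops settle at their operating point, the formation rate is
#'   then pinned to the measured resorption flux minus the placebo imbalance,
#'   and the mean-field baselines are re-normalized there.
#' @param output_months validation timepoints in months.
#' @param seed master RNG seed.
#' @param params a [rate_params()]; `NA` entries are calibrated at setup.
#' @param species species table, see [species_defaults()].
#' @param binding a [binding_params()].
#' @param densities a [seed_densities()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(flags = hypothesis_flags(),
                              treatment_months = 24, followup_months = 24,
                              dose_peak_pM = 40000, cell_dt = 1,
                              fe_interval_days = 10, fe_change_frac = 0.01,
                              fe_rtol = 1e-4, E_max = 10000, nu = 0.3,
                              target_peak = 2500, annual_loss = 0.006,
                              n_subregions = 1000,
                              seeding_mode = "remodelling",
                              record_interval_days = 30, spin_up_days = 30,
                              burn_in_days = 270,
                              output_months = c(1, 6, 12, 24, 30, 36, 42, 48),
                              seed = 1, params = rate_params(),
                              species = species_defaults(),
                              binding = binding_params(),
                              densities = seed_densities()) {
  if (cell_dt <= 0) stop("cell_dt must be positive")
  inj <- if (treatment_months > 0)
    days_per_month * seq(0, treatment_months - 6, by = 6) else numeric(0)
  structure(list(
    flags = flags, treatment_months = treatment_months,
    followup_months = followup_months,
    schedule = dose_schedule(inj, peak_pM = dose_peak_pM),
    cell_dt = cell_dt, fe_interval_days = fe_interval_days,
    fe_change_frac = fe_change_frac, fe_rtol = fe_rtol,
    E_max = E_max, nu = nu, target_peak = target_peak,
    annual_loss = annual_loss, n_subregions = n_subregions,
    seeding_mode = seeding_mode,
    record_interval_days = record_interval_days,
    spin_up_days = spin_up_days, burn_in_days = burn_in_days,
    output_months = output_months, seed = as.integer(seed),
    params = params, species = species, binding = binding,
    densities = densities), class = "simulation_config")
}

# Fill NA strains (freshly formed voxels between FE refreshes) with the mean
# of face-neighbor strains, falling back to the bone median.
fill_strain <- function(strain, bone) {
  s <- unclass(strain)
  need <- which(bone & is.na(s))
  if (length(need) == 0L) return(strain)
  d <- dim(s)
  med <- median(s[bone], na.rm = TRUE)
  nb <- face_neighbors(need, d)
  vals <- matrix(NA_real_, nrow(nb), ncol(nb))
  ok <- !is.na(nb)
  vals[ok] <- s[nb[ok]]
  m <- rowMeans(vals, na.rm = TRUE)
  m[is.nan(m)] <- med
  s[need] <- m
  out <- strain
  out[] <- s
  out
}

# Production-rate calibration: per-osteocyte rates such that the uniform
# initial concentrations are a stationary point of production vs decay
# (including the slow drain through the decaying complexes).
calibrate_production <- function(config, tissue, pop, strain, params) {
  sp <- config$species
  lam <- setNames(sp$lambda, sp$species)
  init <- setNames(sp$init_pM, sp$species)
  nvox <- prod(dim(tissue$osteoid))
  ag <- pop$agents
  ocy <- ag[ag$type == "OCY", ]
  d <- dim(tissue$osteoid)
  eps <- unclass(strain)[vox_index(ocy$i, ocy$j, ocy$k, d)]
  eps[is.na(eps)] <- config$target_peak * 1e-6
  if (config$flags$mechanostat) {
    lo <- mean(strain_response_low(eps))
    hi <- mean(strain_response_high(eps))
  } else {
    lo <- 0.5; hi <- 0.5
  }
  n_ocy <- max(nrow(ocy), 1L)
  need_R <- (lam[["RANKL"]] * init[["RANKL"]] +
               lam[["RANKL_OPG"]] * init[["RANKL_OPG"]]) * nvox
  need_O <- (lam[["OPG"]] * init[["OPG"]] +
               lam[["RANKL_OPG"]] * init[["RANKL_OPG"]]) * nvox
  need_S <- lam[["sclerostin"]] * init[["sclerostin"]] * nvox
  rates <- list(p_RANKL = need_R / (n_ocy * max(lo, 1e-9)),
                p_SOST = need_S / (n_ocy * max(lo, 1e-9)),
                p_OPG = need_O / (n_ocy * max(hi, 1e-9)))
  n_nuc <- max(sum(ag$nuclei[ag$type == "OCL"]), 1)
  # per-nucleus abrasion rate from the turnover target
  if (is.na(params$resorb_rate)) {
    target_flux <- params$annual_turnover * sum(bone_mask(tissue)) / 365
    params$resorb_rate <- target_flux * (1 - tissue$bone_threshold) * 5 / n_nuc
  }
  resorb_flux <- params$resorb_rate * n_nuc / 5 /
    (1 - tissue$bone_threshold) # effective mineral voxels/day
  params$tgf_release <- lam[["TGFb"]] * init[["TGFb"]] * nvox /
    max(resorb_flux, 1e-9)
  list(rates = rates, params = params)
}

#' Run one simulation
#'
#' Executes the iterative multiphysics schedule on a coarse daily step:
#' (1) refresh the micro-FE strain field (at the configured cadence, when the
#' structure has changed enough), (2) cytokine sub-steps (diffusion/decay,
#' binding, strain-driven production, dosing), (3) cell behavior (receptor
#' occupancy, differentiation, fission/fusion, motility, resorption and
#' formation), (4) mineralization, (5) bookkeeping. Hypothesis toggles gate
#' their mechanisms as documented in [hypothesis_flags()].
#'
#' @param config a [simulation_config()].
#' @param tissue the input [tissue_state()] (phantom or loaded scan).
#' @return A `sim_result` list: `table` (the run table rows), `history`
#'   (daily cell counts and turnover), `tissue`, `pop`, `fields`, `config`,
#'   `baseline` (initial morphometry).
#' @export
run_simulation <- function(config, tissue) {
  set.seed(child_seed(config$seed, "engine"))
  d <- dim(tissue$osteoid)
  total_days <- round((config$treatment_months + config$followup_months) *
                        days_per_month)
  materials <- material_map(tissue, config$E_max, config$nu)
  load0 <- load_case(0.01, "displacement")
  scaled <- scale_load_to_peak(tissue, materials, load0,
                               target_peak = config$target_peak,
                               rtol = config$fe_rtol)
  strain <- attr(scaled, "strain")
  # hold the physiologic *force* constant from here on: as the structure
  # remodels, strains redistribute under the same load (the mechanostat
  # feedback), rather than being pinned by a fixed displacement
  load <- load_case(max(attr(strain, "total_force"), 1e-9), mode = "force")
  part <- partition_subregions(tissue, config$n_subregions)
  pop <- seed_initial_cells(tissue, strain, part, mode = config$seeding_mode,
                            densities = config$densities, seed = config$seed)
  if (!config$flags$recycling)
    pop$agents <- pop$agents[pop$agents$type != "osteomorph", ]
  fields <- cytokine_field(tissue, config$species)
  # equilibrate receptor occupancies against the initial fields
  ag <- pop$agents
  viL <- vox_index(ag$i, ag$j, ag$k, d)
  ag$rank_occ <- update_occupancy(ag$rank_occ, fields$conc$RANKL[viL],
                                  config$binding, dt = 1000)
  ag$tgfb_occ <- update_occupancy(ag$tgfb_occ, fields$conc$TGFb[viL],
                                  config$binding, dt = 1000)
  pop$agents <- ag
  cal <- calibrate_production(config, tissue, pop, strain, config$params)
  prod_rates <- cal$rates
  params <- cal$params
  # spin up the cytokine fields, receptor occupancies and marrow cell
  # positions to their joint steady state before any cell transitions, so
  # the rate balancing sees the stationary (spatially structured) signal
  # environment. Two phases: first without RANKL internalization (to measure
  # the occupancy it must be calibrated against), then with it.
  spin_days <- config$spin_up_days %||% 30
  tgf_init <- config$species$init_pM[config$species$species == "TGFb"]
  spin_day <- function(pop, fields, consume) {
    n_sub <- cytokine_substeps(fields, dt = 1)
    for (s in seq_len(n_sub)) fields <- diffuse_decay_step(fields, 1 / n_sub)
    fields <- react_bind_step(fields, config$binding, 1)
    fields <- strain_production_step(fields, pop, strain, 1, prod_rates,
                                     strain_sensitive = config$flags$mechanostat)
    # TGF-beta is sourced by resorption, which has not started yet
    fields$conc$TGFb[] <- tgf_init
    ag <- pop$agents
    viL <- vox_index(ag$i, ag$j, ag$k, d)
    ag$rank_occ <- update_occupancy(ag$rank_occ, fields$conc$RANKL[viL],
                                    config$binding, 1)
    ag$tgfb_occ <- update_occupancy(ag$tgfb_occ, fields$conc$TGFb[viL],
                                    config$binding, 1)
    pop$agents <- ag
    if (consume) fields <- consume_rankl(fields, pop, params$c_int, 1)
    pop <- step_motility(pop, fields, 1, tissue, params)
    list(pop = pop, fields = fields)
  }
  for (sd in seq_len(ceiling(spin_days / 2))) {
    st <- spin_day(pop, fields, consume = FALSE)
    pop <- st$pop; fields <- st$fields
  }
  if (is.na(params$c_int) && params$rankl_consume_frac > 0) {
    ag <- pop$agents
    lineage <- ag$type %in% c("OCL", "osteomorph")
    viL <- vox_index(ag$i[lineage], ag$j[lineage], ag$k[lineage], d)
    bind_basis <- sum((1 - ag$rank_occ[lineage]) * fields$conc$RANKL[viL])
    kap <- params$rankl_consume_frac
    prod_tot <- prod_rates$p_RANKL * sum(ag$type == "OCY") *
      if (config$flags$mechanostat) {
        eps <- unclass(strain)[vox_index(ag$i[ag$type == "OCY"],
                                         ag$j[ag$type == "OCY"],
                                         ag$k[ag$type == "OCY"], d)]
        eps[is.na(eps)] <- config$target_peak * 1e-6
        mean(strain_response_low(eps))
      } else 0.5
    # consumption takes a kappa share of an enlarged production budget
    params$c_int <- kap / (1 - kap) * prod_tot / max(bind_basis, 1e-9)
    prod_rates$p_RANKL <- prod_rates$p_RANKL / (1 - kap)
  }
  for (sd in seq_len(floor(spin_days / 2))) {
    st <- spin_day(pop, fields, consume = TRUE)
    pop <- st$pop; fields <- st$fields
  }
  params <- calibrate_rates(params, pop, tissue, fields,
                            recycling = config$flags$recycling,
                            annual_loss = config$annual_loss,
                            binding = config$binding)
  bone_prev_solve <- bone_mask(tissue)
  warm <- attr(strain, "displacement")
  dt <- config$cell_dt
  rec_days <- round(config$output_months * days_per_month)
  if (total_days >= config$record_interval_days)
    rec_days <- c(rec_days, seq(config$record_interval_days, total_days,
                                by = config$record_interval_days))
  rec_days <- sort(unique(rec_days[rec_days <= total_days]))
  surf_area_um2 <- function(ts)
    offset_surface_fit(bone_mask(ts))$S * ts$spacing^2
  bs_um2 <- surf_area_um2(tissue)
  t <- 0
  cum_hsc <- 0; cum_morph <- 0
  # reservoir attribution: osteomorphs alive at the end of treatment are the
  # discontinuation reservoir; their later fusions are counted separately
  # from recycling churn
  treat_end_day <- round(config$treatment_months * days_per_month)
  reservoir_ids <- integer(0)
  cum_reservoir_fused <- 0
  # one coarse step of the multiphysics schedule; returns the day's turnover
  day_step <- function(day, dosing) {
    # (1) mechanics refresh
    if (day %% config$fe_interval_days == 0) {
      bone_now <- bone_mask(tissue)
      changed <- sum(bone_now != bone_prev_solve)
      if (changed > config$fe_change_frac * sum(bone_now)) {
        new_strain <- try(solve_microfe(tissue, materials, load,
                                        rtol = config$fe_rtol,
                                        warm_start = warm), silent = TRUE)
        if (!inherits(new_strain, "try-error")) {
          strain <<- new_strain
          warm <<- attr(new_strain, "displacement")
          bone_prev_solve <<- bone_now
          bs_um2 <<- surf_area_um2(tissue)
        }
      }
    }
    strain <<- fill_strain(strain, bone_mask(tissue))
    # (2) cytokines
    n_sub <- cytokine_substeps(fields, dt)
    for (s in seq_len(n_sub)) fields <- diffuse_decay_step(fields, dt / n_sub)
    fields <- react_bind_step(fields, config$binding, dt)
    fields <- strain_production_step(fields, pop, strain, dt, prod_rates,
                                     strain_sensitive = config$flags$mechanostat)
    if (dosing) fields <- apply_dose(fields, config$schedule, t, dt)
    # (3) cells
    ag <- pop$agents
    viL <- vox_index(ag$i, ag$j, ag$k, d)
    ag$rank_occ <- update_occupancy(ag$rank_occ, fields$conc$RANKL[viL],
                                    config$binding, dt)
    ag$tgfb_occ <- update_occupancy(ag$tgfb_occ, fields$conc$TGFb[viL],
                                    config$binding, dt)
    pop$agents <- ag
    fields <- consume_rankl(fields, pop, params$c_int, dt)
    pop <- step_differentiation(pop, fields, strain, params, config$flags,
                                dt, tissue, binding = config$binding)
    if (config$flags$recycling)
      pop <- step_fission_fusion(pop, fields, params, dt, tissue)
    new_ocl <- pop$agents[pop$agents$type == "OCL" & pop$agents$age < dt / 2, ]
    cum_hsc <<- cum_hsc + sum(new_ocl$origin == "hsc")
    cum_morph <<- cum_morph + sum(new_ocl$origin == "morph")
    cum_reservoir_fused <<- cum_reservoir_fused +
      sum(attr(pop, "fused_ids") %in% reservoir_ids)
    pop <- step_motility(pop, fields, dt, tissue, params)
    rf <- step_resorption_formation(pop, tissue, fields, params, dt)
    tissue <- rf$tissue; fields <- rf$fields
    # (4) mineralization and placement repair
    tissue <- update_mineral(tissue, dt)
    pop <- relocate_cells(pop, tissue)
    fields$marrow <- marrow_mask(tissue)
    if (!all(is.finite(fields$conc[["RANKL"]][1:2])))
      stop("numerical instability: non-finite concentrations at day ", day)
    tissue <<- tissue; pop <<- pop; fields <<- fields
    c(formed = rf$formed, resorbed = rf$resorbed)
  }
  # drug-free burn-in: let the coupled loops settle at their own operating
  # point, then pin the formation rate to the measured resorption flux (the
  # placebo imbalance target) and re-normalize the mean-field baselines there
  burn_days <- config$burn_in_days %||% 270
  if (burn_days > 0) {
    burn <- matrix(0, burn_days, 2)
    for (day in seq_len(burn_days)) {
      t <- t + dt
      burn[day, ] <- day_step(day, dosing = FALSE)
    }
    tail_win <- max(min(90, ceiling(burn_days / 2)), 1)
    res_flux <- mean(burn[(burn_days - tail_win + 1):burn_days, 2]) / dt
    n_obl_now <- max(sum(pop$agents$type == "OBL"), 1L)
    target_net <- config$annual_loss * sum(bone_mask(tissue)) / 365
    params$form_rate <- max(res_flux - target_net, 0) / n_obl_now
    mm <- marrow_means(fields, c("sclerostin", "estrogen", "TGFb", "RANKL"))
    params$base$SOST <- mm[["sclerostin"]]
    params$base$E <- mm[["estrogen"]]
    params$base$TGFb <- mm[["TGFb"]]
    params$base$occ_serum <- occupancy_equilibrium(mm[["RANKL"]],
                                                   config$binding)
    params$n0_ocl_mass <- max(sum(pop$agents$nuclei[pop$agents$type == "OCL"]),
                              1)
  }
  bmc0 <- bmc(tissue)
  t <- 0
  cum_hsc <- 0; cum_morph <- 0
  history <- vector("list", total_days)
  rows <- list()
  win_formed <- 0; win_resorbed <- 0; win_start <- 0
  for (day in seq_len(total_days)) {
    t <- t + dt
    if (config$treatment_months > 0 && day == treat_end_day)
      reservoir_ids <- pop$agents$id[pop$agents$type == "osteomorph"]
    fr <- day_step(day, dosing = TRUE)
    win_formed <- win_formed + fr[["formed"]]
    win_resorbed <- win_resorbed + fr[["resorbed"]]
    # (5) bookkeeping
    cts <- cell_counts(pop)
    agh <- pop$agents
    occ_of <- function(tp) {
      o <- agh$rank_occ[agh$type == tp]
      if (length(o)) mean(o) else NA_real_
    }
    history[[day]] <- data.table::data.table(
      time_days = t, t(cts), formed = fr[["formed"]],
      resorbed = fr[["resorbed"]],
      cum_ocl_hsc = cum_hsc, cum_ocl_morph = cum_morph,
      cum_reservoir_fused = cum_reservoir_fused,
      o_OCL = occ_of("OCL"), o_morph = occ_of("osteomorph"),
      o_HSC = occ_of("HSC"),
      ocl_mass = sum(agh$nuclei[agh$type == "OCL"]),
      crowd = ocl_crowding(agh, params),
      rankl_marrow = mean(fields$conc$RANKL[fields$marrow]))
    if (day %in% rec_days || day == total_days) {
      vox_um3 <- tissue$spacing^3
      days_win <- t - win_start
      mm <- marrow_means(fields)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        time_days = t, time_months = t / days_per_month,
        BMC = bmc(tissue), pct_BMC = 100 * (bmc(tissue) / bmc0 - 1),
        BFR = win_formed * vox_um3 / bs_um2 / days_win,
        BRR = win_resorbed * vox_um3 / bs_um2 / days_win,
        t(cts), t(mm))
      win_formed <- 0; win_resorbed <- 0; win_start <- t
    }
  }
  structure(list(table = data.table::rbindlist(rows),
                 history = data.table::rbindlist(history),
                 tissue = tissue, pop = pop, fields = fields,
                 config = config, baseline_bmc = bmc0, params = params),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d recorded timepoints, final %%dBMC = %.2f%%\n",
              nrow(x$table), tail(x$table$pct_BMC, 1)))
  invisible(x)
}

#' Run the 16-configuration factorial
#'
#' Executes all 16 on/off combinations of the four mechanistic hypotheses on
#' each phantom with matched seeds, labeled in the canonical Greek order.
#'
#' @param base_config a [simulation_config()]; its `flags` are overridden.
#' @param phantoms a named list of [tissue_state()]s (names become phantom
#'   ids).
#' @param configs optional subset of labels to run (default all 16).
#' @return A `data.table`: the concatenated run tables with `run`, `phantom`,
#'   `P_A`..`P_D` and `BL` (baseline BMC) columns.
#' @export
run_factorial <- function(base_config, phantoms, configs = NULL) {
  if (length(phantoms) == 0L) stop("need at least one phantom")
  if (is.null(names(phantoms)))
    names(phantoms) <- sprintf("phantom%02d", seq_along(phantoms))
  tab <- factorial_table()
  if (!is.null(configs)) tab <- tab[tab$label %in% configs, ]
  out <- list()
  for (p in names(phantoms)) {
    for (r in seq_len(nrow(tab))) {
      cfg <- base_config
      cfg$flags <- hypothesis_flags(tab$P_A[r] == 1, tab$P_B[r] == 1,
                                    tab$P_C[r] == 1, tab$P_D[r] == 1)
      res <- run_simulation(cfg, phantoms[[p]])
      rt <- data.table::copy(res$table)
      rt[, `:=`(run = tab$label[r], phantom = p,
                P_A = tab$P_A[r], P_B = tab$P_B[r],
                P_C = tab$P_C[r], P_D = tab$P_D[r],
                BL = res$baseline_bmc)]
      out[[length(out) + 1L]] <- rt
    }
  }
  data.table::rbindlist(out)
}
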