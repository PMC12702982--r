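#' Cell population container
#'
#' Agents live on the voxel lattice: osteoclasts (OCL), osteoblasts (OBL),
#' lining cells (LC) and surface preosteoclasts (preOCL) occupy bone-surface
#' voxels; osteocytes (OCY) sit inside bone; haematopoietic stem cells (HSC),
#' mesenchymal stem cells (MSC) and osteomorphs reside in the marrow.
#' `rank_occ` is the RANK binding-site occupancy of osteoclast-lineage cells,
#' `tgfb_occ` the TGF-beta receptor occupancy of the osteoblast lineage,
#' `nuclei` the osteoclast nucleus count (mean 5), and `origin` records
#' whether an osteoclast arose from marrow precursors (`"hsc"`) or from
#' osteomorph re-fusion (`"morph"`), which feeds the resurgence accounting.
#'
#' @param agents a `data.table` with columns `id`, `type`, `i`, `j`, `k`,
#'   `age`, `rank_occ`, `tgfb_occ`, `nuclei`, `origin`.
#' @return An object of class `cell_population`.
#' @export
cell_population <- function(agents) {
  need <- c("id", "type", "i", "j", "k", "age", "rank_occ", "tgfb_occ",
            "nuclei", "origin")
  agents <- data.table::as.data.table(agents)
  missing_cols <- setdiff(need, names(agents))
  for (m in missing_cols) agents[[m]] <- switch(
    m, age = 0, rank_occ = 0.5, tgfb_occ = 0.5, nuclei = 1L,
    origin = "seed", id = seq_len(nrow(agents)), stop("missing column ", m))
  structure(list(agents = agents[, need, with = FALSE],
                 next_id = max(0L, agents$id) + 1L),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  print(x$agents[, .N, by = "type"])
  invisible(x)
}

#' Count agents by type
#' @param pop a [cell_population()].
#' @return Named integer vector over all cell types.
#' @export
cell_counts <- function(pop) {
  types <- c("HSC", "preOCL", "OCL", "osteomorph", "MSC", "OBL", "LC",
             "preOCY", "OCY")
  tab <- table(factor(pop$agents$type, levels = types))
  setNames(as.integer(tab), types)
}

cell_types_surface <- c("OCL", "OBL", "LC", "preOCL")
cell_types_marrow <- c("HSC", "MSC", "osteomorph")

new_agents <- function(pop, type, vi, d, nuclei = 1L, origin = "seed",
                       rank_occ = 0.5, tgfb_occ = 0.5) {
  if (length(vi) == 0L) return(pop)
  co <- vox_coords(vi, d)
  n <- length(vi)
  add <- data.table::data.table(
    id = pop$next_id + seq_len(n) - 1L, type = type,
    i = co[, 1L], j = co[, 2L], k = co[, 3L], age = 0,
    rank_occ = rank_occ, tgfb_occ = tgfb_occ,
    nuclei = as.integer(nuclei), origin = origin)
  pop$agents <- data.table::rbindlist(list(pop$agents, add), use.names = TRUE)
  pop$next_id <- pop$next_id + n
  pop
}

#' Seed the initial cell populations
#'
#' Marrow is seeded with MSCs (8000/mm^3) and HSCs (6000/mm^3); osteocytes
#' are embedded in bone at 18,500/mm^3 of bone volume. Surface osteoblasts
#' and osteoclasts are placed by strain:
#' * `"modelling"` mode uses the absolute thresholds: osteoblasts where the
#'   surface effective strain exceeds 4000 microstrain, osteoclasts below
#'   200 microstrain;
#' * `"remodelling"` mode works per subregion: osteoblasts at surface voxels
#'   above the subregion's mean surface strain and osteoclasts below it, but
#'   the subregion is accepted only if that yields 6-40 osteoblasts and
#'   4-40 osteoclasts (basic multicellular units).
#' Osteoclasts receive `1 + Poisson(4)` nuclei (mean 5); preosteoclasts
#' start at parity with the osteoclast count and osteomorphs at nuclei
#' parity; lining cells fill the remaining surface.
#'
#' @param tissue a [tissue_state()].
#' @param strain a `strain_field` on the current tissue.
#' @param partition a [partition_subregions()] result (remodelling mode).
#' @param mode `"remodelling"` or `"modelling"`.
#' @param densities reference densities; see [seed_densities()].
#' @param seed RNG seed.
#' @return A [cell_population()] with an attribute `accepted_subregions`
#'   (remodelling mode): a `data.table` of subregion id, osteoblast and
#'   osteoclast counts for every accepted subregion.
#' @export
seed_initial_cells <- function(tissue, strain, partition = NULL,
                               mode = c("remodelling", "modelling"),
                               densities = seed_densities(), seed = 1) {
  mode <- match.arg(mode)
  set.seed(child_seed(seed, "seeding"))
  d <- dim(tissue$osteoid)
  surf <- extract_surface(tissue)
  if (!any(surf)) stop("no bone surface to seed")
  bone <- bone_mask(tissue)
  marrow <- !bone
  h_mm <- tissue$spacing / 1000
  vox_mm3 <- h_mm^3
  bv_mm3 <- sum(bone) * vox_mm3
  marrow_mm3 <- sum(marrow) * vox_mm3
  n_ocy <- round(densities$ocy_per_mm3_bv * bv_mm3)
  if (n_ocy > sum(bone))
    stop(sprintf("osteocyte density infeasible: %d requested, %d bone voxels",
                 n_ocy, sum(bone)))
  pop <- cell_population(data.table::data.table(
    id = integer(0), type = character(0), i = integer(0), j = integer(0),
    k = integer(0), age = numeric(0), rank_occ = numeric(0),
    tgfb_occ = numeric(0), nuclei = integer(0), origin = character(0)))
  bone_idx <- which(bone)
  marrow_idx <- which(marrow)
  pop <- new_agents(pop, "OCY", sample(bone_idx, n_ocy), d)
  pop <- new_agents(pop, "MSC",
                    sample(marrow_idx, round(densities$msc_per_mm3 * marrow_mm3),
                           replace = TRUE), d)
  pop <- new_agents(pop, "HSC",
                    sample(marrow_idx, round(densities$hsc_per_mm3 * marrow_mm3),
                           replace = TRUE), d)
  surf_idx <- which(surf)
  eps <- unclass(strain)[surf_idx] * 1e6 # microstrain
  eps[is.na(eps)] <- 2500
  accepted <- NULL
  if (mode == "modelling") {
    obl_idx <- surf_idx[eps > 4000]
    ocl_idx <- surf_idx[eps < 200]
  } else {
    if (is.null(partition)) stop("remodelling seeding needs a subregion partition")
    sub <- partition$index[surf_idx]
    ms <- rowsum(eps, sub) / as.vector(table(sub))
    mean_of <- setNames(ms[, 1L], rownames(ms))
    above <- eps > mean_of[as.character(sub)]
    n_ob <- rowsum(as.numeric(above), sub)[, 1L]
    n_oc <- rowsum(as.numeric(!above), sub)[, 1L]
    ok <- n_ob >= 6 & n_ob <= 40 & n_oc >= 4 & n_oc <= 40
    ok_ids <- as.integer(names(n_ob))[ok]
    # active basic multicellular units are sparse on the surface: keep at
    # most bmu_per_mm2 accepted subregions per mm^2 of bone surface, so the
    # seeded workload scales with the domain instead of with the accident
    # of the block-size/surface-density ratio
    bs_mm2 <- mask_area_vox2(bone) * (tissue$spacing / 1000)^2
    max_acc <- max(1L, ceiling(densities$bmu_per_mm2 * bs_mm2))
    if (length(ok_ids) > max_acc) ok_ids <- sort(sample(ok_ids, max_acc))
    keep <- as.integer(names(n_ob)) %in% ok_ids
    accepted <- data.table::data.table(
      subregion = as.integer(names(n_ob))[keep],
      n_OBL = as.integer(n_ob[keep]), n_OCL = as.integer(n_oc[keep]))
    in_ok <- sub %in% ok_ids
    obl_idx <- surf_idx[in_ok & above]
    ocl_idx <- surf_idx[in_ok & !above]
  }
  pop <- new_agents(pop, "OBL", obl_idx, d)
  pop <- new_agents(pop, "OCL", ocl_idx, d,
                    nuclei = 1L + rpois(length(ocl_idx), densities$nuclei_mean - 1))
  # preosteoclasts start at parity with osteoclast count; the osteomorph
  # pool starts at nuclei parity (one osteomorph per osteoclast nucleus),
  # the standing reservoir the fission-fusion loop turns over
  if (length(ocl_idx) > 0L) {
    pop <- new_agents(pop, "preOCL",
                      sample(surf_idx, length(ocl_idx), replace = TRUE), d)
    n_morph0 <- sum(pop$agents$nuclei[pop$agents$type == "OCL"])
    pop <- new_agents(pop, "osteomorph",
                      sample(marrow_idx, n_morph0, replace = TRUE), d)
  }
  lc_idx <- setdiff(surf_idx, union(obl_idx, ocl_idx))
  pop <- new_agents(pop, "LC", lc_idx, d)
  attr(pop, "accepted_subregions") <- accepted
  pop
}

#' Reference seeding densities
#'
#' Clinical reference densities used at initialization: osteocytes per bone
#' volume, stem cells per marrow volume, and the histology-derived surface
#' densities of osteoblasts and osteoclasts (with a mean of 5 nuclei).
#'
#' @param ocy_per_mm3_bv,msc_per_mm3,hsc_per_mm3,obl_per_mm2,ocl_per_mm2,nuclei_mean
#'   overrides for individual densities.
#' @return A named list.
#' @export
seed_densities <- function(ocy_per_mm3_bv = 18500, msc_per_mm3 = 8000,
                           hsc_per_mm3 = 6000, obl_per_mm2 = 6.6,
                           ocl_per_mm2 = 0.65, nuclei_mean = 5,
                           bmu_per_mm2 = 20) {
  list(ocy_per_mm3_bv = ocy_per_mm3_bv, msc_per_mm3 = msc_per_mm3,
       hsc_per_mm3 = hsc_per_mm3, obl_per_mm2 = obl_per_mm2,
       ocl_per_mm2 = ocl_per_mm2, nuclei_mean = nuclei_mean,
       bmu_per_mm2 = bmu_per_mm2)
}

#' Normalized Hill effect curve
#'
#' All concentration effect terms of the cell balance equations share one
#' Hill form, normalized so the effect equals 1 at the baseline
#' concentration: rates are therefore unchanged at homeostasis and modulated
#' (bounded by `e_max` above, 0 below) as the signal departs from baseline.
#'
#' @param conc concentration (or occupancy) value(s).
#' @param baseline value at which the effect is 1.
#' @param e_max plateau of the curve (> 1).
#' @param n Hill exponent.
#' @param direction `"inc"` for an activating, `"dec"` for an inhibitory term.
#' @return Effect multiplier(s) in `[0, e_max]`.
#' @export
effect_curve <- function(conc, baseline, e_max = 2, n = 2,
                         direction = c("inc", "dec")) {
  direction <- match.arg(direction)
  if (baseline <= 0) return(rep(1, length(conc)))
  conc <- pmax(conc, 0)
  if (direction == "inc") {
    K <- baseline * (e_max - 1)^(1 / n)
    e_max * conc^n / (conc^n + K^n)
  } else {
    K <- baseline / (e_max - 1)^(1 / n)
    e_max * K^n / (conc^n + K^n)
  }
}

#' Cell behavior rate parameters
#'
#' Differentiation, proliferation and apoptosis rates of the osteoblast and
#' osteoclast lineages (per day unless noted; `P_OB` and `A_OB` are per
#' week), the osteomorph fission/fusion constants, tissue resorption and
#' formation rates, motility speed and the homeostatic rate-change limit.
#' Several rates default to `NA` and are filled by [calibrate_rates()] so
#' that the seeded population is a balance fixed point.
#'
#' @param ... overrides of individual entries.
#' @return An object of class `rate_params` (a list).
#' @export
rate_params <- function(...) {
  p <- list(
    # osteoblast lineage
    G_MSCtoOB = NA, G_lctoOB = NA, P_OB = 0.035, G_OBtolc = 0.010,
    G_OBtoOCY = NA, A_OB = 0.070,
    # osteoclast lineage
    G_HSCtoPre = NA, G_pre2ocl = NA, A_pre = 0.06, A_OCL = 0.10,
    drug_apop_emax = 10, drug_apop_n = 2, S_HSC = NA, S_MSC = NA,
    k_niche = 0.05, n0_HSC = NA, n0_MSC = NA,
    # osteomorphs: fission calibrated at RANKL 100 ng/mL (5000 pM with the
    # 20 kDa default) to 0.6 OCL/h/(100x100 um^2); 6-month apoptosis half-life
    fiss_ref_rate = 0.28, fiss_ref_conc_pM = 5000, p_fiss_max = 0.28,
    k_fiss = NA, k_fus = NA, lambda_morph = log(2) / 182.5,
    # finite surface niches: osteoclast formation (fusion and preosteoclast
    # conversion) scales with 1 - N/(capacity_mult * baseline nuclei mass)
    ocl_capacity_mult = 2, n0_ocl_mass = NA,
    # tissue exchange: the per-nucleus abrasion rate is calibrated so the
    # total resorption flux turns over annual_turnover of the bone volume
    # per year; form_rate is then balanced against it
    annual_turnover = 0.15, resorb_rate = NA, form_rate = 0.013,
    tgf_release = NA,
    # motility
    speed_um_day = 14.4,
    # RANKL internalization: share of total RANKL production consumed by
    # RANK-bearing cells at baseline; c_int is calibrated from it
    rankl_consume_frac = 0.5, c_int = NA,
    # homeostatic audit limit (fraction/day)
    rate_limit = 0.05,
    # effect-curve shapes
    e_max = 2, hill_n = 2, occ_e_max = 3, occ_hill_n = 2,
    # baselines the effect curves are normalized at (occupancies and marrow
    # means are measured from the spun-up state during calibration)
    base = list(SOST = 50, TGFb = 200, E = 27.5, occ_HSC = 0.5,
                occ_pre = 0.5, occ_OCL = 0.5, occ_serum = 0.05))
  over <- list(...)
  p[names(over)] <- over
  class(p) <- "rate_params"
  p
}

# Per-agent transition probability for a constant rate over dt.
p_of_rate <- function(rate, dt) 1 - exp(-pmax(rate, 0) * dt)

# Crowding factor on osteoclast formation: surface niches are finite, so
# recruitment stops as the nuclei mass approaches its capacity and doubles
# when the pool is depleted (relative to the calibrated baseline).
ocl_crowding <- function(ag, params) {
  if (is.na(params$n0_ocl_mass)) return(1)
  n_mass <- sum(ag$nuclei[ag$type == "OCL"])
  max(0, 1 - n_mass / (params$ocl_capacity_mult * params$n0_ocl_mass))
}

#' Balance the lineage rates at the seeded state
#'
#' Fills the `NA` rates of a [rate_params()] so the seeded population is an
#' expectation fixed point of the cell balance equations at baseline signal
#' levels (all effect terms equal to 1): the lining-cell exchange closes the
#' osteoblast loop, osteoblast-to-osteocyte embedding matches osteocyte loss
#' to resorption, the fission-fusion loop balances the osteomorph pool, and
#' stem-cell sources replace differentiation outflux. The formation rate is
#' set from the seeded osteoclast resorption flux minus the configured
#' placebo imbalance (`annual_loss`, fraction of bone volume lost per year).
#'
#' @param params a [rate_params()].
#' @param pop the seeded [cell_population()].
#' @param tissue the seeded [tissue_state()].
#' @param o_base baseline RANK occupancy measured from the population.
#' @param recycling is the osteomorph mechanism active?
#' @param annual_loss placebo net bone loss per year (fraction of bone
#'   volume); the calibration constraint is a 0.5-5% total drop over 4 years.
#' @return The completed `rate_params`.
#' @export
calibrate_rates <- function(params, pop, tissue, fields = NULL,
                            recycling = TRUE, annual_loss = 0.006,
                            binding = binding_params()) {
  cts <- cell_counts(pop)
  ag <- pop$agents
  occ_of <- function(type) {
    o <- ag$rank_occ[ag$type == type]
    if (length(o) == 0L) 0.5 else o
  }
  o_hsc <- occ_of("HSC"); o_pre <- occ_of("preOCL")
  o_ocl <- occ_of("OCL"); o_morph <- occ_of("osteomorph")
  params$base$occ_HSC <- mean(o_hsc)
  params$base$occ_pre <- mean(o_pre)
  params$base$occ_OCL <- mean(o_ocl)
  if (!is.null(fields)) {
    mm <- marrow_means(fields, c("sclerostin", "estrogen", "TGFb", "RANKL"))
    params$base$SOST <- mm[["sclerostin"]]
    params$base$E <- mm[["estrogen"]]
    params$base$TGFb <- mm[["TGFb"]]
    params$base$occ_serum <- occupancy_equilibrium(mm[["RANKL"]], binding)
  }
  n_obl <- max(cts[["OBL"]], 1L); n_lc <- max(cts[["LC"]], 1L)
  n_msc <- max(cts[["MSC"]], 1L); n_hsc <- max(cts[["HSC"]], 1L)
  n_ocl <- max(cts[["OCL"]], 1L); n_pre <- max(cts[["preOCL"]], 1L)
  n_morph <- cts[["osteomorph"]]
  nuc <- ag$nuclei[ag$type == "OCL"]
  n_nuc <- sum(nuc)
  if (n_nuc == 0L) { n_nuc <- 5 * n_ocl; nuc <- rep(5, n_ocl) }
  # lining-cell loop: LC -> OB influx balances OB -> LC outflux
  params$G_lctoOB <- params$G_OBtolc * n_obl / n_lc
  # per-nucleus abrasion rate from the turnover target (if not yet set)
  if (is.na(params$resorb_rate)) {
    target_flux <- params$annual_turnover * sum(bone_mask(tissue)) / 365
    params$resorb_rate <- target_flux * (1 - tissue$bone_threshold) * 5 /
      max(n_nuc, 1)
  }
  # effective volumetric resorption flux (voxels/day): the gradual abrasion
  # finishes each voxel once it erodes below the bone threshold
  resorb_flux <- params$resorb_rate * n_nuc / 5 /
    (1 - tissue$bone_threshold)
  # osteocyte embedding balances expected osteocyte loss to resorption
  ocy_per_vox <- cts[["OCY"]] / max(sum(bone_mask(tissue)), 1L)
  params$G_OBtoOCY <- resorb_flux * ocy_per_vox / n_obl
  # MSC -> OB then closes the osteoblast balance
  out_ob <- (params$G_OBtolc + params$G_OBtoOCY + params$A_OB / 7 -
               params$P_OB / 7) * n_obl
  influx_lc <- params$G_lctoOB * n_lc
  params$G_MSCtoOB <- max(out_ob - influx_lc, 0) / n_msc
  params$S_MSC <- params$G_MSCtoOB * n_msc
  params$n0_MSC <- n_msc
  # osteoclast loop; differentiation and apoptosis are modulated by the
  # population-mean occupancy (normalized to 1 at baseline), while fission
  # and fusion stay agent-wise. All fluxes are balanced on the realized
  # per-day event-probability scale (1 - exp(-rate)), not the rate scale,
  # so the exponential shaving of large rates does not bias the loop.
  params$k_fiss <- params$fiss_ref_rate /
    max(1 - occupancy_equilibrium(params$fiss_ref_conc_pM), 1e-12)
  p_apop <- 1 - exp(-params$A_OCL)
  a_mass <- sum(nuc * p_apop)
  p_f_i <- if (recycling)
    pmin(params$p_fiss_max, params$k_fiss * (1 - o_ocl)) else rep(0, n_ocl)
  if (length(p_f_i) != length(nuc)) p_f_i <- rep(mean(p_f_i), length(nuc))
  # fission applies to the day's apoptosis survivors
  fiss_mass <- sum(nuc * (1 - p_apop) * (1 - exp(-p_f_i)))
  if (recycling && n_morph > 0L) {
    p_lam <- 1 - exp(-params$lambda_morph)
    fusion_mass <- max(fiss_mass - p_lam * n_morph, 0)
    # only osteomorphs face-adjacent to the surface can fuse: calibrate the
    # fusion constant against their occupancy budget, not the whole pool's
    surf <- extract_surface(tissue)
    d <- dim(tissue$osteoid)
    mrows <- ag$type == "osteomorph"
    nb <- face_neighbors(vox_index(ag$i[mrows], ag$j[mrows], ag$k[mrows], d), d)
    adj <- rowSums(matrix(!is.na(nb) & surf[ifelse(is.na(nb), 1L, nb)],
                          nrow(nb), ncol(nb))) > 0
    o_adj <- o_morph[adj]
    if (sum(o_adj) > 1e-9 && fusion_mass > 0 &&
        fusion_mass < 0.99 * length(o_adj)) {
      params$k_fus <- uniroot(function(k)
        sum(1 - exp(-k * o_adj)) - fusion_mass,
        lower = 0, upper = 1e6, tol = 1e-10)$root
    } else params$k_fus <- fusion_mass / max(sum(o_adj), 1e-9)
  } else {
    params$k_fus <- 0
    fusion_mass <- 0
  }
  pre_flux <- max(a_mass + fiss_mass - fusion_mass, 0) / 5
  # baseline crowding: at the seeded mass the niche factor is 1 - 1/mult
  params$n0_ocl_mass <- n_nuc
  crowd0 <- 1 - 1 / params$ocl_capacity_mult
  params$k_fus <- params$k_fus / crowd0
  # preosteoclast conversion and apoptosis are competing risks within a day
  pre_events <- function(G) n_pre * (1 - exp(-(G + params$A_pre))) *
    G / (G + params$A_pre)
  if (pre_flux > 0 && pre_flux < 0.95 * n_pre) {
    params$G_pre2ocl <- uniroot(function(G) pre_events(G) - pre_flux,
                                lower = 1e-9, upper = 50, tol = 1e-10)$root /
      crowd0
  } else params$G_pre2ocl <- pre_flux / n_pre / crowd0
  out_pre <- pre_events(params$G_pre2ocl) + n_pre *
    (1 - exp(-(params$G_pre2ocl + params$A_pre))) *
    params$A_pre / (params$G_pre2ocl + params$A_pre)
  params$G_HSCtoPre <- -log(max(1 - out_pre / n_hsc, 0.01))
  params$S_HSC <- out_pre
  params$n0_HSC <- n_hsc
  # formation rate from the resorption flux minus the placebo imbalance
  target_net <- annual_loss * sum(bone_mask(tissue)) / 365
  params$form_rate <- max(resorb_flux - target_net, 0) / n_obl
  params
}

#' Equilibrium RANK occupancy at a given free RANKL level
#' @param conc_pM free RANKL concentration in pM.
#' @param params a [binding_params()].
#' @return Occupancy fraction at binding equilibrium.
#' @export
occupancy_equilibrium <- function(conc_pM, params = binding_params()) {
  params$kon_RANK * conc_pM / (params$kon_RANK * conc_pM + params$koff_RANK)
}

#' Stochastic differentiation step
#'
#' Advances all lineage transitions of the cell balance over `dt` with
#' per-agent exponential-waiting-time probabilities `1 - exp(-rate dt)`,
#' where each rate is the baseline rate times its Hill effect terms evaluated
#' at the current marrow-average signal levels (sclerostin, TGF-beta,
#' estrogen) or at the agent's own receptor occupancy:
#' * MSC -> OBL (inhibited by sclerostin; stimulated by TGF-beta when
#'   clast-blast coupling is active), LC <-> OBL, OBL proliferation,
#'   OBL -> OCY embedding, OBL apoptosis (restrained by estrogen);
#' * HSC -> preOCL (gated by RANK occupancy when gate-blocking is active:
#'   low occupancy blocks differentiation and the precursors accumulate),
#'   preOCL -> OCL fusion (always occupancy-dependent), preOCL and OCL
#'   apoptosis, the latter strongly accelerated as occupancy collapses after
#'   an injection;
#' * stem-cell niches replenish toward their seeded sizes.
#'
#' @param pop a [cell_population()].
#' @param fields a [cytokine_field()].
#' @param strain a `strain_field` (placement of new surface cells).
#' @param params a calibrated [rate_params()].
#' @param hypotheses list of toggles `gate_blocking`, `coupling` (see
#'   [hypothesis_flags()]).
#' @param dt timestep in days.
#' @param tissue the current [tissue_state()] (surface placement).
#' @return The updated population.
#' @export
step_differentiation <- function(pop, fields, strain, params, hypotheses,
                                 dt, tissue, binding = binding_params()) {
  ag <- data.table::copy(pop$agents)
  d <- dim(tissue$osteoid)
  surf_idx <- which(extract_surface(tissue))
  mm <- marrow_means(fields, c("sclerostin", "TGFb", "estrogen"))
  e_sost_form <- effect_curve(mm[["sclerostin"]], params$base$SOST,
                              params$e_max, params$hill_n, "dec")
  e_sost_quiesce <- effect_curve(mm[["sclerostin"]], params$base$SOST,
                                 params$e_max, params$hill_n, "inc")
  e_tgf <- if (isTRUE(hypotheses$coupling))
    effect_curve(mm[["TGFb"]], params$base$TGFb, params$e_max,
                 params$hill_n, "inc") else 1
  e_estr <- effect_curve(mm[["estrogen"]], params$base$E, params$e_max,
                         params$hill_n, "dec")
  # the balance equations modulate rates by averaged effect terms; the
  # occupancy entering them is the serum-like equilibrium occupancy at the
  # marrow-mean free RANKL, so local hotspots and spatial sorting of agents
  # cannot bias the population rates
  o_serum <- occupancy_equilibrium(mean(fields$conc$RANKL[fields$marrow]),
                                   binding)
  occ_eff <- function(o, base) effect_curve(o, base, params$occ_e_max,
                                            params$occ_hill_n, "inc")
  ag$fate <- "stay"
  draw <- function(n) runif(n)
  # --- osteoblast lineage
  msc <- ag$type == "MSC"
  r <- params$G_MSCtoOB * e_sost_form * e_tgf
  ag$fate[msc & draw(nrow(ag)) < p_of_rate(r, dt)] <- "MSCtoOB"
  lc <- ag$type == "LC"
  r <- params$G_lctoOB * e_sost_form
  ag$fate[lc & draw(nrow(ag)) < p_of_rate(r, dt)] <- "LCtoOB"
  obl <- ag$type == "OBL"
  u <- draw(nrow(ag))
  rate_lc <- params$G_OBtolc * e_sost_quiesce
  rate_ocy <- params$G_OBtoOCY
  rate_apop <- params$A_OB / 7 * e_estr
  r_tot <- rate_lc + rate_ocy + rate_apop
  leaving <- obl & u < p_of_rate(r_tot, dt)
  if (any(leaving)) {
    pick <- runif(sum(leaving)) * r_tot
    fate <- ifelse(pick < rate_lc, "OBtolc",
                   ifelse(pick < rate_lc + rate_ocy, "OBtoOCY", "OBapop"))
    ag$fate[leaving] <- fate
  }
  prolif <- obl & !leaving & draw(nrow(ag)) < p_of_rate(params$P_OB / 7, dt)
  # --- osteoclast lineage
  hsc <- ag$type == "HSC"
  gate <- if (isTRUE(hypotheses$gate_blocking))
    occ_eff(o_serum, params$base$occ_serum) else 1
  r <- params$G_HSCtoPre * gate
  ag$fate[hsc & draw(nrow(ag)) < p_of_rate(r, dt)] <- "HSCtoPre"
  pre <- ag$type == "preOCL"
  u <- draw(nrow(ag))
  crowd <- ocl_crowding(ag, params)
  rate_fuse <- params$G_pre2ocl * crowd * occ_eff(o_serum,
                                                 params$base$occ_serum)
  r_tot <- rate_fuse + params$A_pre
  leaving <- pre & u < p_of_rate(r_tot, dt)
  if (any(leaving)) {
    pick <- runif(sum(leaving)) * r_tot
    ag$fate[leaving] <- ifelse(pick < rate_fuse, "PretoOCL", "Preapop")
  }
  ocl <- ag$type == "OCL"
  g <- effect_curve(o_serum, params$base$occ_serum,
                    params$drug_apop_emax, params$drug_apop_n, "dec")
  if (is.na(g)) g <- 1
  r <- params$A_OCL * g
  ag$fate[ocl & draw(nrow(ag)) < p_of_rate(r, dt)] <- "OCLapop"
  # --- apply fates
  out <- ag[ag$fate %in% c("OBapop", "Preapop", "OCLapop") == FALSE, ]
  to_surface <- function(tab, newtype, nuclei = NULL) {
    n <- nrow(tab)
    if (n == 0L || length(surf_idx) == 0L) return(tab)
    tgt <- vox_coords(sample(surf_idx, n, replace = TRUE), d)
    tab$i <- tgt[, 1L]; tab$j <- tgt[, 2L]; tab$k <- tgt[, 3L]
    tab$type <- newtype
    tab$age <- 0
    if (!is.null(nuclei)) tab$nuclei <- nuclei
    tab
  }
  sel <- out$fate == "MSCtoOB"
  out[sel, ] <- to_surface(out[sel, ], "OBL")
  sel <- out$fate == "HSCtoPre"
  out[sel, ] <- to_surface(out[sel, ], "preOCL")
  sel <- out$fate == "LCtoOB"
  out$type[sel] <- "OBL"
  sel <- out$fate == "OBtolc"
  out$type[sel] <- "LC"
  sel <- out$fate == "OBtoOCY"
  out$type[sel] <- "OCY" # embeds at its (bone) surface voxel
  sel <- out$fate == "PretoOCL"
  if (any(sel)) {
    out$type[sel] <- "OCL"
    out$age[sel] <- -dt # age increments below; new osteoclasts end at 0
    out$nuclei[sel] <- 1L + rpois(sum(sel), 4)
    out$origin[sel] <- "hsc"
  }
  fate_tab <- table(ag$fate)
  out$fate <- NULL
  pop$agents <- out
  # proliferation and niche replenishment
  if (any(prolif)) {
    src <- ag[prolif, ]
    pop <- new_agents(pop, "OBL", vox_index(src$i, src$j, src$k, d), d)
  }
  marrow_idx <- which(marrow_mask(tissue))
  cts <- cell_counts(pop)
  na0 <- function(x) if (is.null(x) || is.na(x)) 0 else x
  n_new_msc <- rpois(1, max(na0(params$S_MSC) +
    params$k_niche * na0(params$n0_MSC - cts[["MSC"]]), 0) * dt)
  n_new_hsc <- rpois(1, max(na0(params$S_HSC) +
    params$k_niche * na0(params$n0_HSC - cts[["HSC"]]), 0) * dt)
  if (n_new_msc > 0 && length(marrow_idx) > 0)
    pop <- new_agents(pop, "MSC", sample(marrow_idx, n_new_msc, replace = TRUE), d)
  if (n_new_hsc > 0 && length(marrow_idx) > 0)
    pop <- new_agents(pop, "HSC", sample(marrow_idx, n_new_hsc, replace = TRUE), d)
  pop$agents$age <- pop$agents$age + dt
  attr(pop, "events") <- fate_tab
  pop
}

#' Osteomorph fission and fusion step
#'
#' Osteoclasts fission into osteomorphs (one per nucleus) with probability
#' rate `min(p_max, k_fiss (1 - o))`, inversely proportional to RANK
#' occupancy near the calibration point (the linear law is calibrated so a
#' surface tiled with osteoclasts at 100 ng/mL RANKL fissions at
#' 0.6 osteoclasts/hour per 100x100 um^2 patch). Marrow osteomorphs adjacent
#' to the bone surface re-fuse into osteoclasts with probability rate
#' `k_fus o`, and the pool decays by apoptosis with a 6-month half-life.
#'
#' @param pop a [cell_population()].
#' @param fields a [cytokine_field()] (unused directly; occupancies are
#'   per-agent state).
#' @param params a calibrated [rate_params()].
#' @param dt timestep in days.
#' @param tissue the current [tissue_state()].
#' @return The updated population.
#' @export
step_fission_fusion <- function(pop, fields, params, dt, tissue) {
  ag <- data.table::copy(pop$agents)
  d <- dim(tissue$osteoid)
  surf <- extract_surface(tissue)
  marrow <- marrow_mask(tissue)
  ev <- c(fissions = 0, fused = 0, morph_deaths = 0)
  # fission
  ocl_rows <- which(ag$type == "OCL")
  if (length(ocl_rows) > 0L) {
    o <- ag$rank_occ[ocl_rows]
    p <- p_of_rate(pmin(params$p_fiss_max, params$k_fiss * (1 - o)), dt)
    fiss <- ocl_rows[runif(length(ocl_rows)) < p]
    ev[["fissions"]] <- length(fiss)
    if (length(fiss) > 0L) {
      vi <- vox_index(ag$i[fiss], ag$j[fiss], ag$k[fiss], d)
      nb <- face_neighbors(vi, d)
      nb_marrow <- matrix(marrow[nb] & !is.na(nb), nrow(nb), ncol(nb))
      pick_nb <- function(r) {
        ok <- which(nb_marrow[r, ])
        if (length(ok) == 0L) return(NA_integer_)
        nb[r, ok[sample.int(length(ok), 1L)]]
      }
      tgt <- vapply(seq_along(fiss), pick_nb, integer(1))
      reps <- ag$nuclei[fiss]
      keep <- !is.na(tgt)
      morph_vi <- rep(tgt[keep], reps[keep])
      occ0 <- rep(ag$rank_occ[fiss][keep], reps[keep])
      ag <- ag[-fiss, ]
      pop$agents <- ag
      pop <- new_agents(pop, "osteomorph", morph_vi, d, origin = "fission",
                        rank_occ = occ0)
      ag <- pop$agents
    }
  }
  # fusion (osteomorphs adjacent to surface) and apoptosis
  morph_rows <- which(ag$type == "osteomorph")
  if (length(morph_rows) > 0L) {
    u_ap <- runif(length(morph_rows)) < p_of_rate(params$lambda_morph, dt)
    vi <- vox_index(ag$i[morph_rows], ag$j[morph_rows], ag$k[morph_rows], d)
    nb <- face_neighbors(vi, d)
    nb_surf <- matrix(!is.na(nb) & surf[ifelse(is.na(nb), 1L, nb)],
                      nrow(nb), ncol(nb))
    has_surf <- rowSums(nb_surf) > 0L
    crowd <- ocl_crowding(ag, params)
    p_fus <- p_of_rate(params$k_fus * crowd * ag$rank_occ[morph_rows], dt)
    fuse <- has_surf & runif(length(morph_rows)) < p_fus & !u_ap
    died <- u_ap
    ev[["fused"]] <- sum(fuse)
    ev[["morph_deaths"]] <- sum(died)
    fused_ids <- ag$id[morph_rows[fuse]]
    if (any(fuse)) {
      rows <- which(fuse)
      tgt <- vapply(rows, function(r) {
        ok <- which(nb_surf[r, ])
        nb[r, ok[sample.int(length(ok), 1L)]]
      }, integer(1))
      occ0 <- ag$rank_occ[morph_rows[rows]]
      drop <- morph_rows[fuse | died]
      ag2 <- if (length(drop)) ag[-drop, ] else ag
      # fused osteomorphs aggregate: they add nuclei to an osteoclast already
      # on the target voxel, or found one new osteoclast per voxel
      grp <- rowsum(cbind(n = rep(1, length(tgt)), occ = occ0), group = tgt)
      gvi <- as.integer(rownames(grp))
      ocl_here <- ag2$type == "OCL"
      ovi <- vox_index(ag2$i, ag2$j, ag2$k, d)
      hit <- match(gvi, ifelse(ocl_here, ovi, NA_integer_))
      joins <- !is.na(hit)
      if (any(joins))
        ag2$nuclei[hit[joins]] <- ag2$nuclei[hit[joins]] +
          as.integer(grp[joins, "n"])
      pop$agents <- ag2
      if (any(!joins))
        pop <- new_agents(pop, "OCL", gvi[!joins], d,
                          nuclei = as.integer(grp[!joins, "n"]),
                          origin = "morph",
                          rank_occ = grp[!joins, "occ"] / grp[!joins, "n"])
    } else if (any(died)) {
      pop$agents <- ag[-morph_rows[died], ]
    } else pop$agents <- ag
  } else pop$agents <- ag
  attr(pop, "fusion_events") <- ev
  attr(pop, "fused_ids") <- if (exists("fused_ids")) fused_ids else integer(0)
  pop
}

#' Chemotactic motility step
#'
#' Marrow-resident motile cells (osteomorphs, MSCs, HSCs) take lattice steps
#' biased up the local free-RANKL gradient. The per-substep move probability
#' is set so the ensemble mean drift along a linear gradient equals the
#' configured speed (default 14.4 um/day); with a flat field the move
#' direction is uniform over admissible marrow neighbors, giving zero mean
#' drift. Cells never enter bone voxels.
#'
#' @param pop a [cell_population()].
#' @param fields a [cytokine_field()].
#' @param dt timestep in days.
#' @param tissue the current [tissue_state()].
#' @param params a [rate_params()] (uses `speed_um_day`).
#' @return The updated population.
#' @export
step_motility <- function(pop, fields, dt, tissue, params = rate_params()) {
  ag <- pop$agents
  d <- dim(tissue$osteoid)
  marrow <- marrow_mask(tissue)
  conc <- fields$conc$RANKL
  rows <- which(ag$type %in% cell_types_marrow)
  if (length(rows) == 0L) return(pop)
  h <- tissue$spacing
  n_sub <- max(1L, ceiling(params$speed_um_day * dt / h))
  p_step <- params$speed_um_day * dt / (h * n_sub)
  for (s in seq_len(n_sub)) {
    vi <- vox_index(ag$i[rows], ag$j[rows], ag$k[rows], d)
    nb <- face_neighbors(vi, d)
    valid <- !is.na(nb) & matrix(marrow[ifelse(is.na(nb), 1L, nb)],
                                 nrow(nb), ncol(nb))
    cn <- matrix(-Inf, nrow(nb), ncol(nb))
    cn[valid] <- conc[nb[valid]]
    own <- conc[vi]
    best <- max.col(cn, ties.method = "random")
    bix <- cbind(seq_along(rows), best)
    best_val <- cn[bix]
    # biased: uphill neighbor if strictly better, else a uniform marrow move
    uphill <- is.finite(best_val) & best_val > own + 1e-12
    tgt <- rep(NA_integer_, length(rows))
    tgt[uphill] <- nb[bix][uphill]
    flat <- !uphill & rowSums(valid) > 0L
    if (any(flat)) {
      rnd <- cn
      rnd[] <- -Inf
      rnd[valid] <- runif(sum(valid))
      pickcol <- max.col(rnd, ties.method = "first")
      tgt[flat] <- nb[cbind(seq_along(rows), pickcol)][flat]
    }
    move <- !is.na(tgt) & runif(length(rows)) < p_step
    if (any(move)) {
      co <- vox_coords(tgt[move], d)
      ag$i[rows[move]] <- co[, 1L]
      ag$j[rows[move]] <- co[, 2L]
      ag$k[rows[move]] <- co[, 3L]
    }
  }
  pop$agents <- ag
  pop
}

#' Resorption and formation step
#'
#' Each osteoclast removes osteoid (and the mineral within it) from its
#' surface voxel at `resorb_rate * nuclei / 5` voxel fractions per day,
#' releasing TGF-beta into that voxel in proportion to the mineral actually
#' resorbed; each osteoblast deposits osteoid into an adjacent marrow voxel
#' at `form_rate` voxel fractions per day. Resorption cannot drive fractions
#' below 0 and formation cannot exceed osteoid 1.
#'
#' @param pop a [cell_population()].
#' @param tissue a [tissue_state()].
#' @param fields a [cytokine_field()].
#' @param params a calibrated [rate_params()] (`tgf_release` in pM per voxel
#'   fraction of resorbed mineral).
#' @param dt timestep in days.
#' @return `list(tissue, fields, resorbed, formed)` with volumes in voxel
#'   units (multiply by voxel volume for um^3).
#' @export
step_resorption_formation <- function(pop, tissue, fields, params, dt) {
  ag <- pop$agents
  d <- dim(tissue$osteoid)
  osteoid <- tissue$osteoid
  mineral <- tissue$mineral
  resorbed <- 0
  formed <- 0
  ocl <- ag[ag$type == "OCL", ]
  if (nrow(ocl) > 0L) {
    vi <- vox_index(ocl$i, ocl$j, ocl$k, d)
    amt <- rowsum(params$resorb_rate * ocl$nuclei / 5 * dt, group = vi)
    v <- as.integer(rownames(amt))
    old_ost <- osteoid[v]
    old_min <- mineral[v]
    new_ost <- pmax(old_ost - amt[, 1L], 0)
    # a voxel eroded below the bone threshold is cleared outright: the
    # osteoclast finishes it rather than stranding sub-threshold tissue
    new_ost[new_ost < tissue$bone_threshold] <- 0
    new_min <- pmin(old_min, new_ost)
    osteoid[v] <- new_ost
    mineral[v] <- new_min
    resorbed <- sum(old_ost - new_ost)
    tr <- params$tgf_release
    if (is.null(tr) || is.na(tr)) tr <- 0
    rel <- (old_min - new_min) * tr
    if (any(rel > 0)) {
      tg <- fields$conc$TGFb
      tg[v] <- tg[v] + rel
      fields$conc$TGFb <- tg
    }
  }
  obl <- ag[ag$type == "OBL", ]
  if (nrow(obl) > 0L) {
    vi <- vox_index(obl$i, obl$j, obl$k, d)
    nb <- face_neighbors(vi, d)
    room <- matrix(FALSE, nrow(nb), ncol(nb))
    ok <- !is.na(nb)
    room[ok] <- osteoid[nb[ok]] < 1
    # deposit into one admissible neighbor (the fullest, to finish voxels)
    nbo <- matrix(-Inf, nrow(nb), ncol(nb))
    nbo[room] <- osteoid[nb[room]]
    best <- max.col(nbo, ties.method = "first")
    tgt <- nb[cbind(seq_len(nrow(nb)), best)]
    has <- is.finite(nbo[cbind(seq_len(nrow(nb)), best)])
    if (any(has)) {
      amt <- rowsum(rep(params$form_rate * dt, sum(has)), group = tgt[has])
      v <- as.integer(rownames(amt))
      old <- osteoid[v]
      new <- pmin(old + amt[, 1L], 1)
      osteoid[v] <- new
      formed <- sum(new - old)
    }
  }
  tissue$osteoid <- osteoid
  tissue$mineral <- mineral
  list(tissue = tissue, fields = fields, resorbed = resorbed, formed = formed)
}

#' Re-assert placement invariants after tissue change
#'
#' Surface cells whose voxel stopped being surface move to an adjacent
#' surface voxel (or are removed if none exists); marrow cells engulfed by
#' bone move to an adjacent marrow voxel; osteocytes whose voxel was resorbed
#' die. Returns the corrected population.
#'
#' @param pop a [cell_population()].
#' @param tissue the updated [tissue_state()].
#' @return The corrected population.
#' @export
relocate_cells <- function(pop, tissue) {
  ag <- pop$agents
  d <- dim(tissue$osteoid)
  bone <- bone_mask(tissue)
  surf <- extract_surface(tissue)
  marrow <- !bone
  vi <- vox_index(ag$i, ag$j, ag$k, d)
  fix_to <- function(rows, mask) {
    if (length(rows) == 0L) return(integer(0))
    nb <- face_neighbors(vi[rows], d)
    okm <- !is.na(nb) & matrix(mask[ifelse(is.na(nb), 1L, nb)],
                               nrow(nb), ncol(nb))
    vapply(seq_along(rows), function(r) {
      ok <- which(okm[r, ])
      if (length(ok) == 0L) return(NA_integer_)
      nb[r, ok[sample.int(length(ok), 1L)]]
    }, integer(1))
  }
  drop <- logical(nrow(ag))
  bad_surf <- which(ag$type %in% cell_types_surface & !surf[vi])
  if (length(bad_surf)) {
    tgt <- fix_to(bad_surf, surf)
    ok <- !is.na(tgt)
    if (any(ok)) {
      co <- vox_coords(tgt[ok], d)
      ag$i[bad_surf[ok]] <- co[, 1L]
      ag$j[bad_surf[ok]] <- co[, 2L]
      ag$k[bad_surf[ok]] <- co[, 3L]
    }
    drop[bad_surf[!ok]] <- TRUE
  }
  bad_marrow <- which(ag$type %in% cell_types_marrow & !marrow[vi])
  if (length(bad_marrow)) {
    tgt <- fix_to(bad_marrow, marrow)
    ok <- !is.na(tgt)
    if (any(ok)) {
      co <- vox_coords(tgt[ok], d)
      ag$i[bad_marrow[ok]] <- co[, 1L]
      ag$j[bad_marrow[ok]] <- co[, 2L]
      ag$k[bad_marrow[ok]] <- co[, 3L]
    }
    drop[bad_marrow[!ok]] <- TRUE
  }
  drop[ag$type == "OCY" & !bone[vi]] <- TRUE
  pop$agents <- ag[!drop, ]
  pop
}

#' Check agent placement invariants
#'
#' Surface cells (osteoclasts, osteoblasts, lining cells, surface
#' preosteoclasts) must occupy bone-surface voxels, marrow cells (HSC, MSC,
#' osteomorphs) marrow voxels, and osteocytes bone voxels.
#'
#' @param pop a [cell_population()].
#' @param tissue the [tissue_state()] the population lives on.
#' @return `TRUE` if all invariants hold, else `FALSE` (with a message).
#' @export
check_placement <- function(pop, tissue) {
  ag <- pop$agents
  d <- dim(tissue$osteoid)
  vi <- vox_index(ag$i, ag$j, ag$k, d)
  surf <- extract_surface(tissue)
  bone <- bone_mask(tissue)
  bad <- (ag$type %in% cell_types_surface & !surf[vi]) |
    (ag$type %in% cell_types_marrow & bone[vi]) |
    (ag$type == "OCY" & !bone[vi])
  if (any(bad)) {
    message(sum(bad), " agents violate placement invariants")
    return(FALSE)
  }
  TRUE
}

#' Audit homeostatic rate limits
#'
#' Daily relative changes in cell counts are limited to a physiologic maximum
#' at baseline signaling levels (default 5%/day). This audits a recorded
#' count history against the limit.
#'
#' @param history a `data.frame` with columns `time_days`, `type`, `count`.
#' @param limit maximum |daily relative change| (fraction/day).
#' @return A `data.frame` of violations: `type`, `time_days`, `rel_change`.
#' @export
audit_rate_limits <- function(history, limit = 0.05) {
  history <- data.table::as.data.table(history)
  if (length(unique(history$time_days)) < 2L)
    stop("need at least 2 days of history")
  data.table::setorder(history, type, time_days)
  rel <- history[, {
    dtv <- diff(time_days)
    rc <- diff(count) / pmax(head(count, -1L), 1) / dtv
    list(time_days = tail(time_days, -1L), rel_change = rc)
  }, by = "type"]
  as.data.frame(rel[abs(rel$rel_change) > limit, ])
}
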