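#' Default signaling-species parameters
#'
#' Initial marrow concentrations follow the clinical initialization table of
#' the model (RANKL 0.6 pM, OPG 12.3 pM, RANKL-OPG 400 pM, sclerostin 50 pM,
#' TGF-beta 200 pM, estrogen 27.5 pM; denosumab and its complex start at 0).
#' Diffusivities are effective (binding-retarded) marrow diffusivities chosen
#' so a day-scale explicit stencil is stable at 14 um voxels; decay rates give
#' a 26-day denosumab half-life and order-day half-lives for the free
#' cytokines, with the long-lived RANKL-OPG buffer decaying slowly. Estrogen
#' is held constant (postmenopausal steady state): no diffusion, no decay.
#' Molecular weights convert the ng/mL literature reference levels to pM
#' (RANKL 20 kDa, so 100 ng/mL = 5000 pM).
#'
#' @return A `data.frame` with one row per species: `species`, `D` (um^2/day),
#'   `lambda` (1/day), `init_pM`, `mw_kDa`, `marrow_only`.
#' @export
species_defaults <- function() {
  data.frame(
    species = c("RANKL", "OPG", "RANKL_OPG", "sclerostin", "TGFb",
                "estrogen", "denosumab", "RANKL_dmab"),
    D = c(30, 30, 30, 30, 30, 0, 30, 30),
    lambda = c(log(2) / 1, 0.35, 0.01, 0.35, 0.10, 0, log(2) / 26, log(2) / 26),
    init_pM = c(0.6, 12.3, 400, 50, 200, 27.5, 0, 0),
    mw_kDa = c(20, 60, 420, 22, 25, 0.272, 150, 170),
    marrow_only = FALSE,
    stringsAsFactors = FALSE)
}

#' Convert a mass concentration to molar
#'
#' @param ng_ml concentration in ng/mL.
#' @param mw_kDa molecular weight in kDa.
#' @return Concentration in pM.
#' @export
ng_ml_to_pM <- function(ng_ml, mw_kDa) ng_ml * 1000 / mw_kDa

#' Cytokine concentration fields
#'
#' Per-voxel concentrations (pM) of the eight signaling species on the same
#' lattice as the tissue. The two complexes (RANKL-OPG, RANKL-denosumab)
#' carry no signaling activity; they are reversible binding sinks buffering
#' free RANKL.
#'
#' @param tissue a [tissue_state()] providing dims and the marrow mask.
#' @param params species parameter table as from [species_defaults()].
#' @return An object of class `cytokine_field`: list with `conc` (named list
#'   of 3D arrays), `params`, `spacing`, and the current `marrow` mask.
#' @export
cytokine_field <- function(tissue, params = species_defaults()) {
  d <- dim(tissue$osteoid)
  conc <- lapply(seq_len(nrow(params)),
                 function(r) array(params$init_pM[r], d))
  names(conc) <- params$species
  structure(list(conc = conc, params = params, spacing = tissue$spacing,
                 marrow = marrow_mask(tissue)),
            class = "cytokine_field")
}

#' @export
print.cytokine_field <- function(x, ...) {
  m <- vapply(x$conc, mean, numeric(1))
  cat("cytokine_field (mean pM): ",
      paste(sprintf("%s=%.3g", names(m), m), collapse = ", "), "\n")
  invisible(x)
}

#' Mean concentration over the marrow
#'
#' The marrow average is the in-silico analogue of a serum level; the
#' population-level effect terms of the cell balance equations are evaluated
#' at these averages.
#'
#' @param field a [cytokine_field()].
#' @param species species name(s); default all.
#' @return Named numeric vector of marrow means in pM.
#' @export
marrow_means <- function(field, species = names(field$conc)) {
  vapply(species, function(s) mean(field$conc[[s]][field$marrow]), numeric(1))
}

#' Diffusion and decay step
#'
#' Explicit 7-point stencil with zero-flux (Neumann) boundaries at the domain
#' faces, followed by exact exponential decay `exp(-lambda dt)`. Species
#' flagged `marrow_only` also see zero flux at the bone interface. The
#' explicit scheme requires `dt <= h^2 / (6 D)`; a violating call errors and
#' asks for sub-stepping (see [cytokine_substeps()]).
#'
#' @param field a [cytokine_field()].
#' @param dt timestep in days.
#' @return The updated field.
#' @export
diffuse_decay_step <- function(field, dt) {
  if (dt <= 0) stop("dt must be positive")
  h2 <- field$spacing^2
  for (r in seq_len(nrow(field$params))) {
    D <- field$params$D[r]
    lam <- field$params$lambda[r]
    sp <- field$params$species[r]
    if (D > 0) {
      if (dt > h2 / (6 * D) + 1e-12)
        stop(sprintf(paste0("explicit diffusion unstable for %s: dt = %.3g d ",
                            "exceeds h^2/(6 D) = %.3g d; sub-step with ",
                            "cytokine_substeps()"), sp, dt, h2 / (6 * D)))
      a <- field$conc[[sp]]
      kap <- D * dt / h2
      if (field$params$marrow_only[r]) {
        m <- field$marrow
        acc <- array(0, dim(a))
        for (axis in 1:3) for (by in c(-1L, 1L)) {
          allow <- m & shift3d(m, axis, by)
          acc <- acc + (shift3d(a, axis, by) - a) * allow
        }
        a <- a + kap * acc
      } else {
        acc <- -6 * a
        for (axis in 1:3) for (by in c(-1L, 1L))
          acc <- acc + shift3d(a, axis, by)
        a <- a + kap * acc
      }
      field$conc[[sp]] <- a
    }
    if (lam > 0) field$conc[[sp]] <- field$conc[[sp]] * exp(-lam * dt)
  }
  field
}

#' Number of diffusion sub-steps needed for stability
#'
#' @param field a [cytokine_field()].
#' @param dt the outer timestep in days.
#' @return Integer sub-step count such that `dt / n` satisfies the explicit
#'   stability bound for the fastest-diffusing species.
#' @export
cytokine_substeps <- function(field, dt) {
  dmax <- max(field$params$D)
  if (dmax <= 0) return(1L)
  max(1L, as.integer(ceiling(dt / (field$spacing^2 / (6 * dmax)) - 1e-9)))
}

#' Binding kinetics parameters
#'
#' Mass-action rate constants for the two reversible reactions
#' `RANKL + OPG <-> RANKL-OPG` and `RANKL + denosumab <-> RANKL-denosumab`,
#' plus the RANK receptor on/off rates shared (identically, by construction)
#' by osteoclasts and osteomorphs. The RANKL-OPG dissociation constant is
#' chosen so the initial concentration table is a chemical equilibrium
#' (Kd = 0.6 * 12.3 / 400 pM); the denosumab off-rate is deliberately high
#' (Kd 10 pM) so free RANKL recovers as the antibody decays after the final
#' injection.
#'
#' @param kon_RO,koff_RO RANKL+OPG on (1/pM/day) and off (1/day) rates.
#' @param kon_RD,koff_RD RANKL+denosumab rates.
#' @param kon_RANK,koff_RANK RANK receptor rates (same for osteoclasts and
#'   osteomorphs); the 50 pM dissociation constant keeps occupancy responsive
#'   at the locally elevated near-surface RANKL levels.
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(kon_RO = 1, koff_RO = 0.6 * 12.3 / 400,
                           kon_RD = 0.02, koff_RD = 0.2,
                           kon_RANK = 0.1, koff_RANK = 5) {
  p <- list(kon_RO = kon_RO, koff_RO = koff_RO, kon_RD = kon_RD,
            koff_RD = koff_RD, kon_RANK = kon_RANK, koff_RANK = koff_RANK)
  if (any(unlist(p) < 0)) stop("binding rates must be nonnegative")
  structure(p, class = "binding_params")
}

# Backward-Euler reaction extent for A + B <-> C over dt: solves
# x = dt * (kon (A - x)(B - x) - koff (C + x)) per voxel (the stable root of
# the quadratic), which is unconditionally stable for the stiff binding
# kinetics and moves a single extent, conserving A + C and B + C exactly.
bind_extent_be <- function(A, B, C, kon, koff, dt) {
  a <- kon * dt
  b <- -(1 + a * (A + B) + koff * dt)
  cc <- dt * (kon * A * B - koff * C)
  disc <- pmax(b * b - 4 * a * cc, 0)
  x <- 2 * cc / (-b + sqrt(disc)) # stable smaller root, cancellation-free
  pmax(pmin(x, A, B), -C)
}

#' Reversible binding step
#'
#' Advances the two complexation reactions by mass action,
#' `d[C]/dt = kon [A][B] - koff [C]`, using an implicit (backward-Euler)
#' reaction-extent update per voxel: unconditionally stable for stiff
#' on-rates, nonnegativity-preserving, and exactly conservative for the
#' three totals (total RANKL, total OPG, total denosumab) since each channel
#' moves a single extent.
#'
#' @param field a [cytokine_field()].
#' @param params a [binding_params()].
#' @param dt timestep in days.
#' @return The updated field.
#' @export
react_bind_step <- function(field, params, dt) {
  cc <- field$conc
  if (min(cc$RANKL, cc$OPG, cc$RANKL_OPG, cc$denosumab, cc$RANKL_dmab) < 0)
    stop("negative concentration on input to react_bind_step")
  R <- cc$RANKL; O <- cc$OPG; C1 <- cc$RANKL_OPG
  Dm <- cc$denosumab; C2 <- cc$RANKL_dmab
  # two implicit half-steps per channel, alternated, to reduce splitting bias
  for (s in 1:2) {
    d1 <- bind_extent_be(R, O, C1, params$kon_RO, params$koff_RO, dt / 2)
    R <- R - d1; O <- O - d1; C1 <- C1 + d1
    d2 <- bind_extent_be(R, Dm, C2, params$kon_RD, params$koff_RD, dt / 2)
    R <- R - d2; Dm <- Dm - d2; C2 <- C2 + d2
  }
  field$conc$RANKL <- R; field$conc$OPG <- O; field$conc$RANKL_OPG <- C1
  field$conc$denosumab <- Dm; field$conc$RANKL_dmab <- C2
  field
}

#' Dosing schedule
#'
#' Subcutaneous injections mapped to a uniform marrow concentration pulse.
#' The default peak corresponds to the 60 mg dose; the pulse is scaled
#' linearly in the dose. The default peak suppresses free RANKL by more than
#' 95% within days of an injection. A placebo arm is the empty schedule.
#'
#' @param times_days injection times in days, strictly increasing.
#' @param dose_mg dose per injection (mg).
#' @param peak_pM marrow concentration pulse for a 60 mg dose.
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(times_days = numeric(0), dose_mg = 60,
                          peak_pM = 40000) {
  if (length(times_days) > 1 && any(diff(times_days) <= 0))
    stop("injection times must be strictly increasing")
  structure(list(times = times_days, dose_mg = dose_mg, peak_pM = peak_pM),
            class = "dose_schedule")
}

#' Apply scheduled doses
#'
#' Adds the dose-derived denosumab pulse uniformly to marrow voxels for every
#' injection time in the half-open interval `[t - dt, t)` (so an injection at
#' day 0 lands in the first simulated day).
#'
#' @param field a [cytokine_field()].
#' @param schedule a [dose_schedule()].
#' @param t current time in days.
#' @param dt length of the elapsed interval.
#' @return The updated field.
#' @export
apply_dose <- function(field, schedule, t, dt = 1) {
  hits <- sum(schedule$times >= t - dt & schedule$times < t)
  if (hits > 0) {
    pulse <- hits * schedule$peak_pM * schedule$dose_mg / 60
    dmab <- field$conc$denosumab
    dmab[field$marrow] <- dmab[field$marrow] + pulse
    field$conc$denosumab <- dmab
  }
  field
}

#' RANK receptor occupancy dynamics
#'
#' `do/dt = kon L (1 - o) - koff o`, integrated exactly over `dt` for a
#' constant local ligand concentration `L`. The same rate constants apply to
#' osteoclasts and osteomorphs.
#'
#' @param occupancy current occupancy fraction(s) in `[0, 1]`.
#' @param local_conc local free RANKL concentration(s), pM.
#' @param params a [binding_params()] (uses `kon_RANK`, `koff_RANK`).
#' @param dt timestep in days.
#' @return Updated occupancy in `[0, 1]`.
#' @export
update_occupancy <- function(occupancy, local_conc, params, dt) {
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy must lie in [0, 1]")
  rate <- params$kon_RANK * local_conc + params$koff_RANK
  o_inf <- ifelse(rate > 0, params$kon_RANK * local_conc / rate, occupancy)
  pmin(pmax(o_inf + (occupancy - o_inf) * exp(-rate * dt), 0), 1)
}

#' RANKL consumption by RANK-bearing cells
#'
#' Osteoclast-lineage cells sequester RANKL through receptor binding and
#' internalization. The removal is proportional to the binding flux,
#' `c_int * (1 - occupancy) * [RANKL]` per cell and day, applied as an exact
#' exponential sink per voxel, so it self-limits as local RANKL depletes.
#' This is the negative feedback that keeps the surface osteoclast pool
#' self-limiting: crowding depletes local free RANKL, which lowers occupancy
#' and with it fusion and differentiation.
#'
#' @param field a [cytokine_field()].
#' @param pop a `cell_population`.
#' @param c_int per-cell binding-consumption coefficient (1/day at zero
#'   occupancy).
#' @param dt timestep in days.
#' @return The updated field.
#' @export
consume_rankl <- function(field, pop, c_int, dt) {
  if (is.null(c_int) || !is.finite(c_int) || c_int <= 0) return(field)
  ag <- pop$agents
  # osteoclasts and osteomorphs carry high RANK numbers and dominate the
  # sink; precursor pools are excluded so their size cannot feed back on
  # the ligand level
  rows <- ag$type %in% c("OCL", "osteomorph")
  if (!any(rows)) return(field)
  d <- dim(field$conc$RANKL)
  vi <- vox_index(ag$i[rows], ag$j[rows], ag$k[rows], d)
  rate <- rowsum(c_int * (1 - ag$rank_occ[rows]), group = vi)
  v <- as.integer(rownames(rate))
  R <- field$conc$RANKL
  R[v] <- R[v] * exp(-rate[, 1L] * dt)
  field$conc$RANKL <- R
  field
}

#' Hill response of osteocytes to effective strain
#'
#' Low-strain response (drives RANKL and sclerostin production) is a
#' decreasing Hill curve of the local effective strain; the high-strain
#' response (drives OPG) is its complement. The midpoint sits at the
#' physiologic strain peak (2500 microstrain), between the resorption
#' (200 microstrain) and overload (4000 microstrain) thresholds, so a strain
#' histogram whose mode is at the physiologic peak puts most osteocytes near
#' the inflection point.
#'
#' @param eps_eff effective strain (dimensionless, i.e. strain fraction).
#' @param eps50 midpoint in microstrain.
#' @param n_hill Hill exponent.
#' @return Response in `[0, 1]`.
#' @export
strain_response_low <- function(eps_eff, eps50 = 2500, n_hill = 3) {
  ue <- pmax(eps_eff * 1e6, 0)
  eps50^n_hill / (eps50^n_hill + ue^n_hill)
}

#' @rdname strain_response_low
#' @export
strain_response_high <- function(eps_eff, eps50 = 2500, n_hill = 3) {
  1 - strain_response_low(eps_eff, eps50, n_hill)
}

#' Strain-driven cytokine production by osteocytes
#'
#' Each osteocyte deposits RANKL and sclerostin at its own voxel in
#' proportion to the low-strain Hill response, and OPG in proportion to the
#' high-strain response. With the mechanostat disabled
#' (`strain_sensitive = FALSE`) both responses are frozen at their midpoint
#' (baseline) value, making production insensitive to strain.
#'
#' @param field a [cytokine_field()].
#' @param cells a `cell_population` (only `OCY` rows produce).
#' @param strain a `strain_field`; `NA` strains (e.g. freshly formed voxels
#'   not yet re-solved) are treated as the midpoint strain.
#' @param dt timestep in days.
#' @param rates list of per-osteocyte production rates in pM/day at full
#'   response: `p_RANKL`, `p_SOST`, `p_OPG`.
#' @param strain_sensitive mechanostat toggle.
#' @param eps50,n_hill Hill parameters, see [strain_response_low()].
#' @return The updated field.
#' @export
strain_production_step <- function(field, cells, strain, dt, rates,
                                   strain_sensitive = TRUE,
                                   eps50 = 2500, n_hill = 3) {
  ocy <- cells$agents[cells$agents$type == "OCY", ]
  if (nrow(ocy) == 0L) return(field)
  d <- dim(field$conc$RANKL)
  vi <- vox_index(ocy$i, ocy$j, ocy$k, d)
  eps <- unclass(strain)[vi]
  eps[is.na(eps)] <- eps50 * 1e-6
  if (strain_sensitive) {
    lo <- strain_response_low(eps, eps50, n_hill)
    hi <- strain_response_high(eps, eps50, n_hill)
  } else {
    lo <- rep(0.5, length(eps))
    hi <- rep(0.5, length(eps))
  }
  add <- function(a, where, amount) {
    s <- rowsum(amount, group = where)
    a[as.integer(rownames(s))] <- a[as.integer(rownames(s))] + s[, 1L]
    a
  }
  field$conc$RANKL <- add(field$conc$RANKL, vi, rates$p_RANKL * lo * dt)
  field$conc$sclerostin <- add(field$conc$sclerostin, vi, rates$p_SOST * lo * dt)
  field$conc$OPG <- add(field$conc$OPG, vi, rates$p_OPG * hi * dt)
  field
}
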