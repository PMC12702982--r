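# Shared fixtures built in code: small phantoms and solid blocks reused
# across test files (cached per session).

solid_block <- function(n = 6, spacing = 14) {
  vol <- array(1, c(n, n, n))
  tissue_state(vol, vol, spacing = spacing)
}

small_phantom <- local({
  cache <- new.env()
  function(dims = 32, seed = 1, target_bvtv = 0.131, archetype_mix = 0.7) {
    key <- paste(dims, seed, target_bvtv, archetype_mix, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_phantom(phantom_spec(
        dims = dims, seed = seed, target_bvtv = target_bvtv,
        archetype_mix = archetype_mix))
    cache[[key]]
  }
})

seeded_population <- local({
  cache <- new.env()
  function(dims = 32, seed = 1) {
    key <- paste(dims, seed, sep = "_")
    if (is.null(cache[[key]])) {
      ph <- small_phantom(dims, seed)
      mat <- material_map(ph)
      lc <- scale_load_to_peak(ph, mat, load_case(0.01), 2500, rtol = 1e-5)
      strain <- attr(lc, "strain")
      part <- partition_subregions(ph, 1000)
      pop <- seed_initial_cells(ph, strain, part, "remodelling", seed = seed)
      cache[[key]] <- list(tissue = ph, strain = strain, pop = pop,
                           partition = part)
    }
    cache[[key]]
  }
})

# Synthetic factorial run table with known fixed effects.
simulate_factorial_table <- function(beta = c(A = 2, B = 3, C = 0, D = 0),
                                     sigma = 1, n_phantom = 7, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(P_A = 0:1, P_B = 0:1, P_C = 0:1, P_D = 0:1,
                      phantom = sprintf("p%02d", seq_len(n_phantom)))
  bl <- setNames(rnorm(n_phantom, 100, 10), sprintf("p%02d", seq_len(n_phantom)))
  u <- setNames(rnorm(n_phantom, 0, 2), names(bl))
  grid$BL <- bl[grid$phantom]
  grid$BMC <- with(grid, beta["A"] * P_A + beta["B"] * P_B +
                     beta["C"] * P_C + beta["D"] * P_D) +
    0.5 * grid$BL + u[grid$phantom] + rnorm(nrow(grid), 0, sigma)
  grid
}

# Dense direct-solve reference: assembles the same hexahedral stiffness into
# a dense matrix and solves with base R, independently of the CG path.
dense_fe_reference <- function(tissue, materials, applied_strain) {
  bone <- bone_mask(tissue)
  mesh <- osteosim:::fe_mesh(bone)
  h <- tissue$spacing
  K0 <- osteosim:::hex8_stiffness(h, materials$nu)
  ndof <- 3L * mesh$n_nodes
  K <- matrix(0, ndof, ndof)
  for (e in seq_len(nrow(mesh$enodes))) {
    dofs <- as.vector(rbind(3 * (mesh$enodes[e, ] - 1) + 1,
                            3 * (mesh$enodes[e, ] - 1) + 2,
                            3 * (mesh$enodes[e, ] - 1) + 3))
    Ee <- materials$E_max * tissue$mineral[mesh$elem_vox[e]]
    K[dofs, dofs] <- K[dofs, dofs] + Ee * K0
  }
  d <- dim(bone)
  fixed <- logical(ndof); ufix <- numeric(ndof)
  bottom <- which(mesh$node_k == 1L); top <- which(mesh$node_k == d[3] + 1L)
  fixed[3 * (bottom - 1) + 3] <- TRUE
  fixed[3 * (top - 1) + 3] <- TRUE
  ufix[3 * (top - 1) + 3] <- -applied_strain * d[3] * h
  ci <- mean(mesh$node_i[bottom]); cj <- mean(mesh$node_j[bottom])
  a_n <- bottom[which.min((mesh$node_i[bottom] - ci)^2 +
                          (mesh$node_j[bottom] - cj)^2)]
  fixed[3 * (a_n - 1) + 1:2] <- TRUE
  same_y <- bottom[mesh$node_j[bottom] == mesh$node_j[a_n] & bottom != a_n]
  if (length(same_y) > 0) {
    b_n <- same_y[which.max(abs(mesh$node_i[same_y] - mesh$node_i[a_n]))]
    fixed[3 * (b_n - 1) + 2] <- TRUE
  }
  free <- !fixed
  u <- ufix
  u[free] <- solve(K[free, free], -K[free, fixed, drop = FALSE] %*% ufix[fixed])
  q <- vapply(seq_len(nrow(mesh$enodes)), function(e) {
    dofs <- as.vector(rbind(3 * (mesh$enodes[e, ] - 1) + 1,
                            3 * (mesh$enodes[e, ] - 1) + 2,
                            3 * (mesh$enodes[e, ] - 1) + 3))
    as.numeric(t(u[dofs]) %*% K0 %*% u[dofs])
  }, numeric(1))
  out <- array(NA_real_, d)
  out[mesh$elem_vox] <- sqrt(pmax(q, 0) / h^3)
  out
}

# One cached 2-year-treatment / 2-year-follow-up run on the default study
# conditions (32^3 phantom, default config, seed 1); reused by the
# trajectory-shape and resurgence-attribution checks.
treatment_run <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$res)) {
      ph <- small_phantom(32, seed = 1)
      cfg <- simulation_config(treatment_months = 24, followup_months = 24,
                               seed = 1)
      cache$res <- run_simulation(cfg, ph)
    }
    cache$res
  }
})

# Time (days) for the osteoclast pool to recover half its baseline size
# under a fixed post-discontinuation RANKL level, starting from a
# drug-suppressed state with matched reservoirs.
ocl_recovery_time <- function(sp, params, keep_morphs, seed,
                              rankl = 2, max_days = 150) {
  set.seed(seed)
  target <- sum(sp$pop$agents$type == "OCL") / 2
  pop <- sp$pop
  ag <- pop$agents[pop$agents$type != "OCL", ]
  if (!keep_morphs) ag <- ag[ag$type != "osteomorph", ]
  ag$rank_occ <- 0.02
  pop$agents <- ag
  f <- cytokine_field(sp$tissue)
  f$conc$RANKL[] <- rankl
  d <- dim(sp$tissue$osteoid)
  for (day in seq_len(max_days)) {
    ag <- pop$agents
    vi <- vox_index(ag$i, ag$j, ag$k, d)
    ag$rank_occ <- update_occupancy(ag$rank_occ, f$conc$RANKL[vi],
                                    binding_params(), 1)
    pop$agents <- ag
    pop <- step_differentiation(pop, f, sp$strain, params,
                                hypothesis_flags(recycling = keep_morphs),
                                1, sp$tissue)
    if (keep_morphs) pop <- step_fission_fusion(pop, f, params, 1, sp$tissue)
    pop <- step_motility(pop, f, 1, sp$tissue, params)
    if (sum(pop$agents$type == "OCL") >= target) return(day)
  }
  Inf
}
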