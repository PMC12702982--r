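#' Material map for the micro-FE stage
#'
#' Per-voxel Young's modulus assuming a linear correlation between local
#' mineral density and stiffness: `E = E_max * mineral`. Marrow voxels carry
#' no elements.
#'
#' @param tissue a [tissue_state()].
#' @param E_max modulus of fully mineralized tissue in MPa (default 10 GPa).
#' @param nu Poisson ratio (global).
#' @return An object of class `material_map`.
#' @export
material_map <- function(tissue, E_max = 10000, nu = 0.3) {
  stopifnot(E_max > 0, nu > -1, nu < 0.5)
  structure(list(E_max = E_max, nu = nu), class = "material_map")
}

#' Uniaxial load case
#'
#' Displacement-controlled compression along z: bottom surface held at zero
#' axial displacement, top surface moved down uniformly, lateral surfaces
#' traction-free (in-plane rigid modes removed by two point constraints, which
#' leave a uniform uniaxial stress state unconstrained). Force control is
#' realized by a displacement solve followed by linear rescaling.
#'
#' @param magnitude applied compressive strain (fraction, e.g. 0.01) for
#'   displacement control, or total axial force in N for force control.
#' @param mode `"displacement"` or `"force"`.
#' @return An object of class `load_case`.
#' @export
load_case <- function(magnitude = 0.01, mode = c("displacement", "force")) {
  mode <- match.arg(mode)
  if (magnitude <= 0) stop("load magnitude must be positive")
  structure(list(mode = mode, axis = "z", magnitude = magnitude),
            class = "load_case")
}

# 24x24 stiffness of an 8-node cubic hexahedron of side h for unit Young's
# modulus (isotropic, Poisson nu), trilinear shape functions, 2x2x2 Gauss
# quadrature. Node order follows the grid-offset order used by the mesher:
# (0,0,0) (1,0,0) (0,1,0) (1,1,0) (0,0,1) (1,0,1) (0,1,1) (1,1,1).
hex8_stiffness <- function(h, nu) {
  offs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))[, c(1, 2, 3)]
  # expand.grid varies the first column fastest, matching the mesher order
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  gp <- 1 / sqrt(3)
  K <- matrix(0, 24, 24)
  for (gx in c(-gp, gp)) for (gy in c(-gp, gp)) for (gz in c(-gp, gp)) {
    xi <- c(gx, gy, gz)
    dN <- matrix(0, 8, 3) # dN_a/dx_i, physical
    for (a in 1:8) {
      s <- offs[a, ]
      dN[a, 1] <- s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]) / 8 * 2 / h
      dN[a, 2] <- (1 + s[1] * xi[1]) * s[2] * (1 + s[3] * xi[3]) / 8 * 2 / h
      dN[a, 3] <- (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) * s[3] / 8 * 2 / h
    }
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dN[a, 1]
      B[2, c0 + 2] <- dN[a, 2]
      B[3, c0 + 3] <- dN[a, 3]
      B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
      B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
      B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
    }
    K <- K + t(B) %*% D %*% B * (h / 2)^3
  }
  K
}

# Build the voxel mesh: element -> 8 compact node ids, node grid coordinates.
fe_mesh <- function(bone) {
  d <- dim(bone)
  ev <- which(bone)
  if (length(ev) == 0L) stop("no bone voxels to mesh")
  co <- vox_coords(ev, d)
  gdim <- d + 1L
  gidx <- function(i, j, k) i + (j - 1L) * gdim[1] + (k - 1L) * gdim[1] * gdim[2]
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  enode_grid <- matrix(0L, nrow = length(ev), ncol = 8L)
  for (a in 1:8) {
    enode_grid[, a] <- gidx(co[, 1] + offs[a, 1], co[, 2] + offs[a, 2],
                            co[, 3] + offs[a, 3])
  }
  nodes <- sort(unique(as.vector(enode_grid)))
  comp <- match(enode_grid, nodes)
  dim(comp) <- dim(enode_grid)
  k_layer <- ((nodes - 1L) %/% (gdim[1] * gdim[2])) + 1L
  rem <- (nodes - 1L) %% (gdim[1] * gdim[2])
  list(elem_vox = ev, enodes = comp, n_nodes = length(nodes),
       node_i = (rem %% gdim[1]) + 1L, node_j = (rem %/% gdim[1]) + 1L,
       node_k = k_layer, gdim = gdim, node_grid_id = nodes)
}

#' Solve the voxel micro-FE problem
#'
#' One trilinear hexahedral element per bone voxel, Young's modulus scaled by
#' the voxel mineral fraction, Jacobi-preconditioned conjugate gradients on
#' the element-by-element operator. The effective strain per element is the
#' strain-energy-density equivalent strain `eps_eff = sqrt(2 U / E)`.
#'
#' @param tissue a [tissue_state()].
#' @param materials a [material_map()].
#' @param load a [load_case()].
#' @param rtol relative residual tolerance of the solver.
#' @param maxit iteration cap; exceeding it raises an error.
#' @param warm_start optional displacement vector from a previous solve on a
#'   similar structure, named by grid node id (as returned in the result).
#' @return A `strain_field`: 3D array of effective strain (dimensionless) on
#'   bone voxels, `NA` elsewhere, with attributes `applied_strain`,
#'   `total_force` (N, reaction on the loaded face), `strain_energy`
#'   (N * um), `iters`, `relres`, and `displacement` for warm starts.
#' @export
solve_microfe <- function(tissue, materials, load, rtol = 1e-8, maxit = 20000,
                          warm_start = NULL) {
  bone <- bone_mask(tissue)
  d <- dim(bone)
  if (!spans_loading_axis(bone))
    stop("no load path: bone phase does not connect bottom and top faces")
  h <- tissue$spacing
  mesh <- fe_mesh(bone)
  K0 <- hex8_stiffness(h, materials$nu)
  Evec <- materials$E_max * tissue$mineral[mesh$elem_vox]
  Evec[Evec <= 0] <- materials$E_max * 1e-6
  ndof <- 3L * mesh$n_nodes
  edof <- matrix(0L, 24L, ncol = nrow(mesh$enodes))
  for (a in 1:8) {
    base <- 3L * (mesh$enodes[, a] - 1L)
    edof[3 * a - 2, ] <- base
    edof[3 * a - 1, ] <- base + 1L
    edof[3 * a, ] <- base + 2L
  }
  nz_top <- d[3] + 1L
  applied_strain <- if (load$mode == "displacement") load$magnitude else 0.01
  Lz <- d[3] * h
  fixed <- logical(ndof)
  ufix <- numeric(ndof)
  bottom <- which(mesh$node_k == 1L)
  top <- which(mesh$node_k == nz_top)
  if (length(bottom) == 0L || length(top) == 0L)
    stop("no load path: bone does not reach both z faces")
  zdof <- function(n) 3L * (n - 1L) + 3L
  fixed[zdof(bottom)] <- TRUE; ufix[zdof(bottom)] <- 0
  fixed[zdof(top)] <- TRUE; ufix[zdof(top)] <- -applied_strain * Lz
  # pin in-plane rigid modes: node nearest the bottom-face centroid (x and y)
  # and, to kill rotation about z, the y of the farthest same-y bottom node
  ci <- mean(mesh$node_i[bottom]); cj <- mean(mesh$node_j[bottom])
  a_n <- bottom[which.min((mesh$node_i[bottom] - ci)^2 +
                          (mesh$node_j[bottom] - cj)^2)]
  fixed[3L * (a_n - 1L) + 1L] <- TRUE
  fixed[3L * (a_n - 1L) + 2L] <- TRUE
  same_y <- bottom[mesh$node_j[bottom] == mesh$node_j[a_n] & bottom != a_n]
  if (length(same_y) > 0L) {
    b_n <- same_y[which.max(abs(mesh$node_i[same_y] - mesh$node_i[a_n]))]
    fixed[3L * (b_n - 1L) + 2L] <- TRUE
  }
  x0 <- numeric(ndof)
  if (!is.null(warm_start)) {
    m <- match(mesh$node_grid_id, attr(warm_start, "node_grid_id"))
    ok <- !is.na(m)
    um <- matrix(warm_start, nrow = 3L)
    x0m <- matrix(0, nrow = 3L, ncol = mesh$n_nodes)
    x0m[, ok] <- um[, m[ok]]
    x0 <- as.numeric(x0m)
  }
  sol <- cpp_fe_solve(edof, Evec, K0, ndof, fixed, ufix, x0, rtol,
                      as.integer(maxit))
  if (sol$relres > rtol * 10)
    stop(sprintf(paste0("micro-FE solver did not converge (relres %.2e after ",
                        "%d iterations); the system may be near-singular"),
                 sol$relres, sol$iters))
  u <- sol$u
  q <- cpp_fe_element_energy(edof, K0, u) # u' K0 u per element
  eps_eff <- sqrt(pmax(q, 0) / h^3)
  # reaction force on the loaded face: E in MPa, lengths in um -> force in uN
  react <- fe_reactions(edof, Evec, K0, u, ndof)
  total_force <- -sum(react[zdof(top)]) * 1e-6 # MPa*um^2 -> N
  strain_energy <- 0.5 * sum(u * react) * 1e-6 # N*um
  scale <- 1
  u_warm <- u # unscaled displacement: the right warm start for re-solves
  if (load$mode == "force") {
    if (total_force <= 0) stop("zero reaction force; singular load case")
    scale <- load$magnitude / total_force
    u <- u * scale
    eps_eff <- eps_eff * scale
    total_force <- load$magnitude
    strain_energy <- strain_energy * scale^2
    applied_strain <- applied_strain * scale
  }
  out <- array(NA_real_, d)
  out[mesh$elem_vox] <- eps_eff
  structure(out, class = "strain_field", applied_strain = applied_strain,
            total_force = total_force, strain_energy = strain_energy,
            iters = sol$iters, relres = sol$relres,
            displacement = structure(u_warm, node_grid_id = mesh$node_grid_id))
}

# Nodal forces f = A u = sum_e E_e K0 u_e scattered to global dofs.
fe_reactions <- function(edof, Evec, K0, u, ndof) {
  ue <- matrix(u[edof + 1L], nrow = 24L)
  fe <- sweep(K0 %*% ue, 2L, Evec, `*`)
  f <- numeric(ndof)
  tab <- rowsum(as.numeric(fe), group = as.integer(edof) + 1L)
  f[as.integer(rownames(tab))] <- tab[, 1L]
  f
}

#' Scale the load to a physiologic strain peak
#'
#' Rescales the applied load so that the mode of the effective-strain
#' histogram over bone voxels (100 microstrain bins) sits at `target_peak`
#' (default 2500 microstrain). By linearity no second solve is needed.
#'
#' @param tissue a [tissue_state()].
#' @param materials a [material_map()].
#' @param load a [load_case()].
#' @param target_peak target histogram mode in microstrain.
#' @param strain optional precomputed `strain_field` for `load`.
#' @param rtol solver tolerance when `strain` must be computed.
#' @return The scaled [load_case()], with attributes `scale` and `strain`
#'   (the rescaled strain field).
#' @export
scale_load_to_peak <- function(tissue, materials, load, target_peak = 2500,
                               strain = NULL, rtol = 1e-8) {
  if (is.null(strain)) strain <- solve_microfe(tissue, materials, load,
                                               rtol = rtol)
  eps <- strain[!is.na(strain)] * 1e6 # microstrain
  hist_mode <- function(x) {
    breaks <- seq(0, max(x) + 100, by = 100)
    counts <- tabulate(findInterval(x, breaks), nbins = length(breaks))
    breaks[which.max(counts)] + 50
  }
  if (max(eps) - min(eps) < 1e-6 * max(abs(eps))) {
    warning("degenerate strain histogram (all strains equal); scaling by mean")
    scale <- target_peak / mean(eps)
  } else {
    # iterate: re-binning after scaling can shift the modal bin by one, so
    # refine until the rescaled histogram's mode sits at the target
    scale <- 1
    for (it in 1:8) {
      m <- hist_mode(eps * scale)
      if (abs(m - target_peak) <= 50) break
      scale <- scale * target_peak / m
    }
  }
  new_load <- load
  new_load$magnitude <- load$magnitude * scale
  scaled <- strain * scale
  attributes(scaled) <- attributes(strain)
  scaled[] <- unclass(strain) * scale
  attr(scaled, "applied_strain") <- attr(strain, "applied_strain") * scale
  attr(scaled, "total_force") <- attr(strain, "total_force") * scale
  attr(scaled, "strain_energy") <- attr(strain, "strain_energy") * scale^2
  attr(new_load, "scale") <- scale
  attr(new_load, "strain") <- scaled
  new_load
}
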