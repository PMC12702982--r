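#' Voxel tissue state
#'
#' A `tissue_state` holds per-voxel mineral and osteoid volume fractions on an
#' isotropic lattice, together with the voxel spacing. Bone voxels are those
#' whose osteoid fraction is at least `bone_threshold` (default 0.5): the
#' source scans are binary, so partial voxels arise only transiently while
#' osteoclasts and osteoblasts are (re)modeling the surface. The invariant
#' `0 <= mineral <= osteoid <= 1` holds everywhere: mineral can only form
#' within deposited osteoid.
#'
#' @param mineral,osteoid 3D numeric arrays of equal dimension, values in
#'   `[0, 1]`, `mineral <= osteoid` voxel-wise.
#' @param spacing isotropic voxel spacing in micrometres.
#' @param bone_threshold osteoid fraction at or above which a voxel counts as
#'   bone.
#' @return An object of class `tissue_state`.
#' @export
tissue_state <- function(mineral, osteoid, spacing = 14,
                         bone_threshold = 0.5) {
  stopifnot(is.array(mineral), is.array(osteoid),
            identical(dim(mineral), dim(osteoid)), length(dim(mineral)) == 3L)
  if (spacing <= 0) stop("spacing must be positive")
  if (any(mineral < -1e-12) || any(osteoid > 1 + 1e-12))
    stop("mineral and osteoid fractions must lie in [0, 1]")
  if (any(mineral > osteoid + 1e-9))
    stop("mineral must not exceed osteoid in any voxel")
  structure(list(mineral = mineral, osteoid = osteoid,
                 spacing = spacing, bone_threshold = bone_threshold),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  d <- dim(x$osteoid)
  cat(sprintf("tissue_state: %d x %d x %d voxels @ %.3g um, BV/TV = %.4f\n",
              d[1], d[2], d[3], x$spacing, mean(bone_mask(x))))
  invisible(x)
}

#' @export
dim.tissue_state <- function(x) dim(x$osteoid)

#' Bone and marrow masks
#'
#' @param tissue a [tissue_state()].
#' @return Logical 3D array marking bone (resp. marrow) voxels.
#' @export
bone_mask <- function(tissue) tissue$osteoid >= tissue$bone_threshold

#' @rdname bone_mask
#' @export
marrow_mask <- function(tissue) !bone_mask(tissue)

#' Extract the bone surface
#'
#' Surface voxels are bone voxels with at least one face-adjacent
#' (6-connected) marrow voxel; domain boundaries do not count as marrow.
#' Osteoclasts, osteoblasts, preosteoclasts and lining cells reside on these
#' voxels.
#'
#' @param tissue a [tissue_state()].
#' @return Logical 3D array; `TRUE` on surface voxels.
#' @export
extract_surface <- function(tissue) {
  bone <- bone_mask(tissue)
  marrow_adjacent <- array(FALSE, dim(bone))
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    # replicate padding means shifted-in boundary values equal the edge value,
    # so faces on the domain boundary never register as marrow contact
    marrow_adjacent <- marrow_adjacent | !shift3d(bone, axis, by)
  }
  bone & marrow_adjacent
}

#' Partition the domain into near-cubic subregions
#'
#' Splits the voxel domain into `n` blocks arranged on a near-cubic grid
#' (10 x 10 x 10 for the default `n = 1000`), with per-axis block sizes
#' differing by at most one voxel. The remodeling seeding rule accepts or
#' rejects candidate cell placements per subregion.
#'
#' @param tissue a [tissue_state()].
#' @param n number of subregions (default 1000).
#' @return An object of class `subregion_partition`: list with `n_subregions`
#'   and an integer 3D array `index` assigning every voxel to one subregion.
#' @export
partition_subregions <- function(tissue, n = 1000) {
  if (n < 1) stop("n must be at least 1")
  d <- dim(tissue$osteoid)
  # factor n into a near-cubic grid of block counts
  base <- round(n^(1 / 3))
  best <- NULL
  for (a in seq_len(n)) {
    if (n %% a != 0L) next
    rest <- n / a
    for (b in seq_len(rest)) {
      if (rest %% b != 0L) next
      cc <- rest / b
      score <- max(a, b, cc) / min(a, b, cc)
      if (is.null(best) || score < best$score)
        best <- list(g = c(a, b, cc), score = score)
    }
  }
  g <- as.integer(best$g)
  if (any(g > d)) stop("n not expressible as a near-cubic grid of blocks for these dims")
  cuts <- function(len, parts) {
    bounds <- floor(seq(0, len, length.out = parts + 1))
    rep(seq_len(parts), times = diff(bounds))
  }
  ix <- cuts(d[1], g[1]); iy <- cuts(d[2], g[2]); iz <- cuts(d[3], g[3])
  index <- array(0L, d)
  index[] <- ix[slice.index(index, 1)] +
    (iy[slice.index(index, 2)] - 1L) * g[1] +
    (iz[slice.index(index, 3)] - 1L) * g[1] * g[2]
  structure(list(n_subregions = as.integer(n), grid = g, index = index),
            class = "subregion_partition")
}

# Rate constant of the primary mineralization phase: an osteoid-saturated,
# mineral-free voxel reaches 70% mineralization in 7 days.
k_min_default <- function() log(10 / 3) / 7

#' Mineralization kinetics
#'
#' New mineral forms in proportion to the gap between osteoid and mineral in
#' each voxel. The continuous-rate formulation is integrated exactly,
#' `mineral' = osteoid - (osteoid - mineral) exp(-k_min dt)`, so the
#' one-week primary mineralization target (70% from zero) holds for any
#' timestep. The result is clipped to `[0, osteoid]`.
#'
#' @param tissue a [tissue_state()].
#' @param dt timestep in days, positive.
#' @param k_min mineralization rate constant in 1/day; default
#'   `log(10/3)/7`, i.e. 70% of the osteoid gap closes per week.
#' @return The updated [tissue_state()].
#' @export
update_mineral <- function(tissue, dt, k_min = k_min_default()) {
  if (dt <= 0) stop("dt must be positive")
  decay <- exp(-k_min * dt)
  m <- tissue$osteoid - (tissue$osteoid - tissue$mineral) * decay
  tissue$mineral <- pmin(pmax(m, 0), tissue$osteoid)
  tissue
}
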