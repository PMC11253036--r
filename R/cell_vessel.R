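# Vessel-phase Darcy cell problem.  The auxiliary potential h_j solves a
# periodic Laplace/Neumann problem on the vessel voxels:
#   div( K (grad h_j + e_j) ) = 0   in the vessel phase,
#   K (grad h_j + e_j) . n   = 0   on the vessel/matrix interface,
# with zero cell mean.  The cell-averaged flux of problem j is column j of the
# effective conductivity tensor <K (I + (grad h)^T)>, intrinsic average over
# the vessel phase.  Finite volumes on the voxel grid with harmonic-mean face
# conductivities; the zero-mean constraint is a single Lagrange multiplier.

#' Solve the vessel Darcy cell problem
#'
#' Computes the effective (nondimensional) vessel conductivity tensor on a
#' voxelized periodic cell. `K_v` is the local isotropic conductivity: a
#' scalar, or a vector over the vessel voxels (column-major order of the
#' masked array) for heterogeneous media. The returned `effective` tensor is
#' in the units of `K_v`; multiply by `d^2/mu` for the dimensional tensor.
#'
#' @param geom a `periodic_cell`.
#' @param K_v local vessel conductivity (scalar or per-vessel-voxel vector).
#' @return list with `effective` (3x3 tensor), `h` (auxiliary potentials,
#'   vessel-voxel x 3), `geom`.
#' @examples
#' cell <- build_vessel_cell(0.2, axes = "z", resolution = 12)
#' sol <- solve_vessel_cell_problem(cell, K_v = 1)
#' sol$effective[3, 3] # ~1: unimpeded axial conduction
#' @export
solve_vessel_cell_problem <- function(geom, K_v = 1) {
  mask <- geom$phase
  n <- geom$resolution
  h <- geom$h
  nv <- sum(mask)
  if (nv == 0) stop("vessel phase is empty")
  if (!phase_connected(mask)) {
    stop("solver error: vessel phase is not periodically connected ",
         "(singular cell problem)")
  }
  id <- array(0L, dim(mask))
  id[mask] <- seq_len(nv)
  Kvox <- array(0, dim(mask))
  Kvox[mask] <- K_v # recycles a scalar
  if (any(Kvox[mask] <= 0)) stop("K_v must be positive (Eq-SPD requirement)")

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- matrix(0, nv, 3)
  flux_pairs <- vector("list", 3)
  for (k in 1:3) {
    maskE <- shift_array(mask, k, 1L)
    both <- mask & maskE # interior faces: P = voxel, E = P + e_k (periodic)
    P <- id[both]
    E <- shift_array(id, k, 1L)[both]
    Kf <- 2 / (1 / Kvox[both] + 1 / shift_array(Kvox, k, 1L)[both])
    g <- Kf / h^2
    ii <- c(ii, P, E, P, E)
    jj <- c(jj, P, E, E, P)
    xx <- c(xx, -g, -g, g, g)
    # RHS for problem j = k: face normal +e_k at P, -e_k at E
    b[P, k] <- b[P, k] - Kf / h
    b[E, k] <- b[E, k] + Kf / h
    flux_pairs[[k]] <- list(P = P, E = E, Kf = Kf)
  }
  # The pure-Neumann/periodic problem is singular up to constants and its
  # rows sum to zero for compatible data: replace the first (redundant) row
  # by the grounding equation h_1 = 0, then restore the zero-mean convention
  # after the solve.  (A dense zero-mean Lagrange row would destroy the
  # sparsity of the factorization.)
  keep <- ii != 1L
  A <- Matrix::sparseMatrix(
    i = c(ii[keep], 1L), j = c(jj[keep], 1L), x = c(xx[keep], 1 / h),
    dims = c(nv, nv)
  )
  b[1, ] <- 0
  sol <- tryCatch(
    as.matrix(Matrix::solve(A, b)),
    error = function(e) {
      stop("solver error in vessel cell problem: ", conditionMessage(e))
    }
  )
  hj <- sweep(sol, 2, colMeans(sol)) # zero cell mean

  # effective_{k,j} = intrinsic average of the k-flux of problem j; interface
  # faces carry zero flux by the boundary condition.
  eff <- matrix(0, 3, 3)
  for (k in 1:3) {
    fp <- flux_pairs[[k]]
    for (j in 1:3) {
      fl <- fp$Kf * ((hj[fp$E, j] - hj[fp$P, j]) / h + (j == k))
      # each interior face contributes half to each adjacent voxel's average;
      # interface faces carry zero flux and contribute nothing
      eff[k, j] <- sum(fl) / nv
    }
  }
  list(effective = eff, h = hj, geom = geom)
}

#' Effective vessel conductivity for a parameter set
#'
#' End-to-end helper: builds the default interconnected-cylinder cell from the
#' microscale geometry in `params`, takes the local conductivity from the
#' Kozeny-Carman estimate, solves the vessel cell problem and returns the
#' dimensional isotropic effective conductivity (mean of the tensor diagonal,
#' by cubic symmetry), in mm^3 s mg^-1.
#'
#' @param params a `physiological_parameters` object.
#' @param resolution voxels per cell edge.
#' @param c0 Kozeny constant for the local conductivity.
#' @return list with `K_v_eff` (scalar, dimensional), `tensor` (dimensional),
#'   `cell`, `K_v_local` (dimensional scalar).
#' @export
effective_vessel_conductivity <- function(params, resolution = 64, c0 = 5) {
  Kloc_dim <- kozeny_carman(params$V_v_tot, params$S_tot, c0 = c0,
                            mu = params$mu)
  Kref <- params$d^2 / params$mu
  cell <- build_vessel_cell(params$r_c / params$d, resolution = resolution)
  sol <- solve_vessel_cell_problem(cell, K_v = Kloc_dim / Kref)
  tensor <- Kref * sol$effective
  list(
    K_v_eff = mean(diag(tensor)), tensor = tensor, cell = cell,
    K_v_local = Kloc_dim
  )
}
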