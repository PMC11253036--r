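# Voxelized periodic unit cell.  The microvasculature is idealized as a
# periodic network of interconnected cylinders of nondimensional radius
# r_hat_c = r_c/d inside the unit cell; the matrix (interstitial conduit
# network) is the complement.

#' Construct a periodic cell from a phase array
#'
#' @param phase logical 3D array (`TRUE` = vessel voxel), equal extents.
#' @param r_hat_c nondimensional cylinder radius (metadata, optional).
#' @param axes character vector of cylinder axes (metadata, optional).
#' @return object of class `periodic_cell`.
#' @export
periodic_cell <- function(phase, r_hat_c = NA_real_, axes = character()) {
  stopifnot(is.logical(phase), length(dim(phase)) == 3)
  d <- dim(phase)
  if (length(unique(d)) != 1) stop("cell must be cubic")
  structure(
    list(
      phase = phase, resolution = d[1], r_hat_c = r_hat_c, axes = axes,
      h = 1 / d[1]
    ),
    class = "periodic_cell"
  )
}

#' Build the periodic vessel-network cell
#'
#' Voxelizes the union of cylinders of nondimensional radius `r_hat_c` running
#' through the cell center along the requested axes (default: three mutually
#' orthogonal cylinders). Voxel centers sit at `(i - 1/2)/resolution`; a voxel
#' is a vessel voxel when its center lies within `r_hat_c` of a cylinder axis.
#'
#' @param r_hat_c nondimensional cylinder radius, `0 < r_hat_c < 0.5`.
#' @param axes subset of `c("x", "y", "z")`.
#' @param resolution voxels per cell edge, `>= 8`.
#' @return a `periodic_cell`.
#' @examples
#' cell <- build_vessel_cell(0.085, resolution = 16)
#' vessel_volume_fraction(cell)
#' @export
build_vessel_cell <- function(r_hat_c, axes = c("x", "y", "z"),
                              resolution = 64) {
  if (!(r_hat_c > 0 && r_hat_c < 0.5)) {
    stop("invalid geometry: r_hat_c must lie in (0, 0.5) to avoid ",
         "overlapping periodic images")
  }
  if (resolution < 8) stop("resolution must be at least 8")
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  n <- as.integer(resolution)
  xc <- (seq_len(n) - 0.5) / n - 0.5 # centered coordinates
  phase <- array(FALSE, dim = c(n, n, n))
  r2 <- array(0, dim = c(n, n, n))
  sq <- outer(xc^2, xc^2, `+`) # distance^2 from an axis, in the transverse plane
  inside <- sq <= r_hat_c^2
  for (ax in axes) {
    # cylinder along `ax`: transverse coordinates are the other two axes
    for (k in seq_len(n)) {
      if (ax == "z") phase[, , k] <- phase[, , k] | inside
      if (ax == "y") phase[, k, ] <- phase[, k, ] | inside
      if (ax == "x") phase[k, , ] <- phase[k, , ] | inside
    }
  }
  periodic_cell(phase, r_hat_c = r_hat_c, axes = axes)
}

#' Vessel volume fraction of a periodic cell
#' @param cell a `periodic_cell`.
#' @return fraction of voxels labelled vessel.
#' @export
vessel_volume_fraction <- function(cell) mean(cell$phase)

#' @export
print.periodic_cell <- function(x, ...) {
  cat(sprintf(
    "Periodic cell: %d^3 voxels, vessel fraction %.4f",
    x$resolution, vessel_volume_fraction(x)
  ))
  if (!is.na(x$r_hat_c)) {
    cat(sprintf(" (r_hat_c = %g, axes: %s)", x$r_hat_c,
                paste(x$axes, collapse = "")))
  }
  cat("\n")
  invisible(x)
}

# 6-neighbour periodic adjacency of the voxels selected by `mask`; returns
# TRUE when they form a single connected component.
phase_connected <- function(mask) {
  n <- dim(mask)[1]
  id <- array(0L, dim(mask))
  id[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0) return(FALSE)
  edges <- NULL
  for (k in 1:3) {
    shifted <- shift_array(id, k, 1L)
    both <- mask & shift_array(mask, k, 1L)
    edges <- rbind(edges, cbind(id[both], shifted[both]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, sum(mask) - igraph::vcount(g)))
  igraph::components(g)$no == 1
}

# circular shift of a 3D array by `by` along dimension `dimn`
shift_array <- function(a, dimn, by) {
  n <- dim(a)[dimn]
  idx <- ((seq_len(n) - 1 + by) %% n) + 1
  switch(dimn,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE]
  )
}
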