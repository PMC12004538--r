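#' Rectangular grid specification for the descriptor plane
#'
#' The grid covers the bounding box of the molecule's vdW projection
#' (atom positions +/- vdW radii, in the molecule's canonical frame)
#' padded by `pad` Angstrom on each side.
#'
#' @param mol A [molecule()] (any frame; canonicalized internally).
#' @param spacing Grid spacing (Angstrom, > 0).
#' @param pad Padding beyond the vdW bounding box (Angstrom).
#' @return List with node coordinate vectors `x`, `y` and `spacing`.
#' @export
plane_grid <- function(mol, spacing = 0.1, pad = 2) {
  if (spacing <= 0) abort("grid spacing must be positive", class = "nucstack_argument_error")
  m <- canonical_or_identity(mol)
  a <- m$atoms
  xr <- range(a$x - a$vdw, a$x + a$vdw) + c(-pad, pad)
  yr <- range(a$y - a$vdw, a$y + a$vdw) + c(-pad, pad)
  list(x = seq(xr[1], xr[2], by = spacing),
       y = seq(yr[1], yr[2], by = spacing),
       spacing = spacing)
}

#' Mask of the van der Waals projection
#'
#' A node is inside the mask iff its in-plane point lies within the
#' projected disk (radius = vdW radius) of at least one atom, i.e. the
#' union of the atomic circles.
#'
#' @param mol A [molecule()].
#' @param grid A [plane_grid()]; default grid built from `mol`.
#' @return Logical matrix (`length(grid$x)` x `length(grid$y)`).
#' @export
vdw_projection_mask <- function(mol, grid = plane_grid(mol)) {
  if (nrow(mol$atoms) == 0) {
    abort("molecule has no atoms", class = "nucstack_geometry_error")
  }
  m <- canonical_or_identity(mol)
  a <- m$atoms
  mask <- matrix(FALSE, length(grid$x), length(grid$y))
  for (k in seq_len(nrow(a))) {
    dx2 <- (grid$x - a$x[k])^2
    dy2 <- (grid$y - a$y[k])^2
    mask <- mask | outer(dx2, dy2, "+") <= a$vdw[k]^2
  }
  mask
}

#' Point-charge ESP on a plane offset from the molecular plane
#'
#' Evaluates ESP(r) = 332.0637 * sum_i q_i / |r - r_i| (charges in e,
#' distances in Angstrom, ESP in kcal/mol) on a rectangular grid in the
#' plane a signed `height` above the molecular plane, in the molecule's
#' canonical frame. This is the package's native approximation to the
#' quantum-mechanical ESP; DFT grids are imported via
#' [esp_plane_from_cube()] instead.
#'
#' @param mol A [molecule()] with charges assigned.
#' @param height Signed plane height (Angstrom, non-zero); positive means
#'   the +z face of the canonical frame.
#' @param spacing Grid spacing (Angstrom).
#' @param grid Optional [plane_grid()] override.
#' @return Object of class `nucstack_field`: list with `x`, `y`,
#'   `height`, `spacing`, `values` (kcal/mol matrix), `mask`, `backend`.
#' @export
esp_plane_point_charges <- function(mol, height = 3.25, spacing = 0.1,
                                    grid = plane_grid(mol, spacing)) {
  if (height == 0) abort("plane height must be non-zero", class = "nucstack_argument_error")
  m <- canonical_or_identity(mol)
  a <- m$atoms
  vals <- matrix(0, length(grid$x), length(grid$y))
  for (k in seq_len(nrow(a))) {
    d2 <- outer((grid$x - a$x[k])^2, (grid$y - a$y[k])^2, "+") + (height - a$z[k])^2
    if (any(d2 < 1e-12)) {
      abort("grid node coincident with an atom", class = "nucstack_singularity_error")
    }
    vals <- vals + COULOMB_K * a$charge[k] / sqrt(d2)
  }
  new_field(grid, height, vals, vdw_projection_mask(mol, grid), "point-charge")
}

new_field <- function(grid, height, values, mask, backend) {
  stopifnot(all(dim(values) == dim(mask)))
  structure(
    list(x = grid$x, y = grid$y, height = height, spacing = grid$spacing,
         values = values, mask = mask, backend = backend),
    class = "nucstack_field"
  )
}

#' @export
print.nucstack_field <- function(x, ...) {
  cat(sprintf("<planar ESP field: %d x %d nodes, spacing %.3g A, height %+.3g A, %d masked, backend %s>\n",
              length(x$x), length(x$y), x$spacing, x$height, sum(x$mask), x$backend))
  invisible(x)
}

#' ESP descriptor statistics over the vdW projection
#'
#' Max, min, mean and range of the planar ESP restricted to nodes inside
#' the vdW projection mask, plus the heavy-atom count. These are the
#' inputs of the maximum-stacking model.
#'
#' @param field A `nucstack_field`.
#' @param mol The [molecule()] the field was computed for.
#' @param face Face label to record (+1/-1).
#' @return One-row tibble: `mol_id`, `n_ha`, `esp_max`, `esp_min`,
#'   `esp_mean`, `esp_range`, `face`, `backend`.
#' @export
plane_descriptors <- function(field, mol, face = sign(field$height)) {
  v <- field$values[field$mask]
  if (length(v) == 0) {
    abort("empty vdW projection mask", class = "nucstack_mask_error")
  }
  tibble(
    mol_id = mol$name, n_ha = heavy_atom_count(mol),
    esp_max = max(v), esp_min = min(v), esp_mean = mean(v),
    esp_range = max(v) - min(v), face = face, backend = field$backend
  )
}

#' One-call ESP descriptors for a molecule
#'
#' Computes point-charge planar fields on one or both faces and returns
#' descriptor rows. With `face = "auto"` both faces are evaluated and the
#' one with the larger `esp_max` is returned (planar aromatics with
#' mirror-symmetric charges give identical faces, making the choice moot).
#'
#' @param mol A [molecule()] with charges.
#' @param height Unsigned plane offset (Angstrom).
#' @param spacing Grid spacing (Angstrom).
#' @param face `"auto"`, `"both"`, `1` or `-1`.
#' @return Tibble of descriptor rows (1 row, or 2 for `"both"`).
#' @export
esp_descriptors <- function(mol, height = 3.25, spacing = 0.1, face = "auto") {
  one <- function(f) {
    fld <- esp_plane_point_charges(mol, height = f * height, spacing = spacing)
    plane_descriptors(fld, mol, face = f)
  }
  if (identical(face, 1) || identical(face, -1)) return(one(face))
  both <- bind_rows(one(1), one(-1))
  if (identical(face, "both")) return(both)
  both[which.max(both$esp_max), ]
}

# degenerate molecules (fewer than 3 non-collinear heavy atoms) have no
# unique plane; treat their stored coordinates as already in-plane
canonical_or_identity <- function(mol) {
  tryCatch(canonical_frame(mol, nucleobase = FALSE),
           nucstack_geometry_error = function(e) mol)
}
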