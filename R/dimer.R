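#' Stacking pose parameters
#'
#' A pose is the rigid placement of a heterocycle over a nucleobase in the
#' nucleobase's canonical frame: lateral offsets `dx`, `dy` (Angstrom),
#' vertical separation `dz` (> 0, along the nucleobase normal), rotation
#' `theta` about the vertical axis (degrees, normalized to [0, 360)) and
#' the prochiral `face` of the heterocycle (+1 or -1).
#'
#' @param dx,dy Lateral displacement (Angstrom).
#' @param dz Vertical separation (Angstrom, positive).
#' @param theta Rotation about +z (degrees).
#' @param face +1 or -1.
#' @return Object of class `nucstack_pose`.
#' @export
stack_pose <- function(dx = 0, dy = 0, dz = 3.25, theta = 0, face = 1) {
  if (!is.numeric(dz) || dz <= 0) {
    abort("pose dz must be positive", class = "nucstack_pose_error")
  }
  if (!face %in% c(1, -1)) {
    abort("pose face must be +1 or -1", class = "nucstack_pose_error")
  }
  structure(
    list(dx = dx, dy = dy, dz = dz, theta = theta %% 360, face = face),
    class = "nucstack_pose"
  )
}

#' @export
print.nucstack_pose <- function(x, ...) {
  cat(sprintf("<pose: dx %.3f, dy %.3f, dz %.3f A, theta %.2f deg, face %+d>\n",
              x$dx, x$dy, x$dz, x$theta, x$face))
  invisible(x)
}

pose_as_row <- function(pose) {
  tibble(dx = pose$dx, dy = pose$dy, dz = pose$dz,
         theta = pose$theta, face = pose$face)
}

#' Build a parallel stacked dimer
#'
#' The nucleobase is placed in its canonical frame; the heterocycle is
#' canonicalized, optionally flipped to its other face (rotation by pi
#' about the x axis), rotated by `theta` about +z and translated to
#' `(dx, dy, dz)`. By construction the two molecular planes are exactly
#' parallel and the heterocycle heavy-atom centroid sits `dz` above the
#' nucleobase plane.
#'
#' @param het Heterocycle [molecule()].
#' @param nuc Nucleobase (or any planar) [molecule()].
#' @param pose A [stack_pose()].
#' @param pose_id Label.
#' @return Object of class `nucstack_dimer` with fields `nucleobase`,
#'   `heterocycle`, `pose`, `pose_id`.
#' @export
place_stacked <- function(het, nuc, pose = stack_pose(), pose_id = "pose") {
  if (!inherits(pose, "nucstack_pose")) {
    abort("`pose` must be a stack_pose()", class = "nucstack_pose_error")
  }
  nuc_c <- canonical_frame(nuc)
  het_c <- canonical_frame(het, nucleobase = FALSE)
  place_canonical(het_c, nuc_c, pose, pose_id)
}

# fast path: monomers already canonicalized (batch generators)
place_canonical <- function(het_c, nuc_c, pose, pose_id = "pose") {
  rot <- rotation_z(pose$theta)
  if (pose$face == -1) {
    rot <- rot %*% rotation_axis_angle(c(1, 0, 0), pi)
  }
  xyz <- coords_matrix(het_c) %*% t(rot)
  xyz <- sweep(xyz, 2, c(pose$dx, pose$dy, pose$dz), "+")
  het_c <- set_coords(het_c, xyz)
  structure(
    list(nucleobase = nuc_c, heterocycle = het_c, pose = pose, pose_id = pose_id),
    class = "nucstack_dimer"
  )
}

#' @export
print.nucstack_dimer <- function(x, ...) {
  cat(sprintf("<stacked dimer '%s': %s over %s>\n",
              x$pose_id, x$heterocycle$name, x$nucleobase$name))
  print(x$pose)
  invisible(x)
}

#' Apply a rigid transform to a whole dimer
#'
#' @param dimer A `nucstack_dimer`.
#' @inheritParams transform_molecule
#' @export
transform_dimer <- function(dimer, rotation = diag(3), translation = c(0, 0, 0)) {
  dimer$nucleobase <- transform_molecule(dimer$nucleobase, rotation, translation)
  dimer$heterocycle <- transform_molecule(dimer$heterocycle, rotation, translation)
  dimer
}

#' Geometric metrics of a stacked dimer
#'
#' Works for constructed and imported (e.g. crystal-structure) dimers
#' alike. All quantities are computed in the nucleobase canonical frame,
#' so they are invariant under rigid transforms of the whole dimer.
#'
#' @param dimer A `nucstack_dimer`.
#' @return One-row tibble: `separation` (heterocycle heavy-atom centroid
#'   height above the nucleobase plane, Angstrom), `lateral` (in-plane
#'   centroid offset), `dx`, `dy`, `tilt` (angle between plane normals,
#'   degrees, 0 to 90), `theta` (in-plane rotation recovered by 2D
#'   least-squares superposition, degrees in [0, 360)) and `face`.
#' @export
pose_metrics <- function(dimer) {
  tr <- canonical_transform(dimer$nucleobase)
  het <- dimer$heterocycle
  hxyz <- apply_transform(coords_matrix(het), tr)[is_heavy(het), , drop = FALSE]
  ctr <- colMeans(hxyz)
  nuc_n <- c(0, 0, 1)
  sv <- svd(sweep(hxyz, 2, ctr))
  het_n <- sv$v[, 3]
  cosang <- abs(sum(het_n * nuc_n))
  tilt <- acos(pmin(1, cosang)) * 180 / pi
  # recover in-plane rotation against the heterocycle's own canonical frame
  hc <- canonical_frame(het, nucleobase = FALSE)
  cxyz <- coords_matrix(hc)[is_heavy(hc), , drop = FALSE]
  obs <- sweep(hxyz, 2, ctr)
  # face: atom-order circulation flips sign when the molecule is flipped
  face_obs <- if (sign(circulation(obs)) == sign(circulation(cxyz))) 1 else -1
  if (face_obs == -1) {
    cxyz <- cxyz %*% t(rotation_axis_angle(c(1, 0, 0), pi))
  }
  num <- sum(cxyz[, 1] * obs[, 2] - cxyz[, 2] * obs[, 1])
  den <- sum(cxyz[, 1] * obs[, 1] + cxyz[, 2] * obs[, 2])
  theta <- (atan2(num, den) * 180 / pi) %% 360
  tibble(
    separation = ctr[3], lateral = sqrt(ctr[1]^2 + ctr[2]^2),
    dx = ctr[1], dy = ctr[2], tilt = tilt, theta = theta, face = face_obs
  )
}

# signed in-plane circulation over atom order; its sign flips when the
# molecule is viewed from the other face
circulation <- function(centered_xyz) {
  x <- centered_xyz[, 1]
  y <- centered_xyz[, 2]
  n <- length(x)
  sum(x[-n] * y[-1] - y[-n] * x[-1])
}

#' Minimum intermolecular heavy-atom distance
#'
#' @param dimer A `nucstack_dimer`.
#' @return Distance in Angstrom.
#' @export
min_heavy_distance <- function(dimer) {
  a <- coords_matrix(dimer$nucleobase)[is_heavy(dimer$nucleobase), , drop = FALSE]
  b <- coords_matrix(dimer$heterocycle)[is_heavy(dimer$heterocycle), , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Assign heterocycle ring centroids to nucleobase stacking features
#'
#' Stacked minima cluster over a discrete set of loci on each nucleobase,
#' located over atoms and bonds. This projects each heterocycle ring
#' centroid into the nucleobase plane and assigns it to the nearest
#' feature among the nucleobase heavy atoms and heavy-atom bond midpoints.
#' Ties (distance difference below 1e-9 Angstrom) resolve to the atom.
#'
#' @param dimer A `nucstack_dimer`.
#' @return A tibble with one row per heterocycle ring: `ring`, projected
#'   centroid `x`, `y`, `feature` ("atom" or "bond"), atom indices `i`,
#'   `j` (`j` is `NA` for atoms), and in-plane `distance` (Angstrom).
#' @export
locus_assign <- function(dimer) {
  nuc <- dimer$nucleobase
  het <- dimer$heterocycle
  rings <- het$rings
  if (length(rings) == 0) {
    het <- perceive_rings(het)
    rings <- het$rings
  }
  if (length(rings) == 0) {
    abort("heterocycle has no perceived ring", class = "nucstack_geometry_error")
  }
  tr <- canonical_transform(nuc)
  nxyz <- apply_transform(coords_matrix(nuc), tr)
  hxyz <- apply_transform(coords_matrix(het), tr)
  heavy <- which(is_heavy(nuc))
  feats <- tibble(
    feature = "atom", i = heavy, j = NA_integer_,
    fx = nxyz[heavy, 1], fy = nxyz[heavy, 2]
  )
  bonds <- perceive_bonds(nuc)
  bonds <- bonds[bonds$i %in% heavy & bonds$j %in% heavy, ]
  if (nrow(bonds) > 0) {
    feats <- bind_rows(feats, tibble(
      feature = "bond", i = bonds$i, j = bonds$j,
      fx = (nxyz[bonds$i, 1] + nxyz[bonds$j, 1]) / 2,
      fy = (nxyz[bonds$i, 2] + nxyz[bonds$j, 2]) / 2
    ))
  }
  purrr::imap(rings, function(ring, k) {
    ctr <- colMeans(hxyz[ring, , drop = FALSE])
    d <- sqrt((feats$fx - ctr[1])^2 + (feats$fy - ctr[2])^2)
    dmin <- min(d)
    cand <- which(d - dmin < 1e-9)
    atom_cand <- cand[feats$feature[cand] == "atom"]
    pick <- if (length(atom_cand) > 0) atom_cand[1] else cand[1]
    tibble(ring = k, x = ctr[1], y = ctr[2],
           feature = feats$feature[pick],
           i = unname(feats$i[pick]), j = unname(feats$j[pick]),
           distance = unname(d[pick]))
  }) |> bind_rows()
}
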