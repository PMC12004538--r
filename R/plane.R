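#' Fit the least-squares molecular plane
#'
#' Total-least-squares plane through the heavy atoms (minimizing the sum of
#' squared perpendicular distances, via SVD). The normal is canonicalized
#' to point toward +z (positive z component; ties broken toward +x, then +y).
#'
#' @param mol A [molecule()].
#' @return A list of class `nucstack_plane` with `normal` (unit length),
#'   `centroid` (heavy-atom centroid) and `rms` (out-of-plane rms, Angstrom).
#' @export
fit_plane <- function(mol) {
  xyz <- coords_matrix(mol)[is_heavy(mol), , drop = FALSE]
  if (nrow(xyz) < 3) {
    abort("plane fit needs at least 3 heavy atoms", class = "nucstack_geometry_error")
  }
  ctr <- colMeans(xyz)
  centered <- sweep(xyz, 2, ctr)
  sv <- svd(centered)
  if (sv$d[2] < 1e-9) {
    abort("heavy atoms are collinear; no unique plane", class = "nucstack_geometry_error")
  }
  normal <- sv$v[, 3]
  key <- c(normal[3], normal[1], normal[2])
  first <- which(abs(key) > 1e-12)[1]
  if (!is.na(first) && key[first] < 0) normal <- -normal
  normal <- normal / sqrt(sum(normal^2))
  structure(
    list(normal = normal, centroid = ctr,
         rms = sqrt(mean((centered %*% normal)^2))),
    class = "nucstack_plane"
  )
}

#' @export
print.nucstack_plane <- function(x, ...) {
  cat(sprintf("<plane: normal (%.4f, %.4f, %.4f), rms %.4g A>\n",
              x$normal[1], x$normal[2], x$normal[3], x$rms))
  invisible(x)
}

# rotation matrix sending unit vector a to unit vector b
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * a) * a
    axis <- axis / sqrt(sum(axis^2))
    return(rotation_axis_angle(axis, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

rotation_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c_ <- cos(angle); s <- sin(angle); t <- 1 - c_
  matrix(c(
    t * x * x + c_,     t * x * y - s * z, t * x * z + s * y,
    t * x * y + s * z,  t * y * y + c_,    t * y * z - s * x,
    t * x * z - s * y,  t * y * z + s * x, t * z * z + c_
  ), 3, 3, byrow = TRUE)
}

rotation_z <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), -sin(th), 0,
           sin(th),  cos(th), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Canonicalizing rigid transform of a molecule
#'
#' Computes the proper rigid transform `xyz -> (xyz - centroid) %*% t(R)`
#' that [canonical_frame()] applies. Exposed so a whole dimer can be moved
#' into one monomer's canonical frame.
#'
#' @inheritParams canonical_frame
#' @return List with `rotation` (3x3) and `centroid` (length 3).
#' @export
canonical_transform <- function(mol, nucleobase = !is.null(mol$glycosidic_n)) {
  if (nucleobase && is.null(mol$glycosidic_n)) {
    abort("nucleobase orientation requested but glycosidic_n is not annotated",
          class = "nucstack_annotation_error")
  }
  pl <- fit_plane(mol)
  heavy_idx <- which(is_heavy(mol))
  best <- NULL
  for (flip in c(FALSE, TRUE)) {
    nrm <- if (flip) -pl$normal else pl$normal
    r1 <- rotation_between(nrm, c(0, 0, 1))
    xyz <- sweep(coords_matrix(mol), 2, pl$centroid) %*% t(r1)
    if (nucleobase) {
      ref <- xyz[mol$glycosidic_n, 1:2]
      target <- c(-1, -1) / sqrt(2)
    } else {
      off <- heavy_idx[sqrt(rowSums(xyz[heavy_idx, 1:2, drop = FALSE]^2)) > 0.1]
      if (length(off) == 0) {
        abort("no heavy atom off the centroid; in-plane orientation undefined",
              class = "nucstack_geometry_error")
      }
      ref <- xyz[off[1], 1:2]
      target <- c(1, 0)
    }
    ang <- (atan2(target[2], target[1]) - atan2(ref[2], ref[1])) * 180 / pi
    rtot <- rotation_z(ang) %*% r1
    xyz <- sweep(coords_matrix(mol), 2, pl$centroid) %*% t(rtot)
    # face disambiguation: first heavy atom clearly off the reference axis
    # must lie on the +y side of that axis
    ok <- TRUE
    for (k in heavy_idx) {
      perp <- target[1] * xyz[k, 2] - target[2] * xyz[k, 1]
      if (abs(perp) > 0.1) { ok <- perp > 0; break }
    }
    best <- list(rotation = rtot, centroid = pl$centroid)
    if (ok) break
  }
  best
}

apply_transform <- function(xyz, tr) {
  sweep(xyz, 2, tr$centroid) %*% t(tr$rotation)
}

#' Place a molecule in its canonical frame
#'
#' Rigidly moves the molecule so its heavy-atom centroid sits at the
#' origin and its plane normal points along +z, then fixes the in-plane
#' rotation deterministically:
#' * nucleobases (molecules annotated with `glycosidic_n`): rotated so the
#'   glycosidic nitrogen lies on the quadrant-III diagonal (direction
#'   (-1, -1)), matching the convention of drawing nucleobases with the
#'   glycosidic N in the lower left;
#' * other molecules: the first heavy atom lying off the centroid goes to +x.
#'
#' Which of the two faces points up is resolved by requiring the first
#' heavy atom off the reference axis to have positive perpendicular
#' component. All rules depend only on atom order, so the canonical
#' coordinates are invariant under any proper rigid transform of the input.
#'
#' @param mol A [molecule()].
#' @param nucleobase Require glycosidic-N orientation (error if the
#'   annotation is absent).
#' @return The molecule in canonical coordinates.
#' @export
canonical_frame <- function(mol, nucleobase = !is.null(mol$glycosidic_n)) {
  tr <- canonical_transform(mol, nucleobase)
  set_coords(mol, apply_transform(coords_matrix(mol), tr))
}
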