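#' Read a Gaussian cube file
#'
#' Standard cube layout: two comment lines; a line with the atom count
#' and grid origin; three axis lines (voxel counts and voxel vectors);
#' the atom block; then the volumetric data in z-fastest order. Positive
#' voxel counts mean Bohr units (the common case); negative counts mean
#' Angstrom. Coordinates are returned in Angstrom.
#'
#' @param path Cube file path.
#' @return List with `origin` (Angstrom), `axes` (3x3, rows are voxel
#'   vectors in Angstrom), `n` (voxel counts), `atoms` (tibble), `values`
#'   (3D array indexed `[i, j, k]`) and `unit` (`"au"` or `"angstrom"`,
#'   the unit the lengths were stored in).
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) {
    abort("malformed cube file: too short", class = "nucstack_format_error")
  }
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hd <- num(lines[3])
  natoms <- as.integer(hd[1])
  dsets <- 1L
  has_dset_line <- natoms < 0
  natoms <- abs(natoms)
  origin <- hd[2:4]
  ax <- lapply(4:6, function(i) num(lines[i]))
  n <- vapply(ax, function(a) as.integer(a[1]), integer(1))
  bohr <- all(n > 0)
  n <- abs(n)
  axes <- do.call(rbind, lapply(ax, function(a) a[2:4]))
  scale <- if (bohr) BOHR_ANGSTROM else 1
  atoms <- if (natoms > 0) {
    do.call(rbind, lapply(lines[7:(6 + natoms)], num))
  } else {
    matrix(numeric(0), 0, 5)
  }
  data_start <- 7 + natoms + if (has_dset_line) 1 else 0
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[data_start:length(lines)]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) < prod(n)) {
    abort("malformed cube file: data block shorter than grid", class = "nucstack_format_error")
  }
  values <- array(vals[seq_len(prod(n))], dim = rev(n))   # z fastest
  values <- aperm(values, c(3, 2, 1))
  list(
    origin = origin * scale, axes = axes * scale, n = n,
    atoms = tibble(number = atoms[, 1],
                   x = atoms[, 3] * scale, y = atoms[, 4] * scale,
                   z = atoms[, 5] * scale),
    values = values, unit = if (bohr) "au" else "angstrom"
  )
}

#' Write a Gaussian cube file
#'
#' Mainly for constructing synthetic fixtures; axis-aligned grids only.
#'
#' @param values 3D array `[i, j, k]`.
#' @param origin Grid origin (Angstrom).
#' @param spacing Voxel edge lengths, length 3 (Angstrom).
#' @param path Output path.
#' @param atoms Optional atom tibble (`number`, `x`, `y`, `z` in Angstrom).
#' @return `path`, invisibly.
#' @export
write_cube <- function(values, origin, spacing, path, atoms = NULL) {
  n <- dim(values)
  b <- 1 / BOHR_ANGSTROM
  lines <- c(
    "synthetic cube", "generated by nucstack",
    sprintf("%5d %11.6f %11.6f %11.6f",
            if (is.null(atoms)) 0L else nrow(atoms),
            origin[1] * b, origin[2] * b, origin[3] * b),
    sprintf("%5d %11.6f %11.6f %11.6f", n[1], spacing[1] * b, 0, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", n[2], 0, spacing[2] * b, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", n[3], 0, 0, spacing[3] * b)
  )
  if (!is.null(atoms)) {
    lines <- c(lines, sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                              as.integer(atoms$number), 0,
                              atoms$x * b, atoms$y * b, atoms$z * b))
  }
  flat <- as.vector(aperm(values, c(3, 2, 1)))  # z fastest
  body <- vapply(split(flat, ceiling(seq_along(flat) / 6)),
                 function(v) paste(sprintf("%13.5E", v), collapse = " "),
                 character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

# trilinear interpolation in an axis-aligned cube grid
cube_interp <- function(cube, pts) {
  if (any(abs(cube$axes[upper.tri(cube$axes) | lower.tri(cube$axes)]) > 1e-9)) {
    abort("only axis-aligned cube grids are supported", class = "nucstack_format_error")
  }
  sp <- diag(cube$axes)
  fr <- sweep(sweep(pts, 2, cube$origin), 2, sp, "/")
  out <- numeric(nrow(pts))
  for (d in 1:3) {
    if (any(fr[, d] < -1e-9 | fr[, d] > cube$n[d] - 1 + 1e-9)) {
      abort("requested plane lies outside the cube bounds", class = "nucstack_bounds_error")
    }
  }
  fr <- pmax(fr, 0)
  i0 <- pmin(floor(fr[, 1]), cube$n[1] - 2); tx <- fr[, 1] - i0
  j0 <- pmin(floor(fr[, 2]), cube$n[2] - 2); ty <- fr[, 2] - j0
  k0 <- pmin(floor(fr[, 3]), cube$n[3] - 2); tz <- fr[, 3] - k0
  v <- cube$values
  idx <- function(di, dj, dk) v[cbind(i0 + 1 + di, j0 + 1 + dj, k0 + 1 + dk)]
  (1 - tx) * (1 - ty) * (1 - tz) * idx(0, 0, 0) +
    tx * (1 - ty) * (1 - tz) * idx(1, 0, 0) +
    (1 - tx) * ty * (1 - tz) * idx(0, 1, 0) +
    (1 - tx) * (1 - ty) * tz * idx(0, 0, 1) +
    tx * ty * (1 - tz) * idx(1, 1, 0) +
    tx * (1 - ty) * tz * idx(1, 0, 1) +
    (1 - tx) * ty * tz * idx(0, 1, 1) +
    tx * ty * tz * idx(1, 1, 1)
}

#' Sample a volumetric ESP cube onto the descriptor plane
#'
#' Trilinearly interpolates an externally computed (e.g. DFT) ESP grid
#' onto the plane a signed `height` above the molecular plane. The cube
#' must be given in the molecule's own coordinate frame; the plane grid
#' is built in the canonical frame and mapped back before sampling.
#' Values are converted to kcal/mol when the cube stores atomic units
#' (the cube convention; set `convert = FALSE` for pre-converted cubes).
#'
#' @param cube Result of [read_cube()] or a path to a cube file.
#' @param mol The [molecule()] (same coordinate frame as the cube).
#' @param height Signed plane height (Angstrom).
#' @param spacing Plane grid spacing (Angstrom).
#' @param convert Multiply by 627.509 (hartree -> kcal/mol)?
#' @return A `nucstack_field` (values in kcal/mol).
#' @export
esp_plane_from_cube <- function(cube, mol, height = 3.25, spacing = 0.1,
                                convert = TRUE) {
  if (is.character(cube)) cube <- read_cube(cube)
  grid <- plane_grid(mol, spacing)
  tr <- tryCatch(canonical_transform(mol, nucleobase = FALSE),
                 nucstack_geometry_error = function(e) {
                   list(rotation = diag(3), centroid = c(0, 0, 0))
                 })
  nodes <- cbind(
    rep(grid$x, times = length(grid$y)),
    rep(grid$y, each = length(grid$x)),
    height
  )
  # map canonical-frame nodes back to the molecule's original frame
  back <- nodes %*% tr$rotation
  back <- sweep(back, 2, tr$centroid, "+")
  vals <- cube_interp(cube, back)
  vals <- matrix(vals, length(grid$x), length(grid$y))
  if (convert) vals <- vals * HARTREE_KCAL
  new_field(grid, height, vals, vdw_projection_mask(mol, grid), "qm-grid")
}
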