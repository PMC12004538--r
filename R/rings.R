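#' Perceive bonds from interatomic distances
#'
#' Two atoms are bonded when their separation is below 1.2 times the sum of
#' their covalent radii. Used for formats that carry no connectivity (XYZ)
#' and for locus features (bond midpoints).
#'
#' @param mol A [molecule()].
#' @param scale Multiplier on the covalent-radius sum.
#' @return A tibble with columns `i`, `j` (i < j) and `r` (Angstrom).
#' @export
perceive_bonds <- function(mol, scale = 1.2) {
  n <- nrow(mol$atoms)
  if (n < 2) return(tibble(i = integer(), j = integer(), r = numeric()))
  xyz <- coords_matrix(mol)
  rcov <- lookup_element(mol$atoms$element, "covalent")
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(rcov, rcov, "+") * scale
  sel <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  tibble(i = sel[, 1], j = sel[, 2], r = d[sel])
}

#' Perceive rings geometrically
#'
#' Smallest-set-of-smallest-rings style perception on the covalent bond
#' graph: for every bond, the shortest cycle through it is found by
#' removing the bond and taking the shortest remaining path between its
#' endpoints. Unique cycles of length 3-7 are kept; rings whose heavy
#' atoms are coplanar (rms deviation below `planar_tol`) are flagged
#' aromatic-like and stored on the molecule.
#'
#' @param mol A [molecule()].
#' @param bonds Optional precomputed bond table.
#' @param planar_tol RMS out-of-plane tolerance (Angstrom) for flagging.
#' @param min_size Minimum ring size to store (default 5, matching the
#'   aromatic heterocycles this package targets).
#' @return The molecule with `rings` populated.
#' @export
perceive_rings <- function(mol, bonds = NULL, planar_tol = 0.1, min_size = 5) {
  bonds <- bonds %||% perceive_bonds(mol)
  heavy <- which(is_heavy(mol))
  hb <- bonds[bonds$i %in% heavy & bonds$j %in% heavy, ]
  if (nrow(hb) == 0) {
    mol$rings <- list()
    return(mol)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(hb$i), to = as.character(hb$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(heavy))
  )
  cycles <- list()
  for (k in seq_len(nrow(hb))) {
    gk <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(as.character(hb$i[k]), as.character(hb$j[k]))))
    sp <- suppressWarnings(igraph::shortest_paths(
      gk, from = as.character(hb$i[k]), to = as.character(hb$j[k])
    )$vpath[[1]])
    if (length(sp) >= 3 && length(sp) <= 7) {
      ring <- sort(as.integer(igraph::V(g)$name[sp]))
      cycles[[length(cycles) + 1]] <- ring
    }
  }
  cycles <- unique(cycles)
  cycles <- Filter(function(r) length(r) >= min_size, cycles)
  if (length(cycles) > 0) {
    xyz <- coords_matrix(mol)
    keep <- vapply(cycles, function(r) {
      plane_rms(xyz[r, , drop = FALSE]) < planar_tol
    }, logical(1))
    cycles <- cycles[keep]
  }
  mol$rings <- cycles
  mol
}

# rms perpendicular deviation from the least-squares plane of a point set
plane_rms <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  sqrt(mean((sweep(xyz, 2, ctr) %*% sv$v[, 3])^2))
}
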