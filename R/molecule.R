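#' Construct a molecule
#'
#' The central structure container: an ordered atom table plus ring systems
#' and light annotations. Atoms live in a tibble so the usual dplyr verbs
#' apply directly to `mol$atoms`.
#'
#' @param name Molecule label.
#' @param atoms A data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (elementary charge units, zero-filled if absent)
#'   and `vdw` (Angstrom; filled from [element_table()] if absent).
#' @param rings List of integer vectors of atom indices, one per aromatic
#'   ring (>= 5 members each as stored; perception may add them later).
#' @param net_charge Declared net molecular charge in e.
#' @param tautomer_id Optional tautomer label.
#' @param glycosidic_n Optional atom index of the glycosidic nitrogen
#'   (used to orient nucleobases in the canonical frame).
#'
#' @return An object of class `nucstack_molecule`.
#' @export
#' @examples
#' mol <- toy_ring(6, radius = 1.39)
#' heavy_atom_count(mol)
molecule <- function(name, atoms, rings = list(), net_charge = 0,
                     tautomer_id = NULL, glycosidic_n = NULL) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "nucstack_schema_error")
  }
  atoms$element <- normalize_element(atoms$element)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (!"vdw" %in% names(atoms)) atoms$vdw <- lookup_element(atoms$element, "vdw")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    abort("non-finite atomic coordinates", class = "nucstack_geometry_error")
  }
  if (any(atoms$vdw <= 0)) {
    abort("vdW radii must be positive", class = "nucstack_geometry_error")
  }
  n <- nrow(atoms)
  for (r in rings) {
    if (any(r < 1 | r > n)) {
      abort("ring atom index out of range", class = "nucstack_geometry_error")
    }
  }
  structure(
    list(name = name, atoms = atoms, rings = rings,
         net_charge = net_charge, tautomer_id = tautomer_id,
         glycosidic_n = glycosidic_n),
    class = "nucstack_molecule"
  )
}

#' @export
print.nucstack_molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms (%d heavy), %d ring(s), net charge %+g e>\n",
              x$name, nrow(x$atoms), heavy_atom_count(x), length(x$rings),
              x$net_charge))
  invisible(x)
}

#' Count non-hydrogen atoms
#'
#' @param mol A [molecule()].
#' @return Integer count of heavy (non-H) atoms.
#' @export
heavy_atom_count <- function(mol) {
  sum(mol$atoms$element != "H")
}

is_heavy <- function(mol) mol$atoms$element != "H"

coords_matrix <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

#' Apply a rigid transform to a molecule
#'
#' @param mol A [molecule()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric translation (applied after rotation).
#' @return The transformed molecule.
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords_matrix(mol) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(mol, xyz)
}

#' Attach partial charges to a molecule
#'
#' Charges are data here, not computation: the native path imports a
#' per-atom table (in atom order); alternatively a registered provider
#' function may compute them. When the column sum misses `net_charge` by
#' more than `tol` but neutralization is allowed, a uniform per-atom shift
#' is applied (and reported via a message).
#'
#' @param mol A [molecule()].
#' @param charges Numeric vector (atom order), a data frame with columns
#'   `atom_index`/`charge`, a path to such a CSV, or the name of a
#'   registered provider (see [register_charge_provider()]).
#' @param net_charge Declared net charge; defaults to the molecule's.
#' @param neutralize Apply the uniform correction when the sum is off.
#' @param tol Tolerance on the charge sum (e).
#' @return The molecule with `atoms$charge` set.
#' @export
assign_charges <- function(mol, charges, net_charge = mol$net_charge,
                           neutralize = TRUE, tol = 1e-4) {
  q <- resolve_charges(mol, charges)
  if (length(q) != nrow(mol$atoms)) {
    abort(sprintf("charge table has %d rows but molecule has %d atoms",
                  length(q), nrow(mol$atoms)),
          class = "nucstack_alignment_error")
  }
  dq <- net_charge - sum(q)
  if (abs(dq) > tol) {
    if (!neutralize) {
      abort(sprintf("charges sum to %.6f, declared net charge %.6f", sum(q), net_charge),
            class = "nucstack_charge_error")
    }
    q <- q + dq / length(q)
    message(sprintf("neutralization: shifted each charge by %+.6f e", dq / length(q)))
  }
  mol$atoms$charge <- q
  mol$net_charge <- net_charge
  mol
}

resolve_charges <- function(mol, charges) {
  if (is.numeric(charges)) return(charges)
  if (is.data.frame(charges)) {
    if (!all(c("atom_index", "charge") %in% names(charges))) {
      abort("charge table needs columns atom_index, charge",
            class = "nucstack_schema_error")
    }
    return(charges$charge[order(charges$atom_index)])
  }
  if (is.character(charges) && length(charges) == 1) {
    if (file.exists(charges)) {
      tab <- readr::read_csv(charges, show_col_types = FALSE)
      return(resolve_charges(mol, tab))
    }
    prov <- charge_providers_env$providers[[charges]]
    if (is.null(prov)) {
      abort(paste0("unknown charge provider or missing file: ", charges),
            class = "nucstack_config_error")
    }
    return(prov(mol))
  }
  abort("cannot interpret `charges` argument", class = "nucstack_config_error")
}

charge_providers_env <- new.env(parent = emptyenv())
charge_providers_env$providers <- list()

#' Register a charge provider
#'
#' A provider is a function `mol -> numeric vector` of per-atom charges.
#' External engines (AM1-BCC, RESP, ...) plug in here; the package itself
#' only imports tables.
#'
#' @param name Provider name.
#' @param fun Function taking a molecule and returning per-atom charges.
#' @export
register_charge_provider <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  charge_providers_env$providers[[name]] <- fun
  invisible(name)
}

check_charge_sum <- function(mol, tol = 1e-6) {
  abs(sum(mol$atoms$charge) - mol$net_charge) <= tol
}
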