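#' Read a molecular structure file
#'
#' Supports plain XYZ, SDF (V2000) and the ATOM/HETATM coordinate subset of
#' PDB. Element symbols are normalized, coordinates are in Angstrom and
#' charges are zero-filled when the format carries none. Ring perception
#' uses the file's connectivity for SDF and distance-based bonding for
#' XYZ/PDB.
#'
#' @param path File path.
#' @param format One of `"xyz"`, `"sdf"`, `"pdb"`; guessed from the file
#'   extension when omitted.
#' @param name Molecule label; defaults to the file base name.
#' @return A [molecule()].
#' @export
read_structure <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "nucstack_format_error")
  }
  format <- format %||% tolower(tools::file_ext(path))
  name <- name %||% tools::file_path_sans_ext(basename(path))
  mol <- switch(format,
    xyz = read_xyz(path, name),
    sdf = read_sdf(path, name),
    pdb = read_pdb(path, name),
    abort(paste0("unsupported structure format: ", format),
          class = "nucstack_format_error")
  )
  mol
}

read_xyz <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    abort(paste0("malformed XYZ file (line 1): ", path),
          class = "nucstack_format_error")
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < n + 2) {
    abort(paste0("malformed XYZ header/body: ", path),
          class = "nucstack_format_error")
  }
  fields <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 4)
  if (length(bad) > 0) {
    abort(sprintf("malformed XYZ atom record at line %d", bad[1] + 2),
          class = "nucstack_format_error")
  }
  atoms <- suppressWarnings(tibble(
    element = vapply(fields, `[[`, character(1), 1),
    x = as.numeric(vapply(fields, `[[`, character(1), 2)),
    y = as.numeric(vapply(fields, `[[`, character(1), 3)),
    z = as.numeric(vapply(fields, `[[`, character(1), 4))
  ))
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    abort("non-numeric coordinate in XYZ file", class = "nucstack_format_error")
  }
  mol <- molecule(name, atoms)
  perceive_rings(mol)
}

read_sdf <- function(path, name) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("ChemmineR is required to read SDF files", class = "nucstack_config_error")
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path))[[1]],
    error = function(e) abort(paste0("malformed SDF file: ", conditionMessage(e)),
                              class = "nucstack_format_error")
  )
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  atoms <- tibble(element = elements,
                  x = ab[, 1], y = ab[, 2], z = ab[, 3])
  mol <- molecule(name, atoms)
  bonds <- tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]))
  bonds <- dplyr::mutate(bonds,
                         lo = pmin(.data$i, .data$j), hi = pmax(.data$i, .data$j))
  bonds <- tibble(i = bonds$lo, j = bonds$hi, r = NA_real_)
  perceive_rings(mol, bonds = bonds)
}

read_pdb <- function(path, name) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("bio3d is required to read PDB files", class = "nucstack_config_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path)),
    error = function(e) abort(paste0("malformed PDB file: ", conditionMessage(e)),
                              class = "nucstack_format_error")
  )
  at <- pdb$atom
  elements <- trimws(at$elesy)
  fallback <- elements == "" | is.na(elements)
  elements[fallback] <- substr(trimws(at$elety[fallback]), 1, 1)
  atoms <- tibble(element = elements, x = at$x, y = at$y, z = at$z)
  mol <- molecule(name, atoms)
  perceive_rings(mol)
}

#' Write a molecular structure file
#'
#' XYZ and SDF V2000 output. SDF bonds come from distance-based perception
#' (all written as single bonds; this package only needs connectivity).
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @param format `"xyz"` or `"sdf"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  lines <- switch(format,
    xyz = format_xyz(mol),
    sdf = format_sdf(mol),
    abort(paste0("unsupported output format: ", format),
          class = "nucstack_format_error")
  )
  writeLines(lines, path)
  invisible(path)
}

format_xyz <- function(mol) {
  a <- mol$atoms
  c(sprintf("%d", nrow(a)),
    mol$name,
    sprintf("%-2s %14.8f %14.8f %14.8f", a$element, a$x, a$y, a$z))
}

format_sdf <- function(mol) {
  a <- mol$atoms
  bonds <- perceive_bonds(mol)
  header <- c(mol$name, "  nucstack", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(bonds))
  atom_block <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, a$z, a$element)
  bond_block <- if (nrow(bonds) > 0) {
    sprintf("%3d%3d  1  0  0  0  0", bonds$i, bonds$j)
  } else character(0)
  c(header, counts, atom_block, bond_block, "M  END", "$$$$")
}

embedding_env <- new.env(parent = emptyenv())
embedding_env$providers <- list()

#' Register a 3D embedding provider for SMILES input
#'
#' A provider is a function `smiles -> molecule` (coordinates embedded,
#' no planarization required; [from_smiles()] planarizes afterwards).
#'
#' @param name Provider name.
#' @param fun Embedding function.
#' @export
register_embedding_provider <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  embedding_env$providers[[name]] <- fun
  invisible(name)
}

obabel_embed <- function(smiles) {
  if (Sys.which("obabel") == "") {
    abort("openbabel (obabel) not found on PATH", class = "nucstack_config_error")
  }
  out <- suppressWarnings(system2(
    "obabel", c(shQuote(paste0("-:", smiles)), "-oxyz", "--gen3d"),
    stdout = TRUE, stderr = TRUE
  ))
  converted <- any(grepl("1 molecule converted", out, fixed = TRUE))
  body <- out[!grepl("molecule(s)? converted|Open Babel|^==|^\\*{2}|Warning", out)]
  n <- suppressWarnings(as.integer(trimws(body[1])))
  if (!converted || is.na(n) || n < 1) {
    abort(paste0("SMILES parse/embedding failed: ", smiles),
          class = "nucstack_parse_error")
  }
  tmp <- tempfile(fileext = ".xyz")
  on.exit(unlink(tmp))
  writeLines(body[seq_len(n + 2)], tmp)
  read_xyz(tmp, smiles)
}

#' Build a 3D molecule from a SMILES string
#'
#' Coordinates come from a pluggable embedding provider (default:
#' `"openbabel"`, which shells out to the `obabel` CLI with `--gen3d`).
#' After embedding, every perceived planar ring is flattened by projecting
#' its atoms onto the ring's least-squares plane so aromatic ring atoms are
#' coplanar to well under 0.05 Angstrom.
#'
#' @param smiles A SMILES string.
#' @param name Molecule label; defaults to the SMILES itself.
#' @param provider Name of a registered embedding provider.
#' @return A [molecule()].
#' @export
#' @examples
#' \donttest{
#' if (Sys.which("obabel") != "") from_smiles("c1ccccc1", name = "benzene")
#' }
from_smiles <- function(smiles, name = smiles, provider = "openbabel") {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    abort("`smiles` must be a single non-empty string", class = "nucstack_parse_error")
  }
  fun <- embedding_env$providers[[provider]]
  if (is.null(fun)) {
    abort(paste0("unknown embedding provider: ", provider),
          class = "nucstack_config_error")
  }
  mol <- fun(smiles)
  mol$name <- name
  planarize_rings(perceive_rings(mol))
}

# project each ring's atoms onto the ring least-squares plane
planarize_rings <- function(mol) {
  if (length(mol$rings) == 0) return(mol)
  xyz <- coords_matrix(mol)
  for (ring in mol$rings) {
    pts <- xyz[ring, , drop = FALSE]
    ctr <- colMeans(pts)
    nv <- svd(sweep(pts, 2, ctr))$v[, 3]
    d <- sweep(pts, 2, ctr) %*% nv
    xyz[ring, ] <- pts - d %*% t(nv)
  }
  set_coords(mol, xyz)
}
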