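#' Reference descriptors of the five natural nucleobases
#'
#' Bundled ESP_range values (kcal/mol, DFT-derived descriptor constants)
#' and heavy-atom counts for adenine, guanine, cytosine, thymine and
#' uracil, so the maximum-stacking model can be used without any quantum
#' chemistry. The large ESP_range of G (reinforcing local dipoles of the
#' N: adjacent to the amide carbonyl) is what makes it the strongest
#' stacker; in A the imino-nitrogen dipoles largely cancel.
#'
#' @return Tibble with columns `base`, `n_ha`, `esp_range`.
#' @export
#' @examples
#' nucleobase_reference()
nucleobase_reference <- function() {
  tibble::tribble(
    ~base, ~n_ha, ~esp_range,
    "A", 10L, 13.1,
    "G", 11L, 24.3,
    "C",  8L, 22.8,
    "T",  9L, 16.1,
    "U",  8L, 17.7
  )
}

#' Load a bundled nucleobase geometry
#'
#' Idealized planar 3D structures of the five nucleobases (N9-H purines,
#' N1-H pyrimidines), generated from connectivity and flattened; the
#' glycosidic nitrogen is annotated so [canonical_frame()] can apply the
#' conventional orientation (glycosidic N in the lower left). These are
#' synthetic idealized geometries, not optimized quantum-chemistry
#' structures; they serve geometry, masking and pose machinery.
#'
#' @param base One of `"A"`, `"G"`, `"C"`, `"T"`, `"U"`.
#' @return A [molecule()] with `glycosidic_n` set.
#' @export
nucleobase <- function(base = c("A", "G", "C", "T", "U")) {
  base <- match.arg(base)
  dir <- system.file("extdata", "nucleobases", package = "nucstack")
  ann <- readr::read_csv(file.path(dir, "annotations.csv"), show_col_types = FALSE)
  row <- ann[ann$base == base, ]
  mol <- read_structure(file.path(dir, row$file), format = "xyz", name = row$name)
  mol$glycosidic_n <- row$glycosidic_n
  mol
}

#' Tautomerization energies of the annular tautomer pairs
#'
#' Six heterocycle tautomer pairs with the isolated-molecule
#' tautomerization energy `delta_e_het` and the corresponding stacked
#' values for each nucleobase (all kcal/mol; positive favors the first
#' tautomer). Used with [tautomer_shift()] to study how stacking with a
#' nucleobase shifts a tautomeric equilibrium.
#'
#' @return Tibble with columns `t1`, `t2`, `delta_e_het`, `A`, `C`, `G`,
#'   `T`, `U`.
#' @export
tautomer_table <- function() {
  path <- system.file("extdata", "tautomer_shifts.csv", package = "nucstack")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(t1 = "c", t2 = "c"))
}

#' Ribocil binding-site stacking energies
#'
#' Interaction energies (kcal/mol) of the three aromatic components of
#' ribocil with their stacking partners in the FMN riboswitch binding
#' site, alongside the maximum possible stacking interaction of the same
#' heterocycle-nucleobase pair (global-minimum dimer, or model prediction
#' where no optimized dimer exists). Feed rows to [stacking_efficiency()].
#'
#' @return Tibble with columns `component`, `partner`, `e_pose`, `e_max`,
#'   `e_max_source`.
#' @export
ribocil_poses <- function() {
  path <- system.file("extdata", "ribocil_poses.csv", package = "nucstack")
  readr::read_csv(path, show_col_types = FALSE)
}
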