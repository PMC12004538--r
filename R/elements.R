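#' Element property tables
#'
#' Bondi van der Waals radii and single-bond covalent radii (both in
#' Angstrom) for the elements that occur in druglike aromatic heterocycles
#' and nucleobases. The vdW set is used for the plane-projection mask and
#' for clash screening; the covalent set drives distance-based bond
#' perception for formats that carry no connectivity (XYZ).
#'
#' @return A tibble with columns `element`, `vdw`, `covalent`, `mass`.
#' @export
#' @examples
#' element_table()
element_table <- function() {
  tibble::tribble(
    ~element, ~vdw, ~covalent, ~mass,
    "H",  1.20, 0.31,  1.008,
    "C",  1.70, 0.76, 12.011,
    "N",  1.55, 0.71, 14.007,
    "O",  1.52, 0.66, 15.999,
    "F",  1.47, 0.57, 18.998,
    "P",  1.80, 1.07, 30.974,
    "S",  1.80, 1.05, 32.06,
    "Cl", 1.75, 1.02, 35.45,
    "Se", 1.90, 1.20, 78.971,
    "Br", 1.85, 1.20, 79.904,
    "I",  1.98, 1.39, 126.904
  )
}

normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

lookup_element <- function(elements, column = "vdw") {
  tab <- element_table()
  idx <- match(normalize_element(elements), tab$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")),
          class = "nucstack_element_error")
  }
  tab[[column]][idx]
}
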