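#' Read a dimer dataset table with a declared schema
#'
#' CSV ingestion for SI-shaped tables of poses with reference energies
#' and SAPT components. A schema (named character vector mapping the
#' canonical column names used throughout this package to the file's
#' column names) adapts external layouts without code changes. Canonical
#' columns: `pair_id`, `pose_id`, `e_bind`, `e_int`, `elec`, `exch`,
#' `ind`, `disp`, `het`, `base`, `dataset_tag`.
#'
#' @param path CSV path.
#' @param schema Named character vector, e.g.
#'   `c(pair_id = "PairID", e_int = "Eint")`. Identity for shared names.
#' @param check_components Verify elec+exch+ind+disp = e_int (1e-3
#'   kcal/mol) on rows where all five are present.
#' @return A tibble with canonical column names; attribute `provenance`
#'   records the source path.
#' @export
read_dataset <- function(path, schema = NULL, check_components = TRUE) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(tab)) {
        abort(paste0("schema column not in file: ", src),
              class = "nucstack_schema_error")
      }
      names(tab)[names(tab) == src] <- canon
    }
  }
  validate_dataset(tab, check_components = check_components)
  attr(tab, "provenance") <- path
  tab
}

#' Validate a dimer dataset table
#'
#' Checks the key uniqueness and (optionally) the SAPT decomposition
#' identity on complete rows.
#'
#' @param tab Dataset tibble.
#' @param check_components See [read_dataset()].
#' @param tol Component-sum tolerance (kcal/mol).
#' @return The table, invisibly; errors on violation.
#' @export
validate_dataset <- function(tab, check_components = TRUE, tol = 1e-3) {
  if (all(c("pair_id", "pose_id") %in% names(tab))) {
    key <- paste(tab$pair_id, tab$pose_id)
    if (anyDuplicated(key)) {
      abort("duplicate (pair_id, pose_id) keys", class = "nucstack_schema_error")
    }
  }
  comps <- c("elec", "exch", "ind", "disp")
  if (check_components && all(c(comps, "e_int") %in% names(tab))) {
    full <- stats::complete.cases(tab[, c(comps, "e_int")])
    if (any(full)) {
      s <- rowSums(tab[full, comps])
      off <- abs(s - tab$e_int[full]) > tol
      if (any(off)) {
        abort(sprintf("%d row(s) violate elec+exch+ind+disp = e_int (tol %g kcal/mol)",
                      sum(off), tol),
              class = "nucstack_data_error")
      }
    }
  }
  if ("dataset_tag" %in% names(tab)) {
    ok <- tab$dataset_tag %in% c("OSD", "NRSD", "FRSD", "other")
    if (!all(ok)) {
      abort("dataset_tag must be one of OSD, NRSD, FRSD, other",
            class = "nucstack_schema_error")
    }
  }
  invisible(tab)
}

#' Locate the external reference-data directory
#'
#' Full-scale reference tables (the published quantum-chemistry datasets) are not
#' bundled; when a copy is available locally, point this at it (option
#' `nucstack.data_dir` or argument) and the ingestion helpers will pick
#' the files up.
#'
#' @param path Optional override.
#' @return The directory path (may not exist).
#' @export
reference_data_dir <- function(path = getOption("nucstack.data_dir", NULL)) {
  path %||% file.path("data", "reference")
}
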