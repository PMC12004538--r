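#' Default element-keyed Lennard-Jones parameter table
#'
#' Generic aromatic-organic 12-6 parameters (r_min/2 in Angstrom, epsilon
#' in kcal/mol) keyed by element, in the AMBER A/B convention
#' (`A = eps * r_min^12`, `B = 2 * eps * r_min^6`). Real force-field
#' tables (GAFF/GAFF2/Sage exports) drop into the same schema via
#' [read_lj_table()]; sigma/epsilon tables must be converted with
#' `r_min = 2^(1/6) * sigma` at import.
#'
#' @return Tibble with columns `key`, `rmin_half`, `epsilon`.
#' @export
default_lj_table <- function() {
  tibble::tribble(
    ~key, ~rmin_half, ~epsilon,
    "H", 1.4590, 0.0150,
    "C", 1.9080, 0.0860,
    "N", 1.8240, 0.1700,
    "O", 1.6612, 0.2100,
    "S", 2.0000, 0.2500,
    "F", 1.7500, 0.0610,
    "Cl", 1.9480, 0.2650,
    "Br", 2.0200, 0.4200,
    "P", 2.1000, 0.2000
  )
}

#' Read a Lennard-Jones parameter table (CSV or JSON)
#'
#' @param path File path; CSV needs columns `key`, `rmin_half`,
#'   `epsilon`; JSON an array of objects with those fields.
#' @return Parameter tibble.
#' @export
read_lj_table <- function(path) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  need <- c("key", "rmin_half", "epsilon")
  if (!all(need %in% names(tab))) {
    abort("LJ table needs columns key, rmin_half, epsilon",
          class = "nucstack_schema_error")
  }
  if (any(tab$epsilon < 0) || any(tab$rmin_half <= 0)) {
    abort("LJ parameters out of range (epsilon >= 0, rmin_half > 0)",
          class = "nucstack_parameter_error")
  }
  tab
}

#' Attach per-atom Lennard-Jones parameters
#'
#' Atoms are matched by atom type when the molecule's atom table has a
#' `type` column with entries present in the table, falling back to the
#' element symbol.
#'
#' @param mol A [molecule()].
#' @param table Parameter tibble (see [default_lj_table()]) or a path
#'   accepted by [read_lj_table()].
#' @param source Label recorded on the molecule (parameter provenance).
#' @return The molecule with `atoms$rmin_half`, `atoms$epsilon` set.
#' @export
assign_lj <- function(mol, table = default_lj_table(), source = "element-default") {
  if (is.character(table)) table <- read_lj_table(table)
  keys <- if ("type" %in% names(mol$atoms)) {
    ifelse(mol$atoms$type %in% table$key, mol$atoms$type, mol$atoms$element)
  } else {
    mol$atoms$element
  }
  idx <- match(keys, table$key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf("no LJ parameters for atom %d (%s)", bad, keys[bad]),
          class = "nucstack_parameter_error")
  }
  mol$atoms$rmin_half <- table$rmin_half[idx]
  mol$atoms$epsilon <- table$epsilon[idx]
  mol$lj_source <- source
  mol
}

#' Intermolecular pair sums for the scaled MM potential
#'
#' Accumulates, over all intermolecular atom pairs of a stacked dimer:
#' the Coulomb energy `e_coul = sum 332.0637 q_i q_j / r_ij`; the
#' repulsive and attractive Lennard-Jones sums `s_rep = sum A_ij/r^12`
#' and `s_att = sum B_ij/r^6` restricted to heavy-heavy pairs; and the
#' unscaled LJ energy `e_vdw_h` of every pair involving a hydrogen.
#' Lorentz-Berthelot combination: `r_min_ij = rmin_half_i + rmin_half_j`,
#' `eps_ij = sqrt(eps_i * eps_j)`; `A = eps r_min^12`, `B = 2 eps r_min^6`.
#' Scaling constants only ever touch `s_rep`/`s_att`; hydrogen pairs stay
#' at the standard potential.
#'
#' @param dimer A `nucstack_dimer`, or a list of two [molecule()]s.
#' @return One-row tibble: `e_coul`, `s_rep`, `s_att`, `e_vdw_h`
#'   (kcal/mol), plus `r_min_pair` (closest intermolecular contact).
#' @export
pair_sums <- function(dimer) {
  mols <- if (inherits(dimer, "nucstack_dimer")) {
    list(dimer$nucleobase, dimer$heterocycle)
  } else dimer
  a <- mols[[1]]$atoms
  b <- mols[[2]]$atoms
  for (at in list(a, b)) {
    if (!all(c("rmin_half", "epsilon") %in% names(at))) {
      abort("assign_lj() both monomers before pair_sums()",
            class = "nucstack_parameter_error")
    }
  }
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 1e-6)) {
    abort("intermolecular atom pair at near-zero distance",
          class = "nucstack_singularity_error")
  }
  qq <- outer(a$charge, b$charge)
  e_coul <- sum(COULOMB_K * qq / r)
  rmin <- outer(a$rmin_half, b$rmin_half, "+")
  eps <- sqrt(outer(a$epsilon, b$epsilon))
  A <- eps * rmin^12
  B <- 2 * eps * rmin^6
  rep_term <- A / r^12
  att_term <- B / r^6
  heavy <- outer(a$element != "H", b$element != "H", "&")
  tibble(
    e_coul = e_coul,
    s_rep = sum(rep_term[heavy]),
    s_att = sum(att_term[heavy]),
    e_vdw_h = sum(rep_term[!heavy] - att_term[!heavy]),
    r_min_pair = min(r)
  )
}

#' Scaled MM interaction energy
#'
#' `E = e_coul + e_vdw_h + c_r * s_rep - c_a * s_att`. At
#' `c_r = c_a = 1` this is the standard fixed-charge Coulomb + 12-6 LJ
#' intermolecular interaction energy.
#'
#' @param sums Tibble of pair sums (rows vectorized).
#' @param c_r,c_a Dimensionless scaling constants for the heavy-atom-pair
#'   repulsive and attractive LJ sums.
#' @return Numeric vector of energies (kcal/mol).
#' @export
mm_interaction_energy <- function(sums, c_r = 1, c_a = 1) {
  sums$e_coul + sums$e_vdw_h + c_r * sums$s_rep - c_a * sums$s_att
}

#' Fit the heavy-atom-pair vdW scaling constants
#'
#' Solves the 2x2 normal equations minimizing
#' `sum (E_model(c_r, c_a) - E_ref)^2` over the dataset -- the global
#' optimum, since the model is linear in `(c_r, c_a)`. Reports RMSE and
#' r2 before (at `c_r = c_a = 1`) and after scaling; least squares can
#' never worsen the RMSE relative to the unscaled potential on the
#' fitting set.
#'
#' @param data Tibble with pair-sum columns (`e_coul`, `s_rep`, `s_att`,
#'   `e_vdw_h`) and the reference energies in `e_ref` (kcal/mol).
#' @param charge_source Label of the charge model behind `e_coul`; the
#'   fitted constants compensate in part for that electrostatic model and
#'   must not be silently reused with different charges.
#' @return Object of class `scaling_fit` with `c_r`, `c_a`,
#'   `rmse_before`, `rmse_after`, `r2_before`, `r2_after`, `n`,
#'   `charge_source`.
#' @export
fit_vdw_scaling <- function(data, charge_source = "unspecified") {
  if (nrow(data) < 2) {
    abort("need at least 2 rows to fit (c_r, c_a)", class = "nucstack_argument_error")
  }
  X <- cbind(rep_sum = data$s_rep, att_sum = -data$s_att)
  if (qr(X)$rank < 2) {
    abort("collinear s_rep/s_att columns; scaling constants not identifiable",
          class = "nucstack_degeneracy_error")
  }
  y <- data$e_ref - data$e_coul - data$e_vdw_h
  cc <- unname(coef(lm(y ~ 0 + X)))
  before <- mm_interaction_energy(data, 1, 1)
  after <- mm_interaction_energy(data, cc[1], cc[2])
  structure(
    list(c_r = cc[1], c_a = cc[2], n = nrow(data),
         rmse_before = rmse(before, data$e_ref),
         rmse_after = rmse(after, data$e_ref),
         r2_before = r2(before, data$e_ref),
         r2_after = r2(after, data$e_ref),
         charge_source = charge_source),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<vdW scaling fit (%s charges, n = %d): C_R = %.4f, C_A = %.4f; RMSE %.3f -> %.3f kcal/mol, r2 %.3f -> %.3f>\n",
              x$charge_source, x$n, x$c_r, x$c_a,
              x$rmse_before, x$rmse_after, x$r2_before, x$r2_after))
  invisible(x)
}

#' Evaluate a (scaled) MM potential on a labelled dataset
#'
#' @param data Tibble with pair-sum columns and `e_ref`.
#' @param c_r,c_a Scaling constants, or pass `fit` instead.
#' @param fit Optional `scaling_fit`; a warning is emitted when the
#'   dataset's `charge_source` attribute differs from the fit's (the
#'   constants are charge-model-specific).
#' @return One-row tibble with `rmse` and `r2`.
#' @export
evaluate_mm <- function(data, c_r = 1, c_a = 1, fit = NULL) {
  if (nrow(data) == 0) {
    abort("empty dataset", class = "nucstack_argument_error")
  }
  if (!is.null(fit)) {
    src <- attr(data, "charge_source")
    if (!is.null(src) && !identical(src, fit$charge_source)) {
      warn(sprintf("scaling constants were fit for '%s' charges but data uses '%s'",
                   fit$charge_source, src))
    }
    c_r <- fit$c_r
    c_a <- fit$c_a
  }
  pred <- mm_interaction_energy(data, c_r, c_a)
  tibble(rmse = rmse(pred, data$e_ref), r2 = r2(pred, data$e_ref))
}

#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble(term = c("c_r", "c_a"), estimate = c(x$c_r, x$c_a))
}

#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(nobs = x$n, charge_source = x$charge_source,
         rmse_before = x$rmse_before, rmse_after = x$rmse_after,
         r2_before = x$r2_before, r2_after = x$r2_after)
}
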