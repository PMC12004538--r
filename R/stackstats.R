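#' SAPT component correlations with the total interaction energy
#'
#' For each component X in (Elec, Exch, Ind, Disp): the squared Pearson
#' correlation r2(X, Total), and the leave-one-out value
#' r2(Total - X, Total) measuring how well the interaction energy is
#' captured without that component. A component is determinative when
#' removing it collapses the correlation (near-equilibrium dimers:
#' electrostatics and dispersion) and dispensable when removing it
#' strengthens it (induction, exchange).
#'
#' @param table Tibble with columns `elec`, `exch`, `ind`, `disp`,
#'   `total` (kcal/mol).
#' @return Tibble (`component`, `r2`, `r2_without`).
#' @export
component_correlations <- function(table) {
  need <- c("elec", "exch", "ind", "disp", "total")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("component table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "nucstack_schema_error")
  }
  if (nrow(table) < 3) {
    abort("need at least 3 rows for correlations", class = "nucstack_argument_error")
  }
  comps <- c("elec", "exch", "ind", "disp")
  purrr::map(comps, function(cmp) {
    tibble(component = cmp,
           r2 = r2(table[[cmp]], table$total),
           r2_without = r2(table$total - table[[cmp]], table$total))
  }) |> bind_rows()
}

#' Regress the total interaction energy on one component
#'
#' Ordinary least squares `total ~ component`; the residual RMSE says how
#' much of the interaction energy a single component predicts.
#'
#' @param table Component tibble (see [component_correlations()]).
#' @param component Column name, e.g. `"elec"`.
#' @return One-row tibble (`component`, `slope`, `intercept`, `rmse`).
#' @export
regress_on_component <- function(table, component = "elec") {
  if (nrow(table) < 3) {
    abort("need at least 3 rows", class = "nucstack_argument_error")
  }
  x <- table[[component]]
  if (is.null(x)) {
    abort(paste0("no such component column: ", component),
          class = "nucstack_schema_error")
  }
  if (sd(x) == 0) {
    abort("zero-variance predictor", class = "nucstack_degeneracy_error")
  }
  fit <- lm(table$total ~ x)
  res <- unname(fit$residuals)
  tibble(component = component,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         rmse = sqrt(mean(res^2)))
}

#' Summarize stacked local minima per heterocycle/nucleobase pair
#'
#' @param dataset Tibble with columns `het`, `base`, `energy` (binding
#'   energies of local minima, kcal/mol; negative = bound).
#' @return Tibble (`het`, `base`, `count`, `max_binding` = most negative
#'   energy, `mean_binding`). Empty groups are dropped with a warning.
#' @export
summarize_minima <- function(dataset) {
  need <- c("het", "base", "energy")
  missing_cols <- setdiff(need, names(dataset))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "nucstack_schema_error")
  }
  bad <- is.na(dataset$energy)
  if (any(bad)) {
    warn(sprintf("dropping %d rows with missing energies", sum(bad)))
    dataset <- dataset[!bad, ]
  }
  dataset |>
    group_by(.data$het, .data$base) |>
    summarise(count = dplyr::n(),
              max_binding = min(.data$energy),
              mean_binding = mean(.data$energy),
              .groups = "drop")
}

#' Cross-correlation of per-pair energies across nucleobases
#'
#' Squared Pearson correlations of per-heterocycle maximum (or mean)
#' energies between every pair of nucleobases: high values mean that
#' modifying a heterocycle shifts its stacking with all bases together,
#' so selectivity through stacking alone is hard.
#'
#' @param maxtable Tibble with columns `het`, `base`, `energy` (one row
#'   per heterocycle-base).
#' @return Symmetric r2 matrix (bases x bases, unit diagonal).
#' @export
base_cross_correlations <- function(maxtable) {
  wide <- tidyr::pivot_wider(maxtable[, c("het", "base", "energy")],
                             names_from = "base", values_from = "energy")
  if (anyNA(wide)) {
    abort("heterocycle sets differ between nucleobases",
          class = "nucstack_alignment_error")
  }
  bases <- setdiff(names(wide), "het")
  m <- diag(length(bases))
  dimnames(m) <- list(bases, bases)
  for (i in seq_along(bases)) {
    for (j in seq_along(bases)) {
      if (i < j) {
        v <- r2(wide[[bases[i]]], wide[[bases[j]]])
        m[i, j] <- m[j, i] <- v
      }
    }
  }
  m
}

#' Tautomerization energy within a stacked dimer
#'
#' Stacking with a nucleobase shifts a tautomeric equilibrium by the
#' difference of the two tautomers' global-minimum binding energies:
#' `dE(het...nuc) = dE(het) + (BE(t2...nuc) - BE(t1...nuc))`. A positive
#' isolated `dE(het)` with a negative result flags a swapped preferred
#' tautomer upon stacking.
#'
#' @param delta_e_het Isolated tautomerization energy (kcal/mol,
#'   positive favors tautomer 1).
#' @param be_t1,be_t2 Global-minimum binding energies of the two
#'   tautomers with the nucleobase (kcal/mol).
#' @return One-row tibble (`delta_e_stacked`, `swapped`).
#' @export
tautomer_shift <- function(delta_e_het, be_t1, be_t2) {
  vals <- c(delta_e_het, be_t1, be_t2)
  if (any(!is.finite(vals))) {
    abort("missing/non-finite energy", class = "nucstack_data_error")
  }
  d <- delta_e_het + (be_t2 - be_t1)
  tibble(delta_e_stacked = d, swapped = sign(d) != 0 & sign(d) != sign(delta_e_het))
}

#' Stacking efficiency of a binding pose
#'
#' The interaction energy a pose realizes as a percentage of the maximum
#' possible stacking interaction for the same heterocycle-nucleobase
#' pair, rounded (half away from zero) to the nearest integer percent.
#'
#' @param e_pose Pose interaction energy (kcal/mol, negative).
#' @param e_max Maximum (global-minimum) interaction energy (kcal/mol,
#'   negative).
#' @return Integer percent.
#' @export
#' @examples
#' stacking_efficiency(-8.3, -8.8)  # 94
#' stacking_efficiency(-4.9, -6.9)  # 71
stacking_efficiency <- function(e_pose, e_max) {
  if (any(e_max >= 0)) {
    abort("e_max must be negative (a bound dimer)", class = "nucstack_domain_error")
  }
  if (any(e_pose >= 0)) {
    abort("e_pose must be negative", class = "nucstack_domain_error")
  }
  pct <- 100 * e_pose / e_max
  as.integer(sign(pct) * floor(abs(pct) + 0.5))
}
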