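#' Feature maps for the maximum-stacking model
#'
#' The model of the maximum (global-minimum) stacking interaction is
#' linear in two fitted coefficients applied to a declared feature map of
#' the pair descriptors. The shipped `"bilinear"` map is
#' `E = c1 * (N_HA_het * N_HA_nuc) + c2 * (ESP_max_het * ESP_range_nuc)`:
#' a size-size product capturing dispersion growth with heavy-atom count,
#' and an electrostatic product coupling the heterocycle's ESP maximum to
#' the nucleobase's ESP range. Alternative algebraic forms can be
#' registered and selected by name, keeping fitting and prediction code
#' form-agnostic.
#'
#' @param name Map name.
#' @param fun Function `data -> two-column numeric matrix` (columns are
#'   the regressors multiplying c1 and c2).
#' @export
register_feature_map <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  feature_map_env$maps[[name]] <- fun
  invisible(name)
}

feature_map_env <- new.env(parent = emptyenv())
feature_map_env$maps <- list(
  bilinear = function(data) {
    need <- c("n_ha_het", "n_ha_nuc", "esp_max_het", "esp_range_nuc")
    missing_cols <- setdiff(need, names(data))
    if (length(missing_cols) > 0) {
      abort(paste0("feature table lacks column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "nucstack_feature_error")
    }
    cbind(size = data$n_ha_het * data$n_ha_nuc,
          esp = data$esp_max_het * data$esp_range_nuc)
  }
)

get_feature_map <- function(name) {
  fun <- feature_map_env$maps[[name]]
  if (is.null(fun)) {
    abort(paste0("unknown feature map: ", name), class = "nucstack_config_error")
  }
  fun
}

#' Fit the maximum-stacking model
#'
#' Linear least squares of observed global-minimum binding energies on
#' the two feature-map regressors (no intercept): the global RMSE
#' minimum for any form linear in the coefficients.
#'
#' @param data Tibble with the feature-map columns (for `"bilinear"`:
#'   `n_ha_het`, `n_ha_nuc`, `esp_max_het`, `esp_range_nuc`) and the
#'   observed energy column `energy` (kcal/mol, negative = binding).
#' @param feature_map Name of a registered feature map.
#' @return Object of class `maxstack_fit`: coefficients `c1`, `c2`,
#'   training `rmse` and `r2`, the feature-map name and row count.
#' @export
#' @examples
#' tab <- synth_maxstack_table(n = 50, seed = 1, c1 = -0.05, c2 = -0.01, noise_sigma = 0)
#' fit <- fit_max_stacking(tab)
#' glance(fit)
fit_max_stacking <- function(data, feature_map = "bilinear") {
  if (nrow(data) < 2) {
    abort("need at least 2 rows to fit two coefficients",
          class = "nucstack_argument_error")
  }
  X <- get_feature_map(feature_map)(data)
  if (qr(X)$rank < 2) {
    abort(paste0("rank-deficient design: columns ",
                 paste(colnames(X), collapse = ", "), " are collinear"),
          class = "nucstack_degeneracy_error")
  }
  y <- data$energy
  fit <- lm(y ~ 0 + X)
  cc <- unname(coef(fit))
  pred <- drop(X %*% cc)
  structure(
    list(c1 = cc[1], c2 = cc[2], feature_map = feature_map,
         n = nrow(data), rmse = rmse(pred, y), r2 = r2(pred, y),
         data = tibble::as_tibble(data)),
    class = "maxstack_fit"
  )
}

#' @export
print.maxstack_fit <- function(x, ...) {
  cat(sprintf("<maximum-stacking model ('%s'): c1 = %.6g, c2 = %.6g; training n = %d, RMSE = %.3f kcal/mol, r2 = %.3f>\n",
              x$feature_map, x$c1, x$c2, x$n, x$rmse, x$r2))
  invisible(x)
}

#' Predict maximum stacking interactions
#'
#' @param object A `maxstack_fit` (or list with `c1`, `c2`,
#'   `feature_map`).
#' @param newdata Tibble with the feature-map columns.
#' @param ... Unused.
#' @return Numeric vector of predicted energies (kcal/mol).
#' @export
predict.maxstack_fit <- function(object, newdata, ...) {
  X <- get_feature_map(object$feature_map %||% "bilinear")(newdata)
  drop(X %*% c(object$c1, object$c2))
}

#' Evaluate the maximum-stacking model on a labelled table
#'
#' @param fit A `maxstack_fit`.
#' @param data Tibble with feature columns and `energy`.
#' @return One-row tibble with `rmse` and `r2`.
#' @export
evaluate_max_stacking <- function(fit, data) {
  if (nrow(data) == 0) {
    abort("empty evaluation table", class = "nucstack_argument_error")
  }
  pred <- predict(fit, data)
  tibble(rmse = rmse(pred, data$energy), r2 = r2(pred, data$energy))
}

#' Screen a heterocycle library against the nucleobases
#'
#' One prediction per (heterocycle, nucleobase) pair from a heterocycle
#' descriptor table and a nucleobase reference table.
#'
#' @param library Tibble with columns `mol_id`, `n_ha`, `esp_max`.
#' @param fit A `maxstack_fit`.
#' @param nucleobases Tibble with `base`, `n_ha`, `esp_range`
#'   (default [nucleobase_reference()]).
#' @return Tibble (`mol_id`, `base`, `prediction`), one row per pair.
#' @export
screen_library <- function(library, fit, nucleobases = nucleobase_reference()) {
  need <- c("mol_id", "n_ha", "esp_max")
  missing_cols <- setdiff(need, names(library))
  if (length(missing_cols) > 0) {
    abort(paste0("library table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "nucstack_schema_error")
  }
  pairs <- tidyr::crossing(
    library[, need],
    nucleobases[, c("base", "n_ha", "esp_range")] |>
      rename(n_ha_nuc = "n_ha", esp_range_nuc = "esp_range")
  ) |>
    rename(n_ha_het = "n_ha", esp_max_het = "esp_max")
  pairs$prediction <- predict(fit, pairs)
  pairs[, c("mol_id", "base", "prediction")]
}

#' Per-nucleobase summary of a screening run
#'
#' @param screened Output of [screen_library()].
#' @return Tibble (`base`, `n`, `mean`, `min`, `max`) sorted by mean
#'   prediction (strongest stacker first).
#' @export
screen_summary <- function(screened) {
  screened |>
    group_by(.data$base) |>
    summarise(n = dplyr::n(), mean = mean(.data$prediction),
              min = min(.data$prediction), max = max(.data$prediction)) |>
    arrange(.data$mean)
}

rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

# squared Pearson correlation; degenerate variance reports 0 with a warning
r2 <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    warn("zero variance in correlation argument; r2 reported as 0")
    return(0)
  }
  cor(a, b)^2
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.maxstack_fit <- function(x, ...) {
  tibble(term = c("c1", "c2"), estimate = c(x$c1, x$c2))
}

#' @export
glance.maxstack_fit <- function(x, ...) {
  tibble(feature_map = x$feature_map, nobs = x$n, rmse = x$rmse, r.squared = x$r2)
}
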