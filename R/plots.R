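#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_raster
#'   geom_path scale_fill_gradient2 coord_equal labs theme_minimal
#' @export
ggplot2::autoplot

#' Predicted-versus-observed plot for a maximum-stacking fit
#'
#' @param object A `maxstack_fit`.
#' @param data Optional evaluation table (defaults to the training data).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maxstack_fit <- function(object, data = object$data, ...) {
  df <- tibble(observed = data$energy, predicted = predict(object, data))
  ggplot(df, aes(x = .data$predicted, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6) +
    coord_equal() +
    labs(x = "Predicted maximum stacking (kcal/mol)",
         y = "Computed binding energy (kcal/mol)") +
    theme_minimal()
}

#' Scaled-versus-reference energies for an MM scaling fit
#'
#' @param object A `scaling_fit`.
#' @param data Pair-sum dataset with `e_ref` (required; the fit stores
#'   only its summary).
#' @param ... Unused.
#' @return A ggplot, faceted into unscaled and scaled panels.
#' @export
autoplot.scaling_fit <- function(object, data, ...) {
  df <- bind_rows(
    tibble(model = "standard MM",
           predicted = mm_interaction_energy(data, 1, 1), reference = data$e_ref),
    tibble(model = "scaled MM",
           predicted = mm_interaction_energy(data, object$c_r, object$c_a),
           reference = data$e_ref)
  )
  ggplot(df, aes(x = .data$predicted, y = .data$reference)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~model) +
    labs(x = "MM interaction energy (kcal/mol)",
         y = "Reference interaction energy (kcal/mol)") +
    theme_minimal()
}

#' Plot a planar ESP field
#'
#' Raster of the ESP on the descriptor plane with the vdW-projection
#' outline; the conventional diverging scale runs red (negative) to blue
#' (positive).
#'
#' @param field A `nucstack_field`.
#' @param limit Symmetric colour limit (kcal/mol).
#' @param masked_only Blank out nodes outside the vdW projection.
#' @return A ggplot.
#' @export
plot_esp_field <- function(field, limit = 7.5, masked_only = FALSE) {
  df <- tidyr::expand_grid(ix = seq_along(field$x), iy = seq_along(field$y))
  df$x <- field$x[df$ix]
  df$y <- field$y[df$iy]
  df$esp <- field$values[cbind(df$ix, df$iy)]
  df$inside <- field$mask[cbind(df$ix, df$iy)]
  if (masked_only) df$esp[!df$inside] <- NA
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$esp)) +
    geom_raster() +
    scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                         limits = c(-limit, limit), oob = scales_squish,
                         name = "ESP\n(kcal/mol)") +
    coord_equal() +
    labs(x = "x (Å)", y = "y (Å)") +
    theme_minimal()
}

# minimal squish so scales isn't a hard dependency
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot stacking loci over the nucleobase frame
#'
#' @param assignments Output of [locus_assign()] (optionally row-bound
#'   over many dimers).
#' @param nuc The nucleobase [molecule()] for the heavy-atom outline.
#' @return A ggplot.
#' @export
plot_loci <- function(assignments, nuc) {
  nc <- canonical_frame(nuc)
  atoms <- nc$atoms[nc$atoms$element != "H", ]
  ggplot() +
    geom_point(data = atoms, aes(x = .data$x, y = .data$y),
               shape = 21, size = 4, fill = "grey85") +
    geom_point(data = assignments, aes(x = .data$x, y = .data$y),
               colour = "red", alpha = 0.6) +
    coord_equal() +
    labs(x = "x (Å)", y = "y (Å)") +
    theme_minimal()
}
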