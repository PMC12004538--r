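# shared in-code fixtures; everything is generated, nothing is downloaded

# asymmetric charged 5-ring with an apex carbon: no rotational symmetry,
# so canonical frames and pose round-trips are unambiguous
asym_het <- function() {
  assign_lj(toy_ring(5, radius = 1.2,
                     charges = c(0.15, -0.1, 0.05, -0.05, -0.05),
                     apex = TRUE, name = "asym_het"))
}

benzene_like <- function() {
  assign_lj(toy_ring(6, radius = 1.39, charges = c(0.1, -0.1), name = "benzene_like"))
}

# C6H6 with explicit ring + hydrogens, built from geometry (no embedding)
benzene_mol <- function() {
  ang <- 2 * pi * (0:5) / 6
  atoms <- tibble::tibble(
    element = c(rep("C", 6), rep("H", 6)),
    x = c(1.39 * cos(ang), 2.48 * cos(ang)),
    y = c(1.39 * sin(ang), 2.48 * sin(ang)),
    z = 0
  )
  molecule("benzene", atoms, rings = list(1:6))
}

random_rotation <- function() {
  axis <- rnorm(3)
  nucstack:::rotation_axis_angle(axis / sqrt(sum(axis^2)), runif(1, 0, 2 * pi))
}

expect_coords_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(nucstack:::coords_matrix(a) - nucstack:::coords_matrix(b))), tol)
}
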