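single_carbon <- function(q = 0) {
  molecule("c1", tibble::tibble(element = "C", x = 0, y = 0, z = 0, charge = q),
           net_charge = q)
}

test_that("vdW projection mask area matches circle geometry", {
  mol <- single_carbon()
  grid <- plane_grid(mol, spacing = 0.05)
  mask <- vdw_projection_mask(mol, grid)
  expect_equal(sum(mask) * 0.05^2, pi * 1.70^2, tolerance = 0.02)

  two <- molecule("two", tibble::tibble(
    element = c("C", "C"), x = c(0, 6), y = c(0, 0.5), z = 0))
  grid2 <- plane_grid(two, spacing = 0.05)
  expect_equal(sum(vdw_projection_mask(two, grid2)) * 0.05^2,
               2 * pi * 1.70^2, tolerance = 0.02)
  expect_error(
    vdw_projection_mask(molecule("none", tibble::tibble(
      element = character(), x = numeric(), y = numeric(), z = numeric()))),
    class = "nucstack_geometry_error"
  )
})

test_that("benzene mask area agrees with Monte-Carlo integration of the circle union", {
  mol <- benzene_mol()
  grid <- plane_grid(mol, spacing = 0.05)
  mask <- vdw_projection_mask(mol, grid)
  area_grid <- sum(mask) * 0.05^2
  canon <- canonical_frame(mol, nucleobase = FALSE)
  a <- canon$atoms
  box <- c(range(a$x - a$vdw, a$x + a$vdw), range(a$y - a$vdw, a$y + a$vdw))
  area_mc <- withr::with_seed(99, {
    px <- runif(2e5, box[1], box[2])
    py <- runif(2e5, box[3], box[4])
    inside <- rep(FALSE, length(px))
    for (k in seq_len(nrow(a))) {
      inside <- inside | (px - a$x[k])^2 + (py - a$y[k])^2 <= a$vdw[k]^2
    }
    mean(inside) * (box[2] - box[1]) * (box[4] - box[3])
  })
  expect_equal(area_grid, area_mc, tolerance = 0.01)
})

test_that("point-charge ESP reproduces the analytic Coulomb value", {
  mol <- single_carbon(q = 1)
  field <- esp_plane_point_charges(mol, height = 3.25, spacing = 0.1)
  iz <- which.min(abs(field$x))
  jz <- which.min(abs(field$y))
  expect_lt(abs(field$x[iz]) + abs(field$y[jz]), 1e-9)
  expect_equal(field$values[iz, jz], 332.0637 / 3.25, tolerance = 1e-9)
  expect_equal(max(field$values), 332.0637 / 3.25, tolerance = 1e-9)

  zero <- esp_plane_point_charges(single_carbon(0), height = 3.25)
  expect_true(all(zero$values == 0))
  expect_error(esp_plane_point_charges(mol, height = 0),
               class = "nucstack_argument_error")
})

test_that("grid ESP matches an independent double-loop summation", {
  withr::with_seed(5, {
    atoms <- tibble::tibble(
      element = "C",
      x = runif(5, -1.5, 1.5), y = runif(5, -1.5, 1.5), z = 0,
      charge = runif(5, -0.5, 0.5)
    )
  })
  mol <- molecule("rand5", atoms, net_charge = sum(atoms$charge))
  field <- esp_plane_point_charges(mol, height = 3.25, spacing = 0.25)
  canon <- canonical_frame(mol, nucleobase = FALSE)
  a <- canon$atoms
  ref <- matrix(0, length(field$x), length(field$y))
  for (i in seq_along(field$x)) {
    for (j in seq_along(field$y)) {
      for (k in seq_len(nrow(a))) {
        r <- sqrt((field$x[i] - a$x[k])^2 + (field$y[j] - a$y[k])^2 +
                    (3.25 - a$z[k])^2)
        ref[i, j] <- ref[i, j] + 332.0637 * a$charge[k] / r
      }
    }
  }
  expect_lt(max(abs(field$values - ref)), 1e-9)
})

test_that("point-charge ESP is linear in the charges", {
  q1 <- c(0.3, -0.2, 0.1, -0.1, -0.1, 0)
  q2 <- c(-0.05, 0.25, -0.3, 0.2, 0.05, -0.15)
  base <- toy_ring(6)
  f1 <- esp_plane_point_charges(assign_charges(base, q1, net_charge = sum(q1)),
                                spacing = 0.2)
  f2 <- esp_plane_point_charges(assign_charges(base, q2, net_charge = sum(q2)),
                                spacing = 0.2)
  f12 <- esp_plane_point_charges(assign_charges(base, q1 + q2, net_charge = sum(q1 + q2)),
                                 spacing = 0.2)
  expect_lt(max(abs(f12$values - (f1$values + f2$values))), 1e-9)
})

test_that("descriptor statistics summarize the masked field", {
  field <- structure(
    list(x = c(0, 1, 2), y = 0, height = 3.25, spacing = 1,
         values = matrix(c(-3, 0, 5), 3, 1),
         mask = matrix(TRUE, 3, 1), backend = "point-charge"),
    class = "nucstack_field"
  )
  mol <- toy_ring(3)
  d <- plane_descriptors(field, mol)
  expect_equal(d$esp_max, 5)
  expect_equal(d$esp_min, -3)
  expect_equal(d$esp_mean, 2 / 3)
  expect_equal(d$esp_range, 8)
  expect_equal(d$n_ha, 3)

  const <- field
  const$values <- matrix(4.2, 3, 1)
  dc <- plane_descriptors(const, mol)
  expect_equal(dc$esp_range, 0)
  expect_equal(dc$esp_mean, dc$esp_max)

  none <- field
  none$mask <- matrix(FALSE, 3, 1)
  expect_error(plane_descriptors(none, mol), class = "nucstack_mask_error")
})

test_that("descriptors are invariant under rigid motion and face-symmetric", {
  mol <- assign_charges(toy_ring(5, charges = c(0.2, -0.1, -0.1, 0.1, -0.1), apex = TRUE),
                        c(0.2, -0.1, -0.1, 0.1, -0.1, 0))
  ref <- esp_descriptors(mol, spacing = 0.2, face = 1)
  withr::with_seed(51, {
    moved <- transform_molecule(mol, random_rotation(), rnorm(3, sd = 4))
  })
  got <- esp_descriptors(moved, spacing = 0.2, face = 1)
  expect_equal(got$esp_max, ref$esp_max, tolerance = 1e-6)
  expect_equal(got$esp_range, ref$esp_range, tolerance = 1e-6)
  # planar molecule with in-plane charges: both faces identical
  both <- esp_descriptors(mol, spacing = 0.2, face = "both")
  expect_equal(both$esp_max[1], both$esp_max[2], tolerance = 1e-9)
  expect_equal(both$esp_mean[1], both$esp_mean[2], tolerance = 1e-9)
})

test_that("descriptors converge with grid refinement", {
  mol <- assign_charges(toy_ring(6, charges = c(0.15, -0.15)), rep(c(0.15, -0.15), 3))
  d1 <- esp_descriptors(mol, spacing = 0.1, face = 1)
  d2 <- esp_descriptors(mol, spacing = 0.05, face = 1)
  expect_lt(abs(d1$esp_max - d2$esp_max), 0.1)
  expect_lt(abs(d1$esp_range - d2$esp_range), 0.1)
})

test_that("cube ingestion interpolates onto the plane with unit conversion", {
  mol <- single_carbon(q = 1)
  n <- c(21, 21, 17)
  sp <- c(0.5, 0.5, 0.5)
  org <- c(-5, -5, -0.5)
  vals <- array(0, n)
  for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3]) {
    p <- org + (c(i, j, k) - 1) * sp
    vals[i, j, k] <- 7.5
  }
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(vals, org, sp, path)
  field <- esp_plane_from_cube(path, mol, height = 3.25, spacing = 0.5, convert = FALSE)
  expect_true(all(abs(field$values - 7.5) < 1e-4))
  # atomic-unit conversion applied once at the boundary
  fconv <- esp_plane_from_cube(path, mol, height = 3.25, spacing = 0.5, convert = TRUE)
  expect_equal(fconv$values[1, 1], 7.5 * 627.509, tolerance = 1e-3)
  expect_error(esp_plane_from_cube(path, mol, height = 30, spacing = 0.5),
               class = "nucstack_bounds_error")
})

test_that("cube of a point-charge field reproduces the analytic plane", {
  mol <- single_carbon(q = 1)
  sp <- c(0.1, 0.1, 0.1)
  n <- c(81, 81, 11)
  org <- c(-4, -4, 2.8)
  ax <- org[1] + (seq_len(n[1]) - 1) * sp[1]
  ay <- org[2] + (seq_len(n[2]) - 1) * sp[2]
  az <- org[3] + (seq_len(n[3]) - 1) * sp[3]
  r <- sqrt(outer(outer(ax^2, ay^2, "+"), az^2, "+"))
  vals <- 332.0637 / r
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(vals, org, sp, path)
  field <- esp_plane_from_cube(path, mol, height = 3.25, spacing = 0.1, convert = FALSE)
  canonical <- esp_plane_point_charges(mol, height = 3.25, spacing = 0.1)
  common_x <- field$x >= -3.5 & field$x <= 3.5
  common_y <- field$y >= -3.5 & field$y <= 3.5
  rel <- abs(field$values - canonical$values) / abs(canonical$values)
  expect_lt(max(rel[common_x, common_y]), 0.001)
})

test_that("malformed cube files raise format errors", {
  path <- withr::local_tempfile(fileext = ".cube")
  writeLines(c("a", "b", "bad"), path)
  expect_error(read_cube(path), class = "nucstack_format_error")
})
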