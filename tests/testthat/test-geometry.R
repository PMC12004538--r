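test_that("plane fit matches the SVD oracle and canonicalizes the normal", {
  hexagon <- toy_ring(6)
  pl <- fit_plane(hexagon)
  expect_equal(pl$rms, 0)
  expect_equal(pl$normal, c(0, 0, 1))

  lifted <- hexagon
  lifted$atoms$z[3] <- 0.3
  pl2 <- fit_plane(lifted)
  # independent check: total-least-squares residual from a direct SVD
  xyz <- nucstack:::coords_matrix(lifted)
  sv <- svd(sweep(xyz, 2, colMeans(xyz)))
  expect_equal(pl2$rms, sv$d[3] / sqrt(6), tolerance = 1e-12)

  two <- molecule("two", tibble::tibble(element = c("C", "C"),
                                        x = c(0, 1), y = 0, z = 0))
  expect_error(fit_plane(two), class = "nucstack_geometry_error")
  line <- molecule("line", tibble::tibble(element = rep("C", 4),
                                          x = 0:3, y = 0, z = 0))
  expect_error(fit_plane(line), class = "nucstack_geometry_error")
})

test_that("canonical frame is idempotent and rigid-transform invariant", {
  het <- asym_het()
  canon <- canonical_frame(het, nucleobase = FALSE)
  again <- canonical_frame(canon, nucleobase = FALSE)
  expect_coords_equal(canon, again, tol = 1e-9)
  withr::with_seed(21, {
    for (k in 1:5) {
      moved <- transform_molecule(het, random_rotation(), rnorm(3, sd = 10))
      expect_coords_equal(canonical_frame(moved, nucleobase = FALSE), canon, tol = 1e-6)
    }
  })
})

test_that("nucleobase canonical frame puts the glycosidic N in quadrant III", {
  for (b in c("A", "G", "C", "T", "U")) {
    nb <- canonical_frame(nucleobase(b))
    gn <- nb$atoms[nb$glycosidic_n, ]
    expect_lt(gn$x, 0)
    expect_lt(gn$y, 0)
  }
  anon <- toy_ring(6)
  expect_error(canonical_frame(anon, nucleobase = TRUE),
               class = "nucstack_annotation_error")
})

test_that("stacked dimers satisfy the parallel-plane and height guarantees", {
  het <- asym_het()
  nuc <- benzene_like()
  d <- place_stacked(het, nuc, stack_pose(0, 0, 3.25, 0))
  n1 <- fit_plane(d$nucleobase)$normal
  n2 <- fit_plane(d$heterocycle)$normal
  expect_lt(acos(pmin(1, abs(sum(n1 * n2)))), 1e-6)
  hctr <- colMeans(nucstack:::coords_matrix(d$heterocycle)[
    nucstack:::is_heavy(d$heterocycle), , drop = FALSE])
  expect_equal(unname(hctr), c(0, 0, 3.25), tolerance = 1e-6)

  d0 <- place_stacked(het, nuc, stack_pose(0.4, -0.2, 3.3, 0))
  d360 <- place_stacked(het, nuc, stack_pose(0.4, -0.2, 3.3, 360))
  expect_coords_equal(d0$heterocycle, d360$heterocycle, tol = 1e-9)
  expect_error(stack_pose(dz = 0), class = "nucstack_pose_error")
  expect_error(stack_pose(dz = -1), class = "nucstack_pose_error")
})

test_that("pose metrics invert pose construction on both faces", {
  het <- asym_het()
  nuc <- benzene_like()
  withr::with_seed(31, {
    for (k in 1:10) {
      pose <- stack_pose(runif(1, -2.5, 2.5), runif(1, -2.5, 2.5),
                         runif(1, 3, 3.5), runif(1, 0, 360),
                         face = sample(c(1, -1), 1))
      m <- pose_metrics(place_stacked(het, nuc, pose))
      expect_equal(m$dx, pose$dx, tolerance = 1e-6)
      expect_equal(m$dy, pose$dy, tolerance = 1e-6)
      expect_equal(m$separation, pose$dz, tolerance = 1e-6)
      dtheta <- (m$theta - pose$theta) %% 360
      expect_lt(min(dtheta, 360 - dtheta), 1e-6)
      expect_identical(m$face, pose$face)
      expect_lt(m$tilt, 1e-6)
    }
  })
})

test_that("pose metrics are invariant under rigid transforms of the dimer", {
  d <- place_stacked(asym_het(), benzene_like(), stack_pose(1.1, -0.7, 3.4, 123))
  ref <- pose_metrics(d)
  withr::with_seed(41, {
    for (k in 1:5) {
      moved <- transform_dimer(d, random_rotation(), rnorm(3, sd = 8))
      expect_equal(as.data.frame(pose_metrics(moved)), as.data.frame(ref),
                   tolerance = 1e-6)
    }
  })
})

test_that("a tilted heterocycle reports its tilt angle", {
  het <- canonical_frame(asym_het(), nucleobase = FALSE)
  nuc <- benzene_like()
  d <- place_stacked(het, nuc, stack_pose(0, 0, 3.4, 0))
  d$heterocycle <- transform_molecule(
    d$heterocycle, nucstack:::rotation_axis_angle(c(1, 0, 0), 10 * pi / 180))
  expect_equal(pose_metrics(d)$tilt, 10, tolerance = 1e-4)
})

test_that("FRSD sampling respects its bounds and is seed-reproducible", {
  het <- asym_het()
  nuc <- benzene_like()
  expect_equal(nrow(sample_frsd(het, nuc, 0, seed = 1)), 0)
  expect_error(sample_frsd(het, nuc, -1, seed = 1), class = "nucstack_argument_error")
  poses <- sample_frsd(het, nuc, 400, seed = 7)
  expect_true(all(abs(poses$dx) <= 2.5))
  expect_true(all(abs(poses$dy) <= 2.5))
  expect_true(all(poses$dz >= 3.0 & poses$dz <= 3.5))
  expect_true(all(poses$theta >= 0 & poses$theta < 360))
  expect_true(all(poses$face %in% c(1, -1)))
  again <- sample_frsd(het, nuc, 400, seed = 7)
  expect_identical(poses[, setdiff(names(poses), "dimer")],
                   again[, setdiff(names(again), "dimer")])
  # the constructed dimers actually realize the sampled poses
  m <- pose_metrics(poses$dimer[[17]])
  expect_equal(m$dx, poses$dx[17], tolerance = 1e-6)
  expect_equal(m$separation, poses$dz[17], tolerance = 1e-6)
})

test_that("NRSD perturbations stay within the stated deltas", {
  base <- place_stacked(asym_het(), benzene_like(), stack_pose(0.5, 0.5, 3.25, 30))
  out <- perturb_nrsd(base, 300, seed = 9)
  expect_true(all(abs(out$ddx) <= 0.5))
  expect_true(all(abs(out$ddy) <= 0.5))
  expect_true(all(abs(out$ddz) <= 0.25))
  expect_true(all(abs(out$dtheta) <= 15))
  expect_equal(out$dx, 0.5 + out$ddx)
  expect_equal(out$dz, 3.25 + out$ddz)
  frozen <- perturb_nrsd(base, 3, seed = 2, lateral_max = 0, vertical_max = 0, rot_max = 0)
  expect_equal(frozen$dx, rep(0.5, 3))
  expect_equal(frozen$dz, rep(3.25, 3))
  expect_equal(frozen$theta, rep(30, 3))
  expect_equal(nrow(perturb_nrsd(base, 0, seed = 1)), 0)
})

test_that("locus assignment matches an exhaustive nearest-feature search", {
  nuc <- nucleobase("A")
  het <- toy_ring(6)
  # directly over an atom
  nc <- canonical_frame(nuc)
  k <- which(nucstack:::is_heavy(nc))[4]
  d <- place_stacked(het, nuc, stack_pose(nc$atoms$x[k], nc$atoms$y[k], 3.3, 0))
  la <- locus_assign(d)
  expect_identical(la$feature, "atom")
  expect_identical(la$i, k)
  expect_lt(la$distance, 1e-9)
  # exhaustive oracle over random poses
  bonds <- perceive_bonds(nc)
  heavy <- which(nucstack:::is_heavy(nc))
  bonds <- bonds[bonds$i %in% heavy & bonds$j %in% heavy, ]
  feat_xy <- rbind(
    cbind(nc$atoms$x[heavy], nc$atoms$y[heavy]),
    cbind((nc$atoms$x[bonds$i] + nc$atoms$x[bonds$j]) / 2,
          (nc$atoms$y[bonds$i] + nc$atoms$y[bonds$j]) / 2)
  )
  poses <- sample_frsd(het, nuc, 50, seed = 12)
  for (r in seq_len(nrow(poses))) {
    la <- locus_assign(poses$dimer[[r]])
    dists <- sqrt((feat_xy[, 1] - la$x)^2 + (feat_xy[, 2] - la$y)^2)
    expect_equal(la$distance, min(dists), tolerance = 1e-9)
  }
  # midpoint of a bond
  b1 <- bonds[1, ]
  mx <- (nc$atoms$x[b1$i] + nc$atoms$x[b1$j]) / 2
  my <- (nc$atoms$y[b1$i] + nc$atoms$y[b1$j]) / 2
  d2 <- place_stacked(het, nuc, stack_pose(mx, my, 3.3, 0))
  la2 <- locus_assign(d2)
  expect_lt(la2$distance, 1e-9)
  expect_identical(la2$feature, "bond")
})
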