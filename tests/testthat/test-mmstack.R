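two_atom_dimer <- function(r, eps = 0.1, rmin_half = 1.8, q = c(0, 0),
                           elements = c("C", "C")) {
  a <- molecule("a", tibble::tibble(element = elements[1], x = 0, y = 0, z = 0,
                                    charge = q[1]), net_charge = q[1])
  b <- molecule("b", tibble::tibble(element = elements[2], x = 0, y = 0, z = r,
                                    charge = q[2]), net_charge = q[2])
  tab <- tibble::tibble(key = unique(elements), rmin_half = rmin_half, epsilon = eps)
  list(assign_lj(a, tab), assign_lj(b, tab))
}

test_that("the LJ pair at r_min contributes exactly -epsilon", {
  eps <- 0.137
  rmin <- 2 * 1.8
  s <- pair_sums(two_atom_dimer(rmin, eps = eps))
  expect_equal(s$s_rep - s$s_att, -eps, tolerance = 1e-12)
  expect_equal(s$e_coul, 0)
  expect_equal(s$e_vdw_h, 0)
})

test_that("pair sums match an independent double-loop reference", {
  het <- asym_het()
  nuc <- benzene_like()
  d <- place_stacked(het, nuc, stack_pose(0.8, -0.5, 3.3, 72))
  s <- pair_sums(d)
  a <- d$nucleobase$atoms
  b <- d$heterocycle$atoms
  e_coul <- s_rep <- s_att <- e_h <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
      e_coul <- e_coul + 332.0637 * a$charge[i] * b$charge[j] / r
      rmin <- a$rmin_half[i] + b$rmin_half[j]
      eps <- sqrt(a$epsilon[i] * b$epsilon[j])
      A <- eps * rmin^12
      B <- 2 * eps * rmin^6
      if (a$element[i] != "H" && b$element[j] != "H") {
        s_rep <- s_rep + A / r^12
        s_att <- s_att + B / r^6
      } else {
        e_h <- e_h + A / r^12 - B / r^6
      }
    }
  }
  expect_equal(s$e_coul, e_coul, tolerance = 1e-10)
  expect_equal(s$s_rep, s_rep, tolerance = 1e-10)
  expect_equal(s$s_att, s_att, tolerance = 1e-10)
  expect_equal(s$e_vdw_h, e_h, tolerance = 1e-10)
})

test_that("scaled energy at (1,1) equals the unsplit Coulomb + LJ sum", {
  het <- from_smiles("c1cc[nH]c1", name = "pyrrole")  # carries hydrogens
  q <- rep_len(c(0.04, -0.04), nrow(het$atoms))
  het <- assign_lj(assign_charges(het, q - mean(q), net_charge = 0))
  nuc <- assign_lj(assign_charges(benzene_mol(),
                                  rep(c(0.05, -0.05), 6), net_charge = 0))
  d <- place_stacked(het, nuc, stack_pose(0.3, 0.2, 3.4, 25))
  s <- pair_sums(d)
  e_split <- mm_interaction_energy(s, 1, 1)
  a <- d$nucleobase$atoms
  b <- d$heterocycle$atoms
  e_all <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
      rmin <- a$rmin_half[i] + b$rmin_half[j]
      eps <- sqrt(a$epsilon[i] * b$epsilon[j])
      e_all <- e_all + 332.0637 * a$charge[i] * b$charge[j] / r +
        eps * rmin^12 / r^12 - 2 * eps * rmin^6 / r^6
    }
  }
  expect_equal(e_split, e_all, tolerance = 1e-10)
})

test_that("energy is linear in the scaling constants with the right signs", {
  s <- pair_sums(place_stacked(asym_het(), benzene_like(), stack_pose(0, 0, 3.3, 10)))
  e11 <- mm_interaction_energy(s, 1, 1)
  e22 <- mm_interaction_energy(s, 2, 2)
  base <- s$e_coul + s$e_vdw_h
  expect_equal(e22 - base, 2 * (e11 - base), tolerance = 1e-12)
  # repulsive-only configuration is non-negative
  neutral <- toy_ring(6)
  d <- place_stacked(assign_lj(neutral), assign_lj(neutral), stack_pose(0, 0, 3.2, 15))
  s2 <- pair_sums(d)
  expect_gte(mm_interaction_energy(s2, 0.8, 0), 0)
})

test_that("pair sums are invariant under rigid transforms of the dimer", {
  d <- place_stacked(asym_het(), benzene_like(), stack_pose(1.2, 0.4, 3.3, 200))
  ref <- pair_sums(d)
  withr::with_seed(61, {
    moved <- transform_dimer(d, random_rotation(), rnorm(3, sd = 6))
  })
  expect_equal(as.data.frame(pair_sums(moved)), as.data.frame(ref),
               tolerance = 1e-9)
})

test_that("scaling constants are recovered from noise-free synthetic data", {
  data <- synth_mm_dataset(120, seed = 10, c_r = 0.9, c_a = 1.2, noise_sigma = 0)
  fit <- fit_vdw_scaling(data, charge_source = "synthetic")
  expect_equal(fit$c_r, 0.9, tolerance = 1e-9)
  expect_equal(fit$c_a, 1.2, tolerance = 1e-9)
  expect_lt(fit$rmse_after, 1e-9)
  # references equal to the unscaled energies recover (1, 1)
  ident <- synth_mm_dataset(60, seed = 11, c_r = 1, c_a = 1, noise_sigma = 0)
  fit1 <- fit_vdw_scaling(ident, charge_source = "synthetic")
  expect_equal(fit1$c_r, 1, tolerance = 1e-9)
  expect_equal(fit1$c_a, 1, tolerance = 1e-9)
  expect_lt(fit1$rmse_before, 1e-9)
})

test_that("normal-equation identities hold for the scaling fit", {
  data <- synth_mm_dataset(200, seed = 12, c_r = 0.85, c_a = 1.15, noise_sigma = 0.4)
  fit <- fit_vdw_scaling(data, charge_source = "synthetic")
  resid <- mm_interaction_energy(data, fit$c_r, fit$c_a) - data$e_ref
  scale_rep <- sqrt(sum(resid^2) * sum(data$s_rep^2))
  scale_att <- sqrt(sum(resid^2) * sum(data$s_att^2))
  expect_lt(abs(sum(resid * data$s_rep)) / scale_rep, 1e-8)
  expect_lt(abs(sum(resid * data$s_att)) / scale_att, 1e-8)
  expect_lte(fit$rmse_after, fit$rmse_before)
  expect_lte(fit$rmse_after, evaluate_mm(data, 1, 1)$rmse)
})

test_that("evaluation matches a streaming RMSE computation", {
  data <- synth_mm_dataset(50, seed = 14, c_r = 0.9, c_a = 1.2, noise_sigma = 0.3)
  ev <- evaluate_mm(data, 0.9, 1.2)
  pred <- mm_interaction_energy(data, 0.9, 1.2)
  acc <- 0
  for (i in seq_along(pred)) acc <- acc + (pred[i] - data$e_ref[i])^2
  expect_equal(ev$rmse, sqrt(acc / length(pred)), tolerance = 1e-12)
  expect_equal(ev$r2, cor(pred, data$e_ref)^2, tolerance = 1e-12)
  expect_error(evaluate_mm(data[0, ], 1, 1), class = "nucstack_argument_error")
})

test_that("cross-applying charge-specific constants warns", {
  data <- synth_mm_dataset(40, seed = 15, noise_sigma = 0.1)
  fit <- fit_vdw_scaling(data, charge_source = "HF-RESP")
  expect_warning(evaluate_mm(data, fit = fit), "synthetic")
})

test_that("LJ assignment maps atoms by element with clear failures", {
  ring <- toy_ring(6)
  uni <- assign_lj(ring, tibble::tibble(key = "C", rmin_half = 1.9, epsilon = 0.09))
  expect_equal(unique(uni$atoms$epsilon), 0.09)
  benz <- assign_lj(benzene_mol())
  expect_equal(nrow(benz$atoms), 12)
  expect_false(anyNA(benz$atoms$rmin_half))
  se <- molecule("se", tibble::tibble(element = c("C", "Se"),
                                      x = c(0, 2), y = 0, z = 0))
  expect_error(
    assign_lj(se, default_lj_table()[default_lj_table()$key %in% c("C", "H", "N", "O", "S"), ]),
    class = "nucstack_parameter_error"
  )
  expect_error(
    fit_vdw_scaling(tibble::tibble(s_rep = c(1, 2), s_att = c(2, 4),
                                   e_coul = 0, e_vdw_h = 0, e_ref = c(1, 2))),
    class = "nucstack_degeneracy_error"
  )
})
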