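#' Build a planar toy ring
#'
#' A regular polygon of carbons in the z = 0 plane (optionally with one
#' exocyclic apex atom to break rotational symmetry), with a declared
#' per-atom charge pattern. The workhorse of the synthetic-data
#' generators: every geometric invariant (plane fit rms 0, ring
#' perception) holds exactly.
#'
#' @param n_atoms Ring size (>= 3).
#' @param radius Circumradius (Angstrom); 1.39 gives benzene-like C-C
#'   distances for a hexagon.
#' @param charges Charge pattern, recycled around the ring (default 0).
#' @param apex Add one exocyclic carbon 1.5 Angstrom outside atom 1.
#' @param name Molecule label.
#' @return A [molecule()].
#' @export
#' @examples
#' toy_ring(6, radius = 1.39, charges = c(0.1, -0.1))
toy_ring <- function(n_atoms, radius = 1.39, charges = 0, apex = FALSE,
                     name = sprintf("ring%d", n_atoms)) {
  if (!is.numeric(n_atoms) || n_atoms < 3) {
    abort("a ring needs at least 3 atoms", class = "nucstack_argument_error")
  }
  n_atoms <- as.integer(n_atoms)
  ang <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
  atoms <- tibble(
    element = "C",
    x = radius * cos(ang), y = radius * sin(ang), z = 0,
    charge = rep_len(charges, n_atoms)
  )
  rings <- list(seq_len(n_atoms))
  if (apex) {
    atoms <- bind_rows(atoms, tibble(
      element = "C", x = radius + 1.5, y = 0, z = 0, charge = 0
    ))
  }
  molecule(name, atoms, rings = rings, net_charge = sum(atoms$charge))
}

#' Synthetic maximum-stacking training tables
#'
#' Random pair features (heterocycle heavy-atom counts uniform in 5..16,
#' ESP_max uniform between -10 and 40 kcal/mol, nucleobase constants from
#' [nucleobase_reference()]) with observations generated exactly from the
#' bilinear model plus Gaussian noise. Used for generative-recovery and
#' noise-consistency checks of [fit_max_stacking()].
#'
#' @param n Number of rows.
#' @param seed Integer seed (generator is a pure function of its inputs).
#' @param c1,c2 Ground-truth coefficients.
#' @param noise_sigma Gaussian noise sd (kcal/mol).
#' @return Tibble with feature columns and `energy`.
#' @export
synth_maxstack_table <- function(n, seed, c1 = -0.05, c2 = -0.011, noise_sigma = 0) {
  stopifnot(n >= 0, noise_sigma >= 0)
  nucs <- nucleobase_reference()
  withr::with_seed(seed, {
    pick <- sample.int(nrow(nucs), n, replace = TRUE)
    tab <- tibble(
      het_id = sprintf("synth_%04d", seq_len(n)),
      base = nucs$base[pick],
      n_ha_het = sample(5:16, n, replace = TRUE),
      esp_max_het = runif(n, -10, 40),
      n_ha_nuc = nucs$n_ha[pick],
      esp_range_nuc = nucs$esp_range[pick]
    )
    X <- get_feature_map("bilinear")(tab)
    tab$energy <- drop(X %*% c(c1, c2)) + rnorm(n, 0, noise_sigma)
    tab
  })
}

#' Synthetic MM dimer dataset with known scaling constants
#'
#' Fully random stacked poses of two charged toy rings; the reference
#' interaction energy of each pose is the scaled MM energy at known
#' ground-truth `(c_r, c_a)` plus Gaussian noise, so [fit_vdw_scaling()]
#' can be validated by generative recovery.
#'
#' @param n Number of poses.
#' @param seed Integer seed.
#' @param c_r,c_a Ground-truth scaling constants.
#' @param noise_sigma Gaussian noise sd (kcal/mol).
#' @return Tibble: pose parameters, pair-sum columns and `e_ref`; the
#'   `charge_source` attribute is set to `"synthetic"`.
#' @export
synth_mm_dataset <- function(n, seed, c_r = 0.9, c_a = 1.2, noise_sigma = 0) {
  stopifnot(n >= 0, noise_sigma >= 0)
  het <- assign_lj(toy_ring(5, radius = 1.2, charges = c(0.15, -0.1, 0.05, -0.05, -0.05),
                            apex = TRUE, name = "synth_het"))
  nuc <- assign_lj(toy_ring(6, radius = 1.39, charges = c(0.1, -0.1), name = "synth_nuc"))
  poses <- sample_frsd(het, nuc, n, seed = seed)
  if (n == 0) return(tibble())
  sums <- purrr::map(poses$dimer, pair_sums) |> bind_rows()
  out <- bind_cols(poses[, c("pose_id", "dx", "dy", "dz", "theta", "face")], sums)
  noise <- withr::with_seed(seed + 1L, rnorm(n, 0, noise_sigma))
  out$e_ref <- mm_interaction_energy(out, c_r, c_a) + noise
  attr(out, "charge_source") <- "synthetic"
  out
}

#' Synthetic SAPT-style component tables
#'
#' Components load on a shared latent factor: `X_k = loading_k * t +
#' N(0, sigma_k)` with `t ~ N(0, 1)`, and `total` is the row sum, so the
#' decomposition identity holds by construction while the strength of
#' each component's correlation with the total is controlled by its
#' loading/noise ratio.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param loadings Named numeric (elec, exch, ind, disp).
#' @param sigmas Component noise sds, same names.
#' @return Tibble (`pair_id`, `pose_id`, `elec`, `exch`, `ind`, `disp`,
#'   `total`).
#' @export
synth_component_table <- function(n, seed,
                                  loadings = c(elec = 1, exch = -0.4, ind = 0.2, disp = 0.6),
                                  sigmas = c(elec = 0.3, exch = 0.3, ind = 0.3, disp = 0.3)) {
  comps <- c("elec", "exch", "ind", "disp")
  loadings <- loadings[comps]
  sigmas <- sigmas[comps]
  if (anyNA(loadings) || anyNA(sigmas)) {
    abort("loadings and sigmas must name elec, exch, ind, disp",
          class = "nucstack_argument_error")
  }
  if (all(loadings == 0) && all(sigmas == 0)) {
    abort("degenerate correlation structure: all loadings and noise zero",
          class = "nucstack_feasibility_error")
  }
  withr::with_seed(seed, {
    t <- rnorm(n)
    tab <- tibble(pair_id = sprintf("pair_%04d", seq_len(n)),
                  pose_id = sprintf("pose_%04d", seq_len(n)))
    for (k in comps) {
      tab[[k]] <- loadings[[k]] * t + rnorm(n, 0, sigmas[[k]])
    }
    tab$total <- tab$elec + tab$exch + tab$ind + tab$disp
    tab
  })
}

#' Bundled SI-shaped mini-tables
#'
#' Small deterministic tables in the exact schemas the dataset ingesters
#' expect, for integration tests without any download: an energies table
#' (8 heterocycle/nucleobase pairs x 5 poses; SAPT components summing to
#' the interaction energy), a per-pair minima table and a descriptor
#' table. All values are synthetic.
#'
#' @return Named list of tibbles: `energies`, `descriptors`, plus
#'   `pair_count` (poses per pair, documented for the fixture tests).
#' @export
si_fixture <- function() {
  hets <- sprintf("het%02d", 1:4)
  bases <- c("A", "G")
  comps <- synth_component_table(40, seed = 4242,
                                 loadings = c(elec = 1.2, exch = -0.5, ind = 0.3, disp = 0.8))
  grid <- tidyr::crossing(het = hets, base = bases, pose = 1:5)
  energies <- tibble(
    pair_id = paste(grid$het, grid$base, sep = "_"),
    pose_id = sprintf("min_%d", grid$pose),
    het = grid$het, base = grid$base,
    # shift the electrostatic component down so the rows look bound while
    # the decomposition identity elec+exch+ind+disp = e_int holds exactly
    elec = comps$elec - 8, exch = comps$exch, ind = comps$ind, disp = comps$disp,
    e_int = comps$total - 8,
    e_bind = comps$total - 8 + 0.4,
    dataset_tag = "OSD"
  )
  descriptors <- withr::with_seed(4243, tibble(
    mol_id = hets,
    n_ha = sample(5:11, 4),
    esp_max = runif(4, 5, 35),
    esp_min = runif(4, -25, -5)
  )) |>
    mutate(esp_mean = (.data$esp_max + .data$esp_min) / 2,
           esp_range = .data$esp_max - .data$esp_min,
           face = 1, backend = "synthetic")
  list(energies = energies, descriptors = descriptors, pair_count = 5L)
}
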