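#' Sample fully random stacked dimers (FRSD)
#'
#' Random parallel stacked poses with lateral displacements up to
#' +/-2.5 Angstrom along each axis, vertical separations uniform in
#' 3.25 +/- 0.25 Angstrom, uniformly random orientation about the
#' vertical axis, and the heterocycle face drawn uniformly. Poses whose
#' minimum intermolecular heavy-atom distance falls below `clash_cut`
#' are flagged (never rejected, so the requested count is preserved).
#'
#' @param het,nuc Heterocycle and nucleobase [molecule()]s.
#' @param n Number of poses (>= 0).
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @param lateral_max,dz_min,dz_max Sampling bounds (Angstrom).
#' @param clash_cut Heavy-heavy clash threshold (Angstrom).
#' @return A tibble with columns `pose_id`, `dx`, `dy`, `dz`, `theta`,
#'   `face`, `clash_flag` and a list-column `dimer` of `nucstack_dimer`s.
#' @export
sample_frsd <- function(het, nuc, n, seed, lateral_max = 2.5,
                        dz_min = 3.0, dz_max = 3.5, clash_cut = 2.0) {
  if (!is.numeric(n) || length(n) != 1 || n < 0) {
    abort("`n` must be a single non-negative count", class = "nucstack_argument_error")
  }
  n <- as.integer(n)
  if (n == 0) return(empty_pose_table())
  draws <- withr::with_seed(seed, tibble(
    dx = runif(n, -lateral_max, lateral_max),
    dy = runif(n, -lateral_max, lateral_max),
    dz = runif(n, dz_min, dz_max),
    theta = runif(n, 0, 360),
    face = sample(c(1, -1), n, replace = TRUE)
  ))
  build_pose_table(het, nuc, draws, prefix = "frsd", clash_cut = clash_cut)
}

#' Perturb a stacked dimer into nearby random poses (NRSD)
#'
#' Each output pose displaces the input randomly by up to +/-0.5 Angstrom
#' along each lateral axis and +/-0.25 Angstrom vertically, and rotates it
#' by a random angle up to +/-15 degrees about the vertical axis.
#'
#' @param dimer A `nucstack_dimer` (typically an optimized minimum).
#' @param n Number of perturbed copies (>= 0).
#' @param seed Integer seed.
#' @param lateral_max,vertical_max Displacement bounds (Angstrom).
#' @param rot_max Rotation bound (degrees).
#' @param clash_cut Heavy-heavy clash threshold (Angstrom).
#' @return Same shape as [sample_frsd()], plus columns `ddx`, `ddy`,
#'   `ddz`, `dtheta` holding the applied deltas.
#' @export
perturb_nrsd <- function(dimer, n, seed, lateral_max = 0.5,
                         vertical_max = 0.25, rot_max = 15, clash_cut = 2.0) {
  if (!is.numeric(n) || length(n) != 1 || n < 0) {
    abort("`n` must be a single non-negative count", class = "nucstack_argument_error")
  }
  n <- as.integer(n)
  if (n == 0) {
    out <- empty_pose_table()
    out$ddx <- out$ddy <- out$ddz <- out$dtheta <- numeric(0)
    return(out)
  }
  p <- dimer$pose
  deltas <- withr::with_seed(seed, tibble(
    ddx = runif(n, -lateral_max, lateral_max),
    ddy = runif(n, -lateral_max, lateral_max),
    ddz = runif(n, -vertical_max, vertical_max),
    dtheta = runif(n, -rot_max, rot_max)
  ))
  draws <- tibble(
    dx = p$dx + deltas$ddx, dy = p$dy + deltas$ddy,
    dz = p$dz + deltas$ddz, theta = (p$theta + deltas$dtheta) %% 360,
    face = rep(p$face, n)
  )
  out <- build_pose_table(dimer$heterocycle, dimer$nucleobase, draws,
                          prefix = "nrsd", clash_cut = clash_cut)
  dplyr::bind_cols(out, deltas)
}

empty_pose_table <- function() {
  tibble(pose_id = character(), dx = numeric(), dy = numeric(),
         dz = numeric(), theta = numeric(), face = numeric(),
         clash_flag = logical(), dimer = list())
}

build_pose_table <- function(het, nuc, draws, prefix, clash_cut) {
  nuc_c <- canonical_frame(nuc)
  het_c <- canonical_frame(het, nucleobase = FALSE)
  dimers <- purrr::pmap(draws, function(dx, dy, dz, theta, face) {
    place_canonical(het_c, nuc_c, stack_pose(dx, dy, dz, theta, face))
  })
  ids <- sprintf("%s_%04d", prefix, seq_len(nrow(draws)))
  dimers <- purrr::map2(dimers, ids, function(d, id) { d$pose_id <- id; d })
  tibble(
    pose_id = ids,
    dx = draws$dx, dy = draws$dy, dz = draws$dz,
    theta = draws$theta, face = draws$face,
    clash_flag = purrr::map_dbl(dimers, min_heavy_distance) < clash_cut,
    dimer = dimers
  )
}
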