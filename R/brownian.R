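#' Configuration for Brownian ligand-binding simulations
#'
#' Describes an overdamped ligand diffusing in a cubic box with reflecting
#' walls and a flat-bottom spherical attractive well, past a set of fixed
#' receptor atoms.  This emulates the statistics of free-ligand binding runs:
#' long diffusive excursions in bulk punctuated by residence inside the well.
#'
#' The potential is `-well_depth` inside the inner sphere of radius
#' `0.8 * well_radius` and ramps smoothly (half-cosine) to zero at
#' `well_radius`, so the force is continuous everywhere.
#'
#' @param box_edge Cubic box edge, Angstrom.
#' @param diffusion_coeff Diffusion coefficient, Angstrom^2/ns.
#' @param well_center Length-3 vector, Angstrom; must lie inside the box.
#' @param well_depth Well depth, kcal/mol, `>= 0`.
#' @param well_radius Well radius, Angstrom, `> 0`.
#' @param receptor_atoms `p x 3` matrix of fixed receptor coordinates inside
#'   the box.
#' @param dt Time step, ns; the RMS free-diffusion step `sqrt(6 D dt)` must be
#'   below `well_radius / 4` so the well is resolved.
#' @param temperature Kelvin.
#' @param seed Integer seed.
#' @return A `brownian_config` object.
#' @export
brownian_config <- function(box_edge, diffusion_coeff, well_center, well_depth,
                            well_radius, receptor_atoms, dt,
                            temperature = 298, seed = 0L) {
  check_scalar_positive(box_edge, "box_edge")
  check_scalar_positive(diffusion_coeff, "diffusion_coeff")
  check_scalar_positive(well_radius, "well_radius")
  check_scalar_positive(dt, "dt")
  check_scalar_positive(temperature, "temperature")
  if (!is.numeric(well_depth) || length(well_depth) != 1L || well_depth < 0) {
    stop_ligandmsm("`well_depth` must be a single number >= 0")
  }
  well_center <- as.numeric(well_center)
  if (length(well_center) != 3L || any(well_center < 0) ||
      any(well_center > box_edge)) {
    stop_ligandmsm("`well_center` must be a 3-vector inside the box")
  }
  receptor_atoms <- as.matrix(receptor_atoms)
  if (ncol(receptor_atoms) != 3L || any(receptor_atoms < 0) ||
      any(receptor_atoms > box_edge)) {
    stop_ligandmsm("`receptor_atoms` must be a p x 3 matrix inside the box")
  }
  rms_step <- sqrt(6 * diffusion_coeff * dt)
  if (rms_step >= well_radius / 4) {
    stop_ligandmsm(sprintf(
      "time step too large: RMS step %.3g A >= well_radius/4 = %.3g A",
      rms_step, well_radius / 4))
  }
  structure(
    list(box_edge = box_edge, diffusion_coeff = diffusion_coeff,
         well_center = well_center, well_depth = well_depth,
         well_radius = well_radius, receptor_atoms = receptor_atoms,
         dt = dt, temperature = temperature, seed = check_seed(seed)),
    class = "brownian_config"
  )
}

# radial force magnitude dU/dr at radius r (flat bottom + half-cosine ramp
# over the outer 20% of the well radius); returns the vector force on the
# ligand given displacement `dx` (rows) from the well center
well_force <- function(dx, depth, r0) {
  r <- sqrt(rowSums(dx^2))
  inner <- 0.8 * r0
  w <- r0 - inner
  ramp <- r > inner & r < r0
  f <- numeric(length(r))
  # U(r) = -depth/2 * (1 + cos(pi (r - inner)/w)) on the ramp
  f[ramp] <- depth * pi / (2 * w) * sin(pi * (r[ramp] - inner) / w)
  # -grad U = -dU/dr * r_hat ; dU/dr = f above, force points inward
  g <- matrix(0, nrow(dx), 3)
  nz <- ramp & r > 0
  g[nz, ] <- -f[nz] / r[nz] * dx[nz, , drop = FALSE]
  g
}

reflect_into_box <- function(x, L) {
  # fold coordinates into [0, L] by repeated reflection
  x <- x %% (2 * L)
  over <- x > L
  x[over] <- 2 * L - x[over]
  x
}

#' Simulate Brownian ligand-binding trajectories
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' `x <- x + sqrt(2 D dt) xi - (D dt / kB T) grad U(x)` with reflecting walls.
#' Ligands start uniformly distributed in the box outside the well, mirroring
#' binding simulations that place the free ligand away from the receptor.
#'
#' @param config A [brownian_config()].
#' @param n_traj Number of independent ligand trajectories.
#' @param n_frames Frames per trajectory.
#' @return List with one element per trajectory, each a list with `ligand`
#'   (`n_frames x 3` coordinates, Angstrom) and `receptor` (the fixed
#'   receptor coordinates).
#' @export
brownian_binding_trajectories <- function(config, n_traj, n_frames) {
  if (!inherits(config, "brownian_config")) {
    stop_ligandmsm("`config` must be a brownian_config")
  }
  n_traj <- check_count(n_traj, "n_traj")
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  L <- config$box_edge
  D <- config$diffusion_coeff
  dt <- config$dt
  kT <- .R_KCAL * config$temperature
  sigma <- sqrt(2 * D * dt)
  drift <- D * dt / kT
  withr::with_seed(config$seed, {
    lapply(seq_len(n_traj), function(i) {
      # start outside the well
      repeat {
        x0 <- runif(3, 0, L)
        if (sqrt(sum((x0 - config$well_center)^2)) > config$well_radius) break
      }
      xyz <- matrix(0, n_frames, 3)
      xyz[1, ] <- x0
      x <- x0
      noise <- matrix(rnorm(3L * (n_frames - 1L), sd = sigma),
                      ncol = 3)
      for (t in 2:n_frames) {
        f <- well_force(matrix(x - config$well_center, 1), config$well_depth,
                        config$well_radius)
        x <- x + noise[t - 1L, ] + drift * as.numeric(f)
        x <- reflect_into_box(x, L)
        xyz[t, ] <- x
      }
      list(ligand = xyz, receptor = config$receptor_atoms)
    })
  })
}
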