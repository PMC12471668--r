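#' Specification of the synthetic Langevin channel world
#'
#' Describes a population of thermalised, non-interacting tagged particles
#' moving along the axis of a finite channel flanked by bulk reservoirs:
#' a configurable potential of mean force over the channel slab (flat in the
#' reservoirs), reflecting outer walls, an inertial Langevin thermostat so
#' that stationary velocities are Maxwell-Boltzmann, and optionally a
#' confining cylinder for 3-D runs or a no-passing (single-file) constraint.
#'
#' @param temperature Temperature (K).
#' @param n_particles Number of tagged particles.
#' @param box_z Full axial box length (Angstrom); reflecting walls at
#'   `+/- box_z/2`. The default leaves ~30 A reservoirs beyond the channel.
#' @param channel_halfwidth Half-width of the channel slab (Angstrom); maps
#'   to the bulk thresholds `z = +/- channel_halfwidth`.
#' @param barrier_height Height of a single Gaussian barrier at z = 0
#'   (kcal/mol); 0 gives a flat potential.
#' @param barrier_width Gaussian barrier standard deviation (Angstrom).
#' @param potential Optional data frame with columns `z` (Angstrom) and `U`
#'   (kcal/mol) defining an arbitrary piecewise-linear axial potential,
#'   added to the Gaussian term and extrapolated flat beyond its range.
#' @param mass Particle mass (g/mol; default water).
#' @param friction Langevin friction (1/ps; default 10, liquid-like
#'   diffusivity).
#' @param dt Integration time step (ps; default 0.002, the MD convention).
#' @param n_steps Default number of steps for [simulate_langevin()].
#' @param save_stride Store every `save_stride`-th step.
#' @param seed Master RNG seed (single stream; chunked continuation
#'   reproduces a single long run bit-exactly).
#' @param lateral_mode `"none"` (1-D) or `"cylinder"` (3-D with a reflecting
#'   confining cylinder of radius `lateral_radius`).
#' @param lateral_radius Confining cylinder radius (Angstrom).
#' @param single_file Enforce a no-passing constraint: stored frames are
#'   order statistics of the free ensemble, so particle order along z is
#'   preserved (hard-core exclusion in the point-particle limit).
#' @param sigma Nominal exclusion diameter recorded with single-file output
#'   (Angstrom).
#' @return An object of class `langevin_spec`.
#' @export
langevin_spec <- function(temperature = 298.15, n_particles = 100,
                          box_z = 90, channel_halfwidth = 15,
                          barrier_height = 0, barrier_width = 2,
                          potential = NULL, mass = 18.01528, friction = 10,
                          dt = 0.002, n_steps = 10000, save_stride = 1,
                          seed = 1, lateral_mode = c("none", "cylinder"),
                          lateral_radius = 6, single_file = FALSE,
                          sigma = 2.8) {
  lateral_mode <- match.arg(lateral_mode)
  stopifnot(temperature > 0, n_particles >= 1, dt > 0, friction >= 0,
            save_stride >= 1, box_z > 0, channel_halfwidth > 0,
            channel_halfwidth < box_z / 2, mass > 0, barrier_width > 0)
  if (single_file && sigma <= 0) stop("single_file mode requires sigma > 0")
  if (!is.null(potential)) {
    stopifnot(is.data.frame(potential), all(c("z", "U") %in% names(potential)))
  }
  structure(
    list(temperature = temperature, n_particles = as.integer(n_particles),
         box_z = box_z, channel_halfwidth = channel_halfwidth,
         barrier_height = barrier_height, barrier_width = barrier_width,
         potential = potential, mass = mass, friction = friction, dt = dt,
         n_steps = as.integer(n_steps), save_stride = as.integer(save_stride),
         seed = as.integer(seed), lateral_mode = lateral_mode,
         lateral_radius = lateral_radius, single_file = single_file,
         sigma = sigma),
    class = "langevin_spec"
  )
}

#' @export
print.langevin_spec <- function(x, ...) {
  cat(sprintf("Langevin spec: %d particles, T = %g K, box +/-%g A, slab +/-%g A\n",
              x$n_particles, x$temperature, x$box_z / 2, x$channel_halfwidth))
  cat(sprintf("  barrier %g kcal/mol (sd %g A), friction %g /ps, dt %g ps, seed %d\n",
              x$barrier_height, x$barrier_width, x$friction, x$dt, x$seed))
  invisible(x)
}

# Potential (kcal/mol) evaluated on a vector of z.
langevin_potential <- function(spec, z) {
  U <- numeric(length(z))
  if (spec$barrier_height != 0) {
    U <- U + spec$barrier_height * exp(-z^2 / (2 * spec$barrier_width^2))
  }
  if (!is.null(spec$potential)) {
    p <- spec$potential[order(spec$potential$z), ]
    f <- stats::approxfun(p$z, p$U, rule = 2)
    U <- U + f(z)
  }
  U
}

# Acceleration table (A/ps^2) on a uniform grid spanning the box.
langevin_accel_table <- function(spec, h = 0.01) {
  cst <- physical_constants()
  half <- spec$box_z / 2
  zg <- seq(-half - 2 * h, half + 2 * h, by = h)
  U <- langevin_potential(spec, zg)
  # centred finite-difference force; flat extrapolation at the ends
  dU <- c(0, (U[-(1:2)] - U[1:(length(U) - 2)]) / (2 * h), 0)
  list(acc = -dU * cst$kcal_internal / spec$mass, z0 = zg[1], h = h, U = U,
       z = zg)
}

# dt stability diagnostics relative to friction and barrier curvature.
langevin_check_stability <- function(spec, tab) {
  cst <- physical_constants()
  if (spec$friction * spec$dt > 0.5) {
    warning(sprintf("friction*dt = %.3g is marginal for the BAOAB velocity step",
                    spec$friction * spec$dt))
  }
  U <- tab$U
  if (length(U) > 2) {
    d2 <- max(abs(diff(U, differences = 2))) / tab$h^2
    omega <- sqrt(max(d2, 0) * cst$kcal_internal / spec$mass)
    if (omega * spec$dt > 1.5) {
      stop(sprintf("unstable parameters: omega*dt = %.3g at the stiffest point of U(z); reduce dt",
                   omega * spec$dt))
    }
    if (omega * spec$dt > 0.5) {
      warning(sprintf("omega*dt = %.3g is marginal; configurational bias may be visible",
                      omega * spec$dt))
    }
  }
  invisible(TRUE)
}

# Rejection-sample stationary axial positions ~ exp(-U/RT).
sample_boltzmann_z <- function(spec, n) {
  cst <- physical_constants()
  half <- spec$box_z / 2
  beta <- 1 / (cst$R_kcal * spec$temperature)  # 1/(RT), mol/kcal
  out <- numeric(0)
  Umin <- min(langevin_potential(spec, seq(-half, half, length.out = 2001)))
  while (length(out) < n) {
    m <- 2 * (n - length(out)) + 16
    z <- stats::runif(m, -half, half)
    acc <- stats::runif(m) < exp(-(langevin_potential(spec, z) - Umin) * beta)
    out <- c(out, z[acc])
  }
  out[seq_len(n)]
}

#' Simulate thermalised particles in the synthetic channel
#'
#' Integrates inertial Langevin dynamics with the BAOAB splitting, so that
#' stationary velocities are Maxwell-Boltzmann at the spec temperature, with
#' reflecting walls at `+/- box_z/2`. The run is deterministic given the spec
#' seed; positions are initialised from the stationary Boltzmann law of the
#' axial potential and velocities from the Maxwell distribution. Passing the
#' `state` of a previous bundle continues the same run (same RNG stream), so
#' a chunked simulation is bit-identical to a single long one.
#'
#' @param spec A [langevin_spec()].
#' @param n_steps Number of steps (default `spec$n_steps`).
#' @param state Continuation state (`bundle$state` of the previous chunk).
#' @param save_velocities Store velocities alongside positions.
#' @return A [trajectory_bundle()]; for `lateral_mode = "cylinder"` the
#'   bundle carries an `xy` element with per-frame lateral coordinates.
#' @examples
#' b <- simulate_langevin(langevin_spec(n_particles = 5, n_steps = 50))
#' dim(b$z)
#' @export
simulate_langevin <- function(spec, n_steps = spec$n_steps, state = NULL,
                              save_velocities = TRUE) {
  stopifnot(inherits(spec, "langevin_spec"))
  tab <- langevin_accel_table(spec)
  langevin_check_stability(spec, tab)
  half <- spec$box_z / 2
  cst <- physical_constants()
  sigma_v <- sqrt(cst$R_internal * spec$temperature / spec$mass)
  cyl <- spec$lateral_mode == "cylinder"

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  if (is.null(state)) {
    set.seed(spec$seed)
    z <- sample_boltzmann_z(spec, spec$n_particles)
    v <- stats::rnorm(spec$n_particles, 0, sigma_v)
    frame0 <- 0
    xy <- if (cyl) {
      r <- spec$lateral_radius * sqrt(stats::runif(spec$n_particles))
      th <- stats::runif(spec$n_particles, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    } else {
      NULL
    }
    vxy <- if (cyl) {
      matrix(stats::rnorm(2 * spec$n_particles, 0, sigma_v), ncol = 2)
    } else {
      NULL
    }
    fresh <- TRUE
  } else {
    assign(".Random.seed", state$rng, globalenv())
    z <- state$z
    v <- state$v
    frame0 <- state$frame0
    xy <- state$xy
    vxy <- state$vxy
    fresh <- FALSE
  }

  res <- cpp_langevin_chunk(z, v, n_steps, spec$save_stride, spec$dt,
                            spec$friction, spec$temperature, spec$mass,
                            tab$acc, tab$z0, tab$h, half, save_velocities)
  zm <- res$z
  vm <- if (save_velocities) res$vz else NULL
  if (cyl) {
    lat <- cpp_langevin_lateral(xy[, 1], xy[, 2], vxy[, 1], vxy[, 2],
                                n_steps, spec$save_stride, spec$dt,
                                spec$friction, spec$temperature, spec$mass,
                                spec$lateral_radius)
    xy_frames <- list(x = lat$x, y = lat$y)
    xy_new <- cbind(lat$x_final, lat$y_final)
    vxy_new <- cbind(lat$vx_final, lat$vy_final)
  } else {
    xy_frames <- NULL
    xy_new <- NULL
    vxy_new <- NULL
  }

  dtf <- spec$dt * spec$save_stride
  if (fresh) {
    zm <- rbind(matrix(z, 1), zm)
    if (!is.null(vm)) vm <- rbind(matrix(v, 1), vm)
    if (cyl) {
      xy_frames$x <- rbind(matrix(xy[, 1], 1), xy_frames$x)
      xy_frames$y <- rbind(matrix(xy[, 2], 1), xy_frames$y)
    }
    times <- dtf * (0:(nrow(zm) - 1))
  } else {
    times <- dtf * (frame0 + seq_len(nrow(zm)))
  }

  if (spec$single_file && ncol(zm) > 1) {
    for (f in seq_len(nrow(zm))) {
      o <- order(zm[f, ])
      zm[f, ] <- zm[f, o]
      if (!is.null(vm)) vm[f, ] <- vm[f, o]
    }
  }

  new_state <- list(z = res$z_final, v = res$v_final,
                    frame0 = frame0 + n_steps %/% spec$save_stride,
                    rng = get(".Random.seed", globalenv()),
                    xy = xy_new, vxy = vxy_new)
  b <- trajectory_bundle(times, zm, vz = vm, dt_frame = dtf,
                         temperature = spec$temperature, box_z = spec$box_z,
                         spec = spec, state = new_state)
  if (cyl) b$xy <- xy_frames
  b
}

#' Default channel frame for a synthetic spec
#'
#' Dividing plane at z = 0, bulk thresholds at `+/- channel_halfwidth`.
#'
#' @param spec A [langevin_spec()].
#' @return A [channel_frame()].
#' @export
synthetic_channel_frame <- function(spec) {
  channel_frame("synthetic", z_divide = 0,
                z_bulk_ec = spec$channel_halfwidth,
                z_bulk_ic = -spec$channel_halfwidth,
                radius_gate = spec$lateral_radius)
}

#' Matched temperature pair for Arrhenius analysis
#'
#' Simulates the same channel world at two temperatures with seeds derived
#' from the master seed, for end-to-end activation-energy recovery: the
#' pipeline-estimated E_a grows with the imposed barrier height.
#'
#' @param spec A [langevin_spec()]; its `temperature` field is overridden.
#' @param T1,T2 Temperatures (K), `T1 != T2`.
#' @param n_steps Steps per run (default `spec$n_steps`).
#' @return A list of two [trajectory_bundle()]s named `T1` and `T2`.
#' @export
make_arrhenius_pair <- function(spec, T1, T2, n_steps = spec$n_steps) {
  if (T1 == T2) stop("T1 and T2 must differ")
  run <- function(temp, sub) {
    s <- spec
    s$temperature <- temp
    s$seed <- spec$seed + sub
    simulate_langevin(s, n_steps = n_steps)
  }
  list(T1 = run(T1, 1L), T2 = run(T2, 2L))
}

#' Deterministic scripted event fixture
#'
#' Builds a bundle whose tracks pass exactly through the scripted waypoint
#' z values at consecutive frames (1 ps apart); shorter scripts are padded
#' with their final value.
#'
#' @param script List of numeric waypoint vectors, one per particle.
#' @param dt_frame Frame interval (ps).
#' @param temperature Nominal temperature recorded in the bundle (K).
#' @return A [trajectory_bundle()] (an empty script yields a bundle with
#'   zero particles).
#' @examples
#' make_event_fixture(list(c(-16, -5, 1, 8, 16)))
#' @export
make_event_fixture <- function(script, dt_frame = 1, temperature = 298.15) {
  if (!length(script)) {
    return(trajectory_bundle(c(0, dt_frame), matrix(numeric(0), 2, 0),
                             dt_frame = dt_frame, temperature = temperature))
  }
  nf <- max(2, max(lengths(script)))
  z <- vapply(script, function(w) c(w, rep(w[length(w)], nf - length(w))),
              numeric(nf))
  trajectory_bundle((0:(nf - 1)) * dt_frame, matrix(z, nrow = nf),
                    dt_frame = dt_frame, temperature = temperature)
}

#' Linear water-chain fixture for hydrogen-bond analysis
#'
#' A chain of waters along z with known ground-truth bond count: with
#' hydrogens aligned to the chain axis each water donates one bond to the
#' next (N - 1 bonds at sub-cutoff spacing); with `aligned = FALSE` the
#' hydrogens point perpendicular to the chain and the donor angle fails for
#' every pair (0 bonds).
#'
#' @param n_waters Number of waters (>= 2).
#' @param spacing Oxygen-oxygen spacing along z (Angstrom).
#' @param aligned Align the donor hydrogen with the chain axis.
#' @return A `water_set` data frame (see [count_hbonds()]).
#' @export
make_hbond_fixture <- function(n_waters, spacing = 2.8, aligned = TRUE) {
  stopifnot(n_waters >= 2, spacing > 0)
  r_oh <- 0.9572
  theta <- 104.52 * pi / 180
  oz <- (seq_len(n_waters) - 1) * spacing
  if (aligned) {
    h1 <- cbind(0, 0, oz + r_oh)
    h2 <- cbind(r_oh * sin(theta), 0, oz + r_oh * cos(theta))
  } else {
    h1 <- cbind(r_oh, 0, oz)
    h2 <- cbind(r_oh * cos(theta), r_oh * sin(theta), oz)
  }
  structure(
    data.frame(id = seq_len(n_waters), ox = 0, oy = 0, oz = oz,
               h1x = h1[, 1], h1y = h1[, 2], h1z = h1[, 3],
               h2x = h2[, 1], h2y = h2[, 2], h2z = h2[, 3]),
    class = c("water_set", "data.frame")
  )
}

#' Export a synthetic bundle as PDB + DCD
#'
#' Writes the tagged particles as water oxygens (residue `TIP`, atom `OH2`;
#' a three-character residue name keeps strict PDB column alignment)
#' so that the real-mode readers can be exercised on synthetic data. 1-D
#' bundles are placed on the axis (x = y = 0); cylinder-mode bundles use
#' their lateral coordinates.
#'
#' @param bundle A [trajectory_bundle()].
#' @param path_prefix Output stem; `<path>.pdb` and `<path>.dcd` are written.
#' @return `path_prefix`, invisibly.
#' @export
export_trajectory <- function(bundle, path_prefix) {
  stopifnot(inherits(bundle, "trajectory_bundle"))
  np <- ncol(bundle$z)
  nf <- bundle$frames_count
  x <- if (!is.null(bundle$xy)) bundle$xy$x else matrix(0, nf, np)
  y <- if (!is.null(bundle$xy)) bundle$xy$y else matrix(0, nf, np)
  xyz <- matrix(0, nf, 3 * np)
  xyz[, seq(1, 3 * np, 3)] <- x
  xyz[, seq(2, 3 * np, 3)] <- y
  xyz[, seq(3, 3 * np, 3)] <- bundle$z
  bio3d::write.pdb(file = paste0(path_prefix, ".pdb"), xyz = xyz[1, ],
                   type = rep("ATOM", np), resno = seq_len(np),
                   resid = rep("TIP", np), elety = rep("OH2", np),
                   chain = rep("W", np))
  box <- if (is.null(bundle$box_z)) NULL else {
    c(2 * max(abs(x), 1), 2 * max(abs(y), 1), bundle$box_z)
  }
  write_dcd(xyz, paste0(path_prefix, ".dcd"), cell = box,
            dt = bundle$dt_frame)
  invisible(path_prefix)
}
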