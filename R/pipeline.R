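#' TST permeability from particle tracks
#'
#' Runs the full estimator on in-memory tracks: crossing-event detection and
#' kappa, linear density and n(z0), then `k0` and `p_f`. With a list of
#' per-monomer tracks, events are pooled across monomers (the per-channel
#' presentation), the density profile is the monomer average, and the
#' uncertainty is the SEM of per-monomer permeabilities.
#'
#' @param tracks A [particle_tracks()] object or a list of them (monomers).
#' @param frame A [channel_frame()].
#' @param temperature Temperature (K).
#' @param bin_width,margin Passed to [linear_density()].
#' @param constants A [physical_constants()] list.
#' @return A [permeability_result()] with provenance holding the event
#'   summary and density profile.
#' @export
permeability_from_tracks <- function(tracks, frame, temperature,
                                     bin_width = 0.5, margin = 5,
                                     constants = physical_constants()) {
  single <- inherits(tracks, "particle_tracks")
  track_list <- if (single) list(tracks) else tracks
  ev <- lapply(track_list, detect_events, frame = frame)
  events <- do.call(rbind, ev)
  obs <- max(vapply(track_list, function(tr) diff(range(tr$times)), numeric(1)))
  summary <- summarize_events(events, observation_time = obs,
                              n_monomers = length(track_list))
  dens <- linear_density(if (single) tracks else track_list, frame,
                         bin_width = bin_width, margin = margin)
  profile <- if (single) dens else dens$pooled
  n_z0 <- density_at_plane(profile, frame$z_divide)
  unc <- NA_real_
  if (!single && length(track_list) >= 2) {
    per <- vapply(seq_along(track_list), function(i) {
      s <- summarize_events(ev[[i]], observation_time = obs)
      if (!s$kappa_defined) return(NA_real_)
      n0 <- density_at_plane(dens$per_monomer[[i]], frame$z_divide)
      single_channel_pf(rate_constant_k0(s$kappa, temperature, n0, constants),
                        constants)
    }, numeric(1))
    unc <- as.numeric(estimate_uncertainty(per, method = "monomers"))
  }
  permeability_result(summary$kappa, n_z0, temperature, uncertainty_pf = unc,
                      constants = constants,
                      provenance = list(events = summary, profile = profile))
}

#' Chunked simulation plus TST estimation
#'
#' Streams a long Langevin run through the estimator in fixed-size chunks so
#' that arbitrarily long trajectories never materialise in memory: each chunk
#' is simulated (continuing the same RNG stream), scanned by the event state
#' machine (continuing open events across chunk boundaries), accumulated into
#' the density histogram, and discarded. Results are identical to running the
#' estimator on the corresponding single long trajectory.
#'
#' Per-block statistics over `n_blocks` contiguous time blocks provide the
#' standard error of `p_f` (and of any derived ratio) by the block method.
#'
#' @param spec A [langevin_spec()].
#' @param n_steps Total steps (default `spec$n_steps`).
#' @param chunk_frames Stored frames per chunk (default 50000).
#' @param n_blocks Number of time blocks for uncertainty (default 10).
#' @param bin_width,margin Density binning parameters (Angstrom).
#' @param constants A [physical_constants()] list.
#' @return An object of class `tst_estimate`: the [permeability_result()]
#'   (`result`), total attempt/success counts (overall and by direction),
#'   one-way plane crossing counts (`crossings`), the pooled density
#'   profile, the per-block table (`blocks`), and the observation time.
#' @export
simulate_and_estimate <- function(spec, n_steps = spec$n_steps,
                                  chunk_frames = 50000, n_blocks = 10,
                                  bin_width = 0.5, margin = 5,
                                  constants = physical_constants()) {
  stopifnot(inherits(spec, "langevin_spec"))
  frame <- synthetic_channel_frame(spec)
  chunk_steps <- chunk_frames * spec$save_stride
  n_chunks <- ceiling(n_steps / chunk_steps)
  z_lo <- frame$z_bulk_ic - margin
  z_hi <- frame$z_bulk_ec + margin
  n_bins <- ceiling((z_hi - z_lo) / bin_width)
  edges <- z_lo + bin_width * (0:n_bins)

  np <- spec$n_particles
  ev_state <- list(open_dir = integer(np), open_t = numeric(np),
                   z_prev = rep(NA_real_, np), lat_prev = rep(TRUE, np))
  cross_prev <- rep(NA_real_, np)
  sim_state <- NULL
  hist_blocks <- matrix(0, n_blocks, n_bins)
  blocks <- data.frame(frames = numeric(n_blocks), attempts = numeric(n_blocks),
                       successes = numeric(n_blocks), up = numeric(n_blocks),
                       down = numeric(n_blocks))
  dir_tot <- c(`IC->EC` = 0, `EC->IC` = 0)
  dir_succ <- c(`IC->EC` = 0, `EC->IC` = 0)
  total_frames <- 0
  steps_done <- 0

  for (ck in seq_len(n_chunks)) {
    steps <- min(chunk_steps, n_steps - steps_done)
    b <- simulate_langevin(spec, n_steps = steps, state = sim_state,
                           save_velocities = FALSE)
    sim_state <- b$state
    steps_done <- steps_done + steps
    blk <- 1 + floor((ck - 1) * n_blocks / n_chunks)

    res <- cpp_event_machine(b$z, NULL, b$times, frame$z_divide,
                             frame$z_bulk_ic, frame$z_bulk_ec,
                             ev_state$open_dir, ev_state$open_t,
                             ev_state$z_prev, ev_state$lat_prev,
                             ck == n_chunks)
    ev_state <- list(open_dir = res$open_dir, open_t = res$open_t,
                     z_prev = res$z_prev, lat_prev = res$lat_prev)
    resolved <- res$outcome != 3L
    succ <- res$outcome == 1L
    blocks$attempts[blk] <- blocks$attempts[blk] + sum(resolved)
    blocks$successes[blk] <- blocks$successes[blk] + sum(succ)
    up <- res$direction == 1L
    dir_tot <- dir_tot + c(sum(resolved & up), sum(resolved & !up))
    dir_succ <- dir_succ + c(sum(succ & up), sum(succ & !up))

    cc <- cpp_crossing_counts(b$z, frame$z_divide, cross_prev)
    blocks$up[blk] <- blocks$up[blk] + cc[["up"]]
    blocks$down[blk] <- blocks$down[blk] + cc[["down"]]

    hist_blocks[blk, ] <- hist_blocks[blk, ] +
      cpp_bin_counts(b$z, NULL, z_lo, bin_width, n_bins)
    blocks$frames[blk] <- blocks$frames[blk] + nrow(b$z)
    total_frames <- total_frames + nrow(b$z)
  }

  observation_time <- steps_done * spec$dt
  counts_mean <- colSums(hist_blocks) / total_frames
  profile <- density_profile(edges, counts_mean, total_frames, "synthetic")
  n_z0 <- density_at_plane(profile, frame$z_divide)
  attempts <- sum(blocks$attempts)
  successes <- sum(blocks$successes)
  kappa <- if (attempts > 0) successes / attempts else NA_real_

  plane_bin <- findInterval(frame$z_divide, edges)
  blocks$n_z0 <- (hist_blocks[, plane_bin] / pmax(blocks$frames, 1)) /
    (bin_width / 10)
  blocks$kappa <- ifelse(blocks$attempts > 0,
                         blocks$successes / blocks$attempts, NA_real_)
  blocks$pf <- ifelse(is.finite(blocks$kappa),
                      single_channel_pf(
                        rate_constant_k0(pmin(blocks$kappa, 1),
                                         spec$temperature, blocks$n_z0,
                                         constants), constants),
                      NA_real_)
  unc <- as.numeric(estimate_uncertainty(blocks$pf, method = "blocks"))

  result <- permeability_result(kappa, n_z0, spec$temperature,
                                uncertainty_pf = unc, constants = constants)
  structure(
    list(result = result, kappa = kappa, n_z0 = n_z0, pf = result$pf,
         attempts = attempts, successes = successes,
         attempts_by_direction = dir_tot, successes_by_direction = dir_succ,
         crossings = c(up = sum(blocks$up), down = sum(blocks$down)),
         profile = profile, blocks = blocks,
         observation_time = observation_time, n_frames = total_frames,
         frame = frame, temperature = spec$temperature),
    class = "tst_estimate"
  )
}

#' @export
print.tst_estimate <- function(x, ...) {
  cat(sprintf("Chunked TST estimate over %.4g ps (%d frames):\n",
              x$observation_time, x$n_frames))
  cat(sprintf("  attempts %d, successes %d, kappa = %.4f, n(z0) = %.4g /nm\n",
              x$attempts, x$successes, x$kappa, x$n_z0))
  cat(sprintf("  p_f = %.4g cm^3/s\n", x$pf))
  invisible(x)
}

#' Arrhenius activation energy recovered from a synthetic temperature pair
#'
#' Runs the chunked TST estimator at two temperatures on the same channel
#' world (seeds derived from the master seed) and applies the two-point
#' Arrhenius relation to the estimated permeabilities. The standard error of
#' E_a is propagated from the block-method SEMs of the two p_f estimates.
#'
#' @param spec A [langevin_spec()] (its temperature field is overridden).
#' @param T1,T2 Temperatures (K).
#' @param n_steps Steps per temperature (default `spec$n_steps`).
#' @param ... Passed to [simulate_and_estimate()].
#' @return A list with `E_a` (kcal/mol), `se_Ea`, and the two `tst_estimate`
#'   objects.
#' @export
arrhenius_from_spec <- function(spec, T1 = 278.15, T2 = 298.15,
                                n_steps = spec$n_steps, ...) {
  if (T1 == T2) stop("T1 and T2 must differ")
  run <- function(temp, sub) {
    s <- spec
    s$temperature <- temp
    s$seed <- spec$seed + sub
    simulate_and_estimate(s, n_steps = n_steps, ...)
  }
  e1 <- run(T1, 1L)
  e2 <- run(T2, 2L)
  ar <- arrhenius_ea(e1$pf, T1, e2$pf, T2)
  cst <- physical_constants()
  rel <- sqrt((e1$result$uncertainty_pf / e1$pf)^2 +
                (e2$result$uncertainty_pf / e2$pf)^2)
  se <- abs(cst$R_kcal * T1 / (T1 / T2 - 1)) * rel
  list(E_a = ar$E_a, se_Ea = se, estimate_T1 = e1, estimate_T2 = e2)
}
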