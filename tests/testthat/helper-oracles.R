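# Independent brute-force oracles used to cross-check the event machinery.

# Complete bulk-to-bulk traversals: for each particle, classify frames as
# IC-bulk (-1), EC-bulk (+1) or neither, collapse to the sequence of bulk
# visits, and count sign alternations. `state` carries the last bulk visited
# per particle across chunks.
oracle_traversals <- function(z, z_bulk_ic, z_bulk_ec, state = NULL) {
  np <- ncol(z)
  if (is.null(state)) state <- integer(np)  # 0 = no bulk visited yet
  up <- 0L
  down <- 0L
  for (p in seq_len(np)) {
    s <- (z[, p] >= z_bulk_ec) - (z[, p] <= z_bulk_ic)
    s <- s[s != 0L]
    s <- c(state[p], s)
    s <- s[s != 0L]
    if (length(s) > 1) {
      d <- diff(s)
      up <- up + sum(d == 2L)    # -1 -> +1 : IC to EC
      down <- down + sum(d == -2L)
    }
    state[p] <- if (length(s)) s[length(s)] else 0L
  }
  list(up = up, down = down, total = up + down, state = state)
}

# Hand-executed event state machine on a single z series (reference
# implementation, independent of the compiled path).
oracle_event_scan <- function(z, z_divide = 0, z_bulk_ic = -15,
                              z_bulk_ec = 15) {
  open <- 0L
  attempts <- 0L
  successes <- 0L
  for (i in seq_along(z)[-1]) {
    zp <- z[i - 1]
    zc <- z[i]
    if (open != 0L) {
      res <- FALSE
      if (open > 0 && zc >= z_bulk_ec) { successes <- successes + 1; res <- TRUE }
      else if (open > 0 && zc < z_divide) res <- TRUE
      else if (open < 0 && zc <= z_bulk_ic) { successes <- successes + 1; res <- TRUE }
      else if (open < 0 && zc >= z_divide) res <- TRUE
      if (res) { attempts <- attempts + 1; open <- 0L; next }
    } else if ((zp >= z_divide) != (zc >= z_divide)) {
      open <- if (zc >= z_divide) 1L else -1L
      if ((open > 0 && zc >= z_bulk_ec) || (open < 0 && zc <= z_bulk_ic)) {
        attempts <- attempts + 1
        successes <- successes + 1
        open <- 0L
      }
    }
  }
  list(attempts = attempts, successes = successes)
}

# Maxwell-Boltzmann one-way flux prefactor sqrt(RT/2*pi*m) in Angstrom/ps.
mb_flux_prefactor <- function(temperature, mass = 18.01528) {
  sqrt(0.8314462618 * temperature / mass) / sqrt(2 * pi)
}

# Boltzmann CDF of the stationary axial law on [-box/2, box/2].
boltzmann_cdf <- function(spec) {
  half <- spec$box_z / 2
  zg <- seq(-half, half, length.out = 4001)
  U <- spec$barrier_height * exp(-zg^2 / (2 * spec$barrier_width^2))
  w <- exp(-U / (1.987204e-3 * spec$temperature))
  cdf <- cumsum(w) - w / 2
  cdf <- cdf / cdf[length(cdf)]
  approxfun(zg, cdf, yleft = 0, yright = 1)
}
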