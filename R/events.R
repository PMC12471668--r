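#' Detect dividing-plane crossing events
#'
#' Runs the crossing-event state machine over every track: an event opens at
#' each sign change of `z - z_divide` between consecutive frames while the
#' particle is laterally eligible, and is followed until it either reaches the
#' destination bulk (success) or returns across the dividing plane (recross).
#' A particle that leaves the lateral gate while inside the slab resolves its
#' open event as a recross-equivalent failure: it did not reach the bulk.
#' While an event is open, further plane oscillations of the same particle do
#' not open new events; after resolution the particle is immediately eligible
#' again (the resolving transition itself never opens a new event). Events
#' still open at the last frame are emitted as `unresolved` and excluded from
#' both the numerator and the denominator of kappa.
#'
#' @param tracks A [particle_tracks()] object (z unwrapped, times increasing).
#' @param frame A [channel_frame()] supplying `z_divide` and bulk thresholds.
#' @param state Optional continuation state from a previous chunk (internal
#'   use by the chunked pipeline); pass the `state` attribute of a previous
#'   result to continue a scan, with `finalize = FALSE` on all but the last
#'   chunk.
#' @param finalize Emit unresolved events for still-open trajectories
#'   (default TRUE).
#' @return A data frame of class `crossing_events` with columns
#'   `particle_id`, `monomer_id`, `direction` (`"IC->EC"`/`"EC->IC"`),
#'   `t_cross`, `t_resolve` (NA when unresolved) and `outcome` (`"success"`,
#'   `"recross"`, `"unresolved"`); the continuation state is attached as
#'   attribute `state`.
#' @examples
#' tr <- make_event_fixture(list(c(-16, -5, 1, 8, 16)))
#' detect_events(as_particle_tracks(tr), channel_frame("A"))
#' @export
detect_events <- function(tracks, frame, state = NULL, finalize = TRUE) {
  stopifnot(inherits(tracks, "particle_tracks"), inherits(frame, "channel_frame"))
  np <- ncol(tracks$z)
  if (is.null(state)) {
    state <- list(open_dir = integer(np), open_t = numeric(np),
                  z_prev = rep(NA_real_, np), lat_prev = rep(TRUE, np))
  }
  res <- cpp_event_machine(
    tracks$z,
    if (is.null(tracks$lateral_ok)) NULL else tracks$lateral_ok,
    tracks$times, frame$z_divide, frame$z_bulk_ic, frame$z_bulk_ec,
    state$open_dir, state$open_t, state$z_prev, state$lat_prev, finalize
  )
  out <- data.frame(
    particle_id = tracks$particle_ids[res$particle],
    monomer_id = rep(tracks$monomer_id, length(res$particle)),
    direction = c("EC->IC", "", "IC->EC")[res$direction + 2L],
    t_cross = res$t_cross,
    t_resolve = res$t_resolve,
    outcome = c("success", "recross", "unresolved")[res$outcome],
    stringsAsFactors = FALSE
  )
  attr(out, "state") <- list(open_dir = res$open_dir, open_t = res$open_t,
                             z_prev = res$z_prev, lat_prev = res$lat_prev)
  class(out) <- c("crossing_events", "data.frame")
  out
}

#' Summarise crossing events into attempts, successes and kappa
#'
#' The recrossing correction kappa is the number of successful transport
#' events divided by the total number of resolved dividing-plane crossings.
#' Unresolved tail events enter neither count. Cumulative counts on a time
#' grid use the event resolution time, so `kappa(0, t)` only reflects events
#' resolved by `t`.
#'
#' @param events A `crossing_events` data frame (rows from several monomers
#'   may be pooled by `rbind`).
#' @param observation_time Total observation time (ps).
#' @param time_grid Optional increasing vector of times (ps) for the
#'   cumulative series.
#' @param n_monomers Number of channels pooled into `events` (default 1).
#' @return An object of class `event_summary`.
#' @export
summarize_events <- function(events, observation_time, time_grid = NULL,
                             n_monomers = 1) {
  if (observation_time <= 0) stop("observation_time must be positive")
  resolved <- events[events$outcome %in% c("success", "recross"), , drop = FALSE]
  attempts <- nrow(resolved)
  succ <- resolved$outcome == "success"
  successes <- sum(succ)
  dir_lv <- c("IC->EC", "EC->IC")
  attempts_by_dir <- table(factor(resolved$direction, levels = dir_lv))
  successes_by_dir <- table(factor(resolved$direction[succ], levels = dir_lv))
  kappa <- if (attempts > 0) successes / attempts else NA_real_
  cumulative <- NULL
  if (!is.null(time_grid)) {
    tr <- resolved$t_resolve
    ca <- vapply(time_grid, function(t) sum(tr <= t), numeric(1))
    cs <- vapply(time_grid, function(t) sum(tr[succ] <= t), numeric(1))
    cumulative <- data.frame(t_ps = time_grid, attempts = ca, successes = cs,
                             kappa = ifelse(ca > 0, cs / ca, NA_real_))
  }
  structure(
    list(attempts_total = attempts, successes_total = successes,
         attempts_by_direction = attempts_by_dir,
         successes_by_direction = successes_by_dir,
         kappa = kappa, kappa_defined = attempts > 0,
         unresolved = sum(events$outcome == "unresolved"),
         cumulative = cumulative, observation_time = observation_time,
         n_monomers = n_monomers),
    class = "event_summary"
  )
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("Crossing events over %.4g ps (%d channel%s):\n",
              x$observation_time, x$n_monomers,
              if (x$n_monomers == 1) "" else "s"))
  cat(sprintf("  attempts %d (IC->EC %d, EC->IC %d), successes %d, unresolved %d\n",
              x$attempts_total, x$attempts_by_direction[["IC->EC"]],
              x$attempts_by_direction[["EC->IC"]], x$successes_total,
              x$unresolved))
  if (x$kappa_defined) {
    cat(sprintf("  kappa = %.4f (success ratio %.2f%%)\n", x$kappa,
                100 * x$kappa))
  } else {
    cat("  kappa undefined (no resolved attempts)\n")
  }
  invisible(x)
}

#' Plot cumulative attempt and success counts
#'
#' Plots the cumulative number of dividing-plane crossing attempts and, on
#' the same axes, the cumulative number of successful permeation events
#' multiplied by a display scale factor (default 50). The scale factor is
#' cosmetic only; it never enters kappa or the permeability.
#'
#' @param summary An [summarize_events()] result with a cumulative series.
#' @param success_scale Display multiplier for the success curve.
#' @param ... Passed to [graphics::plot()].
#' @return The summary, invisibly.
#' @export
plot_event_counts <- function(summary, success_scale = 50, ...) {
  stopifnot(inherits(summary, "event_summary"))
  cum <- summary$cumulative
  if (is.null(cum) || nrow(cum) == 0) {
    warning("empty cumulative series; nothing to plot")
    plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "t (ps)", ylab = "events")
    return(invisible(summary))
  }
  ymax <- max(cum$attempts, success_scale * cum$successes, 1)
  plot(cum$t_ps, cum$attempts, type = "s", xlab = "t (ps)",
       ylab = "cumulative events", ylim = c(0, ymax), ...)
  lines(cum$t_ps, success_scale * cum$successes, type = "s", lty = 2)
  legend("topleft", lty = c(1, 2), bty = "n",
         legend = c("attempts",
                    if (success_scale == 1) "successes"
                    else sprintf("successes x %g", success_scale)))
  invisible(summary)
}

#' Write crossing events and summaries to disk
#'
#' Events are written as TSV (one row per event), summaries as JSON, and the
#' cumulative series as CSV with columns `t_ps`, `attempts`, `successes`,
#' `kappa`.
#'
#' @param events A `crossing_events` data frame.
#' @param summary An `event_summary`.
#' @param path Output path stem; `<path>-events.tsv`, `<path>-summary.json`
#'   and `<path>-cumulative.csv` are written as applicable.
#' @return `path`, invisibly.
#' @export
write_event_outputs <- function(events = NULL, summary = NULL, path) {
  if (!is.null(events)) {
    utils::write.table(events, paste0(path, "-events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary)) {
    s <- unclass(summary)
    cum <- s$cumulative
    s$cumulative <- NULL
    s$attempts_by_direction <- as.list(s$attempts_by_direction)
    s$successes_by_direction <- as.list(s$successes_by_direction)
    jsonlite::write_json(s, paste0(path, "-summary.json"), auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(cum)) {
      utils::write.csv(cum, paste0(path, "-cumulative.csv"), row.names = FALSE)
    }
  }
  invisible(path)
}
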