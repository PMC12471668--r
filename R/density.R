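#' Linear density of water along the channel axis
#'
#' For every stored frame, each molecule that passes the lateral gate and lies
#' within `[z_bulk_ic - margin, z_bulk_ec + margin]` increments the bin
#' containing its axial coordinate; the profile is the mean count per frame
#' per bin divided by the bin width expressed in nm, i.e. molecules per nm of
#' channel axis. Bins are half-open `[left, right)`.
#'
#' @param tracks A [particle_tracks()] object, or a list of them (one per
#'   monomer) in which case per-monomer profiles plus their bin-by-bin mean
#'   are returned.
#' @param frame A [channel_frame()].
#' @param bin_width Bin width in Angstrom (default 0.5, resolving the ~2.8 A
#'   single-file spacing with >5 bins per water).
#' @param margin Extension beyond the bulk thresholds, Angstrom (default 5).
#' @return A `density_profile` (single tracks) or a list with elements
#'   `per_monomer` and `pooled` (list of tracks).
#' @export
linear_density <- function(tracks, frame, bin_width = 0.5, margin = 5) {
  stopifnot(inherits(frame, "channel_frame"), bin_width > 0)
  if (inherits(tracks, "particle_tracks")) {
    return(density_profile_one(tracks, frame, bin_width, margin))
  }
  per <- lapply(tracks, density_profile_one, frame = frame,
                bin_width = bin_width, margin = margin)
  list(per_monomer = per, pooled = average_density_profiles(per))
}

density_profile_one <- function(tracks, frame, bin_width, margin) {
  nf <- nrow(tracks$z)
  if (nf < 1) stop("density profile requires at least one frame")
  z_lo <- frame$z_bulk_ic - margin
  z_hi <- frame$z_bulk_ec + margin
  n_bins <- ceiling((z_hi - z_lo) / bin_width)
  edges <- z_lo + bin_width * (0:n_bins)
  counts <- cpp_bin_counts(tracks$z,
                           if (is.null(tracks$lateral_ok)) NULL
                           else tracks$lateral_ok,
                           z_lo, bin_width, n_bins)
  density_profile(edges, counts / nf, nf, tracks$monomer_id)
}

#' Construct a density profile from mean bin counts
#'
#' @param bin_edges Bin edges (Angstrom), length nbins + 1.
#' @param counts_mean Mean molecules per frame per bin.
#' @param n_frames Number of frames averaged.
#' @param monomer_id Label (`"pooled-mean"` for monomer averages).
#' @return An object of class `density_profile` with `density` in
#'   molecules/nm.
#' @export
density_profile <- function(bin_edges, counts_mean, n_frames,
                            monomer_id = "pooled") {
  bin_edges <- as.numeric(bin_edges)
  counts_mean <- as.numeric(counts_mean)
  if (length(counts_mean) != length(bin_edges) - 1) {
    stop("counts_mean must have length(bin_edges) - 1 entries")
  }
  widths <- diff(bin_edges)
  structure(
    list(bin_edges = bin_edges, counts_mean = counts_mean,
         density = counts_mean / (widths / 10), n_frames = n_frames,
         monomer_id = as.character(monomer_id)),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Linear density profile [%s]: %d bins over [%g, %g] A, %d frames\n",
              x$monomer_id, length(x$counts_mean), min(x$bin_edges),
              max(x$bin_edges), x$n_frames))
  cat(sprintf("  mean in-range occupancy %.4g molecules/frame\n",
              sum(x$counts_mean)))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  centers <- (head(x$bin_edges, -1) + tail(x$bin_edges, -1)) / 2
  plot(centers, x$density, type = "l", xlab = "z (A)",
       ylab = "linear density (molecules/nm)", ...)
  invisible(x)
}

#' Bin-by-bin mean of per-monomer density profiles
#'
#' @param profiles List of `density_profile` objects on identical grids.
#' @return A `density_profile` labelled `"pooled-mean"`.
#' @export
average_density_profiles <- function(profiles) {
  edges <- profiles[[1]]$bin_edges
  for (p in profiles) {
    if (!isTRUE(all.equal(p$bin_edges, edges))) {
      stop("profiles are on different bin grids")
    }
  }
  cm <- Reduce(`+`, lapply(profiles, `[[`, "counts_mean")) / length(profiles)
  density_profile(edges, cm, profiles[[1]]$n_frames, "pooled-mean")
}

#' Linear density at the dividing plane, n(z0)
#'
#' Returns the density of the bin whose half-open interval `[left, right)`
#' contains `z_divide`; no interpolation or smoothing is applied.
#'
#' @param profile A `density_profile`.
#' @param z_divide Dividing-plane position (Angstrom).
#' @return n(z0) in molecules/nm.
#' @export
density_at_plane <- function(profile, z_divide = 0) {
  stopifnot(inherits(profile, "density_profile"))
  edges <- profile$bin_edges
  if (z_divide < edges[1] || z_divide >= edges[length(edges)]) {
    stop("z_divide lies outside the profile range")
  }
  i <- findInterval(z_divide, edges, rightmost.closed = FALSE)
  profile$density[i]
}

#' Single-file extent of the density profile
#'
#' Length of the maximal contiguous run of bins with density at or below the
#' threshold that contains the dividing-plane bin; 0 when that bin itself
#' exceeds the threshold. Low linear density marks waters spaced too far
#' apart to pass one another -- the single-file region of the pore.
#'
#' @param profile A `density_profile`.
#' @param threshold Density threshold (default 2.5, in the profile's units).
#' @param z_divide Dividing-plane position (Angstrom).
#' @return Extent in Angstrom.
#' @export
single_file_extent <- function(profile, threshold = 2.5, z_divide = 0) {
  stopifnot(inherits(profile, "density_profile"))
  edges <- profile$bin_edges
  i0 <- findInterval(z_divide, edges, rightmost.closed = FALSE)
  if (i0 < 1 || i0 > length(profile$density)) {
    stop("z_divide lies outside the profile range")
  }
  below <- profile$density <= threshold
  if (!below[i0]) return(0)
  lo <- i0
  while (lo > 1 && below[lo - 1]) lo <- lo - 1
  hi <- i0
  while (hi < length(below) && below[hi + 1]) hi <- hi + 1
  edges[hi + 1] - edges[lo]
}

#' Write a density profile as CSV
#'
#' Columns `z_center_A` and `density_per_nm`.
#'
#' @param profile A `density_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(profile, path) {
  centers <- (head(profile$bin_edges, -1) + tail(profile$bin_edges, -1)) / 2
  utils::write.csv(data.frame(z_center_A = centers,
                              density_per_nm = profile$density),
                   path, row.names = FALSE)
  invisible(path)
}
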