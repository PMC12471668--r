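#' Per-particle channel-frame tracks
#'
#' The unit of event detection: for one monomer (or the pooled 1-D synthetic
#' channel), a matrix of axial coordinates `z` (frames x particles, Angstrom,
#' unwrapped across periodic images), the frame times (ps), optional axial
#' velocities, and an optional lateral-gate flag matrix.
#'
#' @param times Strictly increasing frame times (ps).
#' @param z Numeric matrix, frames x particles.
#' @param vz Optional velocity matrix of the same shape (Angstrom/ps).
#' @param lateral_ok Optional logical matrix of the same shape.
#' @param particle_ids Optional particle identifiers (default column index).
#' @param monomer_id Label of the monomer the tracks belong to.
#' @return An object of class `particle_tracks`.
#' @export
particle_tracks <- function(times, z, vz = NULL, lateral_ok = NULL,
                            particle_ids = NULL, monomer_id = "pooled") {
  z <- as.matrix(z)
  times <- as.numeric(times)
  if (length(times) != nrow(z)) stop("times/z length mismatch")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (!is.null(vz)) {
    vz <- as.matrix(vz)
    if (!all(dim(vz) == dim(z))) stop("vz/z dimension mismatch")
  }
  if (!is.null(lateral_ok)) {
    lateral_ok <- as.matrix(lateral_ok)
    if (!all(dim(lateral_ok) == dim(z))) stop("lateral_ok/z dimension mismatch")
  }
  if (is.null(particle_ids)) particle_ids <- seq_len(ncol(z))
  structure(
    list(times = times, z = z, vz = vz, lateral_ok = lateral_ok,
         particle_ids = particle_ids, monomer_id = as.character(monomer_id)),
    class = "particle_tracks"
  )
}

#' @export
print.particle_tracks <- function(x, ...) {
  cat(sprintf("Particle tracks [%s]: %d particles x %d frames (%.4g ps)\n",
              x$monomer_id, ncol(x$z), nrow(x$z),
              if (length(x$times)) diff(range(x$times)) else 0))
  invisible(x)
}

#' Synthetic trajectory container
#'
#' Holds the output of the Langevin generator: channel-frame positions (and
#' optionally velocities) of all tagged particles, the frame interval, the
#' thermostat temperature and the box extent, plus the continuation state used
#' for chunked simulation.
#'
#' @param times Frame times (ps), strictly increasing.
#' @param z,vz Position / optional velocity matrices (frames x particles).
#' @param dt_frame Interval between stored frames (ps).
#' @param temperature Thermostat temperature (K).
#' @param box_z Full axial box length (Angstrom); walls at +/- box_z/2.
#' @param spec The [langevin_spec()] that produced the bundle, if any.
#' @param state Continuation state (internal).
#' @return An object of class `trajectory_bundle`.
#' @export
trajectory_bundle <- function(times, z, vz = NULL, dt_frame = NULL,
                              temperature = 298.15, box_z = NULL, spec = NULL,
                              state = NULL) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("a trajectory bundle needs at least 2 frames")
  if (is.null(dt_frame)) dt_frame <- diff(times[1:2])
  if (dt_frame <= 0) stop("dt_frame must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  structure(
    list(frames_count = nrow(z), dt_frame = dt_frame, times = as.numeric(times),
         z = z, vz = if (is.null(vz)) NULL else as.matrix(vz),
         temperature = temperature, box_z = box_z, spec = spec, state = state),
    class = "trajectory_bundle"
  )
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  cat(sprintf("Trajectory bundle: %d particles x %d frames, dt = %g ps, T = %g K\n",
              ncol(x$z), x$frames_count, x$dt_frame, x$temperature))
  invisible(x)
}

#' Convert a synthetic bundle to particle tracks
#'
#' @param bundle A [trajectory_bundle()].
#' @param monomer_id Label for the resulting tracks.
#' @return A [particle_tracks()] object (1-D: no lateral gate).
#' @export
as_particle_tracks <- function(bundle, monomer_id = "pooled") {
  stopifnot(inherits(bundle, "trajectory_bundle"))
  particle_tracks(bundle$times, bundle$z, vz = bundle$vz,
                  monomer_id = monomer_id)
}

#' Unwrap a periodic coordinate series
#'
#' Applies the minimum-image convention to each consecutive displacement so
#' that the series is continuous across periodic images: any per-frame jump
#' larger than half the box length is folded back.
#'
#' @param z Wrapped coordinate series.
#' @param box Box length along the coordinate; either a scalar or one value
#'   per frame.
#' @return The unwrapped series (same first value as `z`).
#' @examples
#' unwrap_coordinate(c(25, 29, -29), box = 60)  # continues to +31
#' @export
unwrap_coordinate <- function(z, box) {
  n <- length(z)
  if (n < 2) return(z)
  box <- rep_len(box, n)
  dz <- diff(z)
  b <- box[-1]
  dz <- dz - b * round(dz / b)
  z[1] + c(0, cumsum(dz))
}

# ---- DCD I/O -----------------------------------------------------------

#' Write a CHARMM/NAMD-style DCD trajectory
#'
#' Minimal single-precision DCD writer (native little-endian, CHARMM header
#' version 24), used to export synthetic trajectories so that the real-mode
#' readers can be exercised without external data.
#'
#' @param xyz Numeric matrix, frames x (3 * natoms), ordered x1,y1,z1,x2,...
#' @param path Output file path.
#' @param cell Optional per-frame unit cell: a matrix with columns a, b, c
#'   (Angstrom) or a single length-3 vector recycled to all frames.
#' @param dt Frame interval in ps (stored in the header time-step field).
#' @return `path`, invisibly.
#' @export
write_dcd <- function(xyz, path, cell = NULL, dt = 1) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0) stop("xyz must have 3*natoms columns")
  natoms <- ncol(xyz) %/% 3
  nframes <- nrow(xyz)
  has_cell <- !is.null(cell)
  if (has_cell) {
    cell <- if (is.null(dim(cell))) {
      matrix(cell, nframes, 3, byrow = TRUE)
    } else {
      as.matrix(cell)
    }
    if (nrow(cell) != nframes || ncol(cell) != 3) {
      stop("cell must be length 3 or an nframes x 3 matrix")
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header record: 'CORD' + 20 control integers (AKMA time step as float)
  wint(84L)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nframes      # NFILE
  icntrl[2] <- 1L           # ISTART
  icntrl[3] <- 1L           # NSAVC
  icntrl[4] <- nframes      # NSTEP
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L         # CHARMM version flag
  wint(icntrl[1:9])
  writeBin(as.numeric(dt / 0.0488882129), con, size = 4, endian = "little")
  wint(icntrl[11:20])
  wint(84L)
  # title record
  title <- sprintf("%-80s", "Synthetic trajectory written by aqpflux")
  wint(4L + 80L)
  wint(1L)
  writeChar(substr(title, 1, 80), con, nchars = 80, eos = NULL)
  wint(4L + 80L)
  # natoms record
  wint(4L)
  wint(natoms)
  wint(4L)
  xi <- seq(1, 3 * natoms, by = 3)
  for (f in seq_len(nframes)) {
    if (has_cell) {
      wint(48L)
      # XTLABC symmetric-storage order: A, cos(g), B, cos(b), cos(a), C
      writeBin(c(cell[f, 1], 0, cell[f, 2], 0, 0, cell[f, 3]), con,
               size = 8, endian = "little")
      wint(48L)
    }
    for (off in 0:2) {
      wint(4L * natoms)
      writeBin(as.numeric(xyz[f, xi + off]), con, size = 4, endian = "little")
      wint(4L * natoms)
    }
  }
  invisible(path)
}

# Parse just enough of a DCD header to audit frame completeness.
dcd_frame_audit <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n = 1) readBin(con, "integer", n = n, size = 4,
                                  endian = "little")
  if (rint() != 84L) stop("not a DCD file (bad header record): ", path)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a DCD file (missing CORD magic): ", path)
  icntrl <- rint(20)
  rint()  # trailing 84
  nframes_header <- icntrl[1]
  has_cell <- icntrl[11] == 1L
  tlen <- rint()
  seek(con, tlen, origin = "current")
  rint()
  rint()  # leading 4
  natoms <- rint()
  rint()
  header_bytes <- seek(con, where = NA)
  frame_bytes <- 3 * (8 + 4 * natoms) + if (has_cell) 8 + 48 else 0
  complete <- (sz - header_bytes) %/% frame_bytes
  truncated <- (sz - header_bytes) %% frame_bytes != 0
  list(natoms = natoms, nframes_header = nframes_header,
       nframes_complete = as.integer(complete), truncated = truncated,
       has_cell = has_cell)
}

# ---- PSF ----------------------------------------------------------------

#' Read the atom section of a PSF topology file
#'
#' Parses the `!NATOM` block of an X-PLOR/CHARMM PSF file into an atom table.
#'
#' @param path Path to a PSF file.
#' @return A data frame with columns `eleno`, `segid`, `resno`, `resid`,
#'   `elety`, `type`, `charge`, `mass`.
#' @export
read_psf_atoms <- function(path) {
  if (!file.exists(path)) stop("PSF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hit <- grep("!NATOM", lines, fixed = TRUE)
  if (!length(hit)) stop("no !NATOM section in PSF file: ", path)
  natom <- as.integer(strsplit(trimws(lines[hit[1]]), "\\s+")[[1]][1])
  rows <- lines[(hit[1] + 1):(hit[1] + natom)]
  tok <- strsplit(trimws(rows), "\\s+")
  bad <- which(lengths(tok) < 8)
  if (length(bad)) stop("malformed PSF atom line ", bad[1] + hit[1])
  data.frame(
    eleno = as.integer(vapply(tok, `[`, "", 1)),
    segid = vapply(tok, `[`, "", 2),
    resno = as.integer(vapply(tok, `[`, "", 3)),
    resid = vapply(tok, `[`, "", 4),
    elety = vapply(tok, `[`, "", 5),
    type = vapply(tok, `[`, "", 6),
    charge = as.numeric(vapply(tok, `[`, "", 7)),
    mass = as.numeric(vapply(tok, `[`, "", 8)),
    stringsAsFactors = FALSE
  )
}

# ---- reading real trajectories -----------------------------------------

water_resids <- c("TIP3", "TIP4", "TIP", "HOH", "WAT", "SPC", "SOL")
water_oxygen_names <- c("OH2", "OW", "O")

#' Read a topology plus trajectory into water-oxygen coordinates
#'
#' Reads a PDB or PSF topology and a DCD trajectory, selects the water oxygen
#' atoms (the oxygen stands for the whole molecule; hydrogens follow it
#' through the pore), and returns their per-frame coordinates together with
#' the full atom table for downstream structural analyses.
#'
#' @param topology_path Path to a `.pdb` or `.psf` topology.
#' @param trajectory_path Path to a `.dcd` trajectory.
#' @param water_selection Either `NULL` (default: common water residue names
#'   with oxygen atom names `OH2`/`OW`/`O`) or a list with elements `resid`
#'   and/or `elety` giving the residue and atom names to select.
#' @param frame_stride Keep every `frame_stride`-th frame (default 1).
#' @param dt_frame Interval between stored frames in the file, in ps
#'   (default 1; DCD headers do not reliably carry this).
#' @return An object of class `md_trajectory`: list with `atoms` (selected
#'   water-oxygen rows), `all_atoms`, `xyz` (frames x 3*nwater), `box`
#'   (frames x 3 or NULL), `n_frames`, `dt_frame`, `water_ids`.
#' @export
read_topology_and_trajectory <- function(topology_path, trajectory_path,
                                         water_selection = NULL,
                                         frame_stride = 1, dt_frame = 1) {
  if (!file.exists(topology_path)) stop("topology not found: ", topology_path)
  if (!file.exists(trajectory_path)) stop("trajectory not found: ", trajectory_path)
  ext <- tolower(sub(".*\\.", "", topology_path))
  atoms <- if (ext == "psf") {
    read_psf_atoms(topology_path)
  } else {
    pdb <- bio3d::read.pdb(topology_path)
    a <- pdb$atom
    data.frame(eleno = a$eleno, segid = if (is.null(a$segid)) "" else a$segid,
               resno = a$resno, resid = a$resid, elety = a$elety,
               stringsAsFactors = FALSE)
  }
  audit <- dcd_frame_audit(trajectory_path)
  if (audit$natoms != nrow(atoms)) {
    stop(sprintf("atom-count mismatch: topology has %d atoms, trajectory %d",
                 nrow(atoms), audit$natoms))
  }
  if (audit$truncated) {
    stop(sprintf("trajectory appears truncated: last complete frame is %d",
                 audit$nframes_complete))
  }
  xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
  box <- NULL
  if (audit$has_cell) {
    # bio3d returns per-frame (a, b, c, alpha, beta, gamma)
    cell <- bio3d::read.dcd(trajectory_path, cell = TRUE, verbose = FALSE)
    box <- cell[, 1:3, drop = FALSE]
    colnames(box) <- c("a", "b", "c")
  }
  sel_resid <- water_resids
  sel_elety <- water_oxygen_names
  if (!is.null(water_selection)) {
    if (!is.null(water_selection$resid)) sel_resid <- water_selection$resid
    if (!is.null(water_selection$elety)) sel_elety <- water_selection$elety
  }
  wsel <- which(atoms$resid %in% sel_resid & atoms$elety %in% sel_elety)
  if (!length(wsel)) {
    stop("water selection matched no atoms (resid in ",
         paste(sel_resid, collapse = "/"), ", name in ",
         paste(sel_elety, collapse = "/"), ")")
  }
  cols <- as.vector(rbind(3 * (wsel - 1) + 1, 3 * (wsel - 1) + 2, 3 * wsel))
  keep <- seq(1, nrow(xyz), by = frame_stride)
  structure(
    list(atoms = atoms[wsel, , drop = FALSE], all_atoms = atoms,
         xyz = xyz[keep, cols, drop = FALSE],
         box = if (is.null(box)) NULL else box[keep, , drop = FALSE],
         n_frames = length(keep), dt_frame = dt_frame * frame_stride,
         water_ids = atoms$eleno[wsel]),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("MD trajectory: %d frames x %d waters, dt_frame = %g ps\n",
              x$n_frames, length(x$water_ids), x$dt_frame))
  invisible(x)
}

#' Project an MD trajectory into a monomer's channel frame
#'
#' Builds per-water channel-frame tracks: axial coordinate series (unwrapped
#' along the axis with the minimum-image convention, using the per-frame box
#' when available) and the lateral-gate flag series.
#'
#' @param traj An `md_trajectory` from [read_topology_and_trajectory()].
#' @param frame A [channel_frame()].
#' @param unwrap Apply minimum-image unwrapping to each z series (default
#'   TRUE; requires `traj$box` or `box_z`).
#' @param box_z Fallback axial box length (Angstrom) when the trajectory
#'   carries no cell information.
#' @param reference_z Optional per-frame axial coordinate of a reference
#'   group (e.g. the channel's constriction residues), subtracted from every
#'   z so the frame follows protein drift; length must equal the frame
#'   count.
#' @return A [particle_tracks()] object.
#' @export
project_md_tracks <- function(traj, frame, unwrap = TRUE, box_z = NULL,
                              reference_z = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(frame, "channel_frame"))
  if (!is.null(reference_z) && length(reference_z) != traj$n_frames) {
    stop("reference_z must have one value per frame")
  }
  nw <- length(traj$water_ids)
  nf <- traj$n_frames
  z <- matrix(NA_real_, nf, nw)
  lat <- matrix(TRUE, nf, nw)
  for (f in seq_len(nf)) {
    xyz <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    pr <- project_to_channel_frame(xyz, frame)
    z[f, ] <- if (is.null(reference_z)) pr$z else pr$z - reference_z[f]
    lat[f, ] <- pr$lateral_ok
  }
  if (unwrap && nf > 1) {
    bz <- if (!is.null(traj$box)) traj$box[, 3] else box_z
    if (is.null(bz)) {
      warning("no box information; skipping unwrap")
    } else {
      for (p in seq_len(nw)) z[, p] <- unwrap_coordinate(z[, p], bz)
    }
  }
  times <- (seq_len(nf) - 1) * traj$dt_frame
  particle_tracks(times, z, lateral_ok = lat, particle_ids = traj$water_ids,
                  monomer_id = frame$monomer_id)
}

# ---- on-disk cache ------------------------------------------------------

#' Write / read the internal trajectory cache
#'
#' The cache is a flat binary file of doubles (times, z, and vz when present)
#' with a JSON sidecar holding dimensions and metadata. The round trip is
#' bit-exact.
#'
#' @param bundle A [trajectory_bundle()].
#' @param path Cache path stem; `<path>.bin` and `<path>.json` are written.
#' @return `path`, invisibly (writer); a [trajectory_bundle()] (reader).
#' @export
write_trajectory_cache <- function(bundle, path) {
  stopifnot(inherits(bundle, "trajectory_bundle"))
  meta <- list(
    frames_count = bundle$frames_count, n_particles = ncol(bundle$z),
    dt_frame = bundle$dt_frame, temperature = bundle$temperature,
    box_z = bundle$box_z, has_vz = !is.null(bundle$vz),
    endian = .Platform$endian, format = "aqpflux-cache-1"
  )
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(bundle$times), con, size = 8)
  writeBin(as.numeric(bundle$z), con, size = 8)
  if (!is.null(bundle$vz)) writeBin(as.numeric(bundle$vz), con, size = 8)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_cache
#' @export
read_trajectory_cache <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "aqpflux-cache-1")) {
    stop("unrecognised cache format: ", meta$format)
  }
  nf <- meta$frames_count
  np <- meta$n_particles
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  times <- readBin(con, "numeric", n = nf, size = 8)
  z <- matrix(readBin(con, "numeric", n = nf * np, size = 8), nf, np)
  vz <- if (isTRUE(meta$has_vz)) {
    matrix(readBin(con, "numeric", n = nf * np, size = 8), nf, np)
  } else {
    NULL
  }
  trajectory_bundle(times, z, vz = vz, dt_frame = meta$dt_frame,
                    temperature = meta$temperature,
                    box_z = if (is.null(meta$box_z)) NULL else meta$box_z)
}
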