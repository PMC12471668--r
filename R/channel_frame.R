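#' Define a per-monomer channel coordinate frame
#'
#' A channel frame maps laboratory coordinates into the channel's own axial
#' coordinate: `z = dot(position - origin, axis)`. The origin is placed so the
#' dividing plane (the most constricted point of the pore) sits at
#' `z = z_divide` (default 0), with `+z` pointing from the intracellular (IC)
#' to the extracellular (EC) side. Bulk thresholds mark where a permeating
#' molecule is considered to have reached the IC or EC reservoir.
#'
#' @param monomer_id Label for the monomer (e.g. `"A"`).
#' @param origin Numeric length-3 lab-frame origin (Angstrom).
#' @param axis Numeric length-3 channel axis (IC to EC); normalised internally.
#' @param z_divide Dividing-plane position in the channel frame (Angstrom).
#' @param z_bulk_ec,z_bulk_ic EC / IC bulk thresholds (Angstrom). Defaults
#'   +15 / -15.
#' @param radius_gate Lateral cutoff (Angstrom) deciding whether a molecule
#'   inside the slab belongs to this monomer's channel.
#' @return An object of class `channel_frame`.
#' @examples
#' channel_frame("A", origin = c(0, 0, 0), axis = c(0, 0, 1))
#' @export
channel_frame <- function(monomer_id, origin = c(0, 0, 0), axis = c(0, 0, 1),
                          z_divide = 0, z_bulk_ec = 15, z_bulk_ic = -15,
                          radius_gate = 6) {
  origin <- as.numeric(origin)
  axis <- as.numeric(axis)
  stopifnot(length(origin) == 3, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-8) stop("degenerate channel axis (norm < 1e-8)")
  axis <- axis / nrm
  if (!(z_bulk_ic < z_divide && z_divide < z_bulk_ec)) {
    stop("channel frame requires z_bulk_ic < z_divide < z_bulk_ec")
  }
  if (radius_gate <= 0) stop("radius_gate must be positive")
  structure(
    list(monomer_id = as.character(monomer_id), origin = origin, axis = axis,
         z_divide = z_divide, z_bulk_ec = z_bulk_ec, z_bulk_ic = z_bulk_ic,
         radius_gate = radius_gate),
    class = "channel_frame"
  )
}

#' @export
print.channel_frame <- function(x, ...) {
  cat(sprintf("Channel frame '%s': origin (%g, %g, %g), axis (%.3f, %.3f, %.3f)\n",
              x$monomer_id, x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3]))
  cat(sprintf("  dividing plane z = %g; bulk thresholds [%g, %g]; radius gate %g A\n",
              x$z_divide, x$z_bulk_ic, x$z_bulk_ec, x$radius_gate))
  invisible(x)
}

#' Build channel frames from a topology and a monomer specification
#'
#' Each monomer is specified either explicitly (`origin` + `axis`) or by two
#' residue groups: the channel axis is the unit vector from the centroid of
#' the IC-side group to the centroid of the EC-side group, and the origin is
#' the configured constriction point (an explicit `origin`, the centroid of a
#' `constriction` residue group, or the midpoint of the two group centroids).
#'
#' @param topology Path to a PDB file, a `bio3d` `pdb` object, or `NULL` when
#'   all monomers are specified explicitly.
#' @param monomer_spec A list of per-monomer specs. Each element is a list
#'   with `id` and either `origin`/`axis`, or `ec_residues`/`ic_residues`
#'   (residue numbers) plus optionally `origin` or `constriction`.
#' @param channel Optional list of channel parameters applied to every frame:
#'   `z_divide`, `z_bulk_ec`, `z_bulk_ic`, `radius_gate`.
#' @return A list of [channel_frame()] objects.
#' @export
build_channel_frames <- function(topology = NULL, monomer_spec, channel = list()) {
  if (!length(monomer_spec)) stop("monomer_spec must name at least one monomer")
  pdb <- NULL
  if (!is.null(topology)) {
    pdb <- if (inherits(topology, "pdb")) topology else bio3d::read.pdb(topology)
  }
  centroid <- function(resnos) {
    sel <- pdb$atom$resno %in% resnos
    if (!any(sel)) {
      stop("residue group not found in topology: ", paste(resnos, collapse = ","))
    }
    colMeans(pdb$atom[sel, c("x", "y", "z")])
  }
  chan_args <- channel[intersect(names(channel),
                                 c("z_divide", "z_bulk_ec", "z_bulk_ic",
                                   "radius_gate"))]
  frames <- lapply(seq_along(monomer_spec), function(i) {
    m <- monomer_spec[[i]]
    id <- if (!is.null(m$id)) m$id else as.character(i)
    if (!is.null(m$axis)) {
      origin <- if (!is.null(m$origin)) m$origin else c(0, 0, 0)
      axis <- m$axis
    } else {
      if (is.null(m$ec_residues) || is.null(m$ic_residues)) {
        stop("monomer '", id, "' needs either an explicit axis or ",
             "ec_residues/ic_residues groups")
      }
      if (is.null(pdb)) stop("residue-group monomer specs require a topology")
      ec <- centroid(m$ec_residues)
      ic <- centroid(m$ic_residues)
      axis <- ec - ic
      origin <- if (!is.null(m$origin)) {
        m$origin
      } else if (!is.null(m$constriction)) {
        centroid(m$constriction)
      } else {
        (ec + ic) / 2
      }
    }
    do.call(channel_frame,
            c(list(monomer_id = id, origin = origin, axis = axis), chan_args))
  })
  names(frames) <- vapply(frames, function(f) f$monomer_id, character(1))
  frames
}

#' Read a channel/monomer configuration file
#'
#' The YAML config has blocks `system` (e.g. `temperature`), `channel`
#' (`z_divide`, `z_bulk_ec`, `z_bulk_ic`, `radius_gate`) and `monomers`
#' (a list of per-monomer specs as in [build_channel_frames()]).
#'
#' @param path Path to a YAML configuration file.
#' @param topology Optional topology forwarded to [build_channel_frames()].
#' @return A list with elements `system`, `channel` and `frames`.
#' @export
read_channel_config <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$monomers)) stop("config has no 'monomers' block")
  frames <- build_channel_frames(topology, cfg$monomers,
                                 channel = if (is.null(cfg$channel)) list() else cfg$channel)
  list(system = cfg$system, channel = cfg$channel, frames = frames)
}

#' Project laboratory coordinates into a channel frame
#'
#' Computes the axial coordinate `z = dot(position - origin, axis)` and the
#' lateral gate flag for each position. Inside the slab
#' (`z_bulk_ic < z < z_bulk_ec`) a position passes the gate when its distance
#' from the channel axis is at most `radius_gate`; outside the slab the flag
#' is `TRUE` by definition (the molecule is in bulk).
#'
#' @param xyz Numeric matrix with 3 columns (or a length-3 vector) of
#'   lab-frame coordinates in Angstrom.
#' @param frame A [channel_frame()].
#' @return A list with numeric `z` and logical `lateral_ok`, one entry per row.
#' @examples
#' fr <- channel_frame("A")
#' project_to_channel_frame(c(0, 0, 5), fr)$z
#' @export
project_to_channel_frame <- function(xyz, frame) {
  stopifnot(inherits(frame, "channel_frame"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  rel <- sweep(xyz, 2, frame$origin)
  z <- as.numeric(rel %*% frame$axis)
  lat2 <- rowSums((rel - outer(z, frame$axis))^2)
  in_slab <- z > frame$z_bulk_ic & z < frame$z_bulk_ec
  lateral_ok <- !in_slab | lat2 <= frame$radius_gate^2
  list(z = z, lateral_ok = lateral_ok)
}

#' Assign molecules to monomer channels
#'
#' A molecule inside the analysis slab belongs to the monomer whose axis it is
#' nearest to, provided that distance is within the monomer's `radius_gate`;
#' ties are broken by the lowest monomer id. A molecule can belong to at most
#' one monomer per frame.
#'
#' @param xyz Numeric matrix (rows = molecules) of lab coordinates.
#' @param frames List of [channel_frame()] objects.
#' @return Integer vector of frame indices (`NA` when unassigned).
#' @export
assign_to_monomers <- function(xyz, frames) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  ord <- order(vapply(frames, function(f) f$monomer_id, character(1)))
  d2 <- matrix(Inf, nrow(xyz), length(frames))
  for (j in seq_along(frames)) {
    f <- frames[[ord[j]]]
    pr <- project_to_channel_frame(xyz, f)
    rel <- sweep(xyz, 2, f$origin)
    lat2 <- rowSums((rel - outer(pr$z, f$axis))^2)
    in_slab <- pr$z > f$z_bulk_ic & pr$z < f$z_bulk_ec
    d2[, j] <- ifelse(in_slab & lat2 <= f$radius_gate^2, lat2, Inf)
  }
  best <- max.col(-d2, ties.method = "first")
  best[!is.finite(d2[cbind(seq_len(nrow(d2)), best)])] <- NA_integer_
  ord[best]
}
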