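#' Geometric hydrogen-bond criterion
#'
#' The de facto MD convention: a donor-acceptor heavy-atom distance cutoff
#' and a maximum deviation of the donor-hydrogen-acceptor arrangement from
#' linearity.
#'
#' @param d_max Donor-heavy-atom to acceptor distance cutoff (Angstrom).
#' @param angle_max Maximum D-H...A deviation from linearity (degrees).
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(d_max = 3.5, angle_max = 30) {
  stopifnot(d_max > 0, angle_max > 0, angle_max < 90)
  structure(list(d_max = d_max, angle_max = angle_max),
            class = "hbond_criterion")
}

# Deviation (degrees) of D-H...A from linearity: 180 - angle at H.
hbond_angle_dev <- function(D, H, A) {
  u <- D - H
  v <- A - H
  cs <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  cs <- pmin(1, pmax(-1, cs))
  180 - acos(cs) * 180 / pi
}

water_O <- function(w) as.matrix(w[, c("ox", "oy", "oz")])
water_H <- function(w, k) {
  as.matrix(w[, paste0("h", k, c("x", "y", "z"))])
}

#' Select single-file waters in the channel
#'
#' Per frame, the waters that pass the lateral gate and whose axial
#' coordinate lies inside the single-file region (an explicit z interval, or
#' the sub-threshold extent from [single_file_extent()]).
#'
#' @param tracks A [particle_tracks()] object.
#' @param region Numeric length-2 interval `(z_lo, z_hi)` in Angstrom.
#' @return A list (one element per frame) of particle ids.
#' @export
select_single_file_waters <- function(tracks, region) {
  stopifnot(inherits(tracks, "particle_tracks"), length(region) == 2)
  if (region[2] <= region[1]) stop("empty single-file region")
  lat <- tracks$lateral_ok
  lapply(seq_len(nrow(tracks$z)), function(f) {
    keep <- tracks$z[f, ] > region[1] & tracks$z[f, ] < region[2]
    if (!is.null(lat)) keep <- keep & lat[f, ]
    tracks$particle_ids[keep]
  })
}

#' Count hydrogen bonds in one frame
#'
#' A bond is counted when the donor-heavy-atom to acceptor distance is at
#' most `d_max` and the D-H...A deviation from linearity is at most
#' `angle_max`; each donor hydrogen is counted at most once per acceptor,
#' and water-water pairs are counted once (unordered).
#'
#' @param waters A `water_set` data frame (columns `id`, `ox`..`oz`,
#'   `h1x`..`h2z`), e.g. from [make_hbond_fixture()]; for `water-protein`
#'   pairing this is the selected single-file set.
#' @param criterion An [hbond_criterion()].
#' @param pairing `"water-water"` or `"water-protein"`.
#' @param protein_acceptors Data frame of acceptor heavy-atom coordinates
#'   (`x`, `y`, `z`).
#' @param protein_donors Data frame of donor groups: heavy atom (`x`, `y`,
#'   `z`) and its hydrogen (`hx`, `hy`, `hz`); one row per donor hydrogen.
#' @return Integer bond count for the frame.
#' @examples
#' w <- make_hbond_fixture(5, spacing = 2.8)
#' count_hbonds(w, hbond_criterion())  # 4
#' @export
count_hbonds <- function(waters, criterion = hbond_criterion(),
                         pairing = c("water-water", "water-protein"),
                         protein_acceptors = NULL, protein_donors = NULL) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(criterion, "hbond_criterion"))
  need <- c("ox", "oy", "oz", "h1x", "h1y", "h1z", "h2x", "h2y", "h2z")
  if (!all(need %in% names(waters))) {
    miss <- setdiff(need, names(waters))
    stop("water set is missing hydrogen/oxygen columns: ",
         paste(miss, collapse = ", "))
  }
  nw <- nrow(waters)
  O <- water_O(waters)
  if (pairing == "water-water") {
    if (nw < 2) return(0L)
    bonded <- matrix(FALSE, nw, nw)
    pairs <- which(upper.tri(matrix(0, nw, nw)), arr.ind = TRUE)
    d <- sqrt(rowSums((O[pairs[, 1], , drop = FALSE] -
                         O[pairs[, 2], , drop = FALSE])^2))
    close <- d <= criterion$d_max
    for (k in which(close)) {
      i <- pairs[k, 1]
      j <- pairs[k, 2]
      for (dir in list(c(i, j), c(j, i))) {
        for (h in 1:2) {
          dev <- hbond_angle_dev(O[dir[1], , drop = FALSE],
                                 water_H(waters, h)[dir[1], , drop = FALSE],
                                 O[dir[2], , drop = FALSE])
          if (dev <= criterion$angle_max) bonded[i, j] <- TRUE
        }
      }
    }
    return(sum(bonded))
  }
  # water-protein
  n <- 0L
  if (!is.null(protein_acceptors) && nw > 0) {
    A <- as.matrix(protein_acceptors[, c("x", "y", "z")])
    for (h in 1:2) {
      H <- water_H(waters, h)
      for (i in seq_len(nw)) {
        d <- sqrt(colSums((t(A) - O[i, ])^2))
        ok <- d <= criterion$d_max
        if (any(ok)) {
          dev <- hbond_angle_dev(
            matrix(O[i, ], sum(ok), 3, byrow = TRUE),
            matrix(H[i, ], sum(ok), 3, byrow = TRUE),
            A[ok, , drop = FALSE])
          n <- n + sum(dev <= criterion$angle_max)
        }
      }
    }
  }
  if (!is.null(protein_donors) && nw > 0) {
    D <- as.matrix(protein_donors[, c("x", "y", "z")])
    H <- as.matrix(protein_donors[, c("hx", "hy", "hz")])
    if (anyNA(H)) stop("protein donor rows must carry hydrogen coordinates")
    for (r in seq_len(nrow(D))) {
      d <- sqrt(colSums((t(O) - D[r, ])^2))
      ok <- d <= criterion$d_max
      if (any(ok)) {
        dev <- hbond_angle_dev(matrix(D[r, ], sum(ok), 3, byrow = TRUE),
                               matrix(H[r, ], sum(ok), 3, byrow = TRUE),
                               O[ok, , drop = FALSE])
        n <- n + sum(dev <= criterion$angle_max)
      }
    }
  }
  n
}

#' Probability histogram of hydrogen-bond counts
#'
#' @param counts Integer vector of per-frame bond counts.
#' @param kind `"water-water"` or `"water-protein"` (label).
#' @param monomer_id Label (`"averaged"` for monomer means).
#' @return An object of class `hbond_histogram` with `counts_axis`
#'   (0..max), `probability` (sums to 1), `mean` and `n_frames`.
#' @examples
#' hbond_histogram(c(2, 2, 4, 4))$mean  # 3
#' @export
hbond_histogram <- function(counts, kind = "water-water",
                            monomer_id = "pooled") {
  stopifnot(length(counts) >= 1, all(counts >= 0))
  axis <- 0:max(counts)
  p <- tabulate(counts + 1, nbins = length(axis)) / length(counts)
  structure(
    list(counts_axis = axis, probability = p, mean = mean(counts),
         n_frames = length(counts), kind = kind,
         monomer_id = as.character(monomer_id)),
    class = "hbond_histogram"
  )
}

#' @export
print.hbond_histogram <- function(x, ...) {
  cat(sprintf("H-bond histogram [%s, %s]: mean %.3f over %d frames\n",
              x$kind, x$monomer_id, x$mean, x$n_frames))
  invisible(x)
}

#' @export
plot.hbond_histogram <- function(x, ...) {
  graphics::barplot(x$probability, names.arg = x$counts_axis,
                    xlab = "hydrogen bonds", ylab = "probability", ...)
  invisible(x)
}

#' Merge per-monomer hydrogen-bond histograms
#'
#' Weighted average of the per-monomer probability histograms, weights
#' proportional to the number of frames behind each.
#'
#' @param histograms List of `hbond_histogram` objects of one `kind`.
#' @param weights Optional weights (default: frame counts).
#' @return An `hbond_histogram` labelled `"averaged"`.
#' @export
merge_hbond_histograms <- function(histograms, weights = NULL) {
  if (is.null(weights)) {
    weights <- vapply(histograms, `[[`, numeric(1), "n_frames")
  }
  weights <- weights / sum(weights)
  nmax <- max(vapply(histograms, function(h) max(h$counts_axis), numeric(1)))
  axis <- 0:nmax
  p <- numeric(length(axis))
  m <- 0
  for (i in seq_along(histograms)) {
    h <- histograms[[i]]
    p[seq_along(h$probability)] <- p[seq_along(h$probability)] +
      weights[i] * h$probability
    m <- m + weights[i] * h$mean
  }
  structure(
    list(counts_axis = axis, probability = p, mean = m,
         n_frames = sum(vapply(histograms, `[[`, numeric(1), "n_frames")),
         kind = histograms[[1]]$kind, monomer_id = "averaged"),
    class = "hbond_histogram"
  )
}

#' Identify pore-lining residues
#'
#' Residues with any heavy atom within `cutoff` of any selected single-file
#' water in at least a fraction `min_frac` of frames. Explicit residue lists
#' from a configuration file may be used instead.
#'
#' @param protein_frames List (one element per frame) of data frames with
#'   columns `resno`, `x`, `y`, `z` (heavy atoms).
#' @param water_frames List (one element per frame) of matrices/data frames
#'   of selected water oxygen coordinates (columns x, y, z).
#' @param cutoff Distance cutoff (Angstrom).
#' @param min_frac Minimum fraction of frames (default 0.01).
#' @return Sorted vector of residue numbers.
#' @export
find_pore_lining <- function(protein_frames, water_frames, cutoff = 4.5,
                             min_frac = 0.01) {
  stopifnot(length(protein_frames) == length(water_frames))
  nf <- length(protein_frames)
  hits <- list()
  for (f in seq_len(nf)) {
    pa <- protein_frames[[f]]
    W <- as.matrix(water_frames[[f]])
    if (!nrow(pa) || !nrow(W)) next
    P <- as.matrix(pa[, c("x", "y", "z")])
    near <- vapply(seq_len(nrow(P)), function(i) {
      min(sqrt(rowSums(sweep(W, 2, P[i, ])^2))) <= cutoff
    }, logical(1))
    res <- unique(pa$resno[near])
    for (r in res) {
      key <- as.character(r)
      hits[[key]] <- (if (is.null(hits[[key]])) 0 else hits[[key]]) + 1
    }
  }
  counts <- unlist(hits)
  if (is.null(counts)) return(integer(0))
  sort(as.integer(names(counts)[counts / nf >= min_frac]))
}
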