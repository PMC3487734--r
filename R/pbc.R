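# Periodic-boundary geometry. Orthorhombic boxes only: each Cartesian
# displacement component is wrapped into (-L/2, L/2] before the Euclidean
# norm. Triclinic boxes are refused upstream at read time.

# Wrap displacement components into (-L/2, L/2] per axis.
wrap_disp <- function(d, box) {
  for (k in seq_len(3L)) {
    L <- box[k]
    d[, k] <- d[, k] - L * round(d[, k] / L)
    # round() maps exactly -L/2 to -L/2 (round-half-even); fold to +L/2
    fix <- d[, k] <= -L / 2
    if (any(fix)) d[fix, k] <- d[fix, k] + L
  }
  d
}

#' Minimum-image distance between two atoms
#'
#' @param frame an `mh_frame`.
#' @param i,j atom indices (1-based).
#' @return distance in Angstrom. Without a box the raw Euclidean distance is
#'   returned with a warning.
#' @export
minimum_image_distance <- function(frame, i, j) {
  d <- matrix(frame$xyz[j, ] - frame$xyz[i, ], ncol = 3L)
  if (is.null(frame$box)) {
    warning("frame has no box; returning raw distance", call. = FALSE)
  } else {
    d <- wrap_disp(d, frame$box)
  }
  sqrt(sum(d * d))
}

# All pairwise minimum-image distances between two coordinate blocks.
# Returns |A| x |B| matrix. box = NULL -> raw distances.
pair_distances <- function(xyz_a, xyz_b, box = NULL) {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  d2 <- matrix(0, na, nb)
  for (k in seq_len(3L)) {
    dk <- outer(xyz_a[, k], xyz_b[, k], "-")
    if (!is.null(box)) {
      L <- box[k]
      dk <- dk - L * round(dk / L)
    }
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Geometric centre of a selection
#'
#' Unweighted mean of the member coordinates (no mass weighting), matching
#' the convention used for side-chain centres in immersion-depth profiles.
#'
#' @param frame an `mh_frame`.
#' @param sel selection (atom indices).
#' @return numeric 3-vector (Angstrom).
#' @export
geometric_center <- function(frame, sel) {
  idx <- as.integer(sel)
  if (length(idx) == 0L) stop("empty selection", call. = FALSE)
  colMeans(frame$xyz[idx, , drop = FALSE])
}

#' Recentre a membrane frame in z
#'
#' Makes every residue whole across the z boundary (atoms are unwrapped
#' relative to the residue's first atom), then shifts the whole frame so the
#' mean phosphorus z sits at `box_z / 2`, and finally wraps whole residues
#' back into `[0, box_z)` by their centres. Idempotent on an already-centred
#' slab. x and y are untouched.
#'
#' @param system an `mh_system` (all frames are recentred).
#' @param phosphorus selection of the phosphorus reference atoms.
#' @param frame optional single frame index; default all frames.
#' @return the system with recentred frames.
#' @export
recenter_membrane <- function(system, phosphorus, frame = NULL) {
  idx <- as.integer(phosphorus)
  which_frames <- if (is.null(frame)) seq_along(system$frames) else frame
  resid <- system$atoms$resid
  for (fi in which_frames) {
    fr <- system$frames[[fi]]
    if (is.null(fr$box)) stop("recenter_membrane needs a periodic box",
                              call. = FALSE)
    Lz <- fr$box[3L]
    z <- fr$xyz[, 3L]
    # make molecules whole in z relative to their first atom
    first_of <- match(unique(resid), resid)
    zref <- z[first_of][match(resid, unique(resid))]
    dz <- z - zref
    dz <- dz - Lz * round(dz / Lz)
    z <- zref + dz
    # shift so mean phosphorus z = Lz / 2
    shift <- Lz / 2 - mean(z[idx])
    z <- z + shift
    # wrap whole residues back by their centres
    cz <- stats::ave(z, resid)
    z <- z - Lz * floor(cz / Lz)
    fr$xyz[, 3L] <- z
    system$frames[[fi]] <- fr
  }
  system
}
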