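#' Interhelical (kink) angle series
#'
#' Per frame, the angle between two C-alpha difference vectors flanking the
#' hinge: by default the vector from CA(13) to CA(17) against the vector
#' from CA(19) to CA(23), i.e. one helical turn preceding and succeeding the
#' His18 hinge of the IAPP 1-25 fragment.
#'
#' @param system an `mh_system`.
#' @param vec_a,vec_b length-2 author residue numbers `(from, to)` defining
#'   the two CA difference vectors.
#' @return numeric vector of angles (degrees, `[0, 180]`; `NA` where a
#'   vector degenerates), class `mh_angle_series`, with the vector
#'   definitions kept as attributes.
#' @export
interhelical_angle <- function(system, vec_a = c(13L, 17L),
                               vec_b = c(19L, 23L)) {
  ca <- function(resseq) {
    a <- atom_in_residue(system, resid_of_resseq(system, resseq), "CA")
    if (is.na(a)) stop("no CA atom for residue ", resseq, call. = FALSE)
    a
  }
  ia <- vapply(vec_a, ca, integer(1))
  ib <- vapply(vec_b, ca, integer(1))
  ang <- vapply(system$frames, function(fr) {
    va <- fr$xyz[ia[2L], ] - fr$xyz[ia[1L], ]
    vb <- fr$xyz[ib[2L], ] - fr$xyz[ib[1L], ]
    if (vec_norm(va) < 1e-9 || vec_norm(vb) < 1e-9) return(NA_real_)
    vec_angle(va, vb)
  }, numeric(1))
  structure(ang, vec_a = vec_a, vec_b = vec_b, class = "mh_angle_series")
}

#' Binned interhelical-angle distribution
#'
#' Normalised histogram over `[0, 180)` degrees with right-open bins; the
#' default 10-degree width reports midpoints 5, 15, ..., 175.
#'
#' @param series angle series (degrees); `NA` entries are dropped.
#' @param bin_width bin width in degrees (default 10).
#' @return data.frame with `midpoint` and `frequency` (sums to 1).
#' @export
angle_distribution <- function(series, bin_width = 10) {
  a <- as.numeric(series)
  a <- a[!is.na(a)]
  if (length(a) == 0L) stop("no defined angles", call. = FALSE)
  breaks <- seq(0, 180, by = bin_width)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  bin <- findInterval(a, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  data.frame(midpoint = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             frequency = counts / sum(counts))
}

#' Conformational-family classification by kink angle
#'
#' Splits frames into a compact family (angle below the boundary) and an
#' L-shaped family (angle at or above it). The default 60-degree boundary
#' lies midway between the 40- and 90-degree S20G populations.
#'
#' @param series angle series (degrees).
#' @param boundary family boundary in degrees (default 60).
#' @return list with per-frame `family` labels and the family `fractions`.
#' @export
classify_families <- function(series, boundary = 60) {
  a <- as.numeric(series)
  fam <- ifelse(is.na(a), NA_character_,
                ifelse(a < boundary, "compact", "L-shaped"))
  def <- fam[!is.na(fam)]
  if (length(def) == 0L) stop("no defined angles", call. = FALSE)
  fr <- c(compact = mean(def == "compact"),
          `L-shaped` = mean(def == "L-shaped"))
  list(family = fam, fractions = fr, boundary = boundary)
}

#' Least-squares helix axis
#'
#' First principal axis of a set of CA coordinates, oriented from the
#' N-terminal to the C-terminal end of the selection.
#'
#' @param frame an `mh_frame`.
#' @param ca_selection selection of at least 4 CA atoms, in N-to-C order.
#' @return list with unit `axis` (3-vector) and `centroid`.
#' @export
fit_helix_axis <- function(frame, ca_selection) {
  idx <- sort(as.integer(ca_selection))  # N-to-C by atom order
  if (length(idx) < 4L) stop("need at least 4 CA atoms to fit a helix axis",
                             call. = FALSE)
  X <- frame$xyz[idx, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  ax <- svd(Xc, nu = 0L, nv = 1L)$v[, 1L]
  if (sum(ax * (X[nrow(X), ] - X[1L, ])) < 0) ax <- -ax
  list(axis = ax, centroid = ctr)
}

#' Immersion depth below the phosphate plane
#'
#' Signed z-distance from the mean phosphorus z of the interfacial leaflet,
#' positive toward the bilayer core (buried). With the peptide at the upper
#' leaflet, a side-chain centre 7 A below the plane has depth +7 A. Frames
#' are assumed to be recentred ([recenter_membrane()]).
#'
#' @param system an `mh_system`.
#' @param phosphorus selection of phosphorus reference atoms.
#' @param interface `"upper"` or `"lower"`: the leaflet the peptide binds.
#' @param residues author residue numbers: per-residue side-chain geometric
#'   centres are profiled (side chain = heavy side-chain atoms; CA for Gly).
#' @param selection alternatively, one explicit selection whose geometric
#'   centre is tracked (used for whole-helix depths).
#' @param frames frame range (see [resolve_frames()]).
#' @return For `residues`: data.frame `resseq`, `mean_depth`, `sd`,
#'   `n_frames`. For `selection`: numeric per-frame depth vector.
#' @export
immersion_depth <- function(system, phosphorus, interface = c("upper", "lower"),
                            residues = NULL, selection = NULL, frames = NULL) {
  interface <- match.arg(interface)
  p_idx <- as.integer(phosphorus)
  if (length(p_idx) == 0L) stop("empty phosphorus selection", call. = FALSE)
  fr_idx <- resolve_frames(n_frames(system), frames)
  leaflet_p <- function(fr) {
    z <- fr$xyz[p_idx, 3L]
    mid <- (min(z) + max(z)) / 2
    side <- if (interface == "upper") z >= mid else z < mid
    if (!any(side)) stop("interface leaflet has no phosphorus atoms",
                         call. = FALSE)
    mean(z[side])
  }
  depth_of <- function(fr, idx) {
    zc <- mean(fr$xyz[idx, 3L])
    if (interface == "upper") leaflet_p(fr) - zc else zc - leaflet_p(fr)
  }
  if (!is.null(selection)) {
    idx <- as.integer(selection)
    return(vapply(system$frames[fr_idx], depth_of, numeric(1), idx = idx))
  }
  if (is.null(residues)) stop("give `residues` or `selection`", call. = FALSE)
  at <- system$atoms
  sc_mask <- sidechain_heavy_mask(at)
  out <- lapply(residues, function(rs) {
    rid <- resid_of_resseq(system, rs)
    idx <- which(at$resid == rid & sc_mask)
    if (length(idx) == 0L)
      idx <- atom_in_residue(system, rid, "CA")  # bead-less fallback
    d <- vapply(system$frames[fr_idx], depth_of, numeric(1), idx = idx)
    data.frame(resseq = rs, mean_depth = mean(d),
               sd = stats::sd(d), n_frames = length(d))
  })
  do.call(rbind, out)
}

#' Kabsch superposition and RMSD
#'
#' Optimal proper rotation (det +1) after centroid removal, plus the RMSD of
#' the superposed paired coordinate sets.
#'
#' @param mobile,reference N x 3 coordinate matrices of paired atoms (same
#'   order), N >= 3.
#' @return list: `rotation` (3 x 3, orthonormal, det +1), `translation`
#'   (applied as `x %*% t(R) + translation`), `rmsd` (Angstrom).
#' @export
superpose_rmsd <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be equal-size N x 3 matrices",
         call. = FALSE)
  if (nrow(mobile) < 3L) stop("need at least 3 atom pairs", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2L, cm); B <- sweep(reference, 2L, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - (R %*% cm)), rmsd = rmsd)
}

#' Superpose on CA atoms by author residue numbers
#'
#' Convenience wrapper pairing CA atoms of the same residue numbers in two
#' systems/frames (e.g. the ordered helix, residues 5-17).
#'
#' @param mobile_system,reference_system `mh_system`s.
#' @param residues author residue numbers to pair.
#' @param mobile_frame,reference_frame frame indices.
#' @return as [superpose_rmsd()].
#' @export
superpose_ca <- function(mobile_system, reference_system, residues,
                         mobile_frame = 1L, reference_frame = 1L) {
  grab <- function(sys, fr) {
    idx <- vapply(residues, function(rs)
      atom_in_residue(sys, resid_of_resseq(sys, rs), "CA"), integer(1))
    if (anyNA(idx)) stop("missing CA atoms in pairing", call. = FALSE)
    get_frame(sys, fr)$xyz[idx, , drop = FALSE]
  }
  superpose_rmsd(grab(mobile_system, mobile_frame),
                 grab(reference_system, reference_frame))
}
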