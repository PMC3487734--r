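# Ideal-peptide construction by sequential internal-coordinate placement:
# every backbone atom is positioned from a bond length, a bond angle and a
# torsion relative to its three predecessors (the NeRF construction).

# Standard backbone geometry (Angstrom / degrees).
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  omega = 180.0)

# Approximate CA -> side-chain-centroid distances per residue type (A).
.sc_centroid_dist <- c(
  ALA = 1.53, ARG = 4.10, ASN = 2.50, ASP = 2.50, CYS = 2.10, GLN = 3.10,
  GLU = 3.10, GLY = 0.00, HIS = 3.10, ILE = 2.30, LEU = 2.60, LYS = 3.50,
  MET = 3.00, PHE = 3.40, PRO = 1.90, SER = 1.90, THR = 1.90, TRP = 3.90,
  TYR = 3.80, VAL = 1.90)

#' Wild-type IAPP 1-25 sequence
#'
#' `KCNTATCATQRLANFLVHSSNNFGA`; the S20G variant substitutes glycine at
#' position 20.
#' @param s20g apply the S20G substitution.
#' @return 1-letter sequence string.
#' @export
iapp_sequence <- function(s20g = FALSE) {
  seq <- "KCNTATCATQRLANFLVHSSNNFGA"
  if (s20g) {
    v <- strsplit(seq, "")[[1L]]
    stopifnot(v[20L] == "S")
    v[20L] <- "G"
    seq <- paste(v, collapse = "")
  }
  seq
}

# Place atom D given A, B, C and internal coordinates (NeRF).
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- deg2rad(angle_deg); ph <- deg2rad(torsion_deg)
  bc <- unit_vec(C - B)
  n <- unit_vec(cross3(B - A, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  C + as.numeric(m %*% d2)
}

#' Build an ideal helical peptide
#'
#' Backbone (N, CA, C, O) built residue-by-residue from standard bond
#' lengths and angles with per-residue (phi, psi) torsions and omega = 180.
#' Residues inside `span` get the helical torsions; residues before it get
#' coil torsions emulating the disordered N-terminal disulfide-loop region.
#' Side chains are single pseudo-centroid beads (`SCB`) at a canonical
#' CA-centroid distance per residue type (glycine has none). The finished
#' helix is centred at the origin with its principal axis along +x.
#'
#' @param sequence 1-letter sequence (default the IAPP 1-25 wild type).
#' @param s20g apply the S20G substitution to the default sequence.
#' @param phi,psi helical backbone torsions in degrees (defaults -57, -47).
#' @param span helical span as author residue numbers (default `c(5, 25)`,
#'   clipped to the sequence).
#' @param coil_phi,coil_psi torsions used outside the span (-80, 80).
#' @param chain chain id.
#' @return an `mh_system` with one frame and no box.
#' @export
build_ideal_helix <- function(sequence = iapp_sequence(), s20g = FALSE,
                              phi = -57, psi = -47, span = c(5L, 25L),
                              coil_phi = -80, coil_psi = 80, chain = "A") {
  if (s20g && sequence == iapp_sequence()) sequence <- iapp_sequence(TRUE)
  codes <- strsplit(sequence, "")[[1L]]
  if (length(codes) < 4L) stop("sequence must have >= 4 residues",
                               call. = FALSE)
  resn <- .aa_one_to_three[codes]
  if (anyNA(resn)) stop("unknown residue code: ",
                        paste(codes[is.na(resn)], collapse = ""),
                        call. = FALSE)
  nres <- length(resn)
  span <- c(max(1L, span[1L]), min(nres, span[2L]))
  g <- .bb_geom
  in_span <- function(i) i >= span[1L] && i <= span[2L]
  phis <- ifelse(vapply(seq_len(nres), in_span, logical(1)), phi, coil_phi)
  psis <- ifelse(vapply(seq_len(nres), in_span, logical(1)), psi, coil_psi)
  N <- CA <- C <- O <- matrix(NA_real_, nres, 3L)
  # first residue: N at origin, CA on +x, C in the xy plane
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  th <- deg2rad(180 - g$a_n_ca_c)
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in 2:nres) {
    N[i, ]  <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                          g$b_c_n, g$a_ca_c_n, psis[i - 1L])
    CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i, ]  <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                          g$b_ca_c, g$a_n_ca_c, phis[i])
  }
  for (i in seq_len(nres)) {
    # carbonyl O trans to the next amide N
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psis[i] + 180)
  }
  atoms <- list(); coords <- list()
  for (i in seq_len(nres)) {
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (resn[i] != "GLY") {
      dirv <- cbeta_direction(N[i, ], CA[i, ], C[i, ])
      xyz <- rbind(xyz, CA[i, ] + dirv * .sc_centroid_dist[[resn[i]]])
      nm <- c(nm, "SCB")
    }
    atoms[[i]] <- data.frame(
      name = nm, element = c("N", "C", "C", "O", "C")[seq_along(nm)],
      resid = i, resname = unname(resn[i]), resseq = i, chain = chain,
      charge = NA_real_, stringsAsFactors = FALSE)
    coords[[i]] <- xyz
  }
  sys <- new_system(do.call(rbind, atoms),
                    list(new_frame(do.call(rbind, coords))))
  align_helix_x(sys, span)
}

# Unit direction from CA toward the side-chain centroid (virtual C-beta
# direction from the backbone frame).
cbeta_direction <- function(N, CA, C) {
  b <- CA - N; c_ <- C - CA
  a <- cross3(b, c_)
  unit_vec(-0.58273431 * a + 0.56802827 * b - 0.54067466 * c_)
}

# Rotate/translate so the CA principal axis of the span runs along +x
# (N- to C-terminal) and the span CA centroid sits at the origin.
align_helix_x <- function(system, span) {
  fr <- get_frame(system, 1L)
  ca <- vapply(span[1L]:span[2L], function(rs)
    atom_in_residue(system, resid_of_resseq(system, rs), "CA"), integer(1))
  ax <- fit_helix_axis(fr, as_selection(ca))
  v <- ax$axis
  target <- c(1, 0, 0)
  cosang <- sum(v * target)
  if (cosang < 1 - 1e-12) {
    rotax <- cross3(v, target)
    if (vec_norm(rotax) < 1e-9) rotax <- c(0, 0, 1)  # antiparallel
    ang <- rad2deg(acos(pmin(1, pmax(-1, cosang))))
    fr$xyz <- rotate_about(fr$xyz, rotax, ang, origin = ax$centroid)
  }
  ctr <- colMeans(fr$xyz[ca, , drop = FALSE])
  fr$xyz <- sweep(fr$xyz, 2L, ctr)
  system$frames[[1L]] <- fr
  system
}

#' Build a kinked-helix ensemble
#'
#' Rigidly rotates everything C-terminal of the hinge CA about an axis
#' through the hinge CA so that the standard kink-angle vectors (CA 13->17
#' vs CA 19->23 by default) subtend the target angle, then adds i.i.d.
#' Gaussian coordinate noise per frame under the given seed. The rotation
#' axis is the normal of the plane spanned by the two kink vectors, which
#' moves the post-hinge vector within that plane and therefore controls the
#' subtended angle exactly; note that an unkinked ideal helix already
#' subtends about 24 degrees (the i to i+4 CA chords are each ~15 degrees
#' off the helix axis, 240 degrees apart in phase), so this axis choice is
#' what makes small target angles constructible at all. The achieved angle
#' is verified to 0.1 degree. Identical spec + seed gives bit-identical
#' ensembles. `target_angle = NULL` (or 0) leaves the helix unbent and only
#' applies noise.
#'
#' @param helix single-frame `mh_system` from [build_ideal_helix()].
#' @param target_angle target interhelical angle in degrees.
#' @param hinge hinge residue (author numbering, default 18).
#' @param sigma Gaussian coordinate noise in Angstrom (default 0).
#' @param n_frames number of frames (default 1).
#' @param seed RNG seed for the noise (required when `sigma > 0`).
#' @param vec_a,vec_b kink-angle vector definitions (see
#'   [interhelical_angle()]).
#' @return an `mh_system` with `n_frames` frames; the achieved noise-free
#'   angle is stored in the `"built_angle"` attribute.
#' @export
build_kinked_ensemble <- function(helix, target_angle, hinge = 18L,
                                  sigma = 0, n_frames = 1L, seed = NULL,
                                  vec_a = c(13L, 17L), vec_b = c(19L, 23L)) {
  stopifnot(sigma >= 0, n_frames >= 1L)
  if (sigma > 0 && is.null(seed))
    stop("a seed is required for a noisy ensemble", call. = FALSE)
  fr <- get_frame(helix, 1L)
  at <- helix$atoms
  rt <- residue_table(helix)
  span_lo <- min(rt$resseq)
  if (!(hinge > span_lo && hinge < max(rt$resseq)))
    stop("hinge must lie strictly inside the chain", call. = FALSE)
  hinge_rid <- resid_of_resseq(helix, hinge)
  ca_h <- atom_in_residue(helix, hinge_rid, "CA")
  pivot <- fr$xyz[ca_h, ]
  ca_of <- function(rs) atom_in_residue(helix, resid_of_resseq(helix, rs),
                                        "CA")
  va <- fr$xyz[ca_of(vec_a[2L]), ] - fr$xyz[ca_of(vec_a[1L]), ]
  vb <- fr$xyz[ca_of(vec_b[2L]), ] - fr$xyz[ca_of(vec_b[1L]), ]
  rot_axis <- cross3(vb, va)
  if (vec_norm(rot_axis) < 1e-6) rot_axis <- c(0, 1, 0)
  rot_axis <- unit_vec(rot_axis)
  moving <- which(at$resid > hinge_rid |
                    (at$resid == hinge_rid & at$name %in% c("C", "O")))
  angle_at <- function(alpha) {
    xyz <- fr$xyz
    xyz[moving, ] <- rotate_about(xyz[moving, , drop = FALSE], rot_axis,
                                  alpha, origin = pivot)
    tmp <- set_frames(helix, list(new_frame(xyz)))
    as.numeric(interhelical_angle(tmp, vec_a, vec_b))
  }
  base <- angle_at(0)
  if (is.null(target_angle) || target_angle == 0) {
    alpha <- 0   # unkinked reference: identity rotation
  } else {
    if (target_angle < 0.2 || target_angle > 179.5)
      stop("target angle ", target_angle, " unreachable", call. = FALSE)
    # rotation about +rot_axis closes the angle toward vec_a by alpha
    alpha <- base - target_angle
    if (abs(angle_at(alpha) - target_angle) > 0.1) {
      alpha <- target_angle - base   # opposite sense
      if (abs(angle_at(alpha) - target_angle) > 0.1)
        stop("failed to reach target angle ", target_angle, call. = FALSE)
    }
  }
  xyz0 <- fr$xyz
  xyz0[moving, ] <- rotate_about(xyz0[moving, , drop = FALSE], rot_axis,
                                 alpha, origin = pivot)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      noise <- if (sigma > 0)
        matrix(stats::rnorm(length(xyz0), sd = sigma), ncol = 3L) else 0
      new_frame(xyz0 + noise)
    })
  })
  out <- set_frames(helix, frames)
  attr(out, "built_angle") <- angle_at(alpha)
  out
}
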