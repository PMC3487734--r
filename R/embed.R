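#' Embedding specification
#'
#' Defaults reproduce the EPR-derived initial placement of the IAPP 1-25
#' helix: the helix lies parallel to the membrane surface in the upper
#' leaflet with its centre 7 A below the mean phosphate plane, with Thr9,
#' Leu12, Leu16 and Ser20 facing the bilayer core and Gln10, Asn14 and
#' His18 facing the solvent.
#'
#' @param depth helix-centre depth below the phosphate plane (A).
#' @param buried,exposed author residue numbers of the membrane-facing and
#'   solvent-facing side chains (disjoint).
#' @param leaflet `"upper"` or `"lower"`.
#' @param span helical span whose CA centre defines the helix centre.
#' @param clash_cutoff lipids with any bead closer than this to any peptide
#'   atom are deleted (A).
#' @return spec list for [embed_peptide()].
#' @export
embed_spec <- function(depth = 7, buried = c(9L, 12L, 16L, 20L),
                       exposed = c(10L, 14L, 18L),
                       leaflet = c("upper", "lower"), span = c(5L, 25L),
                       clash_cutoff = 1.5) {
  leaflet <- match.arg(leaflet)
  if (length(intersect(buried, exposed)) > 0L)
    stop("buried and exposed residue sets must be disjoint", call. = FALSE)
  list(depth = depth, buried = buried, exposed = exposed, leaflet = leaflet,
       span = span, clash_cutoff = clash_cutoff)
}

# Representative side-chain point of a residue: centroid of side-chain
# heavy atoms, or CA when there are none (Gly).
sidechain_point <- function(system, frame, resseq) {
  rid <- resid_of_resseq(system, resseq)
  idx <- which(system$atoms$resid == rid &
                 sidechain_heavy_mask(system$atoms))
  if (length(idx) == 0L) idx <- atom_in_residue(system, rid, "CA")
  colMeans(frame$xyz[idx, , drop = FALSE])
}

#' Embed a peptide into a slab bilayer
#'
#' Rotates the peptide so its helix axis lies in the xy plane (along x),
#' rolls it about that axis so the buried side-chain centroids point toward
#' the bilayer core and the exposed ones toward the solvent, translates the
#' helical-span CA centre to the requested depth below the leaflet's mean
#' phosphorus plane at the box centre, and deletes clashing lipids.
#'
#' @param bilayer a bilayer `mh_system` ([build_slab_bilayer()]).
#' @param peptide a single-frame peptide `mh_system`.
#' @param spec an [embed_spec()].
#' @return combined `mh_system`; the number of deleted lipids is stored in
#'   the `"removed_lipids"` attribute.
#' @export
embed_peptide <- function(bilayer, peptide, spec = embed_spec()) {
  bfr <- get_frame(bilayer, 1L)
  pfr <- get_frame(peptide, 1L)
  span <- c(max(spec$span[1L], min(peptide$atoms$resseq)),
            min(spec$span[2L], max(peptide$atoms$resseq)))
  ca <- vapply(span[1L]:span[2L], function(rs)
    atom_in_residue(peptide, resid_of_resseq(peptide, rs), "CA"), integer(1))
  # helix axis -> +x
  ax <- fit_helix_axis(pfr, as_selection(ca))
  cosang <- sum(ax$axis * c(1, 0, 0))
  if (cosang < 1 - 1e-12) {
    rotax <- cross3(ax$axis, c(1, 0, 0))
    if (vec_norm(rotax) < 1e-9) rotax <- c(0, 0, 1)
    pfr$xyz <- rotate_about(pfr$xyz, rotax,
                            rad2deg(acos(pmin(1, pmax(-1, cosang)))),
                            origin = ax$centroid)
  }
  # roll about x so buried centroids sit below exposed ones (upper leaflet;
  # mirrored for the lower leaflet)
  tmp_sys <- set_frames(peptide, list(pfr))
  down_sign <- if (spec$leaflet == "upper") -1 else 1
  roll_score <- function(deg) {
    xyz <- rotate_about(pfr$xyz, c(1, 0, 0), deg, origin = ax$centroid)
    ts <- set_frames(peptide, list(new_frame(xyz)))
    f <- get_frame(ts, 1L)
    zb <- mean(vapply(spec$buried, function(r) sidechain_point(ts, f, r)[3L],
                      numeric(1)))
    ze <- mean(vapply(spec$exposed, function(r) sidechain_point(ts, f, r)[3L],
                      numeric(1)))
    down_sign * (zb - ze)   # want buried toward the core
  }
  grid <- seq(0, 359, by = 3)
  best <- grid[which.max(vapply(grid, roll_score, numeric(1)))]
  if (roll_score(best) <= 0)
    stop("cannot orient buried residues (",
         paste(spec$buried, collapse = ","), ") toward the core against ",
         "exposed residues (", paste(spec$exposed, collapse = ","), ")",
         call. = FALSE)
  pfr$xyz <- rotate_about(pfr$xyz, c(1, 0, 0), best, origin = ax$centroid)
  # translate helix centre to depth below the leaflet phosphate plane
  p_idx <- which(bilayer$atoms$name == "P" &
                   bilayer$atoms$resname %in% lipid_resnames())
  la <- assign_leaflets(bilayer, as_selection(p_idx), frame = 1L)
  leaf_p <- la$p_index[la$leaflet == spec$leaflet]
  z_plane <- mean(bfr$xyz[leaf_p, 3L])
  target <- c(bfr$box[1L] / 2, bfr$box[2L] / 2,
              z_plane + down_sign * spec$depth)
  ctr <- colMeans(pfr$xyz[ca, , drop = FALSE])
  pfr$xyz <- sweep(pfr$xyz, 2L, target - ctr, "+")
  # delete clashing lipids
  lip_res <- unique(bilayer$atoms$resid[bilayer$atoms$resname %in%
                                          lipid_resnames()])
  d <- pair_distances(bfr$xyz, pfr$xyz, bfr$box)
  close_atom <- apply(d < spec$clash_cutoff, 1L, any)
  bad <- unique(bilayer$atoms$resid[close_atom])
  bad <- intersect(bad, lip_res)
  keep <- !(bilayer$atoms$resid %in% bad)
  atoms_b <- bilayer$atoms[keep, , drop = FALSE]
  xyz_b <- bfr$xyz[keep, , drop = FALSE]
  # renumber peptide residues after the bilayer block, keep author numbering
  pep_at <- peptide$atoms
  off <- max(atoms_b$resid)
  pep_at$resid <- pep_at$resid + off
  sys <- new_system(rbind(atoms_b, pep_at),
                    list(new_frame(rbind(xyz_b, pfr$xyz), box = bfr$box)))
  attr(sys, "removed_lipids") <- length(bad)
  sys
}
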