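# Geometric hydrogen-bond criterion: donor-acceptor distance below 3.5 A and
# the acceptor-donor-hydrogen angle (vertex at the donor, i.e. the H-D-A
# angle) below 30 degrees. Note that some codes place the vertex at the
# hydrogen instead; the vertex-at-donor convention is used throughout here.
# Both thresholds are strict ("<"). Distances use the minimum image.

#' Hydrogen-bond criterion
#'
#' @param distance_cutoff donor-acceptor distance cutoff in Angstrom
#'   (default 3.5).
#' @param angle_cutoff H-D-A angle cutoff at the donor in degrees
#'   (default 30).
#' @return a criterion object for [detect_hbonds()].
#' @export
hbond_criterion <- function(distance_cutoff = 3.5, angle_cutoff = 30) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0)
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff), class = "mh_hbond_criterion")
}

#' Donor/acceptor chemistry table
#'
#' The packaged table lists, per residue type, which N/O (and thiol S) atoms
#' donate or accept, and the names of the attached hydrogens. It is plain
#' TSV under `inst/extdata/` and can be replaced via `path`.
#'
#' @param path optional path to an alternative table.
#' @return data.frame with columns `resname`, `atom`, `role`, `hydrogens`.
#' @export
hbond_chemistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hbond_chemistry.tsv", package = "memhelix")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = NULL)
}

# Resolve donor triples (donor, hydrogen) and acceptor indices for a subset
# of atoms. Missing backbone amide hydrogens are reconstructed ("auto").
# Returns list(donors = data.frame(d, h_idx | NA, h_xyz rows), acceptors).
resolve_da <- function(system, atom_idx, chem = hbond_chemistry(),
                       frame_i = 1L) {
  at <- system$atoms
  atom_idx <- as.integer(atom_idx)
  donors <- list(); acceptors <- integer(0)
  co <- system$frames[[frame_i]]$xyz
  for (k in atom_idx) {
    rn <- at$resname[k]
    if (!rn %in% c(names(.aa_three_to_one))) next
    rows <- chem[(chem$resname == "*" | chem$resname == rn) &
                   chem$atom == at$name[k], , drop = FALSE]
    if (nrow(rows) == 0L) next
    for (r in seq_len(nrow(rows))) {
      role <- rows$role[r]
      if (role %in% c("acceptor", "both")) acceptors <- c(acceptors, k)
      if (role %in% c("donor", "both")) {
        hn <- strsplit(rows$hydrogens[r], ",")[[1L]]
        hn <- hn[hn != ""]
        res_atoms <- which(at$resid == at$resid[k])
        h_here <- res_atoms[at$name[res_atoms] %in% setdiff(hn, "auto")]
        if (length(h_here) > 0L) {
          for (h in h_here)
            donors[[length(donors) + 1L]] <- list(d = k, h = h, h_xyz = NULL)
        } else if ("auto" %in% hn) {
          # reconstruct the backbone amide H
          rt_i <- at$resid[k]
          prev_c <- which(at$resid == rt_i - 1L & at$name == "C")
          ca <- atom_in_residue(system, rt_i, "CA")
          if (length(prev_c) == 1L && !is.na(ca)) {
            hx <- amide_h_position(co[k, ], co[prev_c, ], co[ca, ])
            donors[[length(donors) + 1L]] <- list(d = k, h = NA_integer_,
                                                  h_xyz = hx)
          }
        } else {
          warning("donor ", rn, " ", at$name[k], " (residue ",
                  at$resseq[k], ") has no attached hydrogen; skipped",
                  call. = FALSE)
        }
      }
    }
  }
  list(donors = donors, acceptors = unique(acceptors))
}

#' Detect hydrogen bonds in one frame
#'
#' @param frame an `mh_frame`.
#' @param donors list of donor entries `list(d = donor index, h = hydrogen
#'   index or NA, h_xyz = explicit hydrogen coordinates when `h` is NA)`.
#' @param acceptors integer vector of acceptor atom indices.
#' @param criterion an [hbond_criterion()].
#' @return data.frame with one row per bonded (donor, hydrogen, acceptor)
#'   triple: columns `donor`, `hydrogen` (NA for reconstructed H),
#'   `acceptor`, `distance`, `angle`.
#' @export
detect_hbonds <- function(frame, donors, acceptors,
                          criterion = hbond_criterion()) {
  out <- list()
  box <- frame$box
  for (dn in donors) {
    dx <- frame$xyz[dn$d, ]
    hx <- if (is.na(dn$h)) dn$h_xyz else frame$xyz[dn$h, ]
    dh <- hx - dx  # intramolecular: no wrapping needed for the bond vector
    for (a in acceptors) {
      if (a == dn$d || identical(a, dn$h)) next
      da <- frame$xyz[a, ] - dx
      if (!is.null(box)) da <- as.numeric(wrap_disp(matrix(da, 1L), box))
      r <- sqrt(sum(da * da))
      if (r >= criterion$distance_cutoff) next
      ang <- vec_angle(dh, da)
      if (ang >= criterion$angle_cutoff) next
      out[[length(out) + 1L]] <- data.frame(
        donor = dn$d, hydrogen = if (is.na(dn$h)) NA_integer_ else dn$h,
        acceptor = a, distance = r, angle = ang)
    }
  }
  if (length(out) == 0L)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  do.call(rbind, out)
}

# Atom indices for one side of an H-bond pair specification.
resolve_pair_group <- function(system, resseq, scope = c("mainchain",
                                                         "sidechain", "any")) {
  scope <- match.arg(scope)
  rid <- resid_of_resseq(system, resseq)
  idx <- which(system$atoms$resid == rid)
  nm <- system$atoms$name[idx]
  bb <- nm %in% c("N", "CA", "C", "O", "OXT", "H", "HN")
  switch(scope, mainchain = idx[bb], sidechain = idx[!bb], any = idx)
}

#' Hydrogen-bond occupancy between two groups
#'
#' Fraction of frames in which at least one hydrogen bond connects the two
#' groups (either direction), e.g. the Leu16 main chain against the Ser20
#' side chain. Also returns per-block fractions over `n_blocks` contiguous
#' blocks of the frame series.
#'
#' @param system an `mh_system`.
#' @param res_a,res_b author residue numbers of the two partners.
#' @param scope_a,scope_b `"mainchain"`, `"sidechain"` or `"any"`.
#' @param criterion an [hbond_criterion()].
#' @param n_blocks number of time blocks (default 100).
#' @param frames frame range (see [resolve_frames()]).
#' @param chem chemistry table ([hbond_chemistry()]).
#' @return list with `occupancy` (overall fraction), `blocks` (per-block
#'   fractions), `present` (per-frame logical) and the pair description.
#' @export
hbond_occupancy <- function(system, res_a, res_b,
                            scope_a = "mainchain", scope_b = "sidechain",
                            criterion = hbond_criterion(), n_blocks = 100L,
                            frames = NULL, chem = hbond_chemistry()) {
  ga <- resolve_pair_group(system, res_a, scope_a)
  gb <- resolve_pair_group(system, res_b, scope_b)
  da_a0 <- resolve_da(system, ga, chem)
  da_b0 <- resolve_da(system, gb, chem)
  if (length(da_a0$donors) * length(da_b0$acceptors) +
      length(da_b0$donors) * length(da_a0$acceptors) == 0L)
    stop("pair specification resolves to no donor-hydrogen-acceptor triples: ",
         res_a, "/", scope_a, " vs ", res_b, "/", scope_b, call. = FALSE)
  fr_idx <- resolve_frames(n_frames(system), frames)
  present <- logical(length(fr_idx))
  for (t in seq_along(fr_idx)) {
    fi <- fr_idx[t]
    fr <- system$frames[[fi]]
    da_a <- resolve_da(system, ga, chem, frame_i = fi)
    da_b <- resolve_da(system, gb, chem, frame_i = fi)
    hb1 <- detect_hbonds(fr, da_a$donors, da_b$acceptors, criterion)
    hit <- nrow(hb1) > 0L
    if (!hit) {
      hb2 <- detect_hbonds(fr, da_b$donors, da_a$acceptors, criterion)
      hit <- nrow(hb2) > 0L
    }
    present[t] <- hit
  }
  list(occupancy = mean(present),
       blocks = block_average(as.numeric(present), n_blocks),
       present = present,
       pair = sprintf("%d(%s)-%d(%s)", res_a, scope_a, res_b, scope_b))
}
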