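# Simplified Kabsch-Sander secondary structure. Backbone H-bond energy
#   E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)   [kcal/mol, r in A]
# (27.888 = 0.42 * 0.20 * 332), a bond exists when E < -0.5 kcal/mol.
# n-turns (n = 3, 4, 5) at residue i when the NH of residue i+n bonds the CO
# of residue i; two consecutive n-turns make a minimal helix (G/H/I).

# Reconstruct the amide hydrogen for united-atom inputs: H sits 1.0 A from N
# along the direction opposing the bisector of (C'(i-1)->N) and (CA->N).
amide_h_position <- function(n_xyz, c_prev_xyz, ca_xyz) {
  d1 <- unit_vec(n_xyz - c_prev_xyz)
  d2 <- unit_vec(n_xyz - ca_xyz)
  n_xyz + unit_vec(d1 + d2) * 1.0
}

# Backbone geometry per frame: matrices of N, CA, C, O, H coordinates
# (NA rows where atoms are missing; H reconstructed when absent).
backbone_geometry <- function(system, frame_i) {
  rt <- residue_table(system)
  rt <- rt[rt$resname %in% names(.aa_three_to_one), , drop = FALSE]
  nr <- nrow(rt)
  co <- system$frames[[frame_i]]$xyz
  g <- function(name) {
    m <- matrix(NA_real_, nr, 3L)
    for (i in seq_len(nr)) {
      a <- atom_in_residue(system, rt$resid[i], name)
      if (!is.na(a)) m[i, ] <- co[a, ]
    }
    m
  }
  N <- g("N"); CA <- g("CA"); C <- g("C"); O <- g("O")
  H <- matrix(NA_real_, nr, 3L)
  for (i in seq_len(nr)) {
    a <- atom_in_residue(system, rt$resid[i], c("H", "HN"))
    if (!is.na(a)) {
      H[i, ] <- co[a, ]
    } else if (i > 1L && rt$chain[i] == rt$chain[i - 1L] &&
               !anyNA(c(N[i, ], C[i - 1L, ], CA[i, ]))) {
      H[i, ] <- amide_h_position(N[i, ], C[i - 1L, ], CA[i, ])
    }
  }
  list(rt = rt, N = N, CA = CA, C = C, O = O, H = H)
}

ks_energy <- function(N_i, H_i, C_j, O_j) {
  r_on <- vec_norm(O_j - N_i)
  r_ch <- vec_norm(C_j - H_i)
  r_oh <- vec_norm(O_j - H_i)
  r_cn <- vec_norm(C_j - N_i)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(-9.9)  # clash guard as in DSSP
  27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Logical matrix HB[i, j]: NH of residue i donates to CO of residue j.
ks_hbond_matrix <- function(geom, e_cut = -0.5) {
  nr <- nrow(geom$N)
  HB <- matrix(FALSE, nr, nr)
  for (i in seq_len(nr)) {
    if (geom$rt$resname[i] == "PRO") next  # proline has no amide H
    if (anyNA(geom$N[i, ]) || anyNA(geom$H[i, ])) next
    for (j in seq_len(nr)) {
      if (abs(i - j) < 2L) next
      if (geom$rt$chain[i] != geom$rt$chain[j]) next
      if (anyNA(geom$C[j, ]) || anyNA(geom$O[j, ])) next
      HB[i, j] <- ks_energy(geom$N[i, ], geom$H[i, ],
                            geom$C[j, ], geom$O[j, ]) < e_cut
    }
  }
  HB
}

# One frame -> per-residue codes in {H, G, I, E, T, C}.
ks_assign_codes <- function(HB) {
  nr <- nrow(HB)
  turn <- function(n) {
    t <- rep(FALSE, nr)
    for (i in seq_len(nr - n)) t[i] <- HB[i + n, i]
    t
  }
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)
  code <- rep("C", nr)
  mark <- function(code, tn, n, sym) {
    for (i in 2:max(2L, nr)) {
      if (i > nr - n) break
      if (tn[i - 1L] && tn[i]) {
        rng <- i:min(nr, i + n - 1L)
        free <- code[rng] == "C" | code[rng] == "T" | code[rng] == sym
        code[rng[free]] <- sym
      }
    }
    code
  }
  # turns first (lowest priority), then helices in DSSP priority H > G > I:
  # a later class never overwrites an earlier one
  for (n in c(3L, 4L, 5L)) {
    tn <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(n)]]
    for (i in which(tn)) {
      rng <- (i + 1L):(i + n - 1L)
      rng <- rng[rng >= 1L & rng <= nr]
      code[rng][code[rng] == "C"] <- "T"
    }
  }
  code <- mark(code, t4, 4L, "H")
  code <- mark(code, t3, 3L, "G")
  code <- mark(code, t5, 5L, "I")
  # simple ladder detection for extended strands
  bridge <- matrix(FALSE, nr, nr)
  for (i in 2:max(2L, nr - 1L)) {
    if (i + 1L > nr) break
    for (j in seq_len(nr)) {
      if (abs(i - j) < 3L || j < 2L || j + 1L > nr) next
      para <- (HB[i, j - 1L] && HB[j + 1L, i]) ||
              (HB[j, i - 1L] && HB[i + 1L, j])
      anti <- (HB[i, j] && HB[j, i]) ||
              (HB[i + 1L, j - 1L] && HB[j + 1L, i - 1L])
      if (para || anti) bridge[i, j] <- TRUE
    }
  }
  strands <- which(apply(bridge, 1L, any))
  code[strands[code[strands] %in% c("C", "T")]] <- "E"
  # chain termini are never helical
  if (nr >= 1L) {
    if (code[1L] %in% c("H", "G", "I")) code[1L] <- "C"
    if (code[nr] %in% c("H", "G", "I")) code[nr] <- "C"
  }
  code
}

#' Assign secondary structure (simplified Kabsch-Sander)
#'
#' Hydrogen-bond energies use the classic electrostatic model with the
#' 27.888 kcal/mol prefactor and a -0.5 kcal/mol threshold; amide hydrogens
#' are reconstructed geometrically when the input has none (united-atom
#' sources). Codes: `H` (alpha), `G` (3-10), `I` (pi) via the two-
#' consecutive-turns minimal-helix rule, `E` (ladder), `T` (turn), else `C`.
#' Bends (`S`) are not assigned.
#'
#' @param system an `mh_system` with backbone N, CA, C, O atoms.
#' @return an object of class `mh_ss`: character matrix (n_residue x
#'   n_frame, rownames = author residue numbers).
#' @export
assign_secondary_structure <- function(system) {
  nf <- n_frames(system)
  rt <- residue_table(system)
  rt <- rt[rt$resname %in% names(.aa_three_to_one), , drop = FALSE]
  nr <- nrow(rt)
  if (nf == 0L || nr == 0L) {
    m <- matrix(character(0), nrow = nr, ncol = 0L)
    rownames(m) <- rt$resseq
    return(structure(m, resseq = rt$resseq, class = "mh_ss"))
  }
  m <- matrix("C", nr, nf)
  for (f in seq_len(nf)) {
    geom <- backbone_geometry(system, f)
    m[, f] <- ks_assign_codes(ks_hbond_matrix(geom))
  }
  rownames(m) <- rt$resseq
  structure(m, resseq = rt$resseq, class = "mh_ss")
}

#' Per-residue helicity
#'
#' Fraction of frames in which a residue carries a helical code. The default
#' helical set {H, G, I} counts alpha-, 3-10- and pi-helix.
#'
#' @param ss an `mh_ss` matrix from [assign_secondary_structure()], or a list
#'   of them (one per replicate trajectory).
#' @param frames frame indices to use (default all; see [resolve_frames()]).
#' @param helical_codes codes counted as helical.
#' @return data.frame with `resseq`, `helicity` (and, for replicate input,
#'   `sd` across replicas and `n_replicas`).
#' @export
helicity <- function(ss, frames = NULL, helical_codes = c("H", "G", "I")) {
  if (is.list(ss) && !inherits(ss, "mh_ss")) {
    per <- lapply(ss, function(s) helicity(s, frames, helical_codes)$helicity)
    M <- do.call(cbind, per)
    return(data.frame(resseq = as.integer(rownames(ss[[1L]])),
                      helicity = rowMeans(M),
                      sd = apply(M, 1L, stats::sd),
                      n_replicas = length(ss)))
  }
  fr <- resolve_frames(ncol(ss), frames)
  if (length(fr) == 0L) stop("empty frame range", call. = FALSE)
  sub <- ss[, fr, drop = FALSE]
  data.frame(resseq = as.integer(rownames(ss)),
             helicity = rowMeans(matrix(sub %in% helical_codes,
                                        nrow = nrow(sub))),
             n_frames = length(fr))
}

#' Resolve a frame-range specification
#'
#' @param n total number of frames.
#' @param frames `NULL`/"all" (all frames), `"last-half"` (the later half,
#'   e.g. frames 51..100 of 100), a length-2 range `c(first, last)`, or an
#'   explicit index vector.
#' @return integer frame indices.
#' @export
resolve_frames <- function(n, frames = NULL) {
  if (is.null(frames)) return(seq_len(n))
  if (is.character(frames)) {
    return(switch(frames,
      "all" = seq_len(n),
      "last-half" = (floor(n / 2) + 1L):n,
      stop("unknown frame range '", frames, "'", call. = FALSE)))
  }
  frames <- as.integer(frames)
  if (length(frames) == 2L && frames[2L] >= frames[1L] &&
      !any(duplicated(frames)))
    frames <- frames[1L]:frames[2L]
  if (any(frames < 1L | frames > n))
    stop("frame indices out of range 1..", n, call. = FALSE)
  frames
}
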